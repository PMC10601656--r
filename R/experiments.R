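#' Smoke-scale optimization defaults
#'
#' A reduced budget (popsize 8, 30 generations, 4 s horizon) that exercises
#' the full training loop quickly; the full-scale budget of the walking
#' protocols is popsize 16, 1000 generations over 10 s (20 s for the
#' self-selected protocol).
#'
#' @return named list of budget settings
#' @export
smoke_opt_config <- function() {
  list(popsize = 8, generations = 30, horizon = 4)
}

#' Self-selected-speed protocol
#'
#' Optimizes walking with the velocity cost removed from the reward (no
#' target speed) over a 20 s horizon from a cold start, then reports the
#' settled mean forward speed over the steady portion (the final half of the
#' episode) of the best solution.
#'
#' @param model `gait_model` or config
#' @param seed master seed
#' @param popsize,generations CMA-ES budget (defaults: full-scale)
#' @param horizon episode length, s
#' @param n_workers parallel evaluation slots
#' @param verbose print progress
#' @return list: `opt` (`cma_result`), `trace` (best episode),
#'   `summary` (`gait_cycles` or NULL), `self_selected_speed`, `walking`
#'   (logical: did the best episode survive and produce >= 2 cycles)
#' @export
run_self_selected <- function(model, seed = 1, popsize = 16,
                              generations = 1000, horizon = 20,
                              n_workers = 1, verbose = FALSE) {
  model <- as_gait_model(model)
  opt <- optimize_gait(model, v_tgt = NULL, horizon = horizon,
                       popsize = popsize, generations = generations,
                       seed = seed, n_workers = n_workers, verbose = verbose)
  tr <- run_episode(model, opt$controller, opt$init, horizon, v_tgt = NULL)
  summ <- NULL
  speed <- NA_real_
  walking <- FALSE
  # steady portion: final half of the horizon
  steady_from <- which(tr$time >= horizon / 2)
  if (!tr$terminated_early && length(steady_from) > 1) {
    i0 <- steady_from[1]
    iN <- length(tr$time)
    speed <- (tr$q[iN, 1] - tr$q[i0, 1]) / (tr$time[iN] - tr$time[i0])
    cyc <- segment_cycles(tr)
    if (nrow(cyc) >= 2) {
      summ <- ensemble_stats(tr,
                             body_weight = sum(model$config$segments$mass) *
                               model$config$gravity)
      walking <- TRUE
    }
  }
  list(opt = opt, trace = tr, summary = summ, self_selected_speed = speed,
       walking = walking, protocol = "self_selected", seed = seed)
}

#' Speed-sweep protocol with neighbor seeding
#'
#' Solves the anchor speed (1.45 m/s) from a cold start, then propagates
#' outward in both directions, warm-starting each speed from its already
#' solved neighbor (e.g. 1.45 -> 1.27 -> 1.10 and 1.45 -> 1.62 -> 1.80).
#'
#' @param model `gait_model` or config
#' @param speeds ordered target speeds, m/s; must include the anchor
#' @param anchor the speed solved first (cold start)
#' @param seed master seed
#' @param popsize,generations CMA-ES budget per speed
#' @param horizon episode length, s
#' @param n_workers parallel evaluation slots
#' @param verbose print progress
#' @return list of per-speed results (each with `opt`, `trace`, `summary`,
#'   `toe_off_pct`, `walking`, `seeded_from`) plus a `table` data.frame
#' @export
run_speed_sweep <- function(model, speeds = c(1.10, 1.27, 1.45, 1.62, 1.80),
                            anchor = 1.45, seed = 1, popsize = 16,
                            generations = 1000, horizon = 10, n_workers = 1,
                            verbose = FALSE) {
  model <- as_gait_model(model)
  if (!any(abs(speeds - anchor) < 1e-9))
    stop("the speed list must include the anchor speed ", anchor)
  speeds <- sort(speeds)
  ia <- which.min(abs(speeds - anchor))
  # anchor first, then outward: decreasing below, increasing above
  order_idx <- c(ia, rev(seq_len(ia - 1)), seq(ia + 1, length.out =
                                                 length(speeds) - ia))
  results <- vector("list", length(speeds))
  names(results) <- sprintf("%.2f", speeds)
  prev_of <- function(i) {
    # the already-solved neighbor: above the anchor the one below, and vice versa
    if (i == ia) return(NULL)
    if (i < ia) i + 1 else i - 1
  }
  for (i in order_idx) {
    v <- speeds[i]
    pi_ <- prev_of(i)
    x0 <- if (is.null(pi_)) NULL else seed_from(results[[pi_]]$opt)
    opt <- optimize_gait(model, v_tgt = v, horizon = horizon,
                         popsize = popsize, generations = generations,
                         seed = seed + i, x0 = x0, n_workers = n_workers,
                         verbose = verbose)
    tr <- run_episode(model, opt$controller, opt$init, horizon, v_tgt = v)
    cyc <- segment_cycles(tr)
    walking <- !tr$terminated_early && nrow(cyc) >= 2
    summ <- if (walking) {
      ensemble_stats(tr, cycles = cyc,
                     body_weight = sum(model$config$segments$mass) *
                       model$config$gravity)
    } else NULL
    results[[i]] <- list(
      v_tgt = v, opt = opt, trace = tr, summary = summ,
      toe_off_pct = if (walking) summ$toe_off_pct else NA_real_,
      mean_speed = if (walking) summ$mean_speed else NA_real_,
      walking = walking,
      seeded_from = if (is.null(pi_)) "cold" else sprintf("%.2f", speeds[pi_]))
    if (!walking && verbose)
      message("speed ", v, " m/s: no stable gait at this budget")
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(v_tgt = r$v_tgt, best_reward = r$opt$best_reward,
               walking = r$walking, mean_speed = r$mean_speed,
               toe_off_pct = r$toe_off_pct, seeded_from = r$seeded_from,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(results = results, table = tab, protocol = "speed_sweep", seed = seed)
}

#' Plantarflexor-weakness protocol
#'
#' Scales the named muscle's maximum isometric force bilaterally (one muscle
#' per run), warm-starts the controller from a previously solved 1.45 m/s
#' solution (no cold-start fallback) and re-optimizes at the same target
#' speed. Reports kinematic and SOL/GAS excitation summaries alongside the
#' unweakened baseline.
#'
#' @param model baseline `gait_model` or config (unweakened)
#' @param seed_solution a `cma_result` solved at 1.45 m/s (required)
#' @param muscle "SOL" or "GAS"
#' @param mif_scale 0.8 or 0.6 (or 1.0 for the baseline identity check)
#' @param seed master seed
#' @param popsize,generations CMA-ES budget
#' @param horizon episode length, s
#' @param v_tgt target speed (the protocol's 1.45 m/s)
#' @param n_workers parallel evaluation slots
#' @param verbose print progress
#' @return list with `opt`, `trace`, `summary`, the weakened `config`, and a
#'   `config_diff` manifest entry showing that only the one muscle's MIF
#'   changed
#' @export
run_weakness <- function(model, seed_solution, muscle = c("SOL", "GAS"),
                         mif_scale = 0.8, seed = 1, popsize = 16,
                         generations = 1000, horizon = 10, v_tgt = 1.45,
                         n_workers = 1, verbose = FALSE) {
  muscle <- match.arg(muscle)
  if (missing(seed_solution) || !inherits(seed_solution, "cma_result"))
    stop("the weakness protocol requires a previously solved seed solution ",
         "(a cma_result at the target speed); no cold-start fallback")
  if (!mif_scale %in% c(1.0, 0.8, 0.6))
    stop("mif_scale must be 1.0, 0.8 or 0.6")
  model <- as_gait_model(model)
  cfg0 <- model$config
  cfg <- scale_muscle_mif(cfg0, muscle, mif_scale)
  changed <- which(cfg$muscles$mif != cfg0$muscles$mif)
  weak_model <- build_model(cfg)
  opt <- optimize_gait(weak_model, v_tgt = v_tgt, horizon = horizon,
                       popsize = popsize, generations = generations,
                       seed = seed, x0 = seed_from(seed_solution),
                       n_workers = n_workers, verbose = verbose)
  tr <- run_episode(weak_model, opt$controller, opt$init, horizon,
                    v_tgt = v_tgt)
  cyc <- segment_cycles(tr)
  walking <- !tr$terminated_early && nrow(cyc) >= 2
  summ <- if (walking) {
    ensemble_stats(tr, cycles = cyc,
                   body_weight = sum(cfg$segments$mass) * cfg$gravity)
  } else NULL
  list(opt = opt, trace = tr, summary = summ, config = cfg,
       muscle = muscle, mif_scale = mif_scale, walking = walking,
       config_diff = list(
         field = "muscles$mif",
         rows = rownames(cfg$muscles)[changed],
         before = cfg0$muscles$mif[changed],
         after = cfg$muscles$mif[changed]),
       protocol = "weakness", seed = seed)
}
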