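#' Covariance matrix adaptation evolution strategy (maximization)
#'
#' Standard (mu/mu_w, lambda) CMA-ES with rank-mu and rank-one covariance
#' updates and cumulative step-size adaptation, following the conventional
#' tutorial parameterization. The objective is maximized. Candidates are
#' clamped onto the box before evaluation; the search distribution is updated
#' with the unclamped samples. Candidate evaluation may be parallelized; the
#' candidate stream and the results are identical for any worker count
#' because all sampling happens before evaluation and the objective is
#' required to be deterministic.
#'
#' @param objective function mapping a parameter vector to a finite scalar
#'   reward (larger is better); must be deterministic
#' @param x0 initial mean
#' @param sigma0 initial step size (same units as x0)
#' @param lower,upper box bounds (scalars or vectors)
#' @param popsize lambda, candidates per generation (>= 4)
#' @param generations number of generations (>= 1)
#' @param seed integer seed controlling the full candidate stream
#' @param n_workers parallel evaluation slots (forked; 1 = serial)
#' @param callback optional function(gen, best_reward, mean_reward, sigma)
#' @return object of class `cma_result`: `best_params`, `best_reward`,
#'   `reward_history` (per-generation best/mean and best-ever),
#'   `evaluations`, `eval_log` (per-evaluation reward and any info attribute),
#'   `seed_provenance`
#' @export
run_cmaes <- function(objective, x0, sigma0, lower = -Inf, upper = Inf,
                      popsize = 16, generations = 1000, seed = 1,
                      n_workers = 1, callback = NULL) {
  n <- length(x0)
  stopifnot(popsize >= 4, generations >= 1, sigma0 > 0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  lambda <- as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- as.numeric(x0)
  sigma <- sigma0
  C <- diag(n)
  pc <- ps <- numeric(n)

  best_reward <- -Inf
  best_x <- m
  hist_best <- hist_mean <- hist_ever <- numeric(generations)
  eval_log <- vector("list", generations)
  evals <- 0L

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  eval_all <- function(xs) {
    if (n_workers > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(xs, objective, mc.cores = n_workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(xs, objective)
    }
  }

  for (g in seq_len(generations)) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                      # N(0, C) samples
    X <- m + sigma * Y
    Xeval <- lapply(seq_len(lambda), function(k) {
      pmin(pmax(X[, k], lower), upper)
    })
    res <- eval_all(Xeval)
    f <- vapply(res, function(r) as.numeric(r)[1], numeric(1))
    if (any(!is.finite(f))) stop("objective returned a non-finite reward")
    evals <- evals + lambda
    ord <- order(f, decreasing = TRUE)
    if (f[ord[1]] > best_reward) {
      best_reward <- f[ord[1]]
      best_x <- Xeval[[ord[1]]]
    }
    hist_best[g] <- f[ord[1]]
    hist_mean[g] <- mean(f)
    hist_ever[g] <- best_reward
    eval_log[[g]] <- data.frame(
      generation = g, reward = f,
      survival = vapply(res, function(r) {
        s <- attr(r, "info")$survival
        if (is.null(s)) NA_real_ else s
      }, numeric(1)))

    sel <- ord[seq_len(mu)]
    y_w <- as.numeric(Y[, sel, drop = FALSE] %*% w)
    m <- m + sigma * y_w
    # step-size path (C^{-1/2} y_w)
    cinv_yw <- as.numeric(B %*% ((t(B) %*% y_w) / D))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) * cinv_yw
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * y_w
    rank_mu <- matrix(0, n, n)
    for (k in seq_len(mu)) {
      rank_mu <- rank_mu + w[k] * tcrossprod(Y[, sel[k]])
    }
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.null(callback)) callback(g, hist_best[g], hist_mean[g], sigma)
  }

  out <- list(best_params = best_x, best_reward = best_reward,
              reward_history = data.frame(generation = seq_len(generations),
                                          best = hist_best, mean = hist_mean,
                                          best_ever = hist_ever),
              evaluations = evals,
              eval_log = do.call(rbind, eval_log),
              seed_provenance = paste0("seed=", seed),
              final_mean = m, final_sigma = sigma)
  class(out) <- "cma_result"
  out
}

#' @export
print.cma_result <- function(x, ...) {
  cat("<cma_result>", x$evaluations, "evaluations,",
      nrow(x$reward_history), "generations\n")
  cat(sprintf("  best reward: %.6g (%s)\n", x$best_reward,
              x$seed_provenance))
  invisible(x)
}

#' Assemble / split the 49-dimensional optimization vector
#'
#' The search space is the 37 controller parameters followed by the 12
#' initial-state parameters, optimized in a normalized `[0, 1]^49` box mapped
#' affinely onto the physical bounds.
#'
#' @return `opt_bounds()` gives the physical bounds (49 rows);
#'   `decode_opt_vector(u)` maps a unit-box vector to a list with
#'   `controller` (named 37-vector) and `init` (an [initial_state()]);
#'   `encode_opt_vector(controller, init)` is its inverse.
#' @export
opt_bounds <- function() {
  cb <- controller_param_bounds()
  ib <- initial_state_bounds()
  rbind(cb, ib)
}

#' @rdname opt_bounds
#' @param u unit-box 49-vector
#' @export
decode_opt_vector <- function(u) {
  stopifnot(length(u) == 49)
  u <- pmin(pmax(as.numeric(u), 0), 1)
  b <- opt_bounds()
  x <- b$lo + u * (b$hi - b$lo)
  ctrl <- setNames(x[1:37], controller_param_names())
  init <- setNames(x[38:49], init_names())
  class(init) <- "initial_state"
  list(controller = ctrl, init = init)
}

#' @rdname opt_bounds
#' @param controller named or plain 37-vector
#' @param init an [initial_state()] or plain 12-vector
#' @export
encode_opt_vector <- function(controller, init) {
  if (!is.null(names(controller))) controller <- pack_params(controller)
  b <- opt_bounds()
  x <- c(as.numeric(controller), as.numeric(init))
  stopifnot(length(x) == 49)
  (x - b$lo) / (b$hi - b$lo)
}

#' Evaluate one candidate of the walking MDP
#'
#' Decodes the unit-box 49-vector, runs one episode with [run_episode()] and
#' returns its total reward. Deterministic given the candidate and
#' configuration. A diverged simulation returns the large negative sentinel
#' reward -1e6 so the optimization continues.
#'
#' @param u unit-box 49-vector (clamped onto `[0,1]` first)
#' @param model `gait_model` (pre-built, reused across evaluations)
#' @param horizon episode length, s
#' @param v_tgt target speed or NULL
#' @param weights [reward_weights()]
#' @return scalar reward with an `info` attribute (survival time, footsteps)
#' @export
evaluate_candidate <- function(u, model, horizon = 10, v_tgt = 1.45,
                               weights = reward_weights()) {
  dec <- decode_opt_vector(u)
  tr <- tryCatch(
    run_episode(model, dec$controller, dec$init, horizon, v_tgt, weights),
    error = function(e) NULL)
  if (is.null(tr) || isTRUE(tr$diverged)) {
    r <- -1e6
    attr(r, "info") <- list(survival = 0, n_footsteps = 0, diverged = TRUE)
    return(r)
  }
  rw <- episode_reward(tr, weights, v_tgt = v_tgt,
                       drop_vel = is.null(v_tgt))
  r <- rw$total
  attr(r, "info") <- list(
    survival = if (length(tr$time)) max(tr$time) else 0,
    n_footsteps = rw$n_footsteps, diverged = FALSE)
  r
}

#' Optimize the walking controller with CMA-ES
#'
#' Searches the normalized 49-dimensional space (37 controller + 12
#' initial-state parameters). Cold starts draw the initial mean uniformly in
#' the unit box under the run seed with sigma0 = 0.25; warm starts (an `x0`
#' from a previous solution) use sigma0 = 0.05.
#'
#' @param model `gait_model` or config
#' @param v_tgt target speed or NULL (self-selected speed)
#' @param horizon episode length, s
#' @param popsize,generations CMA-ES budget
#' @param seed master seed
#' @param x0 optional warm-start mean (unit box 49-vector)
#' @param sigma0 initial step size; default 0.25 cold, 0.05 warm
#' @param n_workers parallel evaluation slots
#' @param weights [reward_weights()]
#' @param verbose print per-generation progress
#' @return `cma_result` augmented with the decoded best controller and
#'   initial state
#' @export
optimize_gait <- function(model, v_tgt = 1.45, horizon = 10, popsize = 16,
                          generations = 1000, seed = 1, x0 = NULL,
                          sigma0 = NULL, n_workers = 1,
                          weights = reward_weights(), verbose = FALSE) {
  model <- as_gait_model(model)
  warm <- !is.null(x0)
  if (is.null(sigma0)) sigma0 <- if (warm) 0.05 else 0.25
  if (!warm) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed + 1)
    x0 <- runif(49)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  if (length(x0) != 49)
    stop("x0 must be a 49-vector (37 controller + 12 initial-state)")
  obj <- function(u) evaluate_candidate(u, model, horizon, v_tgt, weights)
  cb <- if (verbose) {
    function(g, b, m, s) {
      message(sprintf("gen %4d  best %10.4f  mean %10.4f  sigma %.4f",
                      g, b, m, s))
    }
  } else NULL
  res <- run_cmaes(obj, x0, sigma0, lower = 0, upper = 1, popsize = popsize,
                   generations = generations, seed = seed,
                   n_workers = n_workers, callback = cb)
  dec <- decode_opt_vector(res$best_params)
  res$controller <- dec$controller
  res$init <- dec$init
  res$v_tgt <- v_tgt
  res$horizon <- horizon
  res$seed_provenance <- paste0("seed=", seed, if (warm) " (warm start)"
                                else " (cold start)")
  res
}

#' Warm-start seed from a previous optimization
#'
#' Returns the previous best parameter vector as the next initial mean, for
#' the neighbor-speed and weakness protocols where each optimization seeds
#' the next.
#'
#' @param prev a `cma_result`
#' @return unit-box 49-vector
#' @export
seed_from <- function(prev) {
  if (!inherits(prev, "cma_result")) stop("expected a cma_result")
  x0 <- prev$best_params
  if (length(x0) != 49)
    stop("dimension mismatch: previous solution has length ", length(x0),
         ", expected 49")
  x0
}

#' Plot the optimization reward history
#'
#' Per-generation best and mean rewards plus the running best-ever.
#'
#' @param x a `cma_result`
#' @param ... ignored
#' @export
plot.cma_result <- function(x, ...) {
  h <- x$reward_history
  graphics::plot(h$generation, h$best_ever, type = "l", lwd = 2,
                 col = "firebrick", xlab = "generation", ylab = "reward",
                 main = "CMA-ES reward history",
                 ylim = range(h$mean, h$best_ever))
  graphics::lines(h$generation, h$best, col = "steelblue4")
  graphics::lines(h$generation, h$mean, col = "grey50", lty = 2)
  graphics::legend("bottomright", c("best-ever", "generation best",
                                    "generation mean"),
                   col = c("firebrick", "steelblue4", "grey50"),
                   lty = c(1, 1, 2), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}
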