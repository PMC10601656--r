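#' Segment a trace into gait cycles
#'
#' A gait cycle spans successive ipsilateral initial contacts (vertical GRF
#' rising through the threshold after at least 50 ms unloaded). The first
#' cycle is discarded as a startup transient, and the trailing partial cycle
#' is dropped.
#'
#' @param trace a `gait_trace`
#' @param side "R" or "L"
#' @param threshold contact threshold, N
#' @param debounce minimum unloaded time before an initial contact, s
#' @param drop_first discard the first complete cycle (transient)
#' @return data.frame with `start_step`, `end_step`, `duration` (possibly
#'   zero rows)
#' @export
segment_cycles <- function(trace, side = "R", threshold = 20,
                           debounce = 0.05, drop_first = TRUE) {
  side <- match.arg(side, c("R", "L"))
  v <- trace$grf[, paste0("grf_", side, "_vertical")]
  dt <- trace$dt
  need <- max(1L, as.integer(round(debounce / dt)))
  loaded <- v >= threshold
  ics <- integer(0)
  streak <- 0L
  for (i in seq_along(loaded)) {
    if (loaded[i]) {
      if (streak >= need) ics <- c(ics, i)
      streak <- 0L
    } else streak <- streak + 1L
  }
  if (length(ics) < 2) {
    message("fewer than 2 initial contacts on side ", side,
            "; no complete gait cycles")
    return(data.frame(start_step = integer(0), end_step = integer(0),
                      duration = numeric(0)))
  }
  cyc <- data.frame(start_step = ics[-length(ics)], end_step = ics[-1])
  cyc$duration <- (cyc$end_step - cyc$start_step) * dt
  if (drop_first && nrow(cyc) > 0) cyc <- cyc[-1, , drop = FALSE]
  rownames(cyc) <- NULL
  cyc
}

#' Resample a signal onto the 0-100% gait-cycle grid
#'
#' Linear interpolation of the rows `start..end` (the end row is the next
#' initial contact, i.e. 100%) onto 101 evenly spaced points.
#'
#' @param signal numeric vector over the whole trace (one value per control
#'   step)
#' @param start_step,end_step cycle bounds (trace row indices)
#' @return numeric vector of length 101
#' @export
normalize_cycle <- function(signal, start_step, end_step) {
  stopifnot(end_step > start_step)
  if (end_step - start_step < 10)
    stop("cycle spans fewer than 10 control steps")
  idx <- start_step:end_step
  x <- (idx - start_step) / (end_step - start_step) * 100
  approx(x, signal[idx], xout = 0:100)$y
}

#' Toe-off timing as a fraction of the gait cycle
#'
#' The toe-off is the instant within a cycle at which the ipsilateral
#' vertical GRF falls below the threshold and stays below it for the rest of
#' the cycle (which debounces threshold chatter to a single event).
#'
#' @param grf_v vertical GRF over the trace, N
#' @param start_step,end_step cycle bounds
#' @param threshold contact threshold, N
#' @return percent of cycle in (0, 100), or NA with a warning if the foot
#'   never unloads
#' @export
toe_off_fraction <- function(grf_v, start_step, end_step, threshold = 20) {
  idx <- start_step:(end_step - 1L)
  below <- grf_v[idx] < threshold
  if (!any(below)) {
    warning("no unloading event in cycle; toe-off undefined")
    return(NA_real_)
  }
  # last falling edge after which the foot stays unloaded
  stays <- rev(cumprod(rev(below))) == 1
  t_off <- which(stays)[1]
  (t_off - 1) / (end_step - start_step) * 100
}

#' Ensemble statistics over gait cycles
#'
#' Normalizes hip, knee and ankle angles (degrees) of the chosen side and the
#' vertical GRF to the gait cycle, the vertical GRF additionally to the
#' stance phase, and returns pointwise ensemble mean and sample SD, the mean
#' toe-off percentage and mean forward speed.
#'
#' @param trace a `gait_trace`
#' @param side "R" or "L"
#' @param cycles optional precomputed [segment_cycles()] table
#' @param threshold contact threshold, N
#' @param grf_in_bw report GRF in body-weight units (default) or newtons
#' @param body_weight body weight in N used for BW scaling
#' @return object of class `gait_cycles`: `n_cycles`, per-signal `mean` and
#'   `sd` 101-point curves (hip/knee/ankle deg, grf over cycle, grf over
#'   stance), `toe_off_pct`, `mean_speed`, per-cycle curve matrices
#' @export
ensemble_stats <- function(trace, side = "R", cycles = NULL, threshold = 20,
                           grf_in_bw = TRUE, body_weight = 75 * 9.81) {
  side <- match.arg(side, c("R", "L"))
  if (is.null(cycles)) cycles <- segment_cycles(trace, side, threshold)
  if (nrow(cycles) == 0) stop("no complete gait cycles to summarize")
  joff <- if (side == "R") 4 else 7
  grf_v <- trace$grf[, paste0("grf_", side, "_vertical")]
  grf_scaled <- if (grf_in_bw) grf_v / body_weight else grf_v
  sig <- list(hip = trace$q[, joff] * 180 / pi,
              knee = trace$q[, joff + 1] * 180 / pi,
              ankle = trace$q[, joff + 2] * 180 / pi,
              grf = grf_scaled)
  n <- nrow(cycles)
  curves <- lapply(sig, function(s) {
    t(vapply(seq_len(n), function(i) {
      normalize_cycle(s, cycles$start_step[i], cycles$end_step[i])
    }, numeric(101)))
  })
  toe_off <- vapply(seq_len(n), function(i) {
    toe_off_fraction(grf_v, cycles$start_step[i], cycles$end_step[i],
                     threshold)
  }, numeric(1))
  # vertical GRF normalized to the stance phase (initial contact .. toe-off)
  stance_curves <- t(vapply(seq_len(n), function(i) {
    st <- cycles$start_step[i]
    to <- toe_off[i]
    if (is.na(to)) return(rep(NA_real_, 101))
    en <- st + max(10L, as.integer(round(
      to / 100 * (cycles$end_step[i] - st))))
    normalize_cycle(grf_scaled, st, en)
  }, numeric(101)))
  curves$grf_stance <- stance_curves
  mean_sd <- function(m) {
    list(mean = colMeans(m),
         sd = if (nrow(m) >= 2) apply(m, 2, sd) else rep(NA_real_, ncol(m)))
  }
  stats <- lapply(curves, mean_sd)
  # mean forward speed: pelvis displacement over the stepping period
  first <- cycles$start_step[1]; last <- cycles$end_step[n]
  speed <- (trace$q[last, 1] - trace$q[first, 1]) /
    ((last - first) * trace$dt)
  out <- list(n_cycles = n, side = side,
              mean = lapply(stats, `[[`, "mean"),
              sd = lapply(stats, `[[`, "sd"),
              curves = curves,
              toe_off_pct = mean(toe_off, na.rm = TRUE),
              toe_off_per_cycle = toe_off,
              mean_speed = speed, grf_in_bw = grf_in_bw)
  class(out) <- "gait_cycles"
  out
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat("<gait_cycles>", x$n_cycles, "cycles, side", x$side, "\n")
  cat(sprintf("  mean speed %.3f m/s, toe-off %.1f%% of cycle\n",
              x$mean_speed, x$toe_off_pct))
  invisible(x)
}

#' Pearson correlation between two gait curves
#'
#' Both curves must be sampled on the common 101-point percent-cycle grid.
#' Zero-variance input is flagged as an error rather than silently returning
#' zero.
#'
#' @param sim_curve,ref_curve numeric vectors of equal length
#' @return Pearson R
#' @export
correlate_curves <- function(sim_curve, ref_curve) {
  stopifnot(length(sim_curve) == length(ref_curve))
  if (sd(sim_curve) == 0 || sd(ref_curve) == 0)
    stop("correlation undefined: one of the curves has zero variance")
  cor(sim_curve, ref_curve)
}

#' Read reference joint kinematics from CSV
#'
#' Expected columns: `percent_cycle` (0-100), `hip_deg`, `knee_deg`,
#' `ankle_deg`, with flexion/dorsiflexion positive. Curves are resampled onto
#' the 0:100 grid by linear interpolation. A purely synthetic example file
#' (smooth harmonics with gait-like shape, not experimental data) ships as
#' `system.file("extdata", "synthetic_reference_kinematics.csv",
#' package = "neurogait")`.
#'
#' @param path CSV path
#' @return list with 101-point `hip`, `knee`, `ankle` curves (degrees)
#' @export
read_reference_kinematics <- function(path) {
  df <- read.csv(path)
  need <- c("percent_cycle", "hip_deg", "knee_deg", "ankle_deg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("reference kinematics CSV is missing columns: ",
         paste(missing, collapse = ", "))
  resamp <- function(y) approx(df$percent_cycle, y, xout = 0:100,
                               rule = 2)$y
  list(hip = resamp(df$hip_deg), knee = resamp(df$knee_deg),
       ankle = resamp(df$ankle_deg))
}

#' Correlate a simulated gait summary against reference kinematics
#'
#' @param summary a `gait_cycles` object
#' @param reference result of [read_reference_kinematics()] (or an equivalent
#'   list of 101-point `hip`, `knee`, `ankle` curves)
#' @return named vector of Pearson R for hip, knee and ankle
#' @export
kinematic_correlations <- function(summary, reference) {
  vapply(c(hip = "hip", knee = "knee", ankle = "ankle"), function(j) {
    correlate_curves(summary$mean[[j]], reference[[j]])
  }, numeric(1))
}

#' Export a gait-cycle summary
#'
#' Writes the mean and SD curves as CSV (one row per percent of gait cycle)
#' and the scalar results (cycle count, toe-off %, speed, optional
#' correlation coefficients) as JSON.
#'
#' @param summary a `gait_cycles` object
#' @param path_csv,path_json output paths
#' @param correlations optional named R values to include
#' @return invisible list of the two paths
#' @export
write_cycle_summary <- function(summary, path_csv, path_json,
                                correlations = NULL) {
  df <- data.frame(percent = 0:100)
  for (nm in names(summary$mean)) {
    df[[paste0(nm, "_mean")]] <- summary$mean[[nm]]
    df[[paste0(nm, "_sd")]] <- summary$sd[[nm]]
  }
  write.csv(df, path_csv, row.names = FALSE)
  scal <- list(n_cycles = summary$n_cycles, side = summary$side,
               toe_off_pct = summary$toe_off_pct,
               mean_speed = summary$mean_speed,
               grf_in_bw = summary$grf_in_bw)
  if (!is.null(correlations)) scal$correlations <- as.list(correlations)
  jsonlite::write_json(scal, path_json, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = path_csv, json = path_json))
}

#' Plot ensemble gait curves
#'
#' Mean ± SD curves over the gait cycle for hip, knee and ankle angles and
#' the vertical GRF (over stance), in the conventional 2 x 2 panel layout.
#'
#' @param x a `gait_cycles` object
#' @param ... ignored
#' @export
plot.gait_cycles <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(nm, ylab, main, xlab) {
    mu <- x$mean[[nm]]; sd <- x$sd[[nm]]
    if (all(is.na(sd))) sd <- rep(0, length(mu))
    pc <- 0:100
    graphics::plot(pc, mu, type = "n", xlab = xlab, ylab = ylab,
                   main = main, ylim = range(mu - sd, mu + sd, na.rm = TRUE))
    graphics::polygon(c(pc, rev(pc)), c(mu - sd, rev(mu + sd)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(pc, mu, col = "steelblue4", lwd = 2)
  }
  panel("hip", "angle [deg]", "Hip flexion", "% gait cycle")
  panel("knee", "angle [deg]", "Knee flexion", "% gait cycle")
  panel("ankle", "angle [deg]", "Ankle dorsiflexion", "% gait cycle")
  panel("grf_stance", if (x$grf_in_bw) "vertical GRF [BW]" else
    "vertical GRF [N]", "Vertical GRF", "% stance")
  invisible(x)
}
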