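#' Voltage-step protocol for patch clamp fluorometry
#'
#' The standard quenching protocol: families of 100 ms steps from -180 to
#' +120 mV in 30 mV increments from a -15 mV holding potential, repeated
#' four times. The first family is routinely discarded (acceptor
#' equilibration) and the remaining families averaged.
#'
#' @param v_hold holding potential, mV.
#' @param v_start first step voltage, mV.
#' @param v_end last step voltage, mV.
#' @param v_step voltage increment, mV; `(v_end - v_start)` must be a
#'   multiple of it.
#' @param step_duration step length, ms.
#' @param n_families number of protocol repetitions.
#' @return List of class `voltage_protocol`; `$voltages` holds the step
#'   voltages.
#' @export
voltage_protocol <- function(v_hold = -15, v_start = -180, v_end = 120,
                             v_step = 30, step_duration = 100, n_families = 4) {
  if (step_duration <= 0) stop("'step_duration' must be positive")
  if (n_families < 1) stop("'n_families' must be at least 1")
  if (v_step == 0 || (v_end - v_start) %% v_step != 0)
    stop("(v_end - v_start) must be divisible by 'v_step'")
  structure(list(v_hold = v_hold, v_start = v_start, v_end = v_end,
                 v_step = v_step, step_duration = step_duration,
                 n_families = n_families,
                 voltages = seq(v_start, v_end, by = v_step)),
            class = "voltage_protocol")
}

#' Per-cell fluorescence-voltage points from a fluorometry trace
#'
#' Reduces a raw single-cell recording (time, fluorescence, command voltage)
#' to one normalized fluorescence value per step voltage. After background
#' subtraction, the fluorescence in the second quintile of each voltage step
#' (20-40 ms of a 100 ms step) is averaged and divided by the mean
#' fluorescence in an equal-length holding-potential window immediately
#' preceding the step. The first family is discarded and the remaining
#' families averaged per voltage.
#'
#' @param trace data frame with columns `time_ms`, `fluorescence`,
#'   `voltage_mV` (extra columns ignored), covering
#'   `n_families` complete repetitions of the protocol.
#' @param protocol a [voltage_protocol()].
#' @param background scalar background fluorescence measured off-cell,
#'   subtracted from the whole trace.
#' @param cell_id,condition labels carried on the result.
#' @return Data frame of class `fv_series` with columns `voltage_mV`,
#'   `f_norm`.
#' @export
extract_fv_points <- function(trace, protocol = voltage_protocol(),
                              background = 0, cell_id = NA_character_,
                              condition = NA_character_) {
  need <- c("time_ms", "fluorescence", "voltage_mV")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("trace is missing required column(s): ", paste(miss, collapse = ", "))
  if (background < 0) stop("'background' must be non-negative")
  v <- trace$voltage_mV
  f <- trace$fluorescence - background
  t <- trace$time_ms
  on_step <- v != protocol$v_hold
  run <- cumsum(c(on_step[1], diff(on_step) != 0))
  run_ids <- unique(run[on_step])
  n_steps <- length(protocol$voltages)
  expected <- protocol$n_families * n_steps
  if (length(run_ids) != expected)
    stop(sprintf("protocol mismatch: found %d voltage steps, expected %d",
                 length(run_ids), expected))
  hold_mean <- mean(f[!on_step])
  if (hold_mean <= 0)
    warning("background exceeds holding-potential fluorescence (over-subtraction)")
  q <- protocol$step_duration / 5
  ratio <- voltage <- family <- numeric(length(run_ids))
  for (k in seq_along(run_ids)) {
    idx <- which(run == run_ids[k])
    t0 <- t[idx[1L]]
    vstep <- v[idx[1L]]
    in_q2 <- idx[t[idx] >= t0 + q & t[idx] < t0 + 2 * q]
    pre <- which(!on_step & t >= t0 - q & t < t0)
    if (!length(in_q2) || !length(pre))
      stop("protocol mismatch: truncated step or missing pre-step holding window")
    ratio[k] <- mean(f[in_q2]) / mean(f[pre])
    voltage[k] <- vstep
    family[k] <- ceiling(k / n_steps)
  }
  keep <- family > 1          # family 1 discarded: acceptor still equilibrating
  fn <- tapply(ratio[keep], voltage[keep], mean)
  out <- data.frame(voltage_mV = as.numeric(names(fn)), f_norm = as.numeric(fn))
  out <- out[order(out$voltage_mV), , drop = FALSE]
  rownames(out) <- NULL
  if (!setequal(out$voltage_mV, protocol$voltages))
    stop("protocol mismatch: observed step voltages differ from the protocol")
  class(out) <- c("fv_series", "data.frame")
  attr(out, "cell_id") <- cell_id
  attr(out, "condition") <- condition
  out
}

# decreasing-sigmoid Boltzmann: f(-Inf) = top, f(+Inf) = bottom for slope > 0
.boltzmann <- function(v, top, bottom, v50, slope)
  bottom + (top - bottom) / (1 + exp((v - v50) / slope))

#' Boltzmann fit of a fluorescence-voltage series
#'
#' Least-squares fit of
#' `f(V) = bottom + (top - bottom) / (1 + exp((V - v50) / slope))`
#' so that with `slope > 0` fluorescence decreases with depolarization
#' (quenching) and `dff = top - bottom` is positive. Initial values are
#' taken from the data extremes and half-crossing voltage; on failure up to
#' five jittered restarts are attempted.
#'
#' @param series an [extract_fv_points()] result (or any data frame with
#'   `voltage_mV` and `f_norm`).
#' @return List of class `boltzmann_fit` with elements `top`, `bottom`,
#'   `v50`, `slope`, `dff`, `converged`, `degenerate`, and the underlying
#'   `fit` object (NULL when no start converged).
#' @export
fit_boltzmann <- function(series) {
  v <- series$voltage_mV
  f <- series$f_norm
  if (length(unique(v)) < 4L) stop("need at least 4 distinct voltages")
  rng <- diff(range(f))
  if (rng < 1e-10) {
    return(structure(list(top = mean(f), bottom = mean(f), v50 = NA_real_,
                          slope = NA_real_, dff = 0, converged = FALSE,
                          degenerate = TRUE, fit = NULL),
                     class = "boltzmann_fit"))
  }
  half <- (max(f) + min(f)) / 2
  v50_0 <- v[which.min(abs(f - half))]
  starts <- list(c(top = max(f), bottom = min(f), v50 = v50_0, slope = 20))
  set <- function(s, jit) {
    s + c(0, 0, jit[1], jit[2])
  }
  jits <- list(c(0, 0), c(30, 10), c(-30, -10), c(60, 20), c(-60, 5))
  best <- NULL
  for (j in jits) {
    st <- as.list(set(starts[[1]], j))
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ .boltzmann(v, top, bottom, v50, slope),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) best <- fit
      if (stats::deviance(fit) <= rng^2 * 1e-6) break
    }
  }
  if (is.null(best)) {
    # near-flat or otherwise ill-conditioned series defeat the gradient
    # solver; fall back to direct simplex minimization of the RSS
    rss <- function(par) sum((f - .boltzmann(v, par[1], par[2], par[3],
                                             par[4]))^2)
    opt <- tryCatch(stats::optim(unname(starts[[1]]), rss,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 5000,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt)) {
      return(structure(list(top = NA_real_, bottom = NA_real_,
                            v50 = NA_real_, slope = NA_real_, dff = NA_real_,
                            converged = FALSE, degenerate = FALSE, fit = NULL,
                            diagnostics = "no start converged"),
                       class = "boltzmann_fit"))
    }
    p <- list(top = opt$par[1], bottom = opt$par[2], v50 = opt$par[3],
              slope = opt$par[4])
    if (p$slope < 0) {
      tmp <- p$top; p$top <- p$bottom; p$bottom <- tmp
      p$slope <- -p$slope
    }
    return(structure(list(top = p$top, bottom = p$bottom, v50 = p$v50,
                          slope = p$slope, dff = p$top - p$bottom,
                          converged = TRUE, degenerate = FALSE, fit = NULL,
                          diagnostics = "simplex fallback"),
                     class = "boltzmann_fit"))
  }
  p <- as.list(stats::coef(best))
  # canonicalize: slope < 0 swaps the roles of top and bottom
  if (!is.na(p$slope) && p$slope < 0) {
    tmp <- p$top; p$top <- p$bottom; p$bottom <- tmp
    p$slope <- -p$slope
  }
  structure(list(top = p$top, bottom = p$bottom, v50 = p$v50, slope = p$slope,
                 dff = p$top - p$bottom, converged = TRUE, degenerate = FALSE,
                 fit = best),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate (flat) fluorescence-voltage series: dff = 0\n")
  } else if (!x$converged) {
    cat("Boltzmann fit failed to converge\n")
  } else {
    cat(sprintf("Boltzmann fit: top %.4f, bottom %.4f, V50 %.1f mV, slope %.1f mV\n",
                x$top, x$bottom, x$v50, x$slope))
    cat(sprintf("  dF/F = %.4f\n", x$dff))
  }
  invisible(x)
}

#' Fit-free delta-F/F from the extreme voltages
#'
#' `f_norm` at the most hyperpolarized voltage minus `f_norm` at the most
#' depolarized voltage — both already normalized to the holding-potential
#' fluorescence — giving a model-free counterpart to the Boltzmann
#' `top - bottom`.
#'
#' @param series an `fv_series`.
#' @param v_low,v_high the extreme step voltages, mV.
#' @return The fit-free delta-F/F (dimensionless).
#' @export
fit_free_dff <- function(series, v_low = -180, v_high = 120) {
  i_lo <- match(v_low, series$voltage_mV)
  i_hi <- match(v_high, series$voltage_mV)
  if (is.na(i_lo) || is.na(i_hi))
    stop(sprintf("series must contain both extreme voltages (%g and %g mV)",
                 v_low, v_high))
  series$f_norm[i_lo] - series$f_norm[i_hi]
}
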