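#' Dual-channel pH-jump trace
#'
#' Time-aligned donor- and acceptor-channel fluorescence (background
#' subtracted) during rapid solution switches, optionally with the
#' whole-cell current and a per-sample pH label. Application events default
#' to the standard protocol: 2 s applications separated by 20 s.
#'
#' @param time_s sample times, s, strictly increasing.
#' @param donor_f,acceptor_f channel fluorescence, same length as `time_s`.
#' @param current_pA optional current trace.
#' @param ph optional per-sample pH label.
#' @param events optional data frame with columns `start`, `stop` (s) and
#'   optionally `ph`, one row per application; must lie within the trace.
#' @return List of class `ph_jump_trace`.
#' @export
ph_jump_trace <- function(time_s, donor_f, acceptor_f, current_pA = NULL,
                          ph = NULL, events = NULL) {
  n <- length(time_s)
  if (length(donor_f) != n || length(acceptor_f) != n)
    stop("channels must be time-aligned (equal lengths)")
  if (is.unsorted(time_s, strictly = TRUE))
    stop("'time_s' must be strictly increasing")
  if (!is.null(current_pA) && length(current_pA) != n)
    stop("'current_pA' must be time-aligned with the channels")
  if (!is.null(events)) {
    if (!all(c("start", "stop") %in% names(events)))
      stop("'events' needs 'start' and 'stop' columns")
    if (any(events$start < time_s[1]) || any(events$stop > time_s[n]))
      stop("'events' must lie within the trace")
  }
  structure(list(time_s = time_s, donor_f = donor_f, acceptor_f = acceptor_f,
                 current_pA = current_pA, ph = ph, events = events),
            class = "ph_jump_trace")
}

#' Change in apparent FRET during a solution switch
#'
#' The acceptor/donor emission ratio `R(t) = acceptor_f / donor_f` is an
#' apparent (bleed-through-uncorrected) FRET signal; its percentage change
#' between a baseline window and a response window,
#' `100 * (mean R_resp - mean R_base) / mean R_base`,
#' quantifies acid-evoked FRET changes. The same statistic is also returned
#' per individual channel, which exposes intrinsic pH sensitivity of a
#' single fluorophore (the control experiments for pH-sensitive acceptors).
#' Common multiplicative drift on both channels cancels exactly in the
#' ratio.
#'
#' @param trace a [ph_jump_trace()].
#' @param baseline_window,response_window length-2 time intervals (s) within
#'   the trace; the baseline must precede the response.
#' @return List of class `dfret_app`: `ratio_pct`, `acceptor_pct`,
#'   `donor_pct`, and the windows used.
#' @export
delta_fret_app <- function(trace, baseline_window, response_window) {
  stopifnot(inherits(trace, "ph_jump_trace"))
  chk <- function(w, nm) {
    if (length(w) != 2L || w[1] >= w[2])
      stop(sprintf("'%s' must be an increasing length-2 interval", nm))
    if (w[1] < min(trace$time_s) || w[2] > max(trace$time_s))
      stop(sprintf("'%s' must lie within the trace", nm))
  }
  chk(baseline_window, "baseline_window")
  chk(response_window, "response_window")
  if (baseline_window[2] > response_window[1])
    stop("baseline window must precede the response window")
  in_b <- trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]
  in_r <- trace$time_s >= response_window[1] & trace$time_s <= response_window[2]
  if (any(trace$donor_f[in_b | in_r] <= 0))
    stop("donor channel must be positive within the analysis windows")
  pct <- function(x) 100 * (mean(x[in_r]) - mean(x[in_b])) / mean(x[in_b])
  r <- trace$acceptor_f / trace$donor_f
  structure(list(ratio_pct = pct(r),
                 acceptor_pct = pct(trace$acceptor_f),
                 donor_pct = pct(trace$donor_f),
                 baseline_window = baseline_window,
                 response_window = response_window),
            class = "dfret_app")
}

#' @export
print.dfret_app <- function(x, ...) {
  cat(sprintf("dFRET_app = %+.2f%%  (acceptor %+.2f%%, donor %+.2f%%)\n",
              x$ratio_pct, x$acceptor_pct, x$donor_pct))
  invisible(x)
}

#' Exponential fit of current desensitization
#'
#' Locates the peak current (largest absolute deviation from the
#' pre-activation baseline) and fits the decay from the peak onward with
#' `I(t) = I_ss + A * exp(-(t - t_peak) / tau)`; optionally a second
#' exponential component.
#'
#' @param time_s sample times, s.
#' @param current current trace spanning the peak and its decay.
#' @param n_components 1 (default) or 2 exponential components.
#' @return List of class `desensitization_fit`: `tau` (vector of length
#'   `n_components`, s, sorted), `i_ss`, `amplitude`, `t_peak`,
#'   `converged`, and the underlying `fit`.
#' @export
fit_desensitization <- function(time_s, current, n_components = 1) {
  if (length(time_s) != length(current))
    stop("'time_s' and 'current' must have equal length")
  if (!n_components %in% c(1, 2)) stop("'n_components' must be 1 or 2")
  i_peak <- which.max(abs(current - current[1]))
  if (i_peak >= length(current) - 5L)
    stop("no identifiable peak followed by a decay")
  t <- time_s[i_peak:length(time_s)] - time_s[i_peak]
  y <- current[i_peak:length(current)]
  if (abs(y[length(y)] - y[1]) < 1e-12 * max(abs(y), 1e-12))
    stop("no identifiable decay after the peak")
  a0 <- y[1] - y[length(y)]
  tau0 <- max(t[length(t)] / 5, 1e-6)
  fit <- if (n_components == 1) {
    tryCatch(minpack.lm::nlsLM(y ~ iss + a * exp(-t / tau),
                               start = list(iss = y[length(y)], a = a0,
                                            tau = tau0),
                               control = minpack.lm::nls.lm.control(maxiter = 500)),
             error = function(e) NULL)
  } else {
    tryCatch(minpack.lm::nlsLM(y ~ iss + a1 * exp(-t / tau1) + a2 * exp(-t / tau2),
                               start = list(iss = y[length(y)], a1 = a0 * 0.7,
                                            tau1 = tau0 / 2, a2 = a0 * 0.3,
                                            tau2 = tau0 * 2),
                               control = minpack.lm::nls.lm.control(maxiter = 500)),
             error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(structure(list(tau = rep(NA_real_, n_components), i_ss = NA_real_,
                          amplitude = rep(NA_real_, n_components),
                          t_peak = time_s[i_peak], converged = FALSE,
                          fit = NULL),
                     class = "desensitization_fit"))
  }
  p <- stats::coef(fit)
  if (n_components == 1) {
    tau <- p[["tau"]]; amp <- p[["a"]]
  } else {
    ord <- order(c(p[["tau1"]], p[["tau2"]]))
    tau <- c(p[["tau1"]], p[["tau2"]])[ord]
    amp <- c(p[["a1"]], p[["a2"]])[ord]
  }
  structure(list(tau = tau, i_ss = p[["iss"]], amplitude = amp,
                 t_peak = time_s[i_peak], converged = TRUE, fit = fit),
            class = "desensitization_fit")
}

#' Recovery-from-desensitization fit
#'
#' Paired-pulse recovery: the test-pulse peak, normalized to the
#' conditioning peak, as a function of the interpulse interval is fitted
#' with `I(t) = (1 - exp(-t / tau))^m`. At `m = 1` this reduces to plain
#' mono-exponential recovery; `m > 1` produces the sigmoidal onset typical
#' of multi-step recovery. The curve is 0 at `t = 0` and 1 at infinity by
#' construction.
#'
#' @param intervals interpulse intervals, s (at least 4, spanning the rise).
#' @param fractions test/conditioning peak ratios, `>= 0`.
#' @return List of class `recovery_fit`: `tau` (s), `m`, standard errors
#'   `se`, approximate 95 percent `ci` (2 x 2 matrix), `degenerate` flag,
#'   and the underlying `fit`.
#' @export
fit_recovery <- function(intervals, fractions) {
  if (length(intervals) != length(fractions))
    stop("'intervals' and 'fractions' must have equal length")
  if (length(unique(intervals)) < 4L)
    stop("need at least 4 distinct interpulse intervals")
  if (any(fractions < 0)) stop("'fractions' must be non-negative")
  degenerate <- all(abs(fractions - 1) < 0.02)
  t <- intervals
  y <- fractions
  tau0 <- stats::median(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (1 - exp(-t / tau))^m,
                      start = list(tau = tau0, m = 1),
                      lower = c(tau = 1e-6, m = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, m = NA_real_,
                          se = c(tau = NA_real_, m = NA_real_), ci = NULL,
                          degenerate = degenerate, converged = FALSE,
                          fit = NULL),
                     class = "recovery_fit"))
  }
  p <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(tau = NA_real_, m = NA_real_))
  ci <- rbind(tau = p[["tau"]] + c(-1, 1) * 1.96 * se[["tau"]],
              m = p[["m"]] + c(-1, 1) * 1.96 * se[["m"]])
  colnames(ci) <- c("lower", "upper")
  structure(list(tau = p[["tau"]], m = p[["m"]], se = se, ci = ci,
                 degenerate = degenerate, converged = TRUE, fit = fit),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Recovery fit failed to converge\n")
  } else {
    cat(sprintf("Recovery fit: tau = %.3f s, m = %.2f%s\n", x$tau, x$m,
                if (x$degenerate) " [degenerate: full recovery everywhere]" else ""))
  }
  invisible(x)
}
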