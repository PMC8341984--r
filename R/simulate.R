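#' Simulate a patch-clamp-fluorometry quenching experiment
#'
#' Emits per-cell raw traces (time, fluorescence, command voltage) for a
#' voltage-step family protocol, with the true fluorescence-voltage
#' relation a decreasing Boltzmann normalized to the holding potential:
#' given the true `dff`, `v50` and `slope`, the normalized sigmoid is
#' constrained to equal 1 at `v_hold`, so the value recovered by
#' [extract_fv_points()] + [fit_boltzmann()] estimates `dff` directly.
#'
#' Per-sample fluorescence (1 ms sampling) is Poisson photon counts at
#' `photon_rate * B(V)` counts/ms, scaled by `gain`, multiplied by
#' `(1 + N(0, readout_sd))` readout noise, plus `background`. Each step is
#' preceded by a holding segment of equal duration; inter-sweep idle time is
#' not simulated since the extraction only uses the step and its preceding
#' holding window. With `dpa = FALSE` the fluorescence-voltage relation is
#' flat (no acceptor in the membrane).
#'
#' @param dff,v50,slope true Boltzmann parameters of the normalized
#'   fluorescence-voltage relation (dimensionless, mV, mV).
#' @param protocol a [voltage_protocol()].
#' @param photon_rate expected photon counts per ms at the holding-potential
#'   fluorescence.
#' @param background background fluorescence added to every sample (same
#'   scalar the analysis should subtract).
#' @param readout_sd multiplicative Gaussian readout noise SD.
#' @param gain detector gain applied to photon counts.
#' @param n_cells number of cells to simulate.
#' @param dpa simulate quenching (`TRUE`) or the acceptor-free control.
#' @param seed optional integer seed; output is byte-identical given a seed.
#' @return List of class `fv_simulation`: `traces` (list of per-cell data
#'   frames with `time_ms`, `fluorescence`, `voltage_mV`), `truth` (list
#'   with per-cell `dff` and the generator parameters), `protocol`,
#'   `background`.
#' @export
simulate_fv_experiment <- function(dff = 0.45, v50 = -30, slope = 25,
                                   protocol = voltage_protocol(),
                                   photon_rate = 500, background = 50,
                                   readout_sd = 0.02, gain = 1,
                                   n_cells = 6, dpa = TRUE, seed = NULL) {
  if (photon_rate <= 0) stop("'photon_rate' must be positive")
  if (n_cells < 1) stop("'n_cells' must be at least 1")
  if (readout_sd < 0 || background < 0)
    stop("'readout_sd' and 'background' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  true_dff <- if (dpa) dff else 0
  # normalized Boltzmann pinned to 1 at the holding potential
  bnorm <- function(v) {
    if (!dpa) return(rep(1, length(v)))
    bottom <- 1 - true_dff / (1 + exp((protocol$v_hold - v50) / slope))
    bottom + true_dff / (1 + exp((v - v50) / slope))
  }
  dt <- 1                                   # ms per sample
  n_per_seg <- round(protocol$step_duration / dt)
  volts <- protocol$voltages
  seg_v <- as.vector(rbind(rep(protocol$v_hold, length(volts)), volts))
  sweep_v <- rep(rep(seg_v, each = n_per_seg), protocol$n_families)
  n_tot <- length(sweep_v)
  time_ms <- seq(0, by = dt, length.out = n_tot)
  lambda <- photon_rate * bnorm(sweep_v) * dt
  traces <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    counts <- stats::rpois(n_tot, lambda)
    noise <- if (readout_sd > 0) 1 + stats::rnorm(n_tot, 0, readout_sd) else 1
    traces[[cell]] <- data.frame(time_ms = time_ms,
                                 fluorescence = gain * counts * noise + background,
                                 voltage_mV = sweep_v)
  }
  structure(list(traces = traces,
                 truth = list(dff = rep(true_dff, n_cells), v50 = v50,
                              slope = slope, photon_rate = photon_rate,
                              readout_sd = readout_sd, gain = gain,
                              dpa = dpa, seed = seed),
                 protocol = protocol, background = background),
            class = "fv_simulation")
}

#' Simulate a TCSPC decay histogram
#'
#' Multinomial photon sampling from a (mixture of) exponential decay(s)
#' discretized over the repetition window: the probability of a photon in
#' bin `[t, t+dt)` is proportional to `sum_k w_k (exp(-t/tau_k) -
#' exp(-(t+dt)/tau_k))`, renormalized within the window. The expected
#' counts therefore reproduce the analytic mixture exactly. Components with
#' `tau` comparable to the window would wrap around in a real instrument;
#' such components trigger a warning (no correction is applied).
#'
#' @param components data frame (or list coercible to one) with columns
#'   `tau` (ns, positive) and `weight` (summing to 1).
#' @param counts_total total photons to distribute (0 gives an all-zero
#'   histogram).
#' @param bin_ns bin width, ns (25 ps default).
#' @param window_ns repetition window, ns (12.5 ns default, 80 MHz).
#' @param seed optional integer seed.
#' @return A [decay_histogram()] with attribute `truth` (the component
#'   table and `counts_total`).
#' @export
simulate_tcspc <- function(components = data.frame(tau = 4.06, weight = 1),
                           counts_total = 1e6, bin_ns = 0.025,
                           window_ns = 12.5, seed = NULL) {
  components <- as.data.frame(components)
  if (!all(c("tau", "weight") %in% names(components)))
    stop("'components' needs 'tau' and 'weight' columns")
  if (any(components$tau <= 0)) stop("all 'tau' must be positive")
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("'weight' must sum to 1")
  if (counts_total < 0) stop("'counts_total' must be non-negative")
  if (any(components$tau > window_ns))
    warning("component lifetime exceeds the repetition window: wrap-around ignored")
  if (!is.null(seed)) set.seed(seed)
  edges <- seq(0, window_ns, by = bin_ns)
  t_lo <- edges[-length(edges)]
  t_hi <- edges[-1]
  p <- rep(0, length(t_lo))
  for (k in seq_len(nrow(components))) {
    tau <- components$tau[k]
    p <- p + components$weight[k] *
      (exp(-t_lo / tau) - exp(-t_hi / tau)) / (1 - exp(-window_ns / tau))
  }
  p <- p / sum(p)
  counts <- if (counts_total == 0) rep(0L, length(p))
            else as.integer(stats::rmultinom(1, as.integer(counts_total), p))
  h <- decay_histogram(t_lo, counts)
  attr(h, "truth") <- list(components = components, counts_total = counts_total,
                           seed = seed)
  h
}

# combine per-acceptor efficiencies into a total via transfer-rate additivity:
# each acceptor contributes rate (E/(1-E))/tau_d; efficiencies never sum past 1
.rate_additive_total <- function(tau_d, efficiencies) {
  k_extra <- sum(efficiencies / (1 - efficiencies)) / tau_d
  tau_da <- 1 / (1 / tau_d + k_extra)
  1 - tau_da / tau_d
}

#' Simulate a trimer dilution (competition) series for FLIM
#'
#' Emulates co-transfecting a dual-labeled subunit with increasing amounts
#' of unlabeled wild-type subunit. Channels assemble as trimers whose other
#' two positions are labeled with probability equal to the labeled fraction
#' `x = a/(a+b)` for ratio `"a:b"`. A donor-bearing subunit always carries
#' its intra-subunit acceptor (efficiency `e_intra`); each labeled
#' neighbour adds an inter-subunit acceptor (`e_inter`); transfer to
#' acceptors on neighbouring channel complexes (crowding) contributes a
#' rate proportional to the labeled fraction, parameterized by
#' `e_crowding`, its efficiency at `x = 1`. Efficiencies combine by rate
#' additivity, so the donor lifetime of a configuration with acceptor set
#' `S` is `tau_d / (1 + sum_{j in S} E_j / (1 - E_j))`.
#'
#' The amplitude-weighted configuration mixture is summarized per cell as
#' the single-exponential lifetime a mono-exponential fitter reports — the
#' intensity-weighted mean `sum a_i tau_i^2 / sum a_i tau_i` — plus
#' Gaussian cell-to-cell noise. As `x -> 0` the apparent efficiency tends
#' to `e_intra`: the dilution plateau isolates single-subunit FRET.
#'
#' @param ratios character vector of `"a:b"` transfection ratios.
#' @param n_cells_per_ratio cells per ratio.
#' @param tau_donor donor-only lifetime, ns.
#' @param e_intra,e_inter,e_crowding per-geometry FRET efficiencies in
#'   `[0, 1)`.
#' @param tau_sd per-cell lifetime measurement SD, ns.
#' @param seed optional integer seed.
#' @return A [dilution_series()] with attribute `truth` (per-ratio apparent
#'   lifetime/efficiency and the generator parameters).
#' @export
simulate_trimer_mixture <- function(ratios = c("1:0", "1:1", "1:3", "1:7",
                                               "1:15", "1:31"),
                                    n_cells_per_ratio = 30, tau_donor = 4.06,
                                    e_intra = 0.25, e_inter = 0.05,
                                    e_crowding = 0, tau_sd = 0.05,
                                    seed = NULL) {
  effs <- c(e_intra, e_inter, e_crowding)
  if (any(effs < 0) || any(effs >= 1))
    stop("efficiencies must lie in [0, 1)")
  if (tau_donor <= 0) stop("'tau_donor' must be positive")
  if (!is.null(seed)) set.seed(seed)
  frac <- .ratio_fraction(ratios)
  if (any(frac < 0) || any(frac > 1)) stop("labeled fraction outside [0, 1]")
  apparent <- function(x) {
    # neighbour-label count is Binomial(2, x)
    taus <- amps <- numeric(3)
    for (k in 0:2) {
      e_list <- c(e_intra, rep(e_inter, k))
      if (e_crowding > 0 && x > 0) {
        # crowding rate scales with labeled fraction
        e_cr_x <- (x * e_crowding / (1 - e_crowding)) /
          (1 + x * e_crowding / (1 - e_crowding))
        e_list <- c(e_list, e_cr_x)
      }
      e_tot <- .rate_additive_total(tau_donor, e_list)
      taus[k + 1] <- tau_donor * (1 - e_tot)
      amps[k + 1] <- stats::dbinom(k, 2, x)
    }
    sum(amps * taus^2) / sum(amps * taus)
  }
  tau_app <- vapply(frac, apparent, 0)
  ratio_col <- rep(ratios, each = n_cells_per_ratio)
  tau_cells <- rep(tau_app, each = n_cells_per_ratio) +
    stats::rnorm(length(ratio_col), 0, tau_sd)
  out <- dilution_series(ratio_col, tau_cells, donor_only_tau = tau_donor)
  attr(out, "truth") <- list(ratios = ratios, labeled_fraction = frac,
                             tau_apparent = tau_app,
                             eff_apparent = 1 - tau_app / tau_donor,
                             e_intra = e_intra, e_inter = e_inter,
                             e_crowding = e_crowding, tau_sd = tau_sd,
                             seed = seed)
  out
}

#' Simulate a dual-channel pH-jump recording
#'
#' Two-channel fluorescence during a solution switch: during the
#' application window the acceptor/donor ratio relaxes exponentially (time
#' constant `tau_on`) toward a shift of `true_dfret_pct` percent, and each
#' channel can additionally carry an intrinsic pH artifact
#' (`donor_ph_pct`, `acceptor_ph_pct` percent at plateau) emulating
#' pH-sensitive fluorophores. After washout the signals relax back with the
#' same time constant. Multiplicative Gaussian noise is added per channel
#' per sample.
#'
#' A donor-only artifact of -12 percent with zero true FRET change shifts
#' the measured ratio by `100 * (1/0.88 - 1) = +13.6` percent — the
#' artifact pathway this generator exposes for control analyses.
#'
#' @param true_dfret_pct true percentage change of the acceptor/donor ratio
#'   at plateau.
#' @param donor_ph_pct,acceptor_ph_pct intrinsic per-channel artifacts, in
#'   percent at plateau.
#' @param noise_sd multiplicative noise SD per channel.
#' @param tau_on relaxation time constant of the response, s.
#' @param duration,dt trace length and sampling interval, s.
#' @param app_start,app_dur application onset and duration, s.
#' @param donor0,acceptor0 baseline channel intensities.
#' @param seed optional integer seed.
#' @return A [ph_jump_trace()] with attribute `truth`.
#' @export
simulate_ph_jump <- function(true_dfret_pct = -4.6, donor_ph_pct = 0,
                             acceptor_ph_pct = 0, noise_sd = 0.002,
                             tau_on = 0.3, duration = 30, dt = 0.01,
                             app_start = 10, app_dur = 2, donor0 = 1000,
                             acceptor0 = 400, seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (tau_on <= 0 || dt <= 0 || duration <= 0)
    stop("'tau_on', 'dt' and 'duration' must be positive")
  if (app_start < 0 || app_start + app_dur > duration)
    stop("application window must lie within the trace")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = dt)
  # relaxation envelope: 0 before, rises toward 1 during, decays after
  k <- numeric(length(t))
  during <- t >= app_start & t < app_start + app_dur
  after <- t >= app_start + app_dur
  k[during] <- 1 - exp(-(t[during] - app_start) / tau_on)
  k_end <- 1 - exp(-app_dur / tau_on)
  k[after] <- k_end * exp(-(t[after] - app_start - app_dur) / tau_on)
  donor <- donor0 * (1 + donor_ph_pct / 100 * k)
  acceptor <- acceptor0 * (1 + acceptor_ph_pct / 100 * k) *
    (1 + true_dfret_pct / 100 * k)
  if (noise_sd > 0) {
    donor <- donor * (1 + stats::rnorm(length(t), 0, noise_sd))
    acceptor <- acceptor * (1 + stats::rnorm(length(t), 0, noise_sd))
  }
  tr <- ph_jump_trace(t, donor, acceptor,
                      events = data.frame(start = app_start,
                                          stop = app_start + app_dur))
  attr(tr, "truth") <- list(true_dfret_pct = true_dfret_pct,
                            donor_ph_pct = donor_ph_pct,
                            acceptor_ph_pct = acceptor_ph_pct,
                            tau_on = tau_on, seed = seed)
  tr
}

#' Simulate a Gaussian-shaped spectrum
#'
#' Fixture generator for overlap-integral calculations: a Gaussian band
#' `peak * exp(-(l - center)^2 / (2 * width^2))` sampled on a wavelength
#' grid.
#'
#' @param center band centre, nm.
#' @param width Gaussian SD, nm (positive).
#' @param peak peak value (intensity or extinction); may be 0.
#' @param grid wavelength grid, nm (strictly increasing).
#' @return A [fluor_spectrum()].
#' @export
simulate_spectra <- function(center, width, peak, grid = seq(350, 700, by = 1)) {
  if (width <= 0) stop("'width' must be positive")
  if (peak < 0) stop("'peak' must be non-negative")
  fluor_spectrum(grid, peak * exp(-(grid - center)^2 / (2 * width^2)))
}
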