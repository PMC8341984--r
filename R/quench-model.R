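#' Donor/dark-acceptor pairing for two-plane quenching calculations
#'
#' Bundles the constants describing a membrane-tethered (or cytosolic) donor
#' fluorophore paired with a plane of dark acceptors such as dipicrylamine
#' (DPA): the Forster radius, the acceptor surface density, and the axial
#' distance the acceptor travels between the two membrane leaflets when the
#' voltage is stepped between extremes.
#'
#' At 5 uM bath DPA the membrane carries about 1.25e-4 molecules per square
#' Angstrom, the default here. The leaflet-to-leaflet displacement defaults
#' to 25 Angstrom, the accepted transmembrane travel of DPA.
#'
#' @param name label for the pairing (e.g. `"CFP/DPA"`).
#' @param r0 Forster radius in Angstrom; must be positive.
#' @param sigma acceptor surface density in molecules per Angstrom^2.
#' @param displacement leaflet-to-leaflet acceptor travel in Angstrom.
#' @return An object of class `donor_acceptor_system`.
#' @examples
#' cfp <- donor_acceptor_system("CFP/DPA", r0 = 47)
#' yfp <- donor_acceptor_system("YFP/DPA", r0 = 36.5)
#' @export
donor_acceptor_system <- function(name, r0, sigma = 1.25e-4, displacement = 25) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("'r0' must be a single positive number (Angstrom)")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number (molecules/A^2)")
  if (!is.numeric(displacement) || length(displacement) != 1L ||
      !is.finite(displacement) || displacement < 0)
    stop("'displacement' must be a single non-negative number (Angstrom)")
  structure(list(name = name, r0 = r0, sigma = sigma,
                 displacement = displacement),
            class = "donor_acceptor_system")
}

#' @export
print.donor_acceptor_system <- function(x, ...) {
  cat("Donor/acceptor system:", x$name, "\n")
  cat(sprintf("  R0 = %g A, sigma = %g /A^2, leaflet displacement = %g A\n",
              x$r0, x$sigma, x$displacement))
  invisible(x)
}

#' Single-pair FRET efficiency
#'
#' Transfer probability for one donor-acceptor pair separated by `d`,
#' `E = 1 / (1 + (d/r0)^6)`: half-maximal at the Forster radius and falling
#' with the sixth power of distance.
#'
#' @param d donor-acceptor separation in Angstrom (vectorised, `>= 0`).
#' @param r0 Forster radius in Angstrom (positive scalar).
#' @return Transfer probabilities in `[0, 1]`.
#' @examples
#' pair_efficiency(47, 47)      # 0.5 at the Forster radius
#' pair_efficiency(94, 47)      # 1/65 at twice the Forster radius
#' @export
pair_efficiency <- function(d, r0) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("'r0' must be a single positive number")
  if (any(!is.finite(d)) || any(d < 0))
    stop("'d' must be finite and non-negative")
  1 / (1 + (d / r0)^6)
}

#' Tail integral of the planar quenching kernel
#'
#' Evaluates `I(a) = integral from a to Inf of du / (1 + u^3)` via the
#' closed-form antiderivative. This is the kernel appearing in the exponent
#' of the unquenched fraction for a donor facing an infinite plane of
#' acceptors; `I(0) = 2*pi/(3*sqrt(3))`.
#'
#' @param lower lower limit(s) of integration, `>= 0` (vectorised).
#' @return Value(s) of the tail integral.
#' @export
quench_integral <- function(lower) {
  if (any(!is.finite(lower)) || any(lower < 0))
    stop("'lower' must be finite and non-negative")
  anti <- function(u) log((u + 1)^2 / (u^2 - u + 1)) / 6 +
    atan((2 * u - 1) / sqrt(3)) / sqrt(3)
  pi / (2 * sqrt(3)) - anti(lower)
}

#' Unquenched donor fraction facing a plane of acceptors
#'
#' Fraction of donor fluorescence surviving quenching by an infinite plane of
#' acceptors at surface density `sigma`, for a donor an axial distance `ra`
#' from the plane:
#' `P = exp(-sigma * pi * R0^2 * I(ra^2 / R0^2))`, with `I` the tail integral
#' of `1/(1+u^3)` (see [quench_integral()]). The `"inner"` leaflet is the
#' acceptor plane nearest the donor (fully populated at depolarized
#' extremes); the `"outer"` leaflet sits `displacement` Angstrom further
#' (hyperpolarized extremes).
#'
#' @param ra axial donor-to-inner-leaflet distance(s), Angstrom, `>= 0`.
#' @param system a [donor_acceptor_system()].
#' @param leaflet `"inner"` or `"outer"`.
#' @return Unquenched fractions in `[0, 1]`; exactly 1 when `sigma` is 0.
#' @examples
#' cfp <- donor_acceptor_system("CFP/DPA", r0 = 47)
#' unquenched_fraction(24, cfp, "inner")   # about 0.44
#' @export
unquenched_fraction <- function(ra, system, leaflet = c("inner", "outer")) {
  leaflet <- match.arg(leaflet)
  stopifnot(inherits(system, "donor_acceptor_system"))
  if (any(!is.finite(ra)) || any(ra < 0))
    stop("'ra' must be finite and non-negative")
  d <- if (leaflet == "outer") ra + system$displacement else ra
  exp(-system$sigma * pi * system$r0^2 * quench_integral((d / system$r0)^2))
}

#' Monte-Carlo oracle for planar quenching
#'
#' Brute-force check of the continuum unquenched-fraction formula. Each
#' replicate draws a Poisson number of acceptors uniformly over a disc of
#' radius `disc_radius` centred under the donor and computes the product of
#' per-pair survival probabilities `prod(1 - E_i)`.
#'
#' @param ra axial distance to the acceptor plane, Angstrom.
#' @param system a [donor_acceptor_system()]; the disc is populated at the
#'   system's `sigma`, with the plane at `ra` (no leaflet displacement —
#'   pass `ra + displacement` for the far plane).
#' @param disc_radius disc radius in Angstrom; should be at least `10 * r0`
#'   or a truncation-bias warning is raised.
#' @param replicates number of Monte-Carlo replicates.
#' @param seed optional integer seed for reproducibility.
#' @return List with `estimate`, `se` (standard error of the mean) and
#'   `replicates`.
#' @export
mc_quench_oracle <- function(ra, system, disc_radius = 10 * system$r0,
                             replicates = 1e5, seed = NULL) {
  stopifnot(inherits(system, "donor_acceptor_system"))
  if (!is.numeric(ra) || length(ra) != 1L || !is.finite(ra) || ra < 0)
    stop("'ra' must be a single non-negative number")
  if (replicates < 1) stop("'replicates' must be at least 1")
  if (disc_radius < 10 * system$r0)
    warning("disc_radius < 10 * r0: far-field truncation may bias the estimate")
  if (!is.null(seed)) set.seed(seed)
  replicates <- as.integer(replicates)
  lambda <- system$sigma * pi * disc_radius^2
  n <- stats::rpois(replicates, lambda)
  if (sum(n) == 0) return(list(estimate = 1, se = 0, replicates = replicates))
  idx <- rep.int(seq_len(replicates), n)
  r <- disc_radius * sqrt(stats::runif(sum(n)))
  e <- pair_efficiency(sqrt(ra^2 + r^2), system$r0)
  logp <- rep(0, replicates)
  agg <- rowsum(log1p(-e), idx)
  logp[as.integer(rownames(agg))] <- agg[, 1L]
  p <- exp(logp)
  list(estimate = mean(p),
       se = stats::sd(p) / sqrt(replicates),
       replicates = replicates)
}

#' Theoretical voltage-dependent quenching curve
#'
#' Computes, over a grid of axial distances, the unquenched fractions with
#' the acceptor plane at the inner leaflet (depolarized limit, `p_inner`) and
#' outer leaflet (hyperpolarized limit, `p_outer`), and the normalized
#' voltage-dependent quenching
#' `dff_norm = (p_outer - p_inner) / p_outer`,
#' i.e. the fractional fluorescence change referenced to the
#' least-quenched (hyperpolarized) state.
#'
#' For a CFP-like donor (R0 = 47 A) the curve is humped, nearly flat between
#' about 21 and 25 A; for a YFP-like donor (R0 = 36.5 A) the hump sits lower,
#' near 15 A, and the curve falls off monotonically beyond it.
#'
#' @param system a [donor_acceptor_system()].
#' @param grid strictly increasing, non-negative axial distance grid in
#'   Angstrom. The default covers 0-80 A at 0.25 A resolution.
#' @return A data frame of class `quench_curve` with columns `distance_A`,
#'   `p_inner`, `p_outer`, `dff_norm`; the system is stored as an attribute.
#' @examples
#' cfp <- donor_acceptor_system("CFP/DPA", r0 = 47)
#' crv <- quench_curve(cfp)
#' peak_distance(crv)
#' @export
quench_curve <- function(system, grid = seq(0, 80, by = 0.25)) {
  stopifnot(inherits(system, "donor_acceptor_system"))
  if (length(grid) == 0) stop("'grid' must be non-empty")
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("'grid' must be finite and non-negative")
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing")
  p_in <- unquenched_fraction(grid, system, "inner")
  p_out <- unquenched_fraction(grid, system, "outer")
  dff <- ifelse(p_out > 0, (p_out - p_in) / p_out, 0)
  out <- data.frame(distance_A = grid, p_inner = p_in, p_outer = p_out,
                    dff_norm = dff)
  class(out) <- c("quench_curve", "data.frame")
  attr(out, "system") <- system
  out
}

#' Location of the quenching-curve maximum
#'
#' @param curve a [quench_curve()].
#' @return The grid distance (Angstrom) at which `dff_norm` is maximal.
#' @export
peak_distance <- function(curve) {
  stopifnot(inherits(curve, "quench_curve"))
  curve$distance_A[which.max(curve$dff_norm)]
}

# continuous forward model dff_norm(x) for a system (used by the inverter)
.dff_forward <- function(x, system) {
  po <- unquenched_fraction(x, system, "outer")
  (po - unquenched_fraction(x, system, "inner")) / po
}

#' Invert measured quenching to axial distance candidates
#'
#' Finds every axial distance at which the theoretical normalized quenching
#' curve equals a measured value. Grid-bracketed crossings are refined by
#' bisection on the continuous forward model. For a humped (CFP-like) curve
#' a value below the peak has two solutions, one on each limb; both are
#' returned, labelled `"ascending"` and `"descending"` — selecting between
#' them requires external evidence and is deliberately left to the caller.
#'
#' A fluorescent-protein chromophore sits roughly 10 Angstrom from the
#' attachment point (the beta-barrel radius); passing
#' `chromophore_offset = 10` subtracts that much from each candidate to
#' report the position of the tagged residue rather than the chromophore.
#' The offset is off by default since it is an assumption, not a
#' measurement.
#'
#' @param dff_measured measured normalized quenching, in `[0, 1]`.
#' @param curve a [quench_curve()] whose grid covers the solutions.
#' @param tolerance bisection tolerance on `dff_norm` units.
#' @param chromophore_offset Angstrom subtracted from each candidate.
#' @return An object of class `distance_estimate`: list with `candidates`
#'   (Angstrom, possibly empty when the measurement exceeds the curve
#'   maximum), `branch` labels, `input_dff`, `chromophore_offset`, and
#'   `no_solution` flag.
#' @export
invert_distance <- function(dff_measured, curve, tolerance = 1e-6,
                            chromophore_offset = 0) {
  stopifnot(inherits(curve, "quench_curve"))
  if (!is.numeric(dff_measured) || length(dff_measured) != 1L ||
      !is.finite(dff_measured) || dff_measured < 0)
    stop("'dff_measured' must be a single non-negative number")
  system <- attr(curve, "system")
  g <- curve$distance_A
  f <- curve$dff_norm - dff_measured
  cand <- numeric(0)
  branch <- character(0)
  peak_i <- which.max(curve$dff_norm)
  if (dff_measured > max(curve$dff_norm) + tolerance) {
    # explicitly not an error: measurement above the attainable maximum
    res <- list(candidates = numeric(0), branch = character(0),
                input_dff = dff_measured,
                chromophore_offset = chromophore_offset, no_solution = TRUE)
    class(res) <- "distance_estimate"
    return(res)
  }
  if (abs(max(curve$dff_norm) - dff_measured) <= tolerance) {
    cand <- g[peak_i]
    branch <- "peak"
  } else {
    for (i in seq_len(length(g) - 1L)) {
      if (f[i] == 0 || f[i] * f[i + 1L] < 0) {
        lo <- g[i]; hi <- g[i + 1L]
        flo <- .dff_forward(lo, system) - dff_measured
        while (hi - lo > 1e-9 &&
               abs(.dff_forward((lo + hi) / 2, system) - dff_measured) > tolerance) {
          mid <- (lo + hi) / 2
          fm <- .dff_forward(mid, system) - dff_measured
          if (fm == 0) { lo <- hi <- mid; break }
          if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        }
        x <- (lo + hi) / 2
        cand <- c(cand, x)
        branch <- c(branch, if (x <= g[peak_i]) "ascending" else "descending")
      }
    }
    # de-duplicate crossings landing on shared grid nodes
    if (length(cand) > 1L) {
      keep <- c(TRUE, diff(cand) > 1e-6)
      cand <- cand[keep]; branch <- branch[keep]
    }
  }
  res <- list(candidates = cand - chromophore_offset, branch = branch,
              input_dff = dff_measured,
              chromophore_offset = chromophore_offset,
              no_solution = length(cand) == 0L)
  class(res) <- "distance_estimate"
  res
}

#' @export
print.distance_estimate <- function(x, ...) {
  if (x$no_solution) {
    cat(sprintf("No axial distance reproduces dff_norm = %.4g (above curve maximum)\n",
                x$input_dff))
  } else {
    cat(sprintf("Axial distance candidates for dff_norm = %.4g:\n", x$input_dff))
    for (i in seq_along(x$candidates))
      cat(sprintf("  %.2f A (%s limb)\n", x$candidates[i], x$branch[i]))
    if (x$chromophore_offset != 0)
      cat(sprintf("  (chromophore offset of %g A subtracted)\n",
                  x$chromophore_offset))
  }
  invisible(x)
}
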