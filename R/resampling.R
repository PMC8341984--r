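#' Permutation / randomization test for a two-group difference
#'
#' Tests the difference in means (or medians) between two groups. Monte
#' Carlo mode draws `iterations` random relabelings (unpaired) or random
#' within-pair sign flips (paired) and reports the two-sided add-one
#' p-value `(1 + #(|T_perm| >= |T_obs|)) / (1 + iterations)`, which can
#' never be exactly zero. With `exact = TRUE` the full permutation
#' distribution is enumerated instead (all label splits, or all `2^n` sign
#' vectors) and the p-value is the exact tail fraction without the add-one
#' rule.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values;
#'   equal lengths when `paired = TRUE`.
#' @param statistic `"mean"` (default) or `"median"` difference.
#' @param iterations Monte-Carlo iterations (>= 1); 1e5 by default.
#' @param seed optional integer seed (Monte-Carlo mode).
#' @param paired flip within-pair signs instead of shuffling labels.
#' @param exact enumerate the full permutation distribution. Unpaired
#'   enumeration requires `choose(n, n_a) <= 2e5`; paired requires
#'   `n <= 16`.
#' @return List of class `permutation_result`: `statistic_observed`,
#'   `p_value`, `iterations` (number of permutations actually evaluated),
#'   `seed`, `exact`, `paired`.
#' @examples
#' set.seed(1)
#' permutation_test(rnorm(8), rnorm(8, 1), iterations = 1000, seed = 2)
#' @export
permutation_test <- function(group_a, group_b, statistic = c("mean", "median"),
                             iterations = 1e5, seed = NULL, paired = FALSE,
                             exact = FALSE) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "mean") mean else stats::median
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal group lengths")
  if (!exact && iterations < 1) stop("'iterations' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  tol <- 1e-12

  if (paired) {
    d <- group_a - group_b
    n <- length(d)
    t_obs <- stat_fun(d)
    if (exact) {
      if (n > 16L) stop("exact paired enumeration limited to n <= 16")
      total <- 2^n
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      t_perm <- apply(signs * rep(d, each = total), 1, stat_fun)
      p <- mean(abs(t_perm) >= abs(t_obs) - tol)
      n_perm <- total
    } else {
      iterations <- as.integer(iterations)
      t_perm <- vapply(seq_len(iterations), function(i)
        stat_fun(d * sample(c(-1, 1), n, replace = TRUE)), 0)
      p <- (1 + sum(abs(t_perm) >= abs(t_obs) - tol)) / (1 + iterations)
      n_perm <- iterations
    }
  } else {
    pool <- c(group_a, group_b)
    n_a <- length(group_a)
    n <- length(pool)
    t_obs <- stat_fun(group_a) - stat_fun(group_b)
    if (exact) {
      n_comb <- choose(n, n_a)
      if (n_comb > 2e5) stop("exact unpaired enumeration limited to choose(n, n_a) <= 2e5")
      idx <- utils::combn(n, n_a)
      t_perm <- apply(idx, 2, function(s) stat_fun(pool[s]) - stat_fun(pool[-s]))
      p <- mean(abs(t_perm) >= abs(t_obs) - tol)
      n_perm <- n_comb
    } else {
      iterations <- as.integer(iterations)
      t_perm <- vapply(seq_len(iterations), function(i) {
        s <- sample.int(n, n_a)
        stat_fun(pool[s]) - stat_fun(pool[-s])
      }, 0)
      p <- (1 + sum(abs(t_perm) >= abs(t_obs) - tol)) / (1 + iterations)
      n_perm <- iterations
    }
  }
  structure(list(statistic_observed = t_obs, p_value = p,
                 iterations = n_perm, seed = seed, exact = exact,
                 paired = paired, statistic = statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s %s permutation test: T = %.4g, p = %.4g (%s, %d permutations)\n",
              if (x$paired) "Paired" else "Unpaired", x$statistic,
              x$statistic_observed, x$p_value,
              if (x$exact) "exact" else "Monte Carlo", x$iterations))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, adjusts the i-th smallest to
#' `max_{j <= i} (m - j + 1) * p_(j)`, caps at 1, and restores the input
#' order. Adjusted values are always `>=` the raw values and preserve their
#' ordering.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p_values[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test of `before` vs `after`. Zero differences are
#' dropped (with a warning); ranks of the absolute differences (midranks for
#' ties) form the statistic `W+`, whose exact null distribution is built by
#' dynamic programming over all `2^n` sign assignments — exact for any `n`,
#' including tied ranks. The two-sided p-value is `2 * min(P(W <= w),
#' P(W >= w))`, capped at 1.
#'
#' @param before,after paired observations.
#' @return List of class `signed_rank_result`: `statistic` (W+), `p_value`,
#'   `n_used`, `n_zero`, and `flagged` (TRUE when fewer than 5 non-zero
#'   differences remain).
#' @export
wilcoxon_signed_rank <- function(before, after) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length")
  d <- after - before
  n_zero <- sum(d == 0)
  if (n_zero > 0) warning(sprintf("%d zero difference(s) dropped", n_zero))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          n_used = 0L, n_zero = n_zero, flagged = TRUE),
                     class = "signed_rank_result"))
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  # exact null distribution of W+ by DP over doubled (integer) ranks
  r2 <- as.integer(round(2 * r))
  dist <- c(1)                       # probability weights over W*2 = 0..sum(r2)
  for (rk in r2) {
    shifted <- c(rep(0, rk), dist)
    dist <- c(dist, rep(0, rk)) + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):length(dist)])
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(statistic = w_obs, p_value = p, n_used = n,
                 n_zero = n_zero, flagged = n < 5L),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  if (is.na(x$p_value)) {
    cat("Wilcoxon signed-rank: degenerate (all differences zero)\n")
  } else {
    cat(sprintf("Wilcoxon signed-rank: W+ = %g, exact two-sided p = %.4g (n = %d)%s\n",
                x$statistic, x$p_value, x$n_used,
                if (x$flagged) " [flagged: n < 5]" else ""))
  }
  invisible(x)
}
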