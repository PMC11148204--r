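#' Estimated moment-ratio matrix
#'
#' Symmetric matrix of estimated moment ratios
#' `B[k, l] = E[s_k s_l s_ref] / (E[s_k s_ref] E[s_l s_ref])` over all pairs
#' of non-reference components, with the signal-to-noise cutoff applied
#' entrywise.  Under a valid modularization, rows of `B` indexed by one
#' module agree outside the module.
#'
#' @param s A centred `sample_matrix` with at least 4 components.
#' @param theta Signal-to-noise cutoff (default 5).
#' @return A `b_matrix` object: `entries` (symmetric `(d-1) x (d-1)` matrix,
#'   `NA` diagonal) and `cutoff_mask` (which entries were zeroed).
#' @export
b_matrix <- function(s, theta = 5) {
  d <- s$d
  if (d < 4L) stop("need at least 4 components")
  pairs <- ratio_pairs(d)
  ests <- lapply(seq_len(nrow(pairs)), function(i) {
    nested_products(s, pairs$k[i], pairs$l[i])
  })
  rv <- ratio_vector(ests, theta)
  B <- matrix(NA_real_, d - 1L, d - 1L)
  mask <- matrix(FALSE, d - 1L, d - 1L)
  for (i in seq_len(nrow(pairs))) {
    k <- pairs$k[i]; l <- pairs$l[i]
    B[k, l] <- B[l, k] <- rv$b_hat[i]
    mask[k, l] <- mask[l, k] <- !rv$kept[i]
  }
  structure(list(entries = B, cutoff_mask = mask, theta = theta),
            class = "b_matrix")
}

#' Test statistic for a candidate modularization
#'
#' Within-group dispersion of the moment ratios, inverse-variance weighted:
#' `T = 1/2 sum_v b_v^2 / Sigma_vv - 1/2 sum_c (sum_{l in X_c} b_l / Sigma_ll)^2
#'  / (sum_{l in X_c} 1 / Sigma_ll)`, with `1/Inf = 0`.  Singleton sets cancel
#' exactly, so only constrained sets contribute.  Under the candidate
#' modularization, `T` is approximately gamma distributed with shape `zeta`
#' and scale 1.
#'
#' @param b Numeric moment-ratio vector (or a `ratio_vector`).
#' @param sigma Ratio covariance matrix (or a `ratio_covariance`); diagonal
#'   entries may be `Inf`.
#' @param family An `index_set_family` partitioning the ratio indices.
#' @return The statistic `T >= 0`.
#' @export
test_statistic <- function(b, sigma, family) {
  if (inherits(b, "ratio_vector")) b <- b$b_hat
  if (inherits(sigma, "ratio_covariance")) sigma <- sigma$sigma
  dv <- diag(sigma)
  stopifnot(length(b) == length(dv), family$d_X0 == length(b))
  w <- ifelse(is.infinite(dv), 0, 1 / dv)
  t1 <- 0.5 * sum(b^2 * w)
  t2 <- 0
  for (set in family$sets) {
    sw <- sum(w[set])
    if (sw > 0) t2 <- t2 + (sum(b[set] * w[set]))^2 / sw
  }
  max(t1 - 0.5 * t2, 0)
}

#' Conservativeness scaling for correlated moment ratios
#'
#' The largest eigenvalue of the correlation-normalized restriction of the
#' ratio covariance to indices in constrained sets: the diagonal scaling has
#' `1/sqrt(Sigma_vv)` for ratios in a set of size greater than one and 0 for
#' singletons and cut-off ratios (an infinite variance contributes 0).
#' Scaling the covariance by this factor keeps the gamma test conservative
#' when ratios are correlated.  With no constrained set the test is vacuous
#' and the factor is 1.
#'
#' @param sigma Ratio covariance matrix (or `ratio_covariance`).
#' @param family An `index_set_family`.
#' @return The scaling factor `lambda_max`.
#' @export
lambda_max <- function(sigma, family) {
  if (inherits(sigma, "ratio_covariance")) sigma <- sigma$sigma
  constrained <- unlist(family$sets[vapply(family$sets, length, integer(1)) > 1L])
  if (length(constrained) == 0L) return(1)
  dv <- diag(sigma)
  g <- numeric(length(dv))
  use <- intersect(constrained, which(is.finite(dv) & dv > 0))
  g[use] <- 1 / sqrt(dv[use])
  if (all(g == 0)) return(1)
  M <- sigma * outer(g, g)
  M[g == 0, ] <- 0
  M[, g == 0] <- 0
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Minimal admissible nominal significance level
#'
#' Accounts for the possibility that some correlations with the reference
#' component are zero, in which case the cutoff may misclassify ratios:
#' `alpha_min = 1 - erf((theta - 1)/sqrt(2))^d_X0 * erf(6/sqrt(2))^d_X0`.
#' For cutoffs `theta <= 1` the bound is vacuous and 0 is returned.
#'
#' @param d_X0 Total number of moment ratios.
#' @param theta Signal-to-noise cutoff.
#' @return `alpha_min` in `[0, 1)`.
#' @export
alpha_min <- function(d_X0, theta = 5) {
  if (theta <= 1) return(0)
  if (d_X0 == 0) return(0)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  1 - erf((theta - 1) / sqrt(2))^d_X0 * erf(6 / sqrt(2))^d_X0
}

#' Upper-tail gamma p-value of the test statistic
#'
#' One-sided right tail of the gamma distribution with shape `zeta` and scale
#' 1.  For `zeta = 0` the statistic is identically 0 and the p-value is 1.
#'
#' @param T_stat Observed statistic, nonnegative.
#' @param zeta Shape parameter (degrees of freedom), nonnegative.
#' @return Upper-tail probability.
#' @export
gamma_pvalue <- function(T_stat, zeta) {
  stopifnot(T_stat >= 0, zeta >= 0)
  if (zeta == 0) return(1)
  stats::pgamma(T_stat, shape = zeta, scale = 1, lower.tail = FALSE)
}

#' Reject/retain decision with multiple-testing correction
#'
#' Rejects when `p <= alpha_Gamma / n_hypotheses` with
#' `alpha_Gamma = (alpha_star - alpha_min) / (1 - alpha_min)`.  The overall
#' level `alpha_star` must exceed `alpha_min`.
#'
#' @param p Gamma-tail p-value.
#' @param alpha_star Nominal overall significance level.
#' @param alpha_min Minimal admissible nominal level (see [alpha_min()]).
#' @param n_hypotheses Number of candidates tested on the same samples.
#' @return Logical: reject?
#' @export
decide <- function(p, alpha_star = 0.01, alpha_min = 0, n_hypotheses = 1L) {
  stopifnot(alpha_star > 0, alpha_star < 1, n_hypotheses >= 1)
  if (alpha_star <= alpha_min) {
    stop("nominal level below minimal level; increase alpha or reduce the number of ratios")
  }
  alpha_gamma <- (alpha_star - alpha_min) / (1 - alpha_min)
  p <= alpha_gamma / n_hypotheses
}

#' Fit the moment-ratio vector and covariance once for a sample matrix
#'
#' Computes the paired-sample estimates for all component pairs, the ratio
#' vector with cutoff, and the ratio covariance.  The result can be reused
#' across many candidate modularizations tested on the same samples.
#'
#' @param s Centred `sample_matrix`.
#' @param theta Signal-to-noise cutoff.
#' @param lambda_mode `"corrected"` or `"asymptotic"`.
#' @return List with `estimates`, `rv`, `rc`, `d`.
#' @export
moment_ratio_fit <- function(s, theta = 5,
                             lambda_mode = c("corrected", "asymptotic")) {
  lambda_mode <- match.arg(lambda_mode)
  pairs <- ratio_pairs(s$d)
  ests <- lapply(seq_len(nrow(pairs)), function(i) {
    nested_products(s, pairs$k[i], pairs$l[i])
  })
  rv <- ratio_vector(ests, theta)
  rc <- ratio_covariance(ests, rv, lambda_mode)
  list(estimates = ests, rv = rv, rc = rc, d = s$d)
}

#' Test a candidate modularization on recorded samples
#'
#' Full pipeline: paired-sample moment-ratio estimation, equality index sets
#' of the candidate, conservativeness scaling, gamma-tail p-value and the
#' corrected decision rule.
#'
#' @param s Centred `sample_matrix` (or a precomputed [moment_ratio_fit()]).
#' @param m A `modularization`.
#' @param theta Signal-to-noise cutoff (default 5).
#' @param lambda_mode `"corrected"` (default) or `"asymptotic"`.
#' @param alpha_star Overall nominal significance level (default 0.01).
#' @param n_hypotheses Number of candidates tested on the same samples.
#' @param apply_lambda_max Scale the covariance by [lambda_max()]?
#' @return A `mod_test` object with `statistic`, `zeta`, `p_value`,
#'   `lambda_max`, `alpha_min`, `reject`, `family`, `label`.
#' @export
test_modularization <- function(s, m, theta = 5,
                                lambda_mode = c("corrected", "asymptotic"),
                                alpha_star = 0.01, n_hypotheses = 1L,
                                apply_lambda_max = TRUE) {
  lambda_mode <- match.arg(lambda_mode)
  fit <- if (inherits(s, "sample_matrix")) {
    moment_ratio_fit(s, theta, lambda_mode)
  } else s
  f <- index_sets(m, fit$d)
  lm <- if (apply_lambda_max) lambda_max(fit$rc, f) else 1
  T_stat <- test_statistic(fit$rv$b_hat, lm * fit$rc$sigma, f)
  zeta <- degrees_of_freedom(f)
  p <- gamma_pvalue(T_stat, zeta)
  am <- alpha_min(fit$rv$d_X0, theta)
  rej <- decide(p, alpha_star, am, n_hypotheses)
  structure(
    list(statistic = T_stat, zeta = zeta, p_value = p, lambda_max = lm,
         alpha_min = am, reject = rej, family = f, label = m$label,
         theta = theta, lambda_mode = lambda_mode),
    class = "mod_test"
  )
}

#' @export
print.mod_test <- function(x, ...) {
  cat(sprintf("modularization test %s: T = %.4g, zeta = %.2g, p = %.3g, %s\n",
              x$label, x$statistic, x$zeta, x$p_value,
              if (x$reject) "REJECTED" else "retained"))
  invisible(x)
}

#' Test a set of candidate modularizations on the same samples
#'
#' Estimates the moment ratios once and evaluates every candidate, applying
#' the multiple-testing correction with `n_hypotheses` defaulting to the
#' number of candidates.
#'
#' @param s Centred `sample_matrix`.
#' @param candidates List of `modularization` objects (for example from
#'   [enumerate_candidates()]).
#' @param n_hypotheses Number of hypotheses for the correction; defaults to
#'   `length(candidates)`.
#' @inheritParams test_modularization
#' @return Data frame with one row per candidate: `label`, `statistic`,
#'   `zeta`, `lambda_max`, `alpha_min`, `p_value`, `reject`.
#' @export
test_candidates <- function(s, candidates, theta = 5,
                            lambda_mode = c("corrected", "asymptotic"),
                            alpha_star = 0.01, n_hypotheses = NULL,
                            apply_lambda_max = TRUE) {
  lambda_mode <- match.arg(lambda_mode)
  if (is.null(n_hypotheses)) n_hypotheses <- length(candidates)
  fit <- moment_ratio_fit(s, theta, lambda_mode)
  rows <- lapply(candidates, function(m) {
    r <- test_modularization(fit, m, theta, lambda_mode, alpha_star,
                             n_hypotheses, apply_lambda_max)
    data.frame(label = r$label, statistic = r$statistic, zeta = r$zeta,
               lambda_max = r$lambda_max, alpha_min = r$alpha_min,
               p_value = r$p_value, reject = r$reject,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-2 residual of a population moment matrix
#'
#' Population-level oracle for the existence of a binary interface variable:
#' with monomial sequences `P_n` (inside the module) and `Q_m` (outside), the
#' moment matrix `M[n, m] = E[P_n Q_m]` has rank at most 2, i.e. every entry
#' is reproduced from the leading 2 x 2 block:
#' `E[P_n Q_m] = sum_{i,j} E[P_n Q_j] (M_2x2^-1)_{ji} E[P_i Q_m]`.
#' Returns the maximum absolute deviation from this identity.
#'
#' @param M Numeric matrix of moments with an invertible leading 2 x 2 block.
#' @return Maximum absolute residual (0 up to round-off when a binary
#'   interface variable exists).
#' @export
rank2_residual <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L || ncol(M) < 2L) stop("need at least a 2 x 2 moment matrix")
  lead <- M[1:2, 1:2]
  if (abs(det(lead)) < .Machine$double.eps * max(abs(lead))^2 * 4 ||
      det(lead) == 0) {
    stop("condition inapplicable: singular leading block")
  }
  R <- M - M[, 1:2] %*% solve(lead, M[1:2, ])
  max(abs(R))
}
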