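#' Centre a raw sample matrix
#'
#' Normalizes every observable component to zero mean, which is the form
#' required by all moment-ratio estimators in this package.  Samples are rows,
#' components are columns, and the reference component is by convention the
#' last column.  The paired-sample estimators assume an even number of
#' samples; if the input has an odd number of rows the last row is dropped
#' with a warning.
#'
#' @param raw Numeric matrix, one row per sample, one column per component
#'   (at least 3 components).
#' @return A `sample_matrix` object: a list with elements `values` (the
#'   centred matrix), `d` (component count), `n` (sample count, even),
#'   `centered` and `dropped`.
#' @examples
#' s <- center_samples(matrix(rnorm(40), 10, 4))
#' colMeans(s$values)
#' @export
center_samples <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("sample matrix must be numeric")
  if (nrow(raw) < 2L) stop("insufficient samples")
  if (ncol(raw) < 3L) stop("need at least 3 components")
  dropped <- 0L
  if (nrow(raw) %% 2L == 1L) {
    warning("odd number of samples; dropping the last sample")
    raw <- raw[-nrow(raw), , drop = FALSE]
    dropped <- 1L
  }
  if (nrow(raw) < 4L) stop("insufficient samples")
  vals <- sweep(raw, 2L, colMeans(raw))
  structure(
    list(values = vals, d = ncol(vals), n = nrow(vals),
         centered = TRUE, dropped = dropped),
    class = "sample_matrix"
  )
}

#' Wrap an already-centred matrix as a sample matrix
#'
#' Low-level constructor that trusts its input; useful for worked examples and
#' oracles where samples are constructed by hand.
#'
#' @param values Numeric matrix, samples in rows, zero-mean columns.
#' @return A `sample_matrix`.
#' @export
as_sample_matrix <- function(values) {
  values <- as.matrix(values)
  structure(
    list(values = values, d = ncol(values), n = nrow(values),
         centered = TRUE, dropped = 0L),
    class = "sample_matrix"
  )
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("sample_matrix: %d samples x %d components (reference = column %d)\n",
              x$n, x$d, x$d))
  invisible(x)
}

#' Ratio index of a component pair
#'
#' Maps a pair of non-reference components `k < l` onto the linear index `v`
#' of the corresponding moment ratio, bijectively onto
#' `1..(d-1)(d-2)/2`.  Vectorized over `k` and `l`.
#'
#' @param k,l Component indices with `1 <= k < l <= d - 1`.
#' @param d Total number of components (the reference component is `d`).
#' @return Integer ratio index (or vector thereof).
#' @export
vec_index <- function(k, l, d) {
  if (length(k) != length(l)) stop("invalid pair")
  if (any(k < 1L | k >= l | l >= d)) stop("invalid pair")
  as.integer((d - 3) * (d - 2) / 2 - (d - 2 - k) * (d - 1 - k) / 2 + l - 1)
}

#' All component pairs in ratio-index order
#'
#' @param d Total number of components.
#' @return Data frame with columns `k`, `l`, `v`, sorted by `v`.
#' @export
ratio_pairs <- function(d) {
  if (d < 3L) stop("need at least 3 components")
  kl <- which(upper.tri(matrix(0, d - 1, d - 1)), arr.ind = TRUE)
  out <- data.frame(k = kl[, 1L], l = kl[, 2L])
  out$v <- vec_index(out$k, out$l, d)
  out[order(out$v), , drop = FALSE]
}

#' Paired-sample moment products for nested modularizations
#'
#' For a pair of non-reference components `(k, l)` returns the per-term
#' products whose means estimate the numerator `E[s_k s_l s_d]` (odd samples
#' only) and the denominator `E[s_k s_d] E[s_l s_d]` (product across the two
#' halves of the recording).  The acquisition order of the samples is used
#' verbatim so that results are reproducible bit for bit.
#'
#' @param s A centred `sample_matrix`.
#' @param k,l Component indices, `k < l < d`.
#' @return A `pair_moments` object with elements `v`, `k`, `l`, `b1`, `b2` and
#'   the `n/2 x 2` matrix `phi` of per-term products.
#' @export
nested_products <- function(s, k, l) {
  stopifnot(inherits(s, "sample_matrix"), isTRUE(s$centered))
  d <- s$d
  if (!(k >= 1 && k < l && l < d)) stop("invalid pair")
  n <- s$n
  h <- n %/% 2L
  x <- s$values
  odd <- seq.int(1L, n, by = 2L)
  phi1 <- x[odd, k] * x[odd, l] * x[odd, d]
  phi2 <- x[seq_len(h), k] * x[seq_len(h), d] *
    x[h + seq_len(h), l] * x[h + seq_len(h), d]
  phi <- cbind(phi1, phi2, deparse.level = 0)
  structure(
    list(v = vec_index(k, l, d), k = k, l = l,
         b1 = mean(phi1), b2 = mean(phi2), phi = phi, scheme = "nested"),
    class = "pair_moments"
  )
}

#' Moment products for single functional modules
#'
#' The simplest moments for testing a single functional module: one product
#' per sample, numerator `E[s_k s_l]` and denominator `E[s_k s_ref]`.  The
#' regulatory-network application estimates the two module ratios on disjoint
#' sample halves, which is supported through the `samples` argument.
#'
#' @param s A centred `sample_matrix`.
#' @param k Component inside the module whose ratio is estimated.
#' @param l Component outside the module (numerator partner).
#' @param ref Reference component (denominator partner).
#' @param samples Optional integer vector of sample indices to use
#'   (default: all samples).
#' @return A `pair_moments` object.
#' @export
single_module_products <- function(s, k, l, ref, samples = NULL) {
  stopifnot(inherits(s, "sample_matrix"), isTRUE(s$centered))
  if (length(unique(c(k, l, ref))) != 3L) stop("k, l and ref must be distinct")
  if (is.null(samples)) samples <- seq_len(s$n)
  x <- s$values
  phi <- cbind(x[samples, k] * x[samples, l],
               x[samples, k] * x[samples, ref], deparse.level = 0)
  structure(
    list(v = NA_integer_, k = k, l = l, ref = ref,
         b1 = mean(phi[, 1L]), b2 = mean(phi[, 2L]), phi = phi,
         scheme = "single"),
    class = "pair_moments"
  )
}

#' Sample covariance block of two per-term product matrices
#'
#' @param e_v,e_w `pair_moments` objects with the same number of per-term rows.
#' @return The 2 x 2 covariance block between the product columns of `e_v`
#'   and `e_w` (denominator `n - 1`).
#' @export
product_covariance <- function(e_v, e_w = e_v) {
  n <- nrow(e_v$phi)
  if (nrow(e_w$phi) != n) stop("per-term counts differ")
  if (n < 2L) stop("need at least 2 per-term products")
  a <- sweep(e_v$phi, 2L, c(e_v$b1, e_v$b2))
  b <- sweep(e_w$phi, 2L, c(e_w$b1, e_w$b2))
  crossprod(a, b) / (n - 1)
}

#' Moment-ratio vector with signal-to-noise cutoff
#'
#' Forms the vector of estimated moment ratios together with the
#' signal-to-noise statistic of each denominator.  A ratio whose denominator
#' signal-to-noise falls strictly below the cutoff `theta` is set to zero;
#' the cutoff guarantees finite expectations of the ratio estimate for
#' approximately joint-normal moment estimates.
#'
#' @param estimates List of `pair_moments`, ordered by ratio index.
#' @param theta Positive cutoff on the absolute denominator signal-to-noise
#'   (default 5; the regulatory-network variant uses a small cutoff below 1).
#' @return A `ratio_vector` object with elements `b_hat`, `rho`, `kept`,
#'   `b1`, `b2`, `n_terms`, `theta`, `d_X0`.
#' @export
ratio_vector <- function(estimates, theta = 5) {
  if (!(theta > 0)) stop("theta must be positive")
  b1 <- vapply(estimates, function(e) e$b1, numeric(1))
  b2 <- vapply(estimates, function(e) e$b2, numeric(1))
  nt <- vapply(estimates, function(e) nrow(e$phi), numeric(1))
  s22 <- vapply(estimates, function(e) {
    p2 <- e$phi[, 2L]
    sum((p2 - e$b2)^2) / (length(p2) - 1)
  }, numeric(1))
  rho <- ifelse(s22 > 0, sqrt(nt / s22) * b2,
                ifelse(b2 != 0, sign(b2) * Inf, 0))
  kept <- abs(rho) >= theta
  b_hat <- ifelse(kept, b1 / b2, 0)
  structure(
    list(b_hat = b_hat, rho = rho, kept = kept, b1 = b1, b2 = b2,
         n_terms = nt, theta = theta, d_X0 = length(b_hat)),
    class = "ratio_vector"
  )
}

#' Finite-sample variance inflation factor for a moment ratio
#'
#' The asymptotic delta-method variance of a moment ratio underestimates the
#' truncated-ratio variance at finite signal-to-noise.  The corrected mode
#' inflates it by a polynomial in the inverse squared signal-to-noise,
#' `lambda = xi0 * (1 + sum_n xi_n (rho/6)^(-2n))`, calibrated for
#' approximately joint-normal moment estimates; the asymptotic mode returns 1.
#'
#' @param rho Signal-to-noise statistic(s) of surviving ratios (nonzero).
#' @param mode `"corrected"` or `"asymptotic"`.
#' @return Numeric vector of inflation factors.
#' @export
lambda_factor <- function(rho, mode = c("corrected", "asymptotic")) {
  mode <- match.arg(mode)
  if (mode == "asymptotic") return(rep(1, length(rho)))
  if (any(rho == 0)) stop("rho = 0 must be cut off before the correction")
  xi <- c(1.367, 2.047, 4.735, -1.923, -1.231, 2.790)
  r <- (rho / 6)^2
  xi[1L] * (1 + xi[2L] / r + xi[3L] / r^2 + xi[4L] / r^3 +
              xi[5L] / r^4 + xi[6L] / r^5)
}

#' Covariance matrix of the moment-ratio vector
#'
#' Delta-method covariance of the surviving moment ratios with explicit
#' extended-real bookkeeping: a cut-off ratio gets an infinite diagonal entry
#' and zero off-diagonal entries, so that it drops out of the test statistic
#' (with the convention `1/Inf = 0`).
#'
#' @param estimates List of `pair_moments` with equal per-term counts.
#' @param rv The `ratio_vector` computed from the same estimates.
#' @param lambda_mode `"corrected"` (finite-sample inflation) or
#'   `"asymptotic"`.
#' @return A `ratio_covariance` object with elements `sigma` (symmetric matrix
#'   with possibly infinite diagonal), `lambda` and `lambda_mode`.
#' @export
ratio_covariance <- function(estimates, rv,
                             lambda_mode = c("corrected", "asymptotic")) {
  lambda_mode <- match.arg(lambda_mode)
  V <- length(estimates)
  stopifnot(V == rv$d_X0)
  n <- nrow(estimates[[1L]]$phi)
  for (e in estimates) {
    if (nrow(e$phi) != n) stop("per-term counts differ across ratios")
  }
  P1 <- vapply(estimates, function(e) e$phi[, 1L], numeric(n))
  P2 <- vapply(estimates, function(e) e$phi[, 2L], numeric(n))
  P1 <- sweep(matrix(P1, n, V), 2L, rv$b1)
  P2 <- sweep(matrix(P2, n, V), 2L, rv$b2)
  C11 <- crossprod(P1) / (n - 1)
  C12 <- crossprod(P1, P2) / (n - 1)
  C22 <- crossprod(P2) / (n - 1)

  r <- numeric(V)
  r[rv$kept] <- rv$b1[rv$kept] / rv$b2[rv$kept]
  lam <- rep(1, V)
  if (any(rv$kept)) {
    lam[rv$kept] <- lambda_factor(rv$rho[rv$kept], lambda_mode)
  }

  A <- C11 - sweep(C12, 2L, r, `*`) - sweep(t(C12), 1L, r, `*`) +
    outer(r, r) * C22
  denom <- n * outer(rv$b2, rv$b2)
  S <- sqrt(outer(lam, lam)) * A
  S[rv$kept, rv$kept] <- S[rv$kept, rv$kept] / denom[rv$kept, rv$kept]
  S <- (S + t(S)) / 2
  S[!rv$kept, ] <- 0
  S[, !rv$kept] <- 0
  diag(S)[!rv$kept] <- Inf
  structure(
    list(sigma = S, lambda = lam, lambda_mode = lambda_mode),
    class = "ratio_covariance"
  )
}

#' Normalized autocovariance of a recorded series
#'
#' Adequacy gate for the i.i.d.-sampling assumption: the autocovariance of a
#' recorded component at a given lag, divided by its variance.  Recordings are
#' typically subsampled until this falls below 0.05.
#'
#' @param series Numeric vector.
#' @param lag Positive integer lag.
#' @return Normalized autocovariance at `lag`.
#' @export
check_autocorrelation <- function(series, lag = 1L) {
  n <- length(series)
  if (n <= lag) stop("series shorter than lag")
  if (stats::var(series) == 0) stop("zero variance")
  a <- stats::acf(series, lag.max = lag, plot = FALSE, demean = TRUE)
  as.numeric(a$acf[lag + 1L])
}
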