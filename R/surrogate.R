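#' Covariance-matched linear surrogate data
#'
#' Null model for purely linear dependence: each component is permuted
#' independently across samples, destroying all cross-component dependence,
#' then the columns are rescaled to unit variance and mixed by the Cholesky
#' factor of the original sample covariance.  The surrogate has (population)
#' covariance equal to the sample covariance of the input, but by
#' construction admits a fully linear modularization.  Without the
#' standardization the mixed shuffle would have covariance `L D L'` instead
#' of the target `L L'`, so `standardize = TRUE` is the default.
#'
#' @param s Centred `sample_matrix` with positive-definite sample covariance.
#' @param seed Optional integer seed for the per-component shuffles.
#' @param standardize Rescale shuffled components to unit variance before
#'   mixing (default `TRUE`)?
#' @return A centred `sample_matrix` of the same dimensions.
#' @export
linear_surrogate <- function(s, seed = NULL, standardize = TRUE) {
  stopifnot(inherits(s, "sample_matrix"), isTRUE(s$centered))
  x <- s$values
  n <- nrow(x)
  sigma <- stats::cov(x)
  U <- tryCatch(chol(sigma), error = function(e) {
    stop("singular covariance: cannot build a linear surrogate")
  })
  z <- with_local_seed(seed, {
    apply(x, 2L, function(col) col[sample.int(n)])
  })
  if (standardize) {
    sds <- apply(z, 2L, stats::sd)
    if (any(sds == 0)) stop("zero-variance component")
    z <- sweep(z, 2L, sds, `/`)
  }
  y <- z %*% U
  colnames(y) <- colnames(x)
  out <- center_samples(y)
  out
}
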