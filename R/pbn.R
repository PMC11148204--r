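# Probabilistic Boolean networks over variables with values in {1, 2}.
# A variable's conditional probability table stores P(value = 2 | parents) as
# a vector indexed by the parent configuration, first parent varying fastest.

#' Define a binary network variable
#'
#' @param name Variable name.
#' @param parents Character vector of parent names (must precede the variable
#'   in the specification, so the order is topological).
#' @param p2 Numeric vector of length `2^length(parents)`:
#'   `P(name = 2 | parents)` with the first parent varying fastest and parent
#'   states enumerated as 1 then 2.
#' @param observable Is the variable observable (a network component) or a
#'   latent interface variable?
#' @return A `pbn_variable`.
#' @export
pbn_variable <- function(name, parents = character(), p2, observable = TRUE) {
  if (length(p2) != 2^length(parents)) {
    stop("p2 must have one entry per parent configuration")
  }
  if (any(p2 < 0 | p2 > 1)) stop("probabilities must be in [0, 1]")
  structure(list(name = name, parents = parents, p2 = as.numeric(p2),
                 observable = isTRUE(observable)),
            class = "pbn_variable")
}

#' Assemble a probabilistic Boolean network specification
#'
#' @param variables List of [pbn_variable()]s in topological order (every
#'   parent listed before its children).
#' @param observable_order Optional character vector fixing the component
#'   order of the observable variables (the reference component last);
#'   defaults to declaration order.
#' @return A `pbn_spec`.
#' @export
pbn_spec <- function(variables, observable_order = NULL) {
  nms <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate variable names")
  seen <- character(0)
  for (v in variables) {
    if (!all(v$parents %in% seen)) {
      stop("parents of ", v$name, " must be declared first (topological order)")
    }
    seen <- c(seen, v$name)
  }
  observable <- vapply(variables, function(v) v$observable, logical(1))
  obs_names <- nms[observable]
  if (!is.null(observable_order)) {
    if (!setequal(observable_order, obs_names)) {
      stop("observable_order must list exactly the observable variables")
    }
    obs_names <- observable_order
  }
  structure(list(variables = variables, names = nms, observable = observable,
                 obs_names = obs_names),
            class = "pbn_spec")
}

#' @export
print.pbn_spec <- function(x, ...) {
  cat(sprintf("pbn_spec: %d variables (%d observable)\n",
              length(x$variables), sum(x$observable)))
  invisible(x)
}

#' Default five-population network specification
#'
#' The nested two-module network used throughout as the reference simulation:
#' five observable binary population states `x1..x5` and two latent interface
#' variables `y1` (a noiseless AND of `x3`, `x4`) and `y2`.  The data
#' generating modularization is `{{3,4}, {2,3,4}}` with reference component
#' `x5`; `x5` is a noiseless AND of `x1` and `y2`.
#'
#' @return A `pbn_spec` with observable order `x1..x5`.
#' @export
pbn_default_spec <- function() {
  pbn_spec(list(
    pbn_variable("x4", character(), 0.5),
    pbn_variable("x3", "x4", c(0.15, 0.85)),
    pbn_variable("y1", c("x3", "x4"), c(0, 0, 0, 1), observable = FALSE),
    pbn_variable("x2", "y1", c(0.15, 0.85)),
    pbn_variable("y2", c("x2", "y1"), c(0, 1, 1, 0.85), observable = FALSE),
    pbn_variable("x1", "y2", c(0.15, 0.85)),
    pbn_variable("x5", c("x1", "y2"), c(0, 0, 0, 1))
  ), observable_order = c("x1", "x2", "x3", "x4", "x5"))
}

#' The data-generating modularization of the default network
#'
#' @return A `modularization`: nested modules `{3,4}` and `{2,3,4}`,
#'   reference component 5.
#' @export
pbn_default_modularization <- function() {
  m <- modularization(list(c(3, 4), c(2, 3, 4)), ref = 5, kind = "nested",
                      label = "true")
  m
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

parent_config_index <- function(states, parents, names) {
  idx <- rep(1L, nrow(states))
  mult <- 1L
  for (p in parents) {
    idx <- idx + (states[, match(p, names)] - 1L) * mult
    mult <- mult * 2L
  }
  idx
}

#' Draw joint samples of all network variables
#'
#' Ancestral sampling in topological order; deterministic given `seed`.
#'
#' @param spec A `pbn_spec`.
#' @param n Number of i.i.d. joint samples.
#' @param seed Optional integer seed (the caller's random state is restored).
#' @return Integer matrix `n x n_variables` with values in `{1, 2}` and
#'   variable names as column names.
#' @export
sample_states <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    nv <- length(spec$variables)
    states <- matrix(1L, n, nv, dimnames = list(NULL, spec$names))
    for (j in seq_len(nv)) {
      v <- spec$variables[[j]]
      p2 <- v$p2[parent_config_index(states, v$parents, spec$names)]
      states[, j] <- 1L + (stats::runif(n) < p2)
    }
    states
  })
}

#' Exact joint distribution by enumeration
#'
#' @param spec A `pbn_spec` with at most 20 variables.
#' @return List with `states` (configuration matrix, values in `{1, 2}`) and
#'   `prob` (probabilities summing to 1).
#' @export
exact_joint <- function(spec) {
  nv <- length(spec$variables)
  if (nv > 20L) stop("too many variables for enumeration")
  grid <- as.matrix(expand.grid(rep(list(1:2), nv)))
  colnames(grid) <- spec$names
  prob <- rep(1, nrow(grid))
  for (j in seq_len(nv)) {
    v <- spec$variables[[j]]
    p2 <- v$p2[parent_config_index(grid, v$parents, spec$names)]
    prob <- prob * ifelse(grid[, j] == 2L, p2, 1 - p2)
  }
  list(states = grid, prob = prob)
}

#' Marginal distribution of the observable variables
#'
#' @param spec A `pbn_spec`.
#' @return List with `states` (observable configurations) and `prob`.
#' @export
observable_marginal <- function(spec) {
  joint <- exact_joint(spec)
  obs <- joint$states[, spec$obs_names, drop = FALSE]
  key <- apply(obs, 1L, paste, collapse = ",")
  agg <- rowsum(joint$prob, key)
  cfg <- do.call(rbind, lapply(strsplit(rownames(agg), ","), as.integer))
  colnames(cfg) <- colnames(obs)
  list(states = cfg, prob = as.numeric(agg))
}

#' Spike-count configuration
#'
#' Conversion from binary population states to spike counts: each population
#' holds `neurons` neurons firing at `rate_low` Hz in state 1 and `rate_high`
#' Hz in state 2, counted over bins of `bin_width` seconds.  With the
#' defaults the expected population count is 10 (low) or 50 (high) spikes
#' per bin.
#'
#' @param neurons Neurons per population (default 10).
#' @param rate_low,rate_high Firing rates in Hz (defaults 5 and 25).
#' @param bin_width Bin width in seconds (default 0.2).
#' @param n_bins Number of bins per recording (default 4500, i.e. 15 minutes
#'   of 200 ms bins).
#' @return A `spike_config` list.
#' @export
spike_config <- function(neurons = 10, rate_low = 5, rate_high = 25,
                         bin_width = 0.2, n_bins = 4500) {
  stopifnot(rate_low >= 0, rate_high >= 0, bin_width > 0, neurons >= 1)
  structure(list(neurons = neurons, rate_low = rate_low,
                 rate_high = rate_high, bin_width = bin_width,
                 n_bins = n_bins),
            class = "spike_config")
}

state_means <- function(states, cfg) {
  lo <- cfg$neurons * cfg$rate_low * cfg$bin_width
  hi <- cfg$neurons * cfg$rate_high * cfg$bin_width
  ifelse(states == 2L, hi, lo)
}

#' Population spike counts for sampled binary states
#'
#' Draws per-bin population spike counts given the binary states: counts are
#' Poisson with mean `neurons * rate * bin_width` (independent across
#' neurons, hence Poisson for the population sum).  Counts are centred with
#' [center_samples()] unless `center = FALSE`.
#'
#' @param states Matrix of observable binary states (bins x populations,
#'   values in `{1, 2}`).
#' @param cfg A [spike_config()].
#' @param seed Optional integer seed.
#' @param center Centre the counts (default `TRUE`)?
#' @return A centred `sample_matrix` (or the raw count matrix when
#'   `center = FALSE`).
#' @export
spike_count_samples <- function(states, cfg = spike_config(), seed = NULL,
                                center = TRUE) {
  mu <- state_means(states, cfg)
  counts <- with_local_seed(seed, {
    matrix(stats::rpois(length(mu), as.numeric(mu)), nrow(mu), ncol(mu),
           dimnames = dimnames(states))
  })
  if (center) center_samples(counts) else counts
}

#' Simulate one spike-count recording of a network
#'
#' Convenience wrapper: draws binary states from the network and converts
#' them to centred population spike counts.
#'
#' @param spec A `pbn_spec` (default [pbn_default_spec()]).
#' @param cfg A [spike_config()].
#' @param seed Optional integer seed.
#' @return A centred `sample_matrix` with one column per observable variable.
#' @export
simulate_recording <- function(spec = pbn_default_spec(),
                               cfg = spike_config(), seed = NULL) {
  with_local_seed(seed, {
    st <- sample_states(spec, cfg$n_bins)
    obs <- st[, spec$obs_names, drop = FALSE]
    spike_count_samples(obs, cfg)
  })
}

#' Exact moments of population spike counts
#'
#' Closed-form oracle combining the exact observable marginal with the count
#' noise moments.  Because the counts are conditionally Poisson and
#' independent given the states, cross moments of distinct populations equal
#' the corresponding moments of the conditional means, while variances gain
#' the Poisson term (the mean).  Central third cross moments are exact for
#' distinct index triples.
#'
#' @param spec A `pbn_spec`.
#' @param cfg A [spike_config()].
#' @return List with `mean`, `cov_mu` (covariance of conditional means),
#'   `cov_counts` (count covariance: `cov_mu` off the diagonal, plus the
#'   Poisson variance on it), `corr` (count correlation matrix), `m3`
#'   (central third-moment array, valid for distinct triples).
#' @export
exact_count_moments <- function(spec = pbn_default_spec(),
                                cfg = spike_config()) {
  marg <- observable_marginal(spec)
  mu <- state_means(marg$states, cfg)
  p <- marg$prob
  m <- colSums(p * mu)
  mc <- sweep(mu, 2L, m)
  cov_mu <- crossprod(mc, p * mc)
  cov_counts <- cov_mu
  diag(cov_counts) <- diag(cov_mu) + m
  sd_counts <- sqrt(diag(cov_counts))
  corr <- cov_counts / outer(sd_counts, sd_counts)
  d <- ncol(mu)
  m3 <- array(0, dim = c(d, d, d),
              dimnames = list(colnames(mu), colnames(mu), colnames(mu)))
  for (i in seq_len(d)) for (j in seq_len(d)) for (k in seq_len(d)) {
    m3[i, j, k] <- sum(p * mc[, i] * mc[, j] * mc[, k])
  }
  list(mean = m, cov_mu = cov_mu, cov_counts = cov_counts, corr = corr,
       m3 = m3)
}

#' Population moment-ratio matrix from exact count moments
#'
#' @param mom Output of [exact_count_moments()].
#' @param ref Reference component index (default: last).
#' @return Symmetric matrix of population moment ratios
#'   `B[k, l] = E[s_k s_l s_ref] / (E[s_k s_ref] E[s_l s_ref])` over
#'   non-reference components (diagonal `NA`).
#' @export
population_b_matrix <- function(mom, ref = NULL) {
  d <- length(mom$mean)
  if (is.null(ref)) ref <- d
  idx <- setdiff(seq_len(d), ref)
  B <- matrix(NA_real_, length(idx), length(idx))
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a == b) next
    k <- idx[a]; l <- idx[b]
    B[a, b] <- mom$m3[k, l, ref] / (mom$cov_mu[k, ref] * mom$cov_mu[l, ref])
  }
  B
}

#' Coefficient of determination of the optimal linear predictor
#'
#' Computes, under the exact joint distribution of the network, the
#' population R-squared of the least-squares optimal linear predictor of one
#' observable binary variable from all other observable variables.
#'
#' @param spec A `pbn_spec`.
#' @param target Name of the observable variable to predict.
#' @return R-squared in `[0, 1]`.
#' @export
linear_r2 <- function(spec = pbn_default_spec(), target = "x5") {
  marg <- observable_marginal(spec)
  X <- marg$states
  p <- marg$prob
  jt <- match(target, colnames(X))
  if (is.na(jt)) stop("unknown target variable")
  y <- X[, jt]
  Z <- cbind(1, X[, -jt, drop = FALSE])
  beta <- solve(crossprod(Z, p * Z), crossprod(Z, p * y))
  resid <- y - as.numeric(Z %*% beta)
  mse <- sum(p * resid^2)
  vy <- sum(p * (y - sum(p * y))^2)
  if (vy == 0) stop("target has zero variance")
  1 - mse / vy
}
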