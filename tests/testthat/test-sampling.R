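test_that("centring subtracts component means and drops a trailing odd sample", {
  x <- cbind(c(1, 3, 1, 3), c(2, 2, 4, 4), c(5, 1, 5, 1))
  s <- center_samples(x)
  expect_equal(colMeans(s$values), rep(0, 3))
  expect_equal(s$values[, 1], c(-1, 1, -1, 1))
  expect_true(s$centered)

  already <- matrix(c(-1, 1, 0.5, -0.5, 2, -2, 1, 1, -1, -1, 0, 0), 4, 3)
  expect_equal(center_samples(already)$values, center_samples(center_samples(already)$values)$values)

  odd <- matrix(rnorm(15), 5, 3)
  expect_warning(s5 <- center_samples(odd), "odd number of samples")
  expect_equal(s5$n, 4L)
  expect_equal(s5$dropped, 1L)

  expect_error(center_samples(matrix(1, 1, 3)), "insufficient samples")
  expect_error(center_samples(matrix(rnorm(6), 3, 2)), "3 components")
  expect_error(suppressWarnings(center_samples(matrix(rnorm(9), 3, 3))),
               "insufficient samples")
})

test_that("ratio indices agree with lexicographic pair enumeration", {
  for (d in 3:8) {
    v <- 0L
    for (k in seq_len(d - 2)) {
      for (l in seq.int(k + 1, d - 1)) {
        v <- v + 1L
        expect_identical(vec_index(k, l, d), v)
      }
    }
    expect_identical(v, as.integer((d - 1) * (d - 2) / 2))
  }
  expect_identical(vec_index(1, 2, 5), 1L)
  expect_identical(vec_index(2, 3, 5), 4L)
  expect_identical(vec_index(3, 4, 5), 6L)
  expect_error(vec_index(3, 2, 5), "invalid pair")
  expect_error(vec_index(2, 4, 4), "invalid pair")
  pp <- ratio_pairs(5)
  expect_equal(pp$v, 1:6)
})

test_that("paired-sample products implement the split moment scheme", {
  s <- as_sample_matrix(cbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1)))
  e <- nested_products(s, 1, 2)
  expect_equal(e$b1, 1)           # odd samples: 1*1*1 and 1*(-1)*(-1)
  expect_equal(e$b2, 0)           # half-split: +1 and -1
  expect_equal(nrow(e$phi), 2L)

  z <- as_sample_matrix(matrix(0, 6, 3))
  ez <- nested_products(z, 1, 2)
  expect_equal(ez$b1, 0)
  expect_equal(ez$b2, 0)

  set.seed(1)
  s2 <- as_sample_matrix(scale(matrix(rnorm(40), 10, 4), scale = FALSE))
  a <- nested_products(s2, 1, 3)
  s2c <- s2; s2c$values[, 1] <- 2.5 * s2c$values[, 1]
  b <- nested_products(s2c, 1, 3)
  expect_equal(b$b1, 2.5 * a$b1)
  expect_equal(b$b2, 2.5 * a$b2)
  expect_error(nested_products(s2, 2, 1), "invalid pair")
})

test_that("single-module products use one product per sample", {
  s <- as_sample_matrix(cbind(c(1, -1), c(1, 1), c(1, -1)))
  e <- single_module_products(s, 1, 2, 3)
  expect_equal(e$b1, 0)
  expect_equal(e$b2, 1)
  expect_equal(nrow(e$phi), 2L)

  set.seed(2)
  x <- rnorm(2000)
  s2 <- center_samples(cbind(x, x, rnorm(2000)))
  e2 <- single_module_products(s2, 1, 2, 3)
  expect_gt(e2$b1, 0.8)           # self-correlation near the variance

  half <- single_module_products(s2, 1, 2, 3, samples = 1:1000)
  expect_equal(nrow(half$phi), 1000L)
  expect_error(single_module_products(s2, 1, 1, 3), "distinct")
})

test_that("product covariance blocks have Gram structure", {
  const <- make_pair_moments(cbind(rep(2, 5), rep(-1, 5)))
  expect_equal(product_covariance(const), matrix(0, 2, 2))

  hand <- make_pair_moments(cbind(c(1, -1, 1, -1), c(1, 1, 1, 1)))
  cc <- product_covariance(hand)
  expect_equal(cc[1, 1], 4 / 3)
  expect_equal(cc[2, 2], 0)

  set.seed(3)
  e <- make_pair_moments(matrix(rnorm(40), 20, 2))
  cv <- product_covariance(e)
  expect_equal(cv, t(cv))
  expect_true(all(eigen(cv, symmetric = TRUE, only.values = TRUE)$values > -1e-12))

  f <- make_pair_moments(matrix(rnorm(10), 5, 2))
  expect_error(product_covariance(e, f), "per-term counts differ")
})

test_that("the ratio vector applies the strict signal-to-noise cutoff", {
  # denominator column with mean 1 and sample variance exactly 2 over 50 terms
  a <- sqrt(2 * 49 / 50)
  phi2 <- rep(c(1 + a, 1 - a), 25)
  e <- make_pair_moments(cbind(rep(2, 50), phi2))
  rv <- ratio_vector(list(e), theta = 5)
  expect_equal(rv$rho, 5)          # sqrt(50 / 2) * 1
  expect_true(rv$kept)             # 5 is not < 5: boundary kept
  expect_equal(rv$b_hat, 2)

  rv6 <- ratio_vector(list(e), theta = 5.0001)
  expect_false(rv6$kept)
  expect_equal(rv6$b_hat, 0)

  ez <- make_pair_moments(cbind(rnorm(10), rep(0, 10)))
  rvz <- ratio_vector(list(ez), theta = 5)
  expect_equal(rvz$rho, 0)
  expect_equal(rvz$b_hat, 0)

  # exact denominator (zero variance, nonzero mean) is always kept
  ec <- make_pair_moments(cbind(c(2, 2, 2, 2), c(4, 4, 4, 4)))
  rvc <- ratio_vector(list(ec), theta = 5)
  expect_equal(rvc$rho, Inf)
  expect_equal(rvc$b_hat, 0.5)
  expect_error(ratio_vector(list(e), theta = 0), "positive")
})

test_that("the finite-sample variance inflation matches its series", {
  expect_equal(lambda_factor(c(2, 10, 100), "asymptotic"), rep(1, 3))
  expect_equal(lambda_factor(1e12, "corrected"), 1.367, tolerance = 1e-9)
  xi <- c(1.367, 2.047, 4.735, -1.923, -1.231, 2.790)
  expect_equal(lambda_factor(6, "corrected"),
               xi[1] * (1 + sum(xi[2:6])))
  expect_equal(lambda_factor(-6, "corrected"), lambda_factor(6, "corrected"))
  expect_error(lambda_factor(0, "corrected"), "cut off")
})

test_that("ratio covariance keeps extended-real bookkeeping and scale invariance", {
  set.seed(4)
  # two ratios with zero-mean denominators: both cut off
  e1 <- make_pair_moments(matrix(rnorm(40), 20, 2))
  e1$phi[, 2] <- e1$phi[, 2] - mean(e1$phi[, 2]); e1$b2 <- 0
  e2 <- make_pair_moments(matrix(rnorm(40), 20, 2))
  e2$phi[, 2] <- e2$phi[, 2] - mean(e2$phi[, 2]); e2$b2 <- 0
  rv <- ratio_vector(list(e1, e2), theta = 5)
  rc <- ratio_covariance(list(e1, e2), rv, "asymptotic")
  expect_equal(rc$sigma, matrix(c(Inf, 0, 0, Inf), 2, 2))

  # diagonal entry agrees with the direct delta-method expression
  s <- center_samples(matrix(rpois(400 * 4, 20), 400, 4))
  pairs <- ratio_pairs(4)
  ests <- lapply(1:3, function(i) nested_products(s, pairs$k[i], pairs$l[i]))
  rv <- ratio_vector(ests, theta = 0.1)
  rc <- ratio_covariance(ests, rv, "asymptotic")
  for (i in which(rv$kept)) {
    sp <- product_covariance(ests[[i]])
    r <- rv$b1[i] / rv$b2[i]
    direct <- (sp[1, 1] - 2 * r * sp[1, 2] + r^2 * sp[2, 2]) /
      (nrow(ests[[i]]$phi) * rv$b2[i]^2)
    expect_equal(rc$sigma[i, i], direct, tolerance = 1e-12)
  }
  expect_equal(rc$sigma, t(rc$sigma))
  expect_true(all(diag(rc$sigma)[is.finite(diag(rc$sigma))] >= 0))
})

test_that("signal-to-noise and weighted ratios are invariant to component rescaling", {
  set.seed(5)
  s <- simulate_recording(cfg = spike_config(n_bins = 600), seed = 99)
  fit <- moment_ratio_fit(s, theta = 5, lambda_mode = "corrected")
  base <- fit$rv$b_hat^2 / diag(fit$rc$sigma)
  for (rep in 1:3) {
    scales <- exp(runif(5, -1, 1))
    s2 <- s
    s2$values <- sweep(s$values, 2, scales, `*`)
    fit2 <- moment_ratio_fit(s2, theta = 5, lambda_mode = "corrected")
    expect_equal(fit2$rv$rho, fit$rv$rho, tolerance = 1e-10)
    idx <- fit$rv$kept
    expect_equal((fit2$rv$b_hat^2 / diag(fit2$rc$sigma))[idx], base[idx],
                 tolerance = 1e-10)
  }
})

test_that("normalized autocovariance flags non-i.i.d. sampling", {
  set.seed(6)
  expect_lt(abs(check_autocorrelation(rnorm(5000), 1)), 0.05)

  alternating <- rep(c(1, -1), 500)
  expect_equal(check_autocorrelation(alternating, 1), -1, tolerance = 0.01)

  n <- 20000
  ar <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  expect_equal(check_autocorrelation(ar, 1), 0.5, tolerance = 0.05)

  expect_error(check_autocorrelation(rep(1, 100), 1), "zero variance")
  expect_error(check_autocorrelation(c(1, 2), 5), "shorter")
})

test_that("moment estimators are unbiased against the enumeration oracle", {
  spec <- pbn_default_spec()
  cfg <- spike_config()
  mom <- exact_count_moments(spec, cfg)
  R <- 10000L; Nt <- 200L
  st <- sample_states(spec, R * Nt, seed = 42)[, spec$obs_names]
  mu <- ifelse(st == 2L, 50, 10)
  set.seed(43)
  counts <- matrix(rpois(length(mu), as.numeric(mu)), nrow(mu), ncol(mu))
  # centre with the exact population means so the check isolates the
  # estimator itself from the O(1/N) bias of sample-mean centring
  counts <- sweep(counts, 2L, mom$mean)
  colm <- function(j) matrix(counts[, j], Nt, R)
  X3 <- colm(3); X4 <- colm(4); X5 <- colm(5)
  odd <- seq.int(1L, Nt, 2L); h <- Nt %/% 2L
  b1 <- colMeans(X3[odd, ] * X4[odd, ] * X5[odd, ])
  b2 <- colMeans(X3[seq_len(h), ] * X5[seq_len(h), ] *
                   X4[h + seq_len(h), ] * X5[h + seq_len(h), ])
  # the vectorized replication agrees with the packaged estimator
  for (r in 1:3) {
    idx <- (r - 1L) * Nt + seq_len(Nt)
    s <- as_sample_matrix(counts[idx, ])
    e <- nested_products(s, 3, 4)
    expect_equal(e$b1, b1[r], tolerance = 1e-12)
    expect_equal(e$b2, b2[r], tolerance = 1e-12)
  }
  oracle1 <- mom$m3[3, 4, 5]
  oracle2 <- mom$cov_mu[3, 5] * mom$cov_mu[4, 5]
  expect_lt(abs(mean(b1) - oracle1), 3 * sd(b1) / sqrt(R))
  expect_lt(abs(mean(b2) - oracle2), 3 * sd(b2) / sqrt(R))
})
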