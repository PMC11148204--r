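# Shared fixtures: hand-built moment objects, calibration data and synthetic
# regulatory networks.  Everything is generated in code at test time.

make_pair_moments <- function(phi) {
  phi <- as.matrix(phi)
  structure(
    list(v = NA_integer_, k = NA_integer_, l = NA_integer_,
         b1 = mean(phi[, 1L]), b2 = mean(phi[, 2L]), phi = phi,
         scheme = "manual"),
    class = "pair_moments"
  )
}

# Exact flat single-module data: binary interface y with four conditionally
# independent linear readouts.  The module {1, 2} (and every other pair) is
# exact, denominators are well separated, and the disjoint-half estimator
# gives independent ratio estimates.
flat_module_gaussian <- function(n, gain = 2, p_high = 0.4) {
  y <- 1 + (stats::runif(n) < p_high)
  x <- vapply(1:4, function(j) gain * y + stats::rnorm(n), numeric(n))
  center_samples(x)
}

# Flat probabilistic Boolean network: one root driving two latent interfaces,
# each with two observable readout populations; ref = x5.
flat_count_spec <- function(plo = 0.1, phi = 0.9, p5 = 0.3) {
  pbn_spec(list(
    pbn_variable("x5", character(), p5),
    pbn_variable("y1", "x5", c(plo, phi), observable = FALSE),
    pbn_variable("y2", "x5", c(plo, phi), observable = FALSE),
    pbn_variable("x1", "y1", c(plo, phi)),
    pbn_variable("x2", "y1", c(plo, phi)),
    pbn_variable("x3", "y2", c(plo, phi)),
    pbn_variable("x4", "y2", c(plo, phi))
  ), observable_order = c("x1", "x2", "x3", "x4", "x5"))
}

# Population moment-ratio vector of a network from the exact count oracle.
population_b_vector <- function(spec = pbn_default_spec(),
                                cfg = spike_config()) {
  mom <- exact_count_moments(spec, cfg)
  B <- population_b_matrix(mom)
  pairs <- ratio_pairs(length(mom$mean))
  mapply(function(k, l) B[k, l], pairs$k, pairs$l)
}

# Synthetic nested regulatory network with planted indirect edges: per motif,
# an upstream TF (TFa) drives a downstream TF (TFb) which drives three target
# genes with linear readouts of mixed strength.  Gold positives are the
# direct TFb -> TG edges; the TFa -> TG dependencies are indirect and
# removable.
simulate_grn_motifs <- function(n_samples = 800, n_motifs = 4, seed = NULL) {
  run <- function() {
    tfs <- character(0); tgs <- character(0)
    cols <- list(); goldpos <- character(0)
    for (m in seq_len(n_motifs)) {
      a <- 1 + (stats::runif(n_samples) < 0.5)
      b <- ifelse(stats::runif(n_samples) < 0.85, a, 3 - a)
      cols[[paste0("TFa", m)]] <- a + stats::rnorm(n_samples, sd = 0.3)
      cols[[paste0("TFb", m)]] <- b + stats::rnorm(n_samples, sd = 0.3)
      sig <- c(0.8, 0.8, 2.0)
      gn <- paste0("G", m, "_", 1:3)
      for (j in 1:3) cols[[gn[j]]] <- b + stats::rnorm(n_samples, sd = sig[j])
      tfs <- c(tfs, paste0("TFa", m), paste0("TFb", m))
      tgs <- c(tgs, gn)
      goldpos <- c(goldpos, paste(paste0("TFb", m), gn))
    }
    vals <- do.call(cbind, cols)
    ds <- expression_dataset(vals, names(cols), names(cols) %in% tfs)
    full <- expand.grid(tf = tfs, target = tgs, stringsAsFactors = FALSE)
    full$label <- as.integer(paste(full$tf, full$target) %in% goldpos)
    list(ds = ds, gold = full)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Four-gene chain: TFa drives both TGs, TFb sits downstream of TFa, so the
# module containing both TFs (interface = TFa's regulator state) is exact.
grn_chain_dataset <- function(n) {
  a <- 1 + (stats::runif(n) < 0.5)
  b <- ifelse(stats::runif(n) < 0.85, a, 3 - a)
  expression_dataset(
    cbind(t1 = a + stats::rnorm(n, sd = 0.3),
          t2 = b + stats::rnorm(n, sd = 0.3),
          g1 = a + stats::rnorm(n, sd = 0.8),
          g2 = a + stats::rnorm(n, sd = 0.8)),
    is_tf = c(TRUE, TRUE, FALSE, FALSE)
  )
}

# Four-gene network with two independent regulators loading on both targets
# with different weights: no single interface variable exists.
grn_two_regulator_dataset <- function(n, w = 1.3) {
  a1 <- 1 + (stats::runif(n) < 0.5)
  a2 <- 1 + (stats::runif(n) < 0.5)
  expression_dataset(
    cbind(t1 = a1 + stats::rnorm(n, sd = 0.3),
          t2 = a2 + stats::rnorm(n, sd = 0.3),
          g1 = a1 + w * a2 + stats::rnorm(n, sd = 0.5),
          g2 = w * a1 + a2 + stats::rnorm(n, sd = 0.5)),
    is_tf = c(TRUE, TRUE, FALSE, FALSE)
  )
}
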