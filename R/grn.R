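# Re-ranking of predicted transcription-factor (TF) / target-gene (TG)
# interactions: four-node subnetworks of two TFs and two TGs are tested for a
# single functional module containing both TFs, and retained modules (likely
# indirect interactions) demote the weaker TF's edges.

#' Construct an expression dataset
#'
#' @param values Numeric matrix, samples (chips) in rows, genes in columns.
#' @param genes Gene labels (default: column names); must be unique.
#' @param is_tf Logical vector flagging transcription factors.
#' @return An `expression_dataset`.
#' @export
expression_dataset <- function(values, genes = colnames(values), is_tf) {
  values <- as.matrix(values)
  if (is.null(genes)) stop("gene labels required")
  if (anyDuplicated(genes)) stop("gene labels must be unique")
  if (length(genes) != ncol(values)) stop("one label per gene column required")
  if (length(is_tf) != length(genes)) stop("one TF flag per gene required")
  if (sum(is_tf) < 2L || sum(!is_tf) < 2L) {
    stop("need at least 2 TFs and 2 non-TF genes")
  }
  colnames(values) <- genes
  structure(list(values = values, genes = genes, is_tf = as.logical(is_tf)),
            class = "expression_dataset")
}

edge_key <- function(tf, tg) paste(tf, tg, sep = "\r")

#' Rank TF-TG interactions by absolute Pearson correlation
#'
#' All TF / non-TF gene pairs are ranked by the absolute value of their
#' Pearson correlation coefficient (descending), with ties broken by
#' (TF label, TG label).  An artificial p-value `rank/N` is attached so that
#' the re-ranking correction applies uniformly.  Zero-variance genes get a
#' correlation of 0 and rank last.
#'
#' @param ds An `expression_dataset` with at least 3 samples.
#' @return A `ranked_edges` data frame with columns `tf`, `target`,
#'   `confidence` (absolute correlation) and `p_value`.
#' @export
correlation_ranking <- function(ds) {
  if (nrow(ds$values) < 3L) stop("need at least 3 samples")
  tfs <- ds$genes[ds$is_tf]
  tgs <- ds$genes[!ds$is_tf]
  r <- suppressWarnings(
    stats::cor(ds$values[, tfs, drop = FALSE], ds$values[, tgs, drop = FALSE])
  )
  r[!is.finite(r)] <- 0
  edges <- data.frame(
    tf = rep(tfs, times = length(tgs)),
    target = rep(tgs, each = length(tfs)),
    confidence = abs(as.numeric(r)),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$confidence, edges$tf, edges$target), ]
  edges$p_value <- seq_len(nrow(edges)) / nrow(edges)
  rownames(edges) <- NULL
  class(edges) <- c("ranked_edges", "data.frame")
  edges
}

#' Single-module p-value of a two-TF / two-TG subnetwork
#'
#' Tests the functional module containing both TFs: the moment ratios
#' `b_k = E[s_k s_3] / E[s_k s_ref]` for the two TFs `k = 1, 2`, with the
#' second TG as reference, must share one value when a single interface
#' variable mediates the interactions.  The two ratios are estimated on
#' disjoint sample halves (first half for the first TF, second half for the
#' second), so their estimates are uncorrelated and no eigenvalue scaling is
#' needed; the asymptotic variance is used with a small cutoff `theta < 1`.
#' The equality family is the single set `{1, 2}` and the shape parameter is
#' 1/2.
#'
#' @param ds An `expression_dataset`.
#' @param tf_pair Character vector of the two TF labels.
#' @param tg_pair Character vector of the two TG labels; the second is the
#'   reference unless `swap_ref` is `TRUE`, in which case both roles are
#'   evaluated and the larger p-value returned.
#' @param theta Signal-to-noise cutoff, below 1 (default 0.5).
#' @param swap_ref Evaluate both TG role assignments (default `FALSE`)?
#' @return Gamma-tail p-value; 1 when both denominators are cut off
#'   (inconclusive, never evidence against the module).
#' @export
subnetwork_module_pvalue <- function(ds, tf_pair, tg_pair, theta = 0.5,
                                     swap_ref = FALSE) {
  stopifnot(length(tf_pair) == 2L, length(tg_pair) == 2L)
  cols <- match(c(tf_pair, tg_pair), ds$genes)
  if (anyNA(cols)) stop("unknown gene labels")
  if (anyDuplicated(cols)) stop("the four genes must be distinct")
  x <- ds$values[, cols, drop = FALSE]
  s <- suppressWarnings(center_samples(x))
  p <- single_module_test(s, theta)$p_value
  if (swap_ref) {
    p <- max(p, single_module_test(s, theta, l = 4L, ref = 3L)$p_value)
  }
  p
}

#' Disjoint-half single-module test for a four-component subnetwork
#'
#' Core of the subnetwork test: the ratios `b_1 = E[s_1 s_l]/E[s_1 s_ref]`
#' and `b_2 = E[s_2 s_l]/E[s_2 s_ref]` are estimated on the first and second
#' sample halves respectively, so the two ratio estimates are independent and
#' the statistic is exactly gamma distributed (shape 1/2) under the module
#' hypothesis, without any correlation correction.
#'
#' @param s A centred `sample_matrix` with (at least) 4 components; the
#'   module is `{1, 2}`.
#' @param theta Signal-to-noise cutoff, below 1.
#' @param l Numerator partner component (default 3).
#' @param ref Reference component (default 4).
#' @return List with `statistic`, `zeta` (1/2), `p_value`, `rv`.
#' @export
single_module_test <- function(s, theta = 0.5, l = 3L, ref = 4L) {
  if (!(theta < 1)) stop("the single-module test uses a cutoff below 1")
  h <- s$n %/% 2L
  e1 <- single_module_products(s, k = 1L, l = l, ref = ref,
                               samples = seq_len(h))
  e2 <- single_module_products(s, k = 2L, l = l, ref = ref,
                               samples = h + seq_len(h))
  rv <- ratio_vector(list(e1, e2), theta)
  sig <- matrix(0, 2L, 2L)
  for (i in 1:2) {
    if (!rv$kept[i]) {
      sig[i, i] <- Inf
    } else {
      sp <- product_covariance(list(e1, e2)[[i]])
      r <- rv$b1[i] / rv$b2[i]
      sig[i, i] <- (sp[1L, 1L] - 2 * r * sp[1L, 2L] + r^2 * sp[2L, 2L]) /
        (rv$n_terms[i] * rv$b2[i]^2)
    }
  }
  fam <- index_set_family(list(1:2), 2L)
  T_stat <- test_statistic(rv$b_hat, sig, fam)
  zeta <- degrees_of_freedom(fam)
  list(statistic = T_stat, zeta = zeta,
       p_value = gamma_pvalue(T_stat, zeta), rv = rv)
}

#' Re-rank predicted interactions using the single-module test
#'
#' For every sufficiently connected subnetwork of two TFs and two TGs (at
#' least three of its four TF-TG edges in the set of the `set_size` most
#' likely interactions, including both edges of the putative interface TF --
#' the TF owning the subnetwork's most likely edge), the module containing
#' both TFs is tested.  Each edge of the other TF is re-scored as
#' `p <- max(p, c * p_test)`, where `c` is the p-value at the boundary of the
#' most-likely set, so that an irrefutable module (`p_test = 1`) demotes the
#' edge exactly to the set boundary and never past the interactions whose
#' evidence triggered the test.  Corrections from different subnetworks
#' combine by taking the maximum.  The list is re-sorted by corrected p-value
#' with the original rank as tie-breaker.
#'
#' @param ds An `expression_dataset`.
#' @param ranked A `ranked_edges` data frame (for example from
#'   [correlation_ranking()]).
#' @param set_size Size of the set of most likely interactions, the method's
#'   only free parameter.
#' @param theta Cutoff passed to [subnetwork_module_pvalue()].
#' @param swap_ref Passed to [subnetwork_module_pvalue()].
#' @return A `ranked_edges` data frame with updated `p_value` and the
#'   original p-value in `p_original`.
#' @export
rerank <- function(ds, ranked, set_size, theta = 0.5, swap_ref = FALSE) {
  stopifnot(set_size >= 1L, set_size <= nrow(ranked))
  ranked <- ranked[order(ranked$p_value), , drop = FALSE]
  rownames(ranked) <- NULL
  keys <- edge_key(ranked$tf, ranked$target)
  p <- ranked$p_value
  names(p) <- keys
  ml <- ranked[seq_len(set_size), , drop = FALSE]
  ml_keys <- edge_key(ml$tf, ml$target)
  c_scale <- max(ml$p_value)
  corrected <- p

  tfs <- sort(unique(ml$tf))
  ml_targets <- split(ml$target, ml$tf)
  if (length(tfs) >= 2L) {
    for (ia in seq_len(length(tfs) - 1L)) {
      for (ib in seq.int(ia + 1L, length(tfs))) {
        a <- tfs[ia]; b <- tfs[ib]
        for (putative in c(a, b)) {
          other <- if (putative == a) b else a
          tg_cand <- sort(ml_targets[[putative]])
          if (length(tg_cand) < 2L) next
          pairs <- utils::combn(tg_cand, 2L)
          for (jj in seq_len(ncol(pairs))) {
            g1 <- pairs[1L, jj]; g2 <- pairs[2L, jj]
            e_put <- edge_key(putative, c(g1, g2))
            e_oth <- edge_key(other, c(g1, g2))
            in_ml <- c(e_put, e_oth) %in% ml_keys
            if (sum(in_ml) < 3L) next
            four <- c(e_put, e_oth)
            pv4 <- p[four]
            pv4[is.na(pv4)] <- Inf
            best <- four[which.min(pv4)]
            owner <- if (best %in% e_put) putative else other
            if (owner != putative) next
            p_test <- subnetwork_module_pvalue(ds, c(putative, other),
                                               c(g1, g2), theta, swap_ref)
            for (ek in e_oth) {
              if (ek %in% keys) {
                corrected[ek] <- max(corrected[ek], c_scale * p_test)
              }
            }
          }
        }
      }
    }
  }
  ranked$p_original <- ranked$p_value
  ranked$p_value <- as.numeric(corrected)
  ranked <- ranked[order(ranked$p_value, ranked$p_original), , drop = FALSE]
  rownames(ranked) <- NULL
  class(ranked) <- c("ranked_edges", "data.frame")
  ranked
}

#' Select the most-likely-set size on a holdout sample
#'
#' Splits the samples so that every 8th sample (1, 9, 17, ...) forms the
#' holdout, computes the re-ranking corrections on the holdout samples for
#' each candidate size, and returns the size whose corrected ranking
#' maximizes the area under the precision-recall curve against the gold
#' standard.
#'
#' @param ds An `expression_dataset`.
#' @param ranked A `ranked_edges` data frame.
#' @param candidate_sizes Integer vector of set sizes to evaluate.
#' @param gold Gold standard data frame (`tf`, `target`, `label`).
#' @param theta,swap_ref Passed to [rerank()].
#' @param seed Seed for the tie order of unranked gold edges in evaluation.
#' @return The selected set size.
#' @export
holdout_size_selection <- function(ds, ranked, candidate_sizes, gold,
                                   theta = 0.5, swap_ref = FALSE, seed = 1L) {
  if (is.null(gold) || nrow(gold) == 0L) {
    stop("no gold standard: supply set_size explicitly")
  }
  if (length(candidate_sizes) == 1L) return(candidate_sizes)
  hold <- seq.int(1L, nrow(ds$values), by = 8L)
  ds_h <- expression_dataset(ds$values[hold, , drop = FALSE],
                             ds$genes, ds$is_tf)
  auprs <- vapply(candidate_sizes, function(k) {
    rr <- rerank(ds_h, ranked, k, theta, swap_ref)
    evaluate_pr_roc(rr, gold, seed = seed)$aupr
  }, numeric(1))
  candidate_sizes[which.max(auprs)]
}

#' Precision-recall and ROC evaluation against a gold standard
#'
#' Evaluates a ranked edge list against a gold standard of labelled TF-TG
#' pairs.  Only pairs present in the gold standard enter the evaluation;
#' gold pairs missing from the ranked list are appended in random order
#' (challenge convention, seeded for reproducibility).  The precision-recall
#' area uses step-wise integration (one rectangle per recovered positive);
#' the ROC area is the Mann-Whitney statistic of the ranks.
#'
#' @param ranked A `ranked_edges` data frame.
#' @param gold Data frame with columns `tf`, `target`, `label` (0/1).
#' @param seed Seed for the order of appended unranked pairs.
#' @return List with `aupr` and `auroc`.
#' @export
evaluate_pr_roc <- function(ranked, gold, seed = NULL) {
  stopifnot(all(c("tf", "target", "label") %in% names(gold)))
  gkeys <- edge_key(gold$tf, gold$target)
  if (anyDuplicated(gkeys)) stop("duplicate gold-standard pairs")
  lab <- as.integer(gold$label)
  names(lab) <- gkeys
  if (sum(lab) == 0L) stop("gold standard contains no positives")
  rkeys <- edge_key(ranked$tf, ranked$target)
  inref <- rkeys[rkeys %in% gkeys]
  missing <- setdiff(gkeys, inref)
  if (length(missing) > 1L) {
    missing <- with_local_seed(seed, sample(missing))
  }
  ordered <- c(inref, missing)
  y <- lab[ordered]
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  tp <- cumsum(y)
  idx_pos <- which(y == 1L)
  aupr <- sum(tp[idx_pos] / idx_pos) / n_pos
  auroc <- if (n_neg == 0L) 1 else {
    (n_neg - (sum(idx_pos) - n_pos * (n_pos + 1) / 2) / n_pos) / n_neg
  }
  list(aupr = aupr, auroc = auroc)
}

#' Challenge overall score from network-specific p-values
#'
#' `score_ROC = 1/2 sum_i -log10 p_ROC,i`, likewise for the
#' precision-recall p-values, and the overall score is their mean.  The
#' p-values come from a user-supplied null distribution of random networks.
#'
#' @param p_roc,p_pr Numeric vectors (one entry per network) of p-values in
#'   `(0, 1]`.
#' @return List with `score_roc`, `score_pr`, `score`.
#' @export
overall_score <- function(p_roc, p_pr) {
  if (any(c(p_roc, p_pr) <= 0) || any(c(p_roc, p_pr) > 1)) {
    stop("p-values must be in (0, 1]")
  }
  score_roc <- 0.5 * sum(-log10(p_roc))
  score_pr <- 0.5 * sum(-log10(p_pr))
  list(score_roc = score_roc, score_pr = score_pr,
       score = (score_roc + score_pr) / 2)
}

#' Label indirect TF-TG dependencies as removable or nonremovable
#'
#' An indirect dependency (a TF that reaches a target gene through the
#' directed gold standard without a direct edge) is refutable by the
#' single-interface test only when a single interface variable mediates it.
#' If the target's gold-standard regulators that mediate the dependency
#' include two or more TFs that are mutually dependent -- one reachable from
#' the other, or both reachable from a shared regulator -- the dependency is
#' labelled `nonremovable`; otherwise `removable`.
#'
#' @param gold Data frame of directed gold-standard edges (`tf`, `target`).
#' @param tf_set Character vector of TF labels (default: all regulators in
#'   `gold`).
#' @return Data frame with columns `tf`, `target`, `label` for every
#'   indirect TF-TG dependency (target not itself a TF).
#' @export
classify_indirect <- function(gold, tf_set = unique(gold$tf)) {
  if (nrow(gold) == 0L) {
    return(data.frame(tf = character(), target = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(gold[, c("tf", "target")],
                                     directed = TRUE)
  nodes <- igraph::V(g)$name
  reach <- lapply(seq_along(nodes), function(i) {
    setdiff(nodes[igraph::subcomponent(g, i, mode = "out")], nodes[i])
  })
  names(reach) <- nodes
  parents <- split(gold$tf, gold$target)
  direct <- edge_key(gold$tf, gold$target)
  dependent_pair <- function(u, w) {
    if (w %in% reach[[u]] || u %in% reach[[w]]) return(TRUE)
    anc_u <- nodes[vapply(nodes, function(z) u %in% reach[[z]], logical(1))]
    anc_w <- nodes[vapply(nodes, function(z) w %in% reach[[z]], logical(1))]
    length(intersect(setdiff(anc_u, c(u, w)), setdiff(anc_w, c(u, w)))) > 0L
  }
  out <- list()
  for (a in intersect(tf_set, nodes)) {
    for (tg in setdiff(reach[[a]], tf_set)) {
      if (edge_key(a, tg) %in% direct) next
      med <- intersect(parents[[tg]], c(reach[[a]]))
      med <- intersect(med, tf_set)
      label <- "removable"
      if (length(med) >= 2L) {
        prs <- utils::combn(med, 2L)
        for (j in seq_len(ncol(prs))) {
          if (dependent_pair(prs[1L, j], prs[2L, j])) {
            label <- "nonremovable"
            break
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(tf = a, target = tg,
                                            label = label,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tf = character(), target = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
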