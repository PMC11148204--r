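# Delimited-text I/O.  All parsers reject malformed input rather than
# silently coercing; floating-point output uses 6 significant digits.

split_lines <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  strsplit(lines, sep, fixed = TRUE)
}

#' Read a sample matrix from delimited text
#'
#' Expects a header row of unique component labels and one row of numeric
#' values per sample.  The reference component is moved to the last column;
#' by default it is the last column of the file.  The returned matrix is
#' centred with [center_samples()].
#'
#' @param path File path (tab-separated by default).
#' @param ref_label Optional label of the reference component.
#' @param sep Field separator.
#' @return A centred `sample_matrix`.
#' @export
read_sample_matrix <- function(path, ref_label = NULL, sep = "\t") {
  rows <- split_lines(path, sep)
  if (length(rows) == 0L) stop("empty file: ", path)
  header <- rows[[1L]]
  if (anyDuplicated(header)) stop("duplicate component labels in header")
  if (length(rows) == 1L) stop("no samples in ", path)
  body <- rows[-1L]
  widths <- lengths(body)
  bad <- which(widths != length(header))
  if (length(bad) > 0L) {
    stop("ragged row at line ", bad[1L] + 1L, " of ", path)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(body)), length(body), length(header),
           byrow = TRUE)
  )
  if (anyNA(vals)) {
    cell <- which(is.na(t(vals)), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at line ", cell[2L] + 1L, ", column ", cell[1L])
  }
  colnames(vals) <- header
  if (!is.null(ref_label)) {
    j <- match(ref_label, header)
    if (is.na(j)) stop("reference component '", ref_label, "' not found")
    vals <- vals[, c(setdiff(seq_along(header), j), j), drop = FALSE]
  }
  center_samples(vals)
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write a sample matrix (or any numeric matrix) as delimited text
#'
#' @param s A `sample_matrix` or numeric matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_sample_matrix <- function(s, path, sep = "\t") {
  x <- if (inherits(s, "sample_matrix")) s$values else as.matrix(s)
  header <- colnames(x)
  if (is.null(header)) header <- paste0("c", seq_len(ncol(x)))
  lines <- c(paste(header, collapse = sep),
             apply(x, 1L, function(r) paste(fmt6(r), collapse = sep)))
  writeLines(lines, path)
}

#' Read a ranked edge list (`TF<TAB>target<TAB>confidence`)
#'
#' @param path File path.
#' @return A `ranked_edges` data frame with an artificial p-value `rank/N`.
#' @export
read_edge_list <- function(path) {
  rows <- split_lines(path)
  if (any(lengths(rows) != 3L)) stop("edge list rows must have 3 fields")
  conf <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  if (anyNA(conf)) stop("non-numeric confidence in ", path)
  edges <- data.frame(tf = vapply(rows, `[[`, "", 1L),
                      target = vapply(rows, `[[`, "", 2L),
                      confidence = conf, stringsAsFactors = FALSE)
  if (anyDuplicated(edge_key(edges$tf, edges$target))) {
    stop("duplicate edges in ", path)
  }
  if (is.unsorted(rev(edges$confidence))) {
    warning("confidences are not sorted in descending order")
  }
  edges$p_value <- seq_len(nrow(edges)) / nrow(edges)
  class(edges) <- c("ranked_edges", "data.frame")
  edges
}

#' Write a ranked edge list
#'
#' @param edges A `ranked_edges` data frame.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  lines <- paste(edges$tf, edges$target, fmt6(edges$confidence), sep = "\t")
  writeLines(lines, path)
}

#' Read a gold standard (`TF<TAB>target<TAB>{0,1}`)
#'
#' @param path File path.
#' @param ds Optional `expression_dataset`; unknown gene labels raise an
#'   error listing the offenders.
#' @return Data frame with columns `tf`, `target`, `label`.
#' @export
read_gold <- function(path, ds = NULL) {
  rows <- split_lines(path)
  if (any(lengths(rows) != 3L)) stop("gold standard rows must have 3 fields")
  lab <- vapply(rows, `[[`, "", 3L)
  if (!all(lab %in% c("0", "1"))) stop("gold labels must be 0 or 1")
  gold <- data.frame(tf = vapply(rows, `[[`, "", 1L),
                     target = vapply(rows, `[[`, "", 2L),
                     label = as.integer(lab), stringsAsFactors = FALSE)
  if (!is.null(ds)) {
    unknown <- setdiff(unique(c(gold$tf, gold$target)), ds$genes)
    if (length(unknown) > 0L) {
      stop("unknown gene labels in gold standard: ",
           paste(unknown, collapse = ", "))
    }
  }
  gold
}

#' Read an expression matrix (genes in the header row, one sample per row)
#'
#' @param path Expression file path.
#' @param tf_path Path to the TF list (one gene identifier per line).
#' @return An `expression_dataset`.
#' @export
read_expression <- function(path, tf_path) {
  rows <- split_lines(path)
  if (length(rows) < 2L) stop("no samples in ", path)
  genes <- rows[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  body <- rows[-1L]
  if (any(lengths(body) != length(genes))) stop("ragged expression rows")
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(body)), length(body), length(genes),
           byrow = TRUE)
  )
  if (anyNA(vals)) stop("non-numeric expression value in ", path)
  tfs <- readLines(tf_path)
  tfs <- tfs[nzchar(tfs)]
  unknown <- setdiff(tfs, genes)
  if (length(unknown) > 0L) {
    stop("TF labels missing from expression data: ",
         paste(unknown, collapse = ", "))
  }
  expression_dataset(vals, genes, genes %in% tfs)
}

#' Write a modularization to a JSON spec file
#'
#' @param m A `modularization`.
#' @param path Output path.
#' @export
write_modularization <- function(m, path) {
  jsonlite::write_json(
    list(ref = m$ref, kind = m$kind, label = m$label,
         modules = m$modules, linear = m$linear),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
}

#' Read a modularization from a JSON spec file
#'
#' @param path File path.
#' @return A `modularization`.
#' @export
read_modularization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mods <- x$modules
  if (is.matrix(mods)) mods <- lapply(seq_len(nrow(mods)), function(i) mods[i, ])
  if (is.null(mods)) mods <- list()
  if (is.numeric(mods)) mods <- list(mods)
  lin <- x$linear
  if (is.null(lin)) lin <- list()
  if (is.numeric(lin)) lin <- list(lin)
  modularization(mods, ref = x$ref, kind = x$kind,
                 label = if (is.null(x$label)) "" else x$label,
                 linear = lin)
}

#' Write a candidate results table as delimited text
#'
#' One row per tested candidate: label, statistic, shape parameter, scaling,
#' minimal level, p-value (scientific notation) and decision.
#'
#' @param results Data frame from [test_candidates()].
#' @param path Output path.
#' @export
write_results_table <- function(results, path) {
  lines <- c(
    paste(c("label", "T", "zeta", "lambda_max", "alpha_min", "p", "reject"),
          collapse = "\t"),
    vapply(seq_len(nrow(results)), function(i) {
      paste(results$label[i], fmt6(results$statistic[i]),
            fmt6(results$zeta[i]), fmt6(results$lambda_max[i]),
            formatC(results$alpha_min[i], format = "e", digits = 5),
            formatC(results$p_value[i], format = "e", digits = 5),
            ifelse(results$reject[i], "yes", "no"), sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
}
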