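#' Construct a functional module
#'
#' A functional module is a set of at least two observable components that
#' interact with the rest of the network only through a single (possibly
#' latent) interface variable.  The reference component never belongs to a
#' module.
#'
#' @param members Integer vector of component indices.
#' @return Sorted integer vector of class `functional_module`.
#' @export
functional_module <- function(members) {
  m <- sort(unique(as.integer(members)))
  structure(m, class = "functional_module")
}

#' Construct a modularization
#'
#' @param modules List of integer vectors (the functional modules).  May be
#'   empty for the fully linear model.
#' @param ref Index of the reference component (by convention the last
#'   component, `d`).
#' @param kind One of `"flat"`, `"nested"`, `"linear_full"` or `NULL`
#'   (classified on validation).  `"linear_full"` declares the purely linear
#'   model in which all moment ratios share one value.
#' @param label Text label used in result tables.
#' @param linear Optional list of component sets declared as purely linear
#'   modules; each adds an equality constraint over all ratio indices of its
#'   above-diagonal submatrix.
#' @return A `modularization` object.
#' @export
modularization <- function(modules = list(), ref = NULL, kind = NULL,
                           label = "", linear = list()) {
  modules <- lapply(modules, function(m) sort(unique(as.integer(m))))
  linear <- lapply(linear, function(m) sort(unique(as.integer(m))))
  structure(
    list(modules = modules, ref = if (is.null(ref)) NA_integer_ else
      as.integer(ref), kind = kind, label = label, linear = linear),
    class = "modularization"
  )
}

#' @export
print.modularization <- function(x, ...) {
  mods <- if (length(x$modules) == 0) "(none)" else
    paste(vapply(x$modules, function(m) paste0("{", paste(m, collapse = ","), "}"),
                 character(1)), collapse = " ")
  cat(sprintf("modularization %s [%s]: modules %s, ref = %s\n",
              x$label, if (is.null(x$kind)) "?" else x$kind, mods, x$ref))
  invisible(x)
}

disjoint_or_nested <- function(a, b) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

#' Classify a modularization as flat, nested or invalid
#'
#' A modularization is flat if all its modules are pairwise disjoint and
#' nested if every pair of modules is either disjoint or one contains the
#' other.  Each module must have at least two members, exclude the reference
#' component and be a proper subset of the non-reference components.
#'
#' @param m A `modularization`.
#' @param d Total component count (reference component is `d`).
#' @return `"flat"`, `"nested"` or `"invalid"` (with a `reason` attribute).
#' @export
classify_modularization <- function(m, d) {
  invalid <- function(reason) structure("invalid", reason = reason)
  base <- seq_len(d - 1L)
  for (mod in m$modules) {
    if (length(mod) < 2L) return(invalid("module with fewer than 2 components"))
    if (any(!(mod %in% base))) {
      if (d %in% mod) return(invalid("module contains the reference component"))
      return(invalid("component index out of range"))
    }
    if (length(mod) == length(base)) {
      return(invalid("module equals the full set of non-reference components"))
    }
  }
  if (length(m$modules) >= 2L) {
    for (i in seq_len(length(m$modules) - 1L)) {
      for (j in seq.int(i + 1L, length(m$modules))) {
        if (!disjoint_or_nested(m$modules[[i]], m$modules[[j]])) {
          return(invalid("overlapping modules that are not nested"))
        }
      }
    }
  }
  flat <- TRUE
  if (length(m$modules) >= 2L) {
    for (i in seq_len(length(m$modules) - 1L)) {
      for (j in seq.int(i + 1L, length(m$modules))) {
        if (length(intersect(m$modules[[i]], m$modules[[j]])) > 0L) flat <- FALSE
      }
    }
  }
  if (flat) "flat" else "nested"
}

#' Equality index sets implied by a modularization
#'
#' Each functional module `S` forces, for every non-reference component `l`
#' outside `S`, the moment ratios `{v(k, l) : k in S}` to share one value.
#' Constraints from different modules are merged transitively (union-find);
#' unconstrained ratio indices are kept as singleton sets so the family is a
#' partition of all ratio indices.  A declared linear module additionally
#' constrains all above-diagonal ratio indices of its submatrix to one value;
#' the fully linear model constrains all ratio indices.
#'
#' @param m A `modularization` (must classify as flat or nested).
#' @param d Total component count.
#' @return An `index_set_family`: list with `sets` (list of sorted integer
#'   vectors, ordered by smallest element), `d_X` and `d_X0`.
#' @export
index_sets <- function(m, d) {
  cls <- classify_modularization(m, d)
  if (identical(as.character(cls), "invalid")) {
    stop("invalid modularization: ", attr(cls, "reason"))
  }
  d_X0 <- (d - 1L) * (d - 2L) / 2L
  groups <- list()
  for (mod in m$modules) {
    outside <- setdiff(seq_len(d - 1L), mod)
    for (l in outside) {
      vs <- vec_index(pmin(mod, l), pmax(mod, l), d)
      groups <- c(groups, list(vs))
    }
  }
  lin <- m$linear
  if (identical(m$kind, "linear_full")) {
    lin <- c(lin, list(seq_len(d - 1L)))
  }
  for (comp in lin) {
    if (length(comp) >= 2L) {
      pr <- utils::combn(comp, 2L)
      groups <- c(groups, list(vec_index(pr[1L, ], pr[2L, ], d)))
    }
  }
  index_set_family(groups, d_X0)
}

#' Build an index-set family from equality groups
#'
#' Merges overlapping groups transitively and fills in singletons so the
#' result partitions `1..d_X0`.
#'
#' @param groups List of integer vectors of ratio indices (may overlap).
#' @param d_X0 Total number of ratio indices.
#' @return An `index_set_family`.
#' @export
index_set_family <- function(groups, d_X0) {
  parent <- seq_len(d_X0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (g in groups) {
    if (length(g) < 2L) next
    r0 <- find(g[1L])
    for (i in g[-1L]) {
      ri <- find(i)
      if (ri != r0) parent[ri] <- r0
    }
  }
  roots <- vapply(seq_len(d_X0), find, integer(1))
  sets <- split(seq_len(d_X0), roots)
  sets <- lapply(unname(sets), as.integer)
  sets <- sets[order(vapply(sets, min, integer(1)))]
  cover <- sort(unlist(sets))
  stopifnot(identical(cover, seq_len(d_X0)))
  structure(
    list(sets = sets, d_X = length(sets), d_X0 = d_X0),
    class = "index_set_family"
  )
}

#' Degrees of freedom (gamma shape parameter) of an index-set family
#'
#' Half the number of independent equality constraints,
#' `zeta = (d_X0 - d_X) / 2`.
#'
#' @param f An `index_set_family`.
#' @return The shape parameter `zeta`.
#' @export
degrees_of_freedom <- function(f) {
  (f$d_X0 - f$d_X) / 2
}

#' Enumerate all candidate hierarchical modularizations
#'
#' Enumerates every nonempty family of subsets of the non-reference
#' components such that each subset has at least two members, is a proper
#' subset of the non-reference components, and the family is pairwise
#' disjoint-or-nested (laminar).  For five components this yields exactly 25
#' candidates.  The candidates are ordered canonically: by number of modules,
#' then lexicographically on the sorted module lists, and labelled
#' `M1`, `M2`, ...  Optionally the fully linear model `ML` is appended.
#'
#' @param d Total component count (reference fixed to `d`); at least 3.
#' @param include_linear Append the fully linear modularization?
#' @param max_components Enumeration cap on `d` (default 24).
#' @return List of `modularization` objects.
#' @export
enumerate_candidates <- function(d, include_linear = FALSE,
                                 max_components = 24L) {
  if (d < 3L) stop("need at least 3 components")
  if (d > max_components) stop("too many components for enumeration")
  base <- seq_len(d - 1L)
  subs <- list()
  for (size in seq.int(2L, max(2L, d - 2L))) {
    if (size > d - 2L) break
    cc <- utils::combn(base, size)
    subs <- c(subs, lapply(seq_len(ncol(cc)), function(j) cc[, j]))
  }
  key <- function(mod) paste(mod, collapse = ",")
  ord <- order(vapply(subs, length, integer(1)),
               vapply(subs, key, character(1)))
  subs <- subs[ord]
  n_sub <- length(subs)
  families <- list()
  recurse <- function(start, current) {
    for (i in seq.int(start, n_sub)) {
      cand <- subs[[i]]
      ok <- all(vapply(current, function(mod) disjoint_or_nested(mod, cand),
                       logical(1)))
      if (ok) {
        fam <- c(current, list(cand))
        families[[length(families) + 1L]] <<- fam
        if (i < n_sub) recurse(i + 1L, fam)
      }
    }
  }
  if (n_sub > 0L) recurse(1L, list())
  fam_key <- function(fam) {
    fam <- fam[order(vapply(fam, length, integer(1)),
                     vapply(fam, key, character(1)))]
    paste(vapply(fam, key, character(1)), collapse = "|")
  }
  ord <- order(vapply(families, length, integer(1)),
               vapply(families, fam_key, character(1)))
  families <- families[ord]
  out <- lapply(seq_along(families), function(i) {
    m <- modularization(families[[i]], ref = d, label = paste0("M", i))
    m$kind <- as.character(classify_modularization(m, d))
    m
  })
  if (include_linear) {
    out <- c(out, list(modularization(list(), ref = d, kind = "linear_full",
                                      label = "ML")))
  }
  out
}

#' Index-set families for linear-membership testing
#'
#' Tests whether a unit (a module or branch) participates in a larger purely
#' linear module of a fixed total size: one family per combination of
#' candidate groups that contains the unit and totals exactly `size`
#' observable components.  The fixed size keeps the degrees of freedom equal
#' across tested units.
#'
#' @param unit Integer vector of component indices of the unit under test.
#' @param groups List of integer vectors (candidate partners, disjoint from
#'   the unit and from each other).
#' @param size Required total number of observable components.
#' @param d Total component count.
#' @return List of `index_set_family` objects (empty if no combination
#'   reaches `size`; the unit is then not testable).
#' @export
linear_membership_family <- function(unit, groups, size, d) {
  unit <- sort(unique(as.integer(unit)))
  if (length(unit) > size) return(list())
  out <- list()
  ng <- length(groups)
  d_X0 <- (d - 1L) * (d - 2L) / 2L
  for (mask in seq.int(0L, 2L^ng - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ng) - 1L)) != 0L)
    comp <- sort(c(unit, unlist(groups[sel])))
    if (length(comp) != length(unique(comp))) next
    if (length(comp) != size) next
    pr <- utils::combn(comp, 2L)
    out <- c(out, list(index_set_family(
      list(vec_index(pr[1L, ], pr[2L, ], d)), d_X0)))
  }
  out
}
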