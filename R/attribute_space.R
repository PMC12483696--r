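# Latent attribute space for polytomous cognitive diagnosis: attribute
# specifications, pattern enumeration, Q-matrices and per-item latent-group
# partitions.

#' Specify a set of polytomous attributes
#'
#' An attribute specification fixes the number of attributes `K` and, per
#' attribute, the number of ordered mastery levels `M_k` (levels are coded
#' `0, ..., M_k - 1`, with 0 = no mastery).  Attributes may have unequal
#' numbers of levels, e.g. a mix of dichotomous and three-level skills.
#'
#' @param levels Integer vector of length `K`; each entry is the number of
#'   levels `M_k` of attribute `k` and must be at least 2.
#' @return An object of class `attr_spec` with elements `K`, `levels` and
#'   `n_classes` (the number of latent classes, `prod(levels)`).
#' @examples
#' attribute_spec(c(3, 3, 3))$n_classes       # 27
#' attribute_spec(c(2, 2, 2, 2, 3, 3))$n_classes  # 144
#' @export
attribute_spec <- function(levels) {
  levels <- as.integer(levels)
  if (length(levels) < 1L || anyNA(levels))
    stop("'levels' must be a non-empty integer vector")
  if (any(levels < 2L))
    stop("every attribute must have at least 2 levels (M_k >= 2)")
  structure(
    list(K = length(levels), levels = levels, n_classes = prod(levels)),
    class = "attr_spec"
  )
}

#' @export
print.attr_spec <- function(x, ...) {
  cat("Attribute specification: K =", x$K,
      "| levels =", paste(x$levels, collapse = ","),
      "| latent classes =", x$n_classes, "\n")
  invisible(x)
}

.assert_spec <- function(spec) {
  if (!inherits(spec, "attr_spec"))
    stop("'spec' must be an attribute_spec() object")
  invisible(spec)
}

# Positional weights for encoding a pattern as a class index
# (last attribute varies fastest).
.pattern_weights <- function(levels) {
  K <- length(levels)
  rev(cumprod(rev(c(levels[-1L], 1L))))
}

# 1-based class index of each row of a pattern matrix.
.encode_patterns <- function(patterns, levels) {
  w <- .pattern_weights(levels)
  as.integer(patterns %*% w) + 1L
}

#' Enumerate all latent classes (attribute patterns)
#'
#' Lists every combination of attribute levels in lexicographic order with
#' the last attribute varying fastest: the first pattern is all zeros, the
#' last is all maximum levels.
#'
#' @param spec An [attribute_spec()] object.
#' @return Integer matrix with `prod(levels)` rows and `K` columns, named
#'   `A1, ..., AK`.
#' @examples
#' enumerate_patterns(attribute_spec(c(2, 3)))
#' @export
enumerate_patterns <- function(spec) {
  .assert_spec(spec)
  grids <- lapply(rev(spec$levels), function(M) 0:(M - 1L))
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)   # first column fastest
  m <- as.matrix(g[, rev(seq_len(spec$K)), drop = FALSE])
  dimnames(m) <- list(NULL, paste0("A", seq_len(spec$K)))
  storage.mode(m) <- "integer"
  m
}

#' Partition the latent classes into an item's latent groups
#'
#' An item with Q-matrix row `q_row` only involves the attributes with
#' `q_jk > 0`.  Two latent classes that agree on all those required
#' attributes are indistinguishable for the item and fall in the same
#' latent group; the group label is the class's level vector restricted to
#' the required attributes.
#'
#' @param q_row Integer vector of length `K`, entries in `0, ..., M_k - 1`;
#'   at least one entry must be positive.
#' @param spec An [attribute_spec()] object.
#' @return An object of class `latent_groups`: a list with `required`
#'   (indices of required attributes), `q_req` (their required levels),
#'   `groups` (group-label matrix, one row per latent group, same ordering
#'   convention as [enumerate_patterns()]), `group_index` (group of each
#'   latent class), `n_groups` and `sizes`.
#' @examples
#' sp <- attribute_spec(c(3, 3, 3))
#' pg <- partition_groups(c(1, 2, 0), sp)
#' pg$n_groups                       # 9
#' pg$group_index[1:3]               # classes 000, 001, 002 share group 00
#' @export
partition_groups <- function(q_row, spec) {
  .assert_spec(spec)
  q_row <- as.integer(q_row)
  if (length(q_row) != spec$K)
    stop("q_row must have one entry per attribute")
  if (any(q_row < 0L) || any(q_row >= spec$levels))
    stop("q_row entries must lie in 0, ..., M_k - 1")
  required <- which(q_row > 0L)
  if (length(required) == 0L)
    stop("item measures nothing: all-zero Q-matrix row")
  sub_spec <- attribute_spec(spec$levels[required])
  groups <- enumerate_patterns(sub_spec)
  colnames(groups) <- paste0("A", required)
  patterns <- enumerate_patterns(spec)
  gidx <- .encode_patterns(patterns[, required, drop = FALSE],
                           spec$levels[required])
  structure(
    list(required = required, q_req = q_row[required], groups = groups,
         group_index = gidx, n_groups = nrow(groups),
         sizes = tabulate(gidx, nrow(groups))),
    class = "latent_groups"
  )
}

#' @export
print.latent_groups <- function(x, ...) {
  cat("Latent-group partition:", x$n_groups, "groups over attributes",
      paste(x$required, collapse = ","), "\n")
  invisible(x)
}

# Canonical internal model-kind codes.  Aliases cover the names used in the
# polytomous-CDM literature; the additive-logit/log aliases denote the fully
# additive column set applied on that link scale.
.canon_kind <- function(model_kind) {
  s <- gsub("[^a-z]", "", tolower(model_kind))
  out <- switch(s,
    "saturated" = , "spcdm" = "saturated",
    "pgdina" = "pgdina",
    "fam" = , "fa" = , "additive" = , "fullyadditive" = ,
      "additivelogit" = , "additivelog" = "fam",
    "minfam" = , "minfa" = "minfam",
    "maxfam" = , "maxfa" = "maxfam",
    "conjunctive" = , "conj" = , "conjspcdm" = , "pdina" = "conj",
    "disjunctive" = , "disj" = , "disjspcdm" = , "pdino" = "disj",
    NULL)
  if (is.null(out)) stop("unknown model kind: ", model_kind)
  out
}

#' Number of free item parameters of a model kind
#'
#' @param model_kind One of `"saturated"`, `"pG-DINA"`, `"fA-M"`,
#'   `"min-fA-M"`, `"max-fA-M"`, `"conjunctive"`, `"disjunctive"` (several
#'   spelling aliases are accepted; `"additive-logit"`/`"additive-log"`
#'   count as the fully additive model).
#' @param q_row Q-matrix row of the item.
#' @param spec An [attribute_spec()] object.
#' @return Integer parameter count.  The saturated count is the product of
#'   the *maximum* levels of the required attributes (it does not depend on
#'   the required levels), the polytomous G-DINA count is `2^K*_j`, the
#'   fully additive count is `1 + sum(M_k - 1)` over required attributes,
#'   and the conjunctive/disjunctive models always have 2 parameters.
#' @examples
#' sp <- attribute_spec(c(3, 3, 3))
#' count_item_parameters("saturated", c(1, 2, 0), sp)  # 9
#' count_item_parameters("fA-M", c(1, 2, 0), sp)       # 5
#' @export
count_item_parameters <- function(model_kind, q_row, spec) {
  kind <- .canon_kind(model_kind)
  pg <- partition_groups(q_row, spec)
  M <- spec$levels[pg$required]
  as.integer(switch(kind,
    saturated = prod(M),
    pgdina    = 2L^length(pg$required),
    fam       = 1L + sum(M - 1L),
    minfam    = 1L + sum(M - pg$q_req),
    maxfam    = 1L + sum(pg$q_req),
    conj      = 2L,
    disj      = 2L))
}

#' Heuristic coverage report for a Q-matrix
#'
#' Reports, per attribute and level `m >= 1`, how many items require exactly
#' that level, flags attribute levels required by fewer than two items, and
#' flags all-zero rows.  This is a coverage heuristic, not an
#' identifiability check.
#'
#' @param Q Integer matrix, items in rows, attributes in columns.
#' @param spec An [attribute_spec()] object.
#' @return A list of class `qmatrix_report` with `coverage` (data frame of
#'   attribute, level, n_items), `undercovered` (rows of `coverage` with
#'   fewer than 2 items), `zero_rows` and `out_of_range` (item/attribute
#'   pairs with entries at or above `M_k`).
#' @export
validate_qmatrix <- function(Q, spec) {
  .assert_spec(spec)
  Q <- as.matrix(Q)
  if (ncol(Q) != spec$K) stop("Q must have one column per attribute")
  cov <- do.call(rbind, lapply(seq_len(spec$K), function(k) {
    data.frame(attribute = k, level = seq_len(spec$levels[k] - 1L),
               n_items = vapply(seq_len(spec$levels[k] - 1L),
                                function(m) sum(Q[, k] == m), integer(1)))
  }))
  oor <- which(Q < 0 | Q >= matrix(spec$levels, nrow(Q), spec$K, byrow = TRUE),
               arr.ind = TRUE)
  structure(
    list(coverage = cov,
         undercovered = cov[cov$n_items < 2L, , drop = FALSE],
         zero_rows = which(rowSums(Q > 0) == 0L),
         out_of_range = oor),
    class = "qmatrix_report"
  )
}

#' @export
print.qmatrix_report <- function(x, ...) {
  cat("Q-matrix coverage report\n")
  if (nrow(x$undercovered)) {
    cat("Attribute levels required by < 2 items:\n")
    print(x$undercovered, row.names = FALSE)
  } else cat("All attribute levels required by >= 2 items.\n")
  if (length(x$zero_rows))
    cat("All-zero rows (items measuring nothing):",
        paste(x$zero_rows, collapse = ", "), "\n")
  if (NROW(x$out_of_range))
    cat("Entries out of range:", NROW(x$out_of_range), "\n")
  invisible(x)
}
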