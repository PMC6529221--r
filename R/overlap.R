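# Voxel-overlap scoring between registered binary masks: the package's proxy
# for potential connectivity. For masks A and B on one grid, P1 is the
# percentage of A's voxels that fall inside B and P2 the reverse; the reported
# score combines them (mean by default, max/min as alternatives).

#' Directional percentage overlap
#'
#' `100 * |A intersect B| / |A|`: the percentage of mask `a`'s voxels that lie
#' inside mask `b`. Undefined (error) for an empty `a`.
#'
#' @param a,b [lh_mask] objects on one grid.
#' @return Percentage in \[0, 100\].
#' @export
directional_overlap <- function(a, b) {
  stopifnot(inherits(a, "lh_mask"), inherits(b, "lh_mask"))
  assert_same_grid(a, b)
  na <- sum(a$data)
  if (na == 0L) {
    stop("mask `a` is empty: directional overlap undefined", call. = FALSE)
  }
  100 * sum(a$data & b$data) / na
}

#' Bidirectional overlap score
#'
#' Computes P1 (overlap of `a` in `b`), P2 (overlap of `b` in `a`) and their
#' mean, max and min. The mean is the headline score; max and min behave
#' similarly in practice and are reported alongside.
#'
#' @param a,b Non-empty [lh_mask] objects on one grid.
#' @return A one-row tibble with columns `p1`, `p2`, `mean_score`,
#'   `max_score`, `min_score` (percent).
#' @examples
#' g <- overlap_design(target_fraction = 0.5, size_a = 100, size_b = 200,
#'                     seed = 1)
#' pr <- generate_mask_pair(g)
#' overlap_score(pr$a, pr$b)
#' @export
overlap_score <- function(a, b) {
  p1 <- directional_overlap(a, b)
  p2 <- directional_overlap(b, a)
  tibble::tibble(p1 = p1, p2 = p2, mean_score = (p1 + p2) / 2,
                 max_score = max(p1, p2), min_score = min(p1, p2))
}

combined_score <- function(a, b, combine) {
  s <- overlap_score(a, b)
  switch(combine, mean = s$mean_score, max = s$max_score, min = s$min_score)
}

#' Pairwise overlap matrix between two mask collections
#'
#' `values[i, j]` is the combined overlap score of `set1[[i]]` against
#' `set2[[j]]`. With identical sets and the mean rule the matrix is symmetric
#' with diagonal 100. The true diagonal is always stored; the `-1` sentinel
#' some heatmaps use for self-comparisons is applied only at render time
#' (see [autoplot.lh_overlap_matrix()]).
#'
#' @param set1,set2 Named lists of non-empty [lh_mask] objects on one grid.
#'   Names become row/column labels; unnamed lists are labelled by cell type.
#' @param combine `"mean"` (default), `"max"` or `"min"`.
#' @return An `lh_overlap_matrix`: list with `values` (numeric matrix, percent),
#'   `combine` and the label vectors.
#' @export
pairwise_matrix <- function(set1, set2 = set1,
                            combine = c("mean", "max", "min")) {
  combine <- match.arg(combine)
  label_of <- function(set) {
    nm <- names(set)
    if (is.null(nm)) nm <- vapply(set, function(m) m$cell_type, character(1))
    make.unique(nm)
  }
  empties <- c(
    label_of(set1)[vapply(set1, function(m) sum(m$data) == 0, logical(1))],
    label_of(set2)[vapply(set2, function(m) sum(m$data) == 0, logical(1))])
  if (length(empties)) {
    stop(sprintf("empty mask(s): %s", paste(unique(empties), collapse = ", ")),
         call. = FALSE)
  }
  rows <- label_of(set1); cols <- label_of(set2)
  vals <- matrix(NA_real_, length(set1), length(set2),
                 dimnames = list(rows, cols))
  for (i in seq_along(set1)) {
    for (j in seq_along(set2)) {
      vals[i, j] <- combined_score(set1[[i]], set2[[j]], combine)
    }
  }
  structure(list(values = vals, combine = combine,
                 row_labels = rows, col_labels = cols),
            class = "lh_overlap_matrix")
}

#' @export
print.lh_overlap_matrix <- function(x, ...) {
  cat(sprintf("<lh_overlap_matrix> %d x %d (%s rule), scores %% in [%.1f, %.1f]\n",
              nrow(x$values), ncol(x$values), x$combine,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Tidy an overlap matrix into long form
#' @param x An `lh_overlap_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `score`.
#' @method tidy lh_overlap_matrix
#' @export
tidy.lh_overlap_matrix <- function(x, ...) {
  tibble::tibble(
    row = rep(x$row_labels, times = ncol(x$values)),
    col = rep(x$col_labels, each = nrow(x$values)),
    score = as.numeric(x$values)
  )
}

#' Classify significant potential interactions
#'
#' A cell-type pair counts as a significant potential interaction when its
#' overlap score strictly exceeds the threshold (15% by default, the cutoff
#' validated against double-labelling). Row summaries report the fraction of
#' rows with at least one significant partner and the complementary fraction
#' with none; for a square matrix over one set, the diagonal (self-overlap) is
#' excluded.
#'
#' @param m An `lh_overlap_matrix`.
#' @param threshold Percent cutoff, strict `>`. Default 15.
#' @return An `lh_interaction_summary`: list with `significant` (logical
#'   matrix), `threshold`, `frac_rows_with_any`, `frac_rows_with_none`.
#' @export
classify_interactions <- function(m, threshold = 15) {
  stopifnot(inherits(m, "lh_overlap_matrix"))
  sig <- m$values > threshold
  consider <- matrix(TRUE, nrow(sig), ncol(sig))
  if (identical(m$row_labels, m$col_labels)) diag(consider) <- FALSE
  any_hit <- vapply(seq_len(nrow(sig)),
                    function(i) any(sig[i, ] & consider[i, ]), logical(1))
  structure(list(significant = sig, threshold = threshold,
                 frac_rows_with_any = mean(any_hit),
                 frac_rows_with_none = mean(!any_hit),
                 row_labels = m$row_labels, col_labels = m$col_labels),
            class = "lh_interaction_summary")
}

#' @export
print.lh_interaction_summary <- function(x, ...) {
  cat(sprintf(
    "<lh_interaction_summary> >%g%% rule: %.0f%% of rows with a partner, %.0f%% without\n",
    x$threshold, 100 * x$frac_rows_with_any, 100 * x$frac_rows_with_none))
  invisible(x)
}

#' One-row summary of an interaction classification
#' @param x An `lh_interaction_summary`.
#' @param ... Unused.
#' @return Tibble with threshold, n rows, and the two row fractions.
#' @method glance lh_interaction_summary
#' @export
glance.lh_interaction_summary <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 n_rows = nrow(x$significant),
                 frac_rows_with_any = x$frac_rows_with_any,
                 frac_rows_with_none = x$frac_rows_with_none)
}

#' Hierarchical clustering of an overlap matrix
#'
#' Agglomerative clustering of the row vectors and column vectors
#' independently, by Euclidean distance and complete linkage — the ordering
#' used for overlap heatmaps. Scores are used as-is (no standardisation).
#'
#' @param m An `lh_overlap_matrix` with at least 2 rows and 2 columns.
#' @return List with `row_order`, `col_order` (leaf orders) and `row_tree`,
#'   `col_tree` (`hclust` objects).
#' @export
cluster_matrix <- function(m) {
  stopifnot(inherits(m, "lh_overlap_matrix"))
  if (nrow(m$values) < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  if (ncol(m$values) < 2L) stop("need at least 2 columns to cluster", call. = FALSE)
  rt <- stats::hclust(stats::dist(m$values, method = "euclidean"),
                      method = "complete")
  ct <- stats::hclust(stats::dist(t(m$values), method = "euclidean"),
                      method = "complete")
  list(row_order = rt$order, col_order = ct$order,
       row_tree = rt, col_tree = ct)
}

#' Relationship between two overlap matrices
#'
#' Ordinary least squares of one set of overlap scores on another over shared
#' label pairs (diagonal excluded), e.g. axonal versus dendritic overlap of
#' the same output-neuron pairs. A weak relationship (small R-squared) means
#' neurons whose dendrites overlap do not particularly co-project their axons.
#'
#' @param axon_m,dend_m `lh_overlap_matrix` objects with identical row and
#'   column label sets; `axon_m` supplies the response, `dend_m` the predictor.
#' @return An `lh_overlap_relation`: list with `slope`, `intercept`,
#'   `r_squared`, `n_pairs`, and the underlying `lm` fit.
#' @export
axon_dendrite_relation <- function(axon_m, dend_m) {
  stopifnot(inherits(axon_m, "lh_overlap_matrix"),
            inherits(dend_m, "lh_overlap_matrix"))
  if (!identical(dimnames(axon_m$values), dimnames(dend_m$values))) {
    stop("matrices must share row/column label sets", call. = FALSE)
  }
  keep <- matrix(TRUE, nrow(axon_m$values), ncol(axon_m$values))
  if (identical(axon_m$row_labels, axon_m$col_labels)) diag(keep) <- FALSE
  y <- axon_m$values[keep]
  x <- dend_m$values[keep]
  if (stats::sd(x) == 0) {
    warning("constant predictor: r_squared set to 0")
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          n_pairs = length(y), fit = NULL),
                     class = "lh_overlap_relation"))
  }
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 n_pairs = length(y), fit = fit),
            class = "lh_overlap_relation")
}

#' @export
print.lh_overlap_relation <- function(x, ...) {
  cat(sprintf("<lh_overlap_relation> R^2 = %.3f over %d pairs (slope %.3f)\n",
              x$r_squared, x$n_pairs, x$slope))
  invisible(x)
}

#' @method tidy lh_overlap_relation
#' @export
tidy.lh_overlap_relation <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance lh_overlap_relation
#' @export
glance.lh_overlap_relation <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_pairs = x$n_pairs)
}

#' Screen coverage percentage
#'
#' Percentage of known core cell types covered by a driver-line collection:
#' `100 * n_covered / n_total`. With 63 covered of 165 known core lateral-horn
#' cell types this is ~38%.
#'
#' @param n_covered Covered cell-type count.
#' @param n_total Known cell-type count.
#' @return Percentage (not rounded).
#' @export
coverage_percentage <- function(n_covered, n_total) {
  if (n_total <= 0 || n_covered < 0 || n_covered > n_total) {
    stop("need 0 <= n_covered <= n_total, n_total > 0", call. = FALSE)
  }
  100 * n_covered / n_total
}
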