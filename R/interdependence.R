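# Pairwise regulon-overlap testing.
#
# The interdependence statistic is the hypergeometric survival function
#   sf(m; N, M, n) = P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n)
# for the overlap X of two fixed-size exon sets (sizes M and n) drawn
# without replacement from a shared universe of N exons. A pair is called
# interdependent when sf(m) <= alpha for the observed overlap m.

#' Hypergeometric survival function for regulon overlap
#'
#' Computes `P(X >= m)` for `X ~ Hypergeometric(N, M, n)`: the probability
#' that two sets of sizes `M` and `n`, drawn without replacement from a
#' universe of `N` exons, share at least `m` elements. The upper-tail sum
#' is accumulated in log space so that extreme tails (the regime where
#' planted co-regulation lives) do not underflow pairwise products of
#' binomial coefficients.
#'
#' @param m observed overlap (integer >= 0).
#' @param N universe size.
#' @param M size of the first set.
#' @param n size of the second set.
#' @return the p-value `P(X >= m)`, clamped to \[0, 1\]; exactly 1 when
#'   `m <= 0` and exactly 0 when `m > min(M, n)`.
#' @export
hypergeom_sf <- function(m, N, M, n) {
  if (length(m) > 1L)
    return(vapply(seq_along(m), function(i)
      hypergeom_sf(m[i], N[min(i, length(N))], M[min(i, length(M))],
                   n[min(i, length(n))]), numeric(1)))
  for (v in list(m = m, N = N, M = M, n = n))
    if (is.na(v) || v < 0 || v != round(v))
      stopf("hypergeom_sf arguments must be non-negative integers")
  if (M > N || n > N) stopf("hypergeom_sf requires M <= N and n <= N")
  if (m <= 0) return(1)
  hi <- min(M, n)
  if (m > hi) return(0)
  lo <- max(0L, M + n - N)
  i <- max(m, lo):hi
  log_terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  p <- exp(logsumexp(log_terms))
  min(max(p, 0), 1)
}

#' Test one RBP pair for interdependent regulation
#'
#' Overlap counts: `m` = shared affected exons, `M` and `n` = the two
#' regulon sizes, `N` = size of the union of the two unfiltered universes.
#' A pair with no overlapping exon is reported with status `"no_overlap"`
#' (and p-value 1) rather than silently merged into the non-significant
#' class, so three-state summaries can be drawn.
#'
#' @param reg_a,reg_b `regulon` objects from one cell line and policy.
#' @param alpha significance level (p <= alpha called significant).
#' @param universe `"union"` (default) joins the two unfiltered universes
#'   as a set; `"sum"` adds their sizes (sensitivity variant in which
#'   shared exons are double-counted).
#' @return one-row tibble: `rbp_a`, `rbp_b`, `m`, `N`, `M`, `n`,
#'   `p_value`, `significant`, `status`.
#' @export
test_pair <- function(reg_a, reg_b, alpha = 0.05,
                      universe = c("union", "sum")) {
  universe <- match.arg(universe)
  check_regulon_collection(list(reg_a, reg_b))
  assert_scalar_number(alpha, "alpha", 0, 1)
  m <- length(intersect(reg_a$affected, reg_b$affected))
  N <- if (universe == "union")
    length(union(reg_a$universe, reg_b$universe))
  else length(reg_a$universe) + length(reg_b$universe)
  M <- length(reg_a$affected)
  n <- length(reg_b$affected)
  if (N == 0L) stopf("combined universe is empty for pair %s/%s",
                     reg_a$rbp_name, reg_b$rbp_name)
  p <- hypergeom_sf(m, N, M, n)
  tibble::tibble(
    rbp_a = reg_a$rbp_name, rbp_b = reg_b$rbp_name,
    m = m, N = N, M = M, n = n, p_value = p,
    significant = p <= alpha,
    status = if (m == 0L) "no_overlap" else "tested"
  )
}

#' Test all RBP pairs
#'
#' Runs [test_pair()] for each of the `k(k-1)/2` unordered RBP pairs, in
#' lexicographic order of names.
#'
#' @inheritParams test_pair
#' @param regulons list of >= 2 `regulon` objects (one cell line, one
#'   policy, distinct RBP names).
#' @param adjust `"none"` (default; raw p-values, matching a raw
#'   `p <= alpha` call over all pairs) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values, in which case `significant` is based on the
#'   adjusted value reported in `p_adjusted`.
#' @return tibble with one row per pair.
#' @export
all_pairs <- function(regulons, alpha = 0.05, universe = c("union", "sum"),
                      adjust = c("none", "BH")) {
  universe <- match.arg(universe)
  adjust <- match.arg(adjust)
  regulons <- check_regulon_collection(regulons)
  if (length(regulons) < 2L) stopf("need at least two regulons")
  regulons <- regulons[order(names(regulons))]
  idx <- utils::combn(length(regulons), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j)
    test_pair(regulons[[idx[1, j]]], regulons[[idx[2, j]]],
              alpha = alpha, universe = universe))
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted <= alpha
  }
  out
}

#' Build the interdependence matrix
#'
#' For each RBP (rows), the interdependently regulated exons are those of
#' its affected exons shared with at least one other RBP in the
#' collection. Cell `(r, c)` holds the percentage of row `r`'s
#' interdependent exons that are also affected by column RBP `c`; the
#' diagonal is 100 whenever the row has any interdependent exon. Per-RBP
#' interdependent fractions (share of all affected exons that are
#' interdependent) are returned alongside.
#'
#' @param regulons list of `regulon` objects (one cell line, one policy).
#' @param pair_results optional tibble from [all_pairs()], attached to the
#'   result for significance overlays.
#' @return an `interdependence_matrix`: list with `rbp_order`,
#'   `cells` (numeric matrix, full precision percentages), `row_totals`,
#'   `n_affected`, `per_rbp_interdependent_fraction`, `pair_results`.
#' @export
build_matrix <- function(regulons, pair_results = NULL) {
  regulons <- check_regulon_collection(regulons)
  regulons <- regulons[order(names(regulons))]
  rbps <- names(regulons)
  k <- length(rbps)
  affected <- lapply(regulons, `[[`, "affected")
  n_aff <- vapply(affected, length, 1L)

  multi <- table(unlist(affected, use.names = FALSE))
  interdep <- lapply(affected, function(a) a[multi[a] >= 2L])
  row_totals <- vapply(interdep, length, 1L)

  cells <- matrix(0, k, k, dimnames = list(rbps, rbps))
  for (r in seq_len(k)) {
    if (row_totals[r] == 0L) next
    for (c in seq_len(k)) {
      shared <- length(intersect(interdep[[r]], affected[[c]]))
      cells[r, c] <- 100 * shared / row_totals[r]
    }
  }
  frac <- ifelse(n_aff > 0, 100 * row_totals / n_aff, NA_real_)
  structure(list(rbp_order = rbps, cells = cells,
                 row_totals = stats::setNames(as.integer(row_totals), rbps),
                 n_affected = stats::setNames(as.integer(n_aff), rbps),
                 per_rbp_interdependent_fraction = stats::setNames(frac, rbps),
                 pair_results = pair_results),
            class = "interdependence_matrix")
}

#' @export
print.interdependence_matrix <- function(x, ...) {
  cat(sprintf("<interdependence_matrix> %d RBPs; display cells are %%, rounded\n",
              length(x$rbp_order)))
  print(round(x$cells))
  invisible(x)
}

#' Hierarchically cluster the interdependence matrix
#'
#' Complete-linkage agglomerative clustering on Euclidean distances
#' between matrix rows (and, separately, columns), via [stats::hclust()].
#' Rows are put in lexicographic name order before clustering so the
#' result is deterministic for a given matrix.
#'
#' @param matrix an `interdependence_matrix` or a plain numeric matrix
#'   with row and column names.
#' @return list with `rows` and `cols`, each an `hclust` object, plus
#'   `row_order` / `col_order` leaf name orderings.
#' @export
cluster_matrix <- function(matrix) {
  m <- if (inherits(matrix, "interdependence_matrix")) matrix$cells else matrix
  if (!is.matrix(m) || nrow(m) < 2L)
    stopf("need a matrix with at least 2 rows to cluster")
  if (anyNA(m)) stopf("matrix has missing cells; encode absent overlaps as 0")
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  hr <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = "complete")
  list(rows = hr, cols = hc,
       row_order = rownames(m)[hr$order], col_order = colnames(m)[hc$order])
}
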