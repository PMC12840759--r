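# Significance filters producing per-RBP regulons (affected-exon sets).
#
# Two stock policies mirror the two study designs this package targets:
#   * HeLa-style:   |dPSI| > 0.15, no FDR requirement (the source tables
#                   carry no usable statistics).
#   * ENCODE-style: |dPSI| > 0.10 and FDR <= 0.05.
# The dPSI inequality is strict ("greater than"), the FDR bound inclusive.

#' Define a significance filter policy
#'
#' @param min_abs_delta_psi exclusive lower bound on |delta PSI|
#'   (fraction; thresholds quoted in percent are divided by 100 here).
#' @param max_fdr inclusive upper bound on FDR, or `NULL` for no FDR filter.
#' @param name policy label.
#' @return a `filter_policy` object.
#' @export
filter_policy <- function(min_abs_delta_psi, max_fdr = NULL, name = "custom") {
  assert_scalar_number(min_abs_delta_psi, "min_abs_delta_psi", 0, 1 - 1e-12)
  if (!is.null(max_fdr)) assert_scalar_number(max_fdr, "max_fdr", 0, 1)
  structure(list(name = name, min_abs_delta_psi = min_abs_delta_psi,
                 max_fdr = max_fdr), class = "filter_policy")
}

#' @rdname filter_policy
#' @export
hela_policy <- function() filter_policy(0.15, NULL, name = "hela")

#' @rdname filter_policy
#' @export
encode_policy <- function() filter_policy(0.10, 0.05, name = "encode")

policy_equal <- function(a, b) {
  isTRUE(all.equal(a$min_abs_delta_psi, b$min_abs_delta_psi)) &&
    ((is.null(a$max_fdr) && is.null(b$max_fdr)) ||
       (!is.null(a$max_fdr) && !is.null(b$max_fdr) &&
          isTRUE(all.equal(a$max_fdr, b$max_fdr))))
}

#' Filter a knockdown table into a regulon
#'
#' Applies a significance policy to a deduplicated table and returns the
#' RBP's regulon: the set of affected exon keys, their direction of
#' regulation (increase/decrease of inclusion upon knockdown), and the
#' unfiltered universe (all exons in the table). Records with missing
#' delta PSI contribute to neither set and are counted in the result.
#'
#' @param table a deduplicated `knockdown_table`.
#' @param policy a `filter_policy`.
#' @return an object of class `regulon` with elements `rbp_name`,
#'   `rbp_family`, `cell_line`, `policy`, `affected` (character keys),
#'   `directions` (named character, `"increase"`/`"decrease"`),
#'   `delta_psi`, `psi_control`, `fdr` (named numeric over affected keys),
#'   `universe` (character keys), `n_dropped_missing_dpsi`.
#' @export
apply_filter <- function(table, policy) {
  stopifnot(inherits(table, "knockdown_table"), inherits(policy, "filter_policy"))
  r <- table$records
  keys <- exon_key_of(r)
  if (anyDuplicated(keys))
    stopf("table for %s contains duplicate exon keys; run deduplicate() first",
          table$rbp_name)
  has_dpsi <- !is.na(r$delta_psi)
  n_dropped <- sum(!has_dpsi)
  r <- r[has_dpsi, , drop = FALSE]
  keys <- keys[has_dpsi]

  pass <- abs(r$delta_psi) > policy$min_abs_delta_psi
  if (!is.null(policy$max_fdr)) {
    if (all(is.na(r$fdr)) && nrow(r) > 0L)
      stopf("policy '%s' requires an FDR column but table for %s has none",
            policy$name, table$rbp_name)
    pass <- pass & !is.na(r$fdr) & r$fdr <= policy$max_fdr
  }

  affected <- keys[pass]
  dpsi <- r$delta_psi[pass]
  directions <- ifelse(dpsi > 0, "increase", "decrease")
  names(directions) <- affected
  names(dpsi) <- affected
  psi_c <- r$psi_control[pass]
  names(psi_c) <- affected
  fdr <- r$fdr[pass]
  names(fdr) <- affected

  structure(list(
    rbp_name = table$rbp_name, rbp_family = table$rbp_family,
    cell_line = table$cell_line, policy = policy,
    affected = affected, directions = directions, delta_psi = dpsi,
    psi_control = psi_c, fdr = fdr, universe = keys,
    n_dropped_missing_dpsi = n_dropped
  ), class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s (%s): %d affected / %d exons [policy %s]\n",
              x$rbp_name, x$cell_line, length(x$affected),
              length(x$universe), x$policy$name))
  invisible(x)
}

check_regulon_collection <- function(regulons) {
  if (length(regulons) < 1L) stopf("need at least one regulon")
  stopifnot(all(vapply(regulons, inherits, TRUE, "regulon")))
  cls <- unique(vapply(regulons, `[[`, "", "cell_line"))
  if (length(cls) > 1L)
    stopf("regulons span multiple cell lines: %s", paste(cls, collapse = ", "))
  p0 <- regulons[[1]]$policy
  same <- vapply(regulons, function(r) policy_equal(r$policy, p0), TRUE)
  if (!all(same)) stopf("regulons computed under different filter policies")
  names(regulons) <- vapply(regulons, `[[`, "", "rbp_name")
  if (anyDuplicated(names(regulons)))
    stopf("duplicate RBP names in regulon collection")
  invisible(regulons)
}

#' Per-RBP affected-exon counts
#'
#' @param regulons list of `regulon` objects from one cell line and policy.
#' @return tibble with columns `rbp_name`, `n_affected`.
#' @export
affected_counts <- function(regulons) {
  regulons <- check_regulon_collection(regulons)
  tibble::tibble(
    rbp_name = unname(vapply(regulons, `[[`, "", "rbp_name")),
    n_affected = unname(vapply(regulons, function(r) length(r$affected), 1L))
  )
}
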