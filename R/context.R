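# Cross-cell-line comparison and indirect-effect (cross-RBP) detection.

#' Relative importance of RBPs across cell lines
#'
#' Normalises each RBP's affected-exon count by the largest count observed
#' for any RBP within the same cell line, yielding a scale-free importance
#' in \[0, 1\] comparable across cell lines.
#'
#' @param counts tibble/data frame with columns `rbp_name`, `cell_line`,
#'   `n_affected`.
#' @return tibble with an added `relative_importance` column.
#' @export
relative_importance <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("rbp_name", "cell_line", "n_affected") %in% names(counts)))
  maxima <- tapply(counts$n_affected, counts$cell_line, max)
  if (any(maxima == 0))
    stopf("cell line(s) with no affected exons for any RBP: %s",
          paste(names(maxima)[maxima == 0], collapse = ", "))
  counts$relative_importance <-
    counts$n_affected / as.numeric(maxima[counts$cell_line])
  counts
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Pairs significant in every cell line
#'
#' Intersects the significant RBP pairs across the per-cell-line pair test
#' results and reports per-line significant fractions.
#'
#' @param pair_results_by_line named list of tibbles from [all_pairs()],
#'   one per cell line.
#' @return list with `shared` (tibble of unordered pairs significant in
#'   every line) and `per_line` (tibble: `cell_line`, `n_tested`,
#'   `n_significant`, `pct_significant`).
#' @export
shared_significant_pairs <- function(pair_results_by_line) {
  stopifnot(is.list(pair_results_by_line), length(pair_results_by_line) >= 1L)
  if (is.null(names(pair_results_by_line)))
    names(pair_results_by_line) <- paste0("line", seq_along(pair_results_by_line))
  rbp_sets <- lapply(pair_results_by_line, function(pr)
    unique(c(pr$rbp_a, pr$rbp_b)))
  if (length(Reduce(intersect, rbp_sets)) == 0L)
    stopf("no RBPs are shared across the provided cell lines")
  sig_sets <- lapply(pair_results_by_line, function(pr)
    pair_key(pr$rbp_a, pr$rbp_b)[pr$significant])
  shared_keys <- Reduce(intersect, sig_sets)
  parts <- strsplit(shared_keys, "|", fixed = TRUE)
  shared <- tibble::tibble(
    rbp_a = vapply(parts, `[`, "", 1) %||% character(),
    rbp_b = vapply(parts, `[`, "", 2) %||% character()
  )
  per_line <- do.call(rbind, lapply(names(pair_results_by_line), function(nm) {
    pr <- pair_results_by_line[[nm]]
    tibble::tibble(cell_line = nm, n_tested = nrow(pr),
                   n_significant = sum(pr$significant),
                   pct_significant = 100 * mean(pr$significant))
  }))
  list(shared = shared, per_line = per_line)
}

#' Detect cross-RBP splicing responses to knockdowns
#'
#' Scans each knockdown table for exons lying in the gene of a *different*
#' RBP whose inclusion changes by more than the threshold: evidence that
#' part of a knockdown's apparent regulon is an indirect effect routed
#' through another splicing factor. Changes in the knocked-down RBP's own
#' gene are reported separately as autoregulation, not as cross hits.
#'
#' @param tables list of deduplicated `knockdown_table`s.
#' @param rbp_gene_map tibble/data frame with columns `rbp_name` and
#'   `gene_symbol` (and optionally `gene_id`) for every knocked-down RBP.
#' @param min_abs_delta_psi exclusive |dPSI| threshold for a responding
#'   exon (default 0.15).
#' @return list with `cross` (tibble: `knocked_down_rbp`, `responding_rbp`,
#'   `n_responding_exons`, `max_abs_delta_psi`) and `autoregulation`
#'   (tibble: `rbp_name`, `n_exons`, `max_abs_delta_psi`).
#' @export
detect_cross_regulation <- function(tables, rbp_gene_map,
                                    min_abs_delta_psi = 0.15) {
  stopifnot(all(vapply(tables, inherits, TRUE, "knockdown_table")))
  map <- tibble::as_tibble(rbp_gene_map)
  stopifnot(all(c("rbp_name", "gene_symbol") %in% names(map)))
  kd_names <- vapply(tables, `[[`, "", "rbp_name")
  unmapped <- setdiff(kd_names, map$rbp_name)
  if (length(unmapped) > 0L)
    stopf("RBP(s) missing from the gene map: %s",
          paste(unmapped, collapse = ", "))

  match_rbp <- function(records) {
    hit <- match(records$gene_symbol, map$gene_symbol)
    if ("gene_id" %in% names(map)) {
      by_id <- match(records$gene_id, map$gene_id)
      hit[is.na(hit)] <- by_id[is.na(hit)]
    }
    map$rbp_name[hit]
  }

  cross_rows <- list(); auto_rows <- list()
  for (tb in tables) {
    r <- tb$records
    target <- match_rbp(r)
    responding <- !is.na(target) & !is.na(r$delta_psi) &
      abs(r$delta_psi) > min_abs_delta_psi
    if (!any(responding)) next
    hits <- data.frame(target = target[responding],
                       adp = abs(r$delta_psi[responding]))
    for (tg in unique(hits$target)) {
      sub <- hits[hits$target == tg, , drop = FALSE]
      row <- tibble::tibble(knocked_down_rbp = tb$rbp_name,
                            responding_rbp = tg,
                            n_responding_exons = nrow(sub),
                            max_abs_delta_psi = max(sub$adp))
      if (tg == tb$rbp_name) {
        auto_rows[[length(auto_rows) + 1L]] <-
          tibble::tibble(rbp_name = tb$rbp_name, n_exons = nrow(sub),
                         max_abs_delta_psi = max(sub$adp))
      } else {
        cross_rows[[length(cross_rows) + 1L]] <- row
      }
    }
  }
  empty_cross <- tibble::tibble(knocked_down_rbp = character(),
                                responding_rbp = character(),
                                n_responding_exons = integer(),
                                max_abs_delta_psi = numeric())
  empty_auto <- tibble::tibble(rbp_name = character(), n_exons = integer(),
                               max_abs_delta_psi = numeric())
  cross <- if (length(cross_rows)) do.call(rbind, cross_rows) else empty_cross
  cross <- cross[order(cross$knocked_down_rbp, cross$responding_rbp), ,
                 drop = FALSE]
  auto <- if (length(auto_rows)) do.call(rbind, auto_rows) else empty_auto
  list(cross = cross, autoregulation = auto)
}

#' Per-RBP regulon overlap across cell lines
#'
#' Jaccard index of each shared RBP's affected-exon sets between every
#' pair of cell lines. Requires that all lines use one genome build;
#' no coordinate liftover is performed.
#'
#' @param regulons_by_line named list (cell line -> list of `regulon`s).
#' @return tibble: `rbp_name`, `line_a`, `line_b`, `n_a`, `n_b`,
#'   `n_shared`, `jaccard`.
#' @export
cross_line_exon_overlap <- function(regulons_by_line) {
  stopifnot(is.list(regulons_by_line), length(regulons_by_line) >= 2L)
  by_line <- lapply(regulons_by_line, function(regs) {
    names(regs) <- vapply(regs, `[[`, "", "rbp_name")
    regs
  })
  lines <- names(by_line)
  rows <- list()
  for (i in seq_len(length(lines) - 1L)) for (j in (i + 1L):length(lines)) {
    shared_rbps <- intersect(names(by_line[[i]]), names(by_line[[j]]))
    for (rbp in shared_rbps) {
      a <- by_line[[i]][[rbp]]$affected
      b <- by_line[[j]][[rbp]]$affected
      u <- length(union(a, b))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rbp_name = rbp, line_a = lines[i], line_b = lines[j],
        n_a = length(a), n_b = length(b),
        n_shared = length(intersect(a, b)),
        jaccard = if (u == 0L) NA_real_ else length(intersect(a, b)) / u)
    }
  }
  if (length(rows) == 0L)
    return(tibble::tibble(rbp_name = character(), line_a = character(),
                          line_b = character(), n_a = integer(),
                          n_b = integer(), n_shared = integer(),
                          jaccard = numeric()))
  do.call(rbind, rows)
}
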