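# Enhancer/silencer classification of RBP activity.
#
# An exon whose inclusion DECREASES upon knockdown is taken to be enhanced
# by the RBP in wildtype conditions; an increase marks silencing. Summaries
# are reported over three exon populations per RBP: total (all affected),
# independent (affected by this RBP only), interdependent (affected by two
# or more RBPs).

#' Summarise direction of regulation for one RBP
#'
#' @param regulon a `regulon`.
#' @param multiplicity a `multiplicity_profile` built over the regulon
#'   collection this regulon belongs to (see [build_multiplicity()]);
#'   may be `NULL` when `population = "total"`.
#' @param population `"total"`, `"independent"`, or `"interdependent"`.
#' @return one-row tibble: `rbp_name`, `population`, `n_exons`,
#'   `pct_increase`, `pct_decrease`. Percentages are `NA` when the
#'   population is empty.
#' @export
summarize_direction <- function(regulon, multiplicity = NULL,
                                population = c("total", "independent",
                                               "interdependent")) {
  population <- match.arg(population)
  stopifnot(inherits(regulon, "regulon"))
  keys <- regulon$affected
  if (population != "total") {
    if (!inherits(multiplicity, "multiplicity_profile"))
      stopf("a multiplicity profile is required for the %s population",
            population)
    counts <- multiplicity$per_exon$count
    names(counts) <- multiplicity$per_exon$key
    if (!all(keys %in% names(counts)))
      stopf("multiplicity profile does not cover regulon %s", regulon$rbp_name)
    keys <- if (population == "independent")
      keys[counts[keys] == 1L] else keys[counts[keys] >= 2L]
  }
  n <- length(keys)
  dirs <- regulon$directions[keys]
  tibble::tibble(
    rbp_name = regulon$rbp_name,
    population = population,
    n_exons = n,
    pct_increase = if (n > 0) 100 * mean(dirs == "increase") else NA_real_,
    pct_decrease = if (n > 0) 100 * mean(dirs == "decrease") else NA_real_
  )
}

#' Direction summaries for all RBPs and populations
#'
#' @param regulons list of `regulon` objects (one cell line, one policy).
#' @param multiplicity optional pre-built `multiplicity_profile`; computed
#'   from `regulons` when omitted.
#' @return tibble with one row per RBP x population.
#' @export
direction_table <- function(regulons, multiplicity = NULL) {
  regulons <- check_regulon_collection(regulons)
  if (is.null(multiplicity)) multiplicity <- build_multiplicity(regulons)
  rows <- lapply(regulons, function(r)
    do.call(rbind, lapply(c("total", "independent", "interdependent"),
                          function(p) summarize_direction(r, multiplicity, p))))
  do.call(rbind, rows)
}
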