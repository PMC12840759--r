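# Regulator multiplicity: how many RBPs affect each exon, and what that
# multiplicity implies for direction consistency, wildtype inclusion
# levels, and exon sequence features.

#' Count affecting RBPs per exon
#'
#' Combines the affected-exon sets of a regulon collection and, for every
#' exon in the union, records how many RBPs affect it and with which
#' directions. Wildtype (control) PSI values reported by different source
#' tables for the same exon are averaged: wildtype inclusion is a property
#' of the cell line, and residual differences between control batches are
#' treated as noise.
#'
#' @param regulons list of `regulon` objects (one cell line, one policy).
#' @return a `multiplicity_profile`: list with `per_exon` (tibble: `key`,
#'   `count`, `n_increase`, `n_decrease`, `psi_control`) and `bins`
#'   (named list mapping multiplicity to exon keys).
#' @export
build_multiplicity <- function(regulons) {
  regulons <- check_regulon_collection(regulons)
  long <- do.call(rbind, lapply(regulons, function(r) {
    if (length(r$affected) == 0L) return(NULL)
    data.frame(key = r$affected,
               increase = unname(r$directions[r$affected] == "increase"),
               psi_control = unname(r$psi_control[r$affected]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0L) {
    per_exon <- tibble::tibble(key = character(), count = integer(),
                               n_increase = integer(), n_decrease = integer(),
                               psi_control = numeric())
    return(structure(list(per_exon = per_exon, bins = list()),
                     class = "multiplicity_profile"))
  }
  split_idx <- split(seq_len(nrow(long)), long$key)
  keys <- names(split_idx)
  count <- vapply(split_idx, length, 1L)
  n_inc <- vapply(split_idx, function(i) sum(long$increase[i]), 1L)
  psi <- vapply(split_idx, function(i) {
    v <- long$psi_control[i]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  per_exon <- tibble::tibble(key = keys, count = unname(count),
                             n_increase = unname(n_inc),
                             n_decrease = unname(count - n_inc),
                             psi_control = unname(psi))
  bins <- split(per_exon$key, per_exon$count)
  structure(list(per_exon = per_exon, bins = bins),
            class = "multiplicity_profile")
}

#' @export
print.multiplicity_profile <- function(x, ...) {
  cat(sprintf("<multiplicity_profile> %d exons, multiplicity 1..%s\n",
              nrow(x$per_exon),
              if (nrow(x$per_exon)) max(x$per_exon$count) else 0))
  invisible(x)
}

#' Direction consistency by multiplicity bin
#'
#' Classifies every exon as `increase_only`, `decrease_only`, or `both`
#' (affected in both directions by different RBPs) and tabulates the class
#' fractions per multiplicity bin. Single-RBP exons can only fall in the
#' two exclusive classes.
#'
#' @param profile a `multiplicity_profile`.
#' @return tibble: `count`, `n_exons`, `pct_increase_only`,
#'   `pct_decrease_only`, `pct_both`.
#' @export
direction_consistency <- function(profile) {
  stopifnot(inherits(profile, "multiplicity_profile"))
  pe <- profile$per_exon
  if (nrow(pe) == 0L)
    return(tibble::tibble(count = integer(), n_exons = integer(),
                          pct_increase_only = numeric(),
                          pct_decrease_only = numeric(),
                          pct_both = numeric()))
  cls <- ifelse(pe$n_decrease == 0L, "increase_only",
                ifelse(pe$n_increase == 0L, "decrease_only", "both"))
  counts <- sort(unique(pe$count))
  rows <- lapply(counts, function(k) {
    sel <- pe$count == k
    n <- sum(sel)
    tibble::tibble(count = k, n_exons = n,
                   pct_increase_only = 100 * sum(cls[sel] == "increase_only") / n,
                   pct_decrease_only = 100 * sum(cls[sel] == "decrease_only") / n,
                   pct_both = 100 * sum(cls[sel] == "both") / n)
  })
  do.call(rbind, rows)
}

#' Wildtype inclusion distributions of independent vs interdependent exons
#'
#' Splits exons into the independently regulated population (multiplicity
#' 1) and the interdependently regulated population (multiplicity >= 2),
#' histograms their wildtype (control) PSI values, and reports the
#' fraction of each population at intermediate inclusion. "Intermediate"
#' defaults to PSI in \[0.35, 0.65\], a symmetric window around 50%
#' inclusion.
#'
#' @param profile a `multiplicity_profile`.
#' @param intermediate length-2 numeric, the inclusive intermediate-PSI
#'   window.
#' @param n_bins number of histogram bins on \[0, 1\].
#' @return list with `histogram` (tibble: `population`, `bin_mid`,
#'   `n`, `density`), `intermediate_fraction` (named numeric for
#'   `independent` and `interdependent`), `intermediate_window`, and
#'   `psi_coverage` (fraction of exons with a wildtype PSI).
#' @export
inclusion_distributions <- function(profile, intermediate = c(0.35, 0.65),
                                    n_bins = 40) {
  stopifnot(inherits(profile, "multiplicity_profile"),
            length(intermediate) == 2L, intermediate[1] < intermediate[2])
  pe <- profile$per_exon
  coverage <- if (nrow(pe) > 0) mean(!is.na(pe$psi_control)) else 0
  if (nrow(pe) == 0L || all(is.na(pe$psi_control)))
    stopf("no exons with wildtype PSI available")
  if (coverage < 0.9)
    warning(sprintf("wildtype PSI available for only %.0f%% of exons",
                    100 * coverage))
  pops <- list(independent = pe$psi_control[pe$count == 1L],
               interdependent = pe$psi_control[pe$count >= 2L])
  pops <- lapply(pops, function(v) v[!is.na(v)])
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  hist_rows <- lapply(names(pops), function(nm) {
    v <- pops[[nm]]
    if (length(v) == 0L) return(NULL)
    h <- graphics::hist(pmin(pmax(v, 0), 1), breaks = breaks, plot = FALSE)
    tibble::tibble(population = nm, bin_mid = h$mids, n = h$counts,
                   density = h$density)
  })
  inter_frac <- vapply(pops, function(v) {
    if (length(v) == 0L) return(NA_real_)
    mean(v >= intermediate[1] & v <= intermediate[2])
  }, numeric(1))
  list(histogram = do.call(rbind, hist_rows),
       intermediate_fraction = inter_frac,
       intermediate_window = intermediate,
       psi_coverage = coverage)
}

FEATURE_NAMES <- c("ss5_score", "ss3_score", "phylop", "exon_length",
                   "upstream_intron_length", "downstream_intron_length")

#' Regress exon features on regulator multiplicity
#'
#' Bins exons by multiplicity, averages each feature per bin, and fits an
#' ordinary least-squares line of bin mean against multiplicity. The
#' default regression is unweighted (each bin is one observation); set
#' `weighted = TRUE` to weight bins by exon count. Exons absent from the
#' feature table are excluded and counted in the result. Genome-wide
#' reference values (e.g. the transcriptome-median 5' splice-site score)
#' are echoed into the output for plotting, never used in the fit.
#'
#' @param profile a `multiplicity_profile`.
#' @param features feature tibble keyed by exon (see
#'   [read_feature_table()]).
#' @param weighted weight bins by size in the regression.
#' @param genome_reference optional named numeric of per-feature reference
#'   values.
#' @return list with `trends` (tibble: `feature`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_bins`, `reference`), `bin_means` (tibble:
#'   `count`, `n_exons`, one column per feature), `n_missing_features`.
#' @export
feature_trend <- function(profile, features, weighted = FALSE,
                          genome_reference = NULL) {
  stopifnot(inherits(profile, "multiplicity_profile"))
  pe <- profile$per_exon
  matched <- match(pe$key, features$key)
  n_missing <- sum(is.na(matched))
  keep <- !is.na(matched)
  pe <- pe[keep, , drop = FALSE]
  feat <- features[matched[keep], , drop = FALSE]

  counts <- sort(unique(pe$count))
  if (length(counts) < 3L)
    stopf("need at least 3 multiplicity bins with feature coverage, have %d",
          length(counts))
  bin_means <- do.call(rbind, lapply(counts, function(k) {
    sel <- pe$count == k
    row <- tibble::tibble(count = k, n_exons = sum(sel))
    for (f in FEATURE_NAMES)
      row[[f]] <- mean(as.numeric(feat[[f]][sel]), na.rm = TRUE)
    row
  }))

  trends <- do.call(rbind, lapply(FEATURE_NAMES, function(f) {
    y <- bin_means[[f]]
    x <- bin_means$count
    ref <- if (!is.null(genome_reference) && f %in% names(genome_reference))
      unname(genome_reference[[f]]) else NA_real_
    if (stats::sd(y) == 0) {
      # constant feature: flat line, no explainable variance, no test
      return(tibble::tibble(feature = f, slope = 0, intercept = y[1],
                            r_squared = 0, p_value = NA_real_,
                            slope_se = NA_real_, n_bins = length(x),
                            reference = ref))
    }
    w <- if (weighted) bin_means$n_exons else NULL
    fit <- stats::lm(y ~ x, weights = w)
    sm <- summary(fit)
    tibble::tibble(
      feature = f,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = if (nrow(sm$coefficients) >= 2 &&
                    sm$coefficients[2, "Std. Error"] > 0)
        sm$coefficients[2, "Pr(>|t|)"] else NA_real_,
      slope_se = if (nrow(sm$coefficients) >= 2)
        sm$coefficients[2, "Std. Error"] else NA_real_,
      n_bins = length(x),
      reference = ref
    )
  }))
  list(trends = trends, bin_means = bin_means, n_missing_features = n_missing)
}
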