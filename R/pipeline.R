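# End-to-end orchestration over a directory of knockdown tables.
#
# All computation lives in the stage functions; this layer only reads a
# run configuration, sequences the stages, writes their outputs, and
# records a manifest. The numbered scripts under analysis/ are thin
# narrative drivers over the same functions.

default_run_config <- function() {
  list(
    input_dir = NULL,
    dialect = "canonical",
    filter = list(name = "hela", min_abs_delta_psi = 0.15, max_fdr = NULL),
    alpha = 0.05,
    universe = "union",
    intermediate_window = c(0.35, 0.65),
    feature_table = NULL,
    rbp_gene_map = NULL,
    genome_reference = NULL,
    cell_line = "unspecified",
    output_dir = "results"
  )
}

#' Validate a run configuration
#'
#' Collects *all* problems rather than failing at the first: missing
#' inputs, out-of-range parameters, unknown dialects.
#'
#' @param config a list, or path to a YAML file with the same fields
#'   (`input_dir`, `dialect`, `filter`, `alpha`, `universe`,
#'   `intermediate_window`, `feature_table`, `rbp_gene_map`,
#'   `cell_line`, `output_dir`).
#' @return the merged config (defaults filled in) with class
#'   `run_config`; if any check fails, an error listing every problem.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  errors <- character(0)
  err <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  if (is.null(cfg$input_dir)) err("input_dir: required")
  else if (!dir.exists(cfg$input_dir)) err("input_dir: not found (%s)", cfg$input_dir)
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1L ||
      cfg$alpha <= 0 || cfg$alpha >= 1)
    err("alpha: out of range (0, 1)")
  if (!cfg$universe %in% c("union", "sum"))
    err("universe: must be 'union' or 'sum'")
  d <- tryCatch(get_dialect(cfg$dialect), error = function(e) conditionMessage(e))
  if (is.character(d)) err("dialect: %s", d)
  f <- cfg$filter
  if (!is.numeric(f$min_abs_delta_psi) || f$min_abs_delta_psi < 0 ||
      f$min_abs_delta_psi >= 1)
    err("filter.min_abs_delta_psi: out of range [0, 1)")
  if (!is.null(f$max_fdr) && (!is.numeric(f$max_fdr) || f$max_fdr < 0 ||
                              f$max_fdr > 1))
    err("filter.max_fdr: out of range [0, 1]")
  iw <- cfg$intermediate_window
  if (!is.numeric(iw) || length(iw) != 2L || iw[1] >= iw[2] ||
      iw[1] < 0 || iw[2] > 1)
    err("intermediate_window: must be an increasing pair inside [0, 1]")
  if (!is.null(cfg$feature_table) && !file.exists(cfg$feature_table))
    err("feature_table: not found (%s)", cfg$feature_table)
  if (!is.null(cfg$rbp_gene_map) && !file.exists(cfg$rbp_gene_map))
    err("rbp_gene_map: not found (%s)", cfg$rbp_gene_map)

  if (length(errors) > 0L)
    stopf("invalid run configuration:\n%s",
          paste("  -", errors, collapse = "\n"))
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full interdependence analysis
#'
#' Sequences read -> deduplicate -> filter -> pair tests -> matrix ->
#' direction -> multiplicity -> inclusion distributions -> feature trends
#' over every `*.tsv` knockdown table in `input_dir`, writing one TSV/JSON
#' artifact per stage plus a manifest with row counts and checksums. The
#' feature and gene-map stages are optional and skipped (with a log line)
#' when their inputs are absent.
#'
#' @param config a `run_config`, plain list, or YAML path (see
#'   [validate_config()]).
#' @param quiet suppress progress messages.
#' @return the manifest (named list), invisibly written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  record <- function(label, path, n_rows) {
    artifacts[[label]] <<- list(path = path, n_rows = n_rows,
                                md5 = unname(tools::md5sum(path)))
  }

  paths <- sort(list.files(cfg$input_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(paths) < 2L)
    stopf("need at least 2 knockdown tables in %s, found %d",
          cfg$input_dir, length(paths))
  policy <- filter_policy(cfg$filter$min_abs_delta_psi, cfg$filter$max_fdr,
                          name = cfg$filter$name %||% "custom")

  say("reading %d knockdown tables", length(paths))
  tables <- stage("read", lapply(paths, read_knockdown_table,
                                 dialect = cfg$dialect,
                                 cell_line = cfg$cell_line))
  tables <- stage("deduplicate", lapply(tables, deduplicate))
  regulons <- stage("filter", lapply(tables, apply_filter, policy = policy))
  names(regulons) <- vapply(regulons, `[[`, "", "rbp_name")
  dropped <- vapply(regulons, `[[`, 1L, "n_dropped_missing_dpsi")
  if (any(dropped > 0))
    say("dropped %d records with missing dPSI across %d tables",
        sum(dropped), sum(dropped > 0))

  counts <- affected_counts(regulons)
  say("filter '%s': %s affected exons over %d RBPs",
      policy$name, sum(counts$n_affected), nrow(counts))
  record("affected_counts",
         write_tsv(counts, file.path(out, "affected_counts.tsv")),
         nrow(counts))

  pairs <- stage("pairs", all_pairs(regulons, alpha = cfg$alpha,
                                    universe = cfg$universe))
  say("%d pair tests, %d significant at alpha %.3g",
      nrow(pairs), sum(pairs$significant), cfg$alpha)
  record("pair_tests", write_tsv(pairs, file.path(out, "pair_tests.tsv")),
         nrow(pairs))

  mat <- stage("matrix", build_matrix(regulons, pairs))
  mat_df <- data.frame(rbp = rownames(mat$cells), round(mat$cells, 6),
                       check.names = FALSE)
  record("interdependence_matrix",
         write_tsv(mat_df, file.path(out, "interdependence_matrix.tsv")),
         nrow(mat_df))
  if (length(regulons) >= 2L) {
    cl <- stage("cluster", cluster_matrix(mat))
    jsonlite::write_json(list(row_order = cl$row_order,
                              col_order = cl$col_order),
                         file.path(out, "cluster_order.json"),
                         auto_unbox = TRUE)
    record("cluster_order", file.path(out, "cluster_order.json"),
           length(cl$row_order))
  }

  profile <- stage("multiplicity", build_multiplicity(regulons))
  dirs <- stage("direction", direction_table(regulons, profile))
  record("direction_summary",
         write_tsv(dirs, file.path(out, "direction_summary.tsv")), nrow(dirs))
  consistency <- stage("multiplicity", direction_consistency(profile))
  record("direction_consistency",
         write_tsv(consistency, file.path(out, "direction_consistency.tsv")),
         nrow(consistency))
  mult_hist <- tibble::tibble(count = as.integer(names(profile$bins)),
                              n_exons = lengths(profile$bins))
  record("multiplicity_histogram",
         write_tsv(mult_hist, file.path(out, "multiplicity_histogram.tsv")),
         nrow(mult_hist))

  incl <- stage("inclusion", tryCatch(
    inclusion_distributions(profile, intermediate = cfg$intermediate_window),
    error = function(e) { say("inclusion stage skipped: %s",
                              conditionMessage(e)); NULL }))
  if (!is.null(incl)) {
    record("inclusion_distributions",
           write_tsv(incl$histogram,
                     file.path(out, "inclusion_distributions.tsv")),
           nrow(incl$histogram))
  }

  if (!is.null(cfg$feature_table)) {
    features <- stage("features", read_feature_table(cfg$feature_table))
    trends <- stage("features", feature_trend(
      profile, features,
      genome_reference = unlist(cfg$genome_reference)))
    record("feature_trends",
           write_tsv(trends$trends, file.path(out, "feature_trends.tsv")),
           nrow(trends$trends))
    record("feature_bin_means",
           write_tsv(trends$bin_means, file.path(out, "feature_bin_means.tsv")),
           nrow(trends$bin_means))
  } else say("feature stage skipped: no feature table configured")

  if (!is.null(cfg$rbp_gene_map)) {
    map <- utils::read.delim(cfg$rbp_gene_map, sep = "\t",
                             stringsAsFactors = FALSE)
    xreg <- stage("cross_regulation",
                  detect_cross_regulation(tables, map,
                                          policy$min_abs_delta_psi))
    record("cross_regulation",
           write_tsv(xreg$cross, file.path(out, "cross_regulation.tsv")),
           nrow(xreg$cross))
    record("autoregulation",
           write_tsv(xreg$autoregulation, file.path(out, "autoregulation.tsv")),
           nrow(xreg$autoregulation))
  } else say("cross-regulation stage skipped: no RBP gene map configured")

  summary <- list(
    n_tables = length(tables),
    n_pairs_tested = nrow(pairs),
    n_pairs_significant = sum(pairs$significant),
    pct_pairs_significant = 100 * mean(pairs$significant),
    n_affected_union = nrow(profile$per_exon),
    max_multiplicity = if (nrow(profile$per_exon)) max(profile$per_exon$count) else 0L,
    pct_exons_independent = if (nrow(profile$per_exon))
      100 * mean(profile$per_exon$count == 1L) else NA,
    intermediate_fraction = if (!is.null(incl))
      as.list(incl$intermediate_fraction) else NULL
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  record("summary", file.path(out, "summary.json"), 1L)

  manifest <- list(config = unclass(cfg), artifacts = artifacts,
                   summary = summary)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("wrote %d artifacts to %s", length(artifacts), out)
  invisible(manifest)
}
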