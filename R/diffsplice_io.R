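# Reading, validating and writing skipped-exon differential-splicing tables.
#
# Two dialects are registered out of the box:
#   * "canonical"   -- the package's own TSV (one PSI column per condition,
#                      fractions, knockdown-minus-control sign).
#   * "rmats_se_jc" -- rMATS SE.MATS.JC(EC)-style output, with comma-separated
#                      replicate inclusion levels and a configurable
#                      assignment of sample 1/2 to knockdown/control.
# Further dialects can be declared in a YAML/JSON column-mapping file.

CANONICAL_COLUMNS <- c(
  "GeneID", "geneSymbol", "chr", "strand",
  "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
  "downstreamES", "downstreamEE",
  "PSI_control", "PSI_kd", "IncLevelDifference", "FDR"
)

RECORD_COLUMNS <- c(
  "gene_id", "gene_symbol", "chrom", "strand",
  "exon_start", "exon_end",
  "upstream_exon_start", "upstream_exon_end",
  "downstream_exon_start", "downstream_exon_end",
  "psi_control", "psi_knockdown", "delta_psi", "fdr"
)

#' Describe a differential-splicing table dialect
#'
#' A dialect maps source columns onto the package's skipped-exon record
#' fields and states the conventions the reader must normalise:
#' PSI units, the sign of the inclusion-level difference, and the
#' coordinate convention.
#'
#' @param name dialect name.
#' @param columns named character vector mapping record fields
#'   (`gene_id`, `gene_symbol`, `chrom`, `strand`, `exon_start`, `exon_end`,
#'   `upstream_exon_start`, ..., `psi_control`, `psi_knockdown`,
#'   `delta_psi`, `fdr`) to source column names. `psi_control`/
#'   `psi_knockdown` and `fdr` may be omitted when the source lacks them.
#' @param psi_units `"fraction"`, `"percent"`, or `"auto"` (percent assumed
#'   when any |value| exceeds 1).
#' @param sign `"kd_minus_control"` or `"control_minus_kd"`; the reader flips
#'   the latter so positive `delta_psi` always means increased inclusion
#'   upon knockdown.
#' @param coords coordinate convention of the source, `"0based_halfopen"`
#'   (rMATS; kept as-is) or `"1based_closed"` (start is decremented).
#' @param replicate_sep if not `NA`, PSI columns hold `replicate_sep`-joined
#'   per-replicate values which are averaged (rMATS `IncLevel1/2`).
#' @return an object of class `sd_dialect`.
#' @export
dialect <- function(name, columns,
                    psi_units = c("auto", "fraction", "percent"),
                    sign = c("kd_minus_control", "control_minus_kd"),
                    coords = c("0based_halfopen", "1based_closed"),
                    replicate_sep = NA_character_) {
  psi_units <- match.arg(psi_units)
  sign <- match.arg(sign)
  coords <- match.arg(coords)
  required <- setdiff(RECORD_COLUMNS,
                      c("psi_control", "psi_knockdown", "fdr", "gene_symbol"))
  missing <- setdiff(required, names(columns))
  if (length(missing) > 0L)
    stopf("dialect '%s' lacks mappings for: %s", name,
          paste(missing, collapse = ", "))
  structure(list(name = name, columns = columns, psi_units = psi_units,
                 sign = sign, coords = coords, replicate_sep = replicate_sep),
            class = "sd_dialect")
}

canonical_dialect <- function() {
  dialect(
    name = "canonical",
    columns = c(
      gene_id = "GeneID", gene_symbol = "geneSymbol",
      chrom = "chr", strand = "strand",
      exon_start = "exonStart_0base", exon_end = "exonEnd",
      upstream_exon_start = "upstreamES", upstream_exon_end = "upstreamEE",
      downstream_exon_start = "downstreamES",
      downstream_exon_end = "downstreamEE",
      psi_control = "PSI_control", psi_knockdown = "PSI_kd",
      delta_psi = "IncLevelDifference", fdr = "FDR"
    ),
    psi_units = "auto", sign = "kd_minus_control", coords = "0based_halfopen"
  )
}

# rMATS convention: IncLevelDifference = IncLevel1 - IncLevel2.  With the
# knockdown as sample 1 (the usual layout for KD-vs-control runs) the sign
# already matches kd-minus-control; `kd_sample = 2` declares the opposite.
rmats_se_jc_dialect <- function(kd_sample = 1) {
  if (!kd_sample %in% c(1, 2)) stopf("kd_sample must be 1 or 2")
  cols <- c(
    gene_id = "GeneID", gene_symbol = "geneSymbol",
    chrom = "chr", strand = "strand",
    exon_start = "exonStart_0base", exon_end = "exonEnd",
    upstream_exon_start = "upstreamES", upstream_exon_end = "upstreamEE",
    downstream_exon_start = "downstreamES", downstream_exon_end = "downstreamEE",
    psi_knockdown = if (kd_sample == 1) "IncLevel1" else "IncLevel2",
    psi_control = if (kd_sample == 1) "IncLevel2" else "IncLevel1",
    delta_psi = "IncLevelDifference", fdr = "FDR"
  )
  dialect(name = "rmats_se_jc", columns = cols, psi_units = "auto",
          sign = if (kd_sample == 1) "kd_minus_control" else "control_minus_kd",
          coords = "0based_halfopen", replicate_sep = ",")
}

#' Look up or construct a registered dialect
#'
#' @param x a dialect name (`"canonical"`, `"rmats_se_jc"`,
#'   `"rmats_se_jc_kd2"`), an `sd_dialect` object, or a path to a YAML/JSON
#'   column-mapping file with fields `name`, `columns`, and optionally
#'   `psi_units`, `sign`, `coords`, `replicate_sep`.
#' @return an `sd_dialect`.
#' @export
get_dialect <- function(x) {
  if (inherits(x, "sd_dialect")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stopf("dialect must be a name, a file path, or an sd_dialect object")
  registered <- c("canonical", "rmats_se_jc", "rmats_se_jc_kd2")
  if (x == "canonical") return(canonical_dialect())
  if (x == "rmats_se_jc") return(rmats_se_jc_dialect(1))
  if (x == "rmats_se_jc_kd2") return(rmats_se_jc_dialect(2))
  if (file.exists(x)) {
    mapping <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
    cols <- unlist(mapping$columns)
    return(dialect(name = mapping$name %||% "custom", columns = cols,
                   psi_units = mapping$psi_units %||% "auto",
                   sign = mapping$sign %||% "kd_minus_control",
                   coords = mapping$coords %||% "0based_halfopen",
                   replicate_sep = mapping$replicate_sep %||% NA_character_))
  }
  stopf("unknown dialect '%s'; registered dialects: %s", x,
        paste(registered, collapse = ", "))
}

parse_psi_column <- function(x, sep) {
  if (!is.na(sep) && is.character(x)) {
    vapply(strsplit(x, sep, fixed = TRUE), function(v) {
      v <- suppressWarnings(as.numeric(v))
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1))
  } else {
    suppressWarnings(as.numeric(x))
  }
}

#' Construct a knockdown table object
#'
#' @param rbp_name name of the knocked-down RBP.
#' @param records a data frame of skipped-exon records (see
#'   [read_knockdown_table()] for columns).
#' @param cell_line cell line label.
#' @param rbp_family `"SR"`, `"hnRNP"`, or `"other"`.
#' @return an object of class `knockdown_table`.
#' @export
knockdown_table <- function(rbp_name, records, cell_line = "unspecified",
                            rbp_family = c("other", "SR", "hnRNP")) {
  rbp_family <- match.arg(rbp_family)
  if (!nzchar(rbp_name)) stopf("rbp_name must be nonempty")
  records <- tibble::as_tibble(records)
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing) > 0L)
    stopf("records lack columns: %s", paste(missing, collapse = ", "))
  bad <- which(!is.na(records$exon_start) & !is.na(records$exon_end) &
                 records$exon_start >= records$exon_end)
  if (length(bad) > 0L)
    stopf("exon_start >= exon_end in row(s) %s", paste(utils::head(bad, 5), collapse = ", "))
  structure(list(rbp_name = rbp_name, rbp_family = rbp_family,
                 cell_line = cell_line, records = records),
            class = "knockdown_table")
}

#' @export
print.knockdown_table <- function(x, ...) {
  cat(sprintf("<knockdown_table> %s (%s, %s): %d skipped-exon records\n",
              x$rbp_name, x$rbp_family, x$cell_line, nrow(x$records)))
  invisible(x)
}

#' Read a skipped-exon differential-splicing table
#'
#' Parses one knockdown-vs-control table into normalised skipped-exon
#' records: PSI values as fractions in \[0, 1\] (percent sources are
#' rescaled), coordinates 0-based half-open, and the sign convention fixed
#' so that positive `delta_psi` means increased inclusion upon knockdown.
#'
#' @param path TSV file path.
#' @param dialect dialect name, mapping-file path, or `sd_dialect` object.
#' @param rbp_name,cell_line,rbp_family table metadata; `rbp_name` defaults
#'   to the file name without extension.
#' @return a `knockdown_table` whose `records` tibble has columns
#'   `gene_id`, `gene_symbol`, `chrom`, `strand`, `exon_start`, `exon_end`,
#'   `upstream_exon_start/_end`, `downstream_exon_start/_end`,
#'   `psi_control`, `psi_knockdown`, `delta_psi`, `fdr`.
#' @export
read_knockdown_table <- function(path, dialect = "canonical",
                                 rbp_name = NULL, cell_line = "unspecified",
                                 rbp_family = "other") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- get_dialect(dialect)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "NaN", ""))
  missing <- setdiff(unname(d$columns), names(raw))
  if (length(missing) > 0L)
    stopf("table %s does not match dialect '%s': missing column(s) %s",
          path, d$name, paste(missing, collapse = ", "))

  get <- function(field) {
    if (!field %in% names(d$columns)) return(rep(NA, nrow(raw)))
    col <- d$columns[[field]]
    if (!col %in% names(raw)) return(rep(NA, nrow(raw)))
    raw[[col]]
  }

  int_field <- function(field) {
    x <- suppressWarnings(as.numeric(get(field)))
    bad <- which(is.na(x) & !is.na(get(field)))
    if (length(bad) > 0L)
      stopf("unparseable coordinate in column '%s' at data line %d of %s",
            d$columns[[field]], bad[1], path)
    as.integer(round(x))
  }

  strand <- as.character(get("strand"))
  strand[strand %in% c("−", "-")] <- "-"  # minus sign or hyphen
  ok <- strand %in% c("+", "-")
  if (!all(ok))
    stopf("unrecognised strand symbol(s) %s in %s",
          paste(unique(strand[!ok]), collapse = ", "), path)

  rec <- tibble::tibble(
    gene_id = as.character(get("gene_id")),
    gene_symbol = as.character(get("gene_symbol")),
    chrom = as.character(get("chrom")),
    strand = strand,
    exon_start = int_field("exon_start"),
    exon_end = int_field("exon_end"),
    upstream_exon_start = int_field("upstream_exon_start"),
    upstream_exon_end = int_field("upstream_exon_end"),
    downstream_exon_start = int_field("downstream_exon_start"),
    downstream_exon_end = int_field("downstream_exon_end"),
    psi_control = parse_psi_column(get("psi_control"), d$replicate_sep),
    psi_knockdown = parse_psi_column(get("psi_knockdown"), d$replicate_sep),
    delta_psi = suppressWarnings(as.numeric(get("delta_psi"))),
    fdr = suppressWarnings(as.numeric(get("fdr")))
  )

  if (d$coords == "1based_closed") {
    for (f in c("exon_start", "upstream_exon_start", "downstream_exon_start"))
      rec[[f]] <- rec[[f]] - 1L
  }

  # unit normalisation: percent sources divided by 100
  psi_cols <- c("psi_control", "psi_knockdown", "delta_psi")
  is_percent <- switch(d$psi_units,
    percent = TRUE,
    fraction = FALSE,
    auto = any(abs(unlist(rec[psi_cols])) > 1 + 1e-9, na.rm = TRUE))
  if (is_percent) for (f in psi_cols) rec[[f]] <- rec[[f]] / 100

  if (d$sign == "control_minus_kd") rec$delta_psi <- -rec$delta_psi

  knockdown_table(rbp_name %||% tools::file_path_sans_ext(basename(path)),
                  rec, cell_line = cell_line, rbp_family = rbp_family)
}

#' Write a knockdown table in the canonical dialect
#'
#' @param table a `knockdown_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_knockdown_table <- function(table, path) {
  stopifnot(inherits(table, "knockdown_table"))
  r <- table$records
  out <- data.frame(
    GeneID = r$gene_id, geneSymbol = r$gene_symbol, chr = r$chrom,
    strand = r$strand, exonStart_0base = r$exon_start, exonEnd = r$exon_end,
    upstreamES = r$upstream_exon_start, upstreamEE = r$upstream_exon_end,
    downstreamES = r$downstream_exon_start,
    downstreamEE = r$downstream_exon_end,
    PSI_control = r$psi_control, PSI_kd = r$psi_knockdown,
    IncLevelDifference = r$delta_psi, FDR = r$fdr,
    check.names = FALSE
  )
  utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate exon entries
#'
#' Reduces a knockdown table to at most one record per exon key
#' `(chrom, strand, exon_start, exon_end)`. Among duplicates the record
#' with the largest |delta PSI| is kept; ties are broken by smallest FDR,
#' then first occurrence. Idempotent.
#'
#' @param table a `knockdown_table`.
#' @return a deduplicated `knockdown_table`.
#' @export
deduplicate <- function(table) {
  stopifnot(inherits(table, "knockdown_table"))
  r <- table$records
  if (nrow(r) <= 1L) return(table)
  keys <- exon_key_of(r)
  abs_dpsi <- abs(r$delta_psi)
  abs_dpsi[is.na(abs_dpsi)] <- -Inf
  fdr <- r$fdr
  fdr[is.na(fdr)] <- Inf
  ord <- order(keys, -abs_dpsi, fdr, seq_len(nrow(r)))
  keep <- ord[!duplicated(keys[ord])]
  table$records <- r[sort(keep), , drop = FALSE]
  table
}

FEATURE_COLUMNS <- c("chr", "strand", "exonStart_0base", "exonEnd",
                     "exon_len", "up_intron_len", "down_intron_len",
                     "ss5_maxent", "ss3_maxent", "phylop")

#' Read an exon feature table
#'
#' Features (splice-site strengths, conservation, lengths) are consumed as
#' a precomputed table keyed by exon; this package never computes them from
#' sequence.
#'
#' @param path TSV with columns `chr`, `strand`, `exonStart_0base`,
#'   `exonEnd`, `exon_len`, `up_intron_len`, `down_intron_len`,
#'   `ss5_maxent`, `ss3_maxent`, `phylop`.
#' @return tibble with a `key` column plus the six feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(FEATURE_COLUMNS, names(raw))
  if (length(missing) > 0L)
    stopf("feature table missing column(s): %s", paste(missing, collapse = ", "))
  keys <- exon_key(raw$chr, raw$strand, raw$exonStart_0base, raw$exonEnd)
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0L)
    stopf("duplicated exon key(s) in feature table: %s",
          paste(utils::head(unique(dup), 3), collapse = ", "))
  for (f in c("exon_len", "up_intron_len", "down_intron_len")) {
    if (any(raw[[f]] <= 0, na.rm = TRUE))
      stopf("non-positive %s in feature table", f)
  }
  tibble::tibble(
    key = keys,
    exon_length = as.integer(raw$exon_len),
    upstream_intron_length = as.integer(raw$up_intron_len),
    downstream_intron_length = as.integer(raw$down_intron_len),
    ss5_score = as.numeric(raw$ss5_maxent),
    ss3_score = as.numeric(raw$ss3_maxent),
    phylop = as.numeric(raw$phylop)
  )
}

#' Write an exon feature table
#'
#' @param features tibble as returned by [read_feature_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  parts <- strsplit(features$key, ":", fixed = TRUE)
  out <- data.frame(
    chr = vapply(parts, `[`, "", 1), strand = vapply(parts, `[`, "", 2),
    exonStart_0base = as.integer(vapply(parts, `[`, "", 3)),
    exonEnd = as.integer(vapply(parts, `[`, "", 4)),
    exon_len = features$exon_length,
    up_intron_len = features$upstream_intron_length,
    down_intron_len = features$downstream_intron_length,
    ss5_maxent = features$ss5_score, ss3_maxent = features$ss3_score,
    phylop = features$phylop, check.names = FALSE
  )
  utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
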