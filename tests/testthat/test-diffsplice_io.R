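test_that("canonical tables round-trip through write and read", {
  tb <- toy_table("SRSF1", affected = c(2, 5), universe_n = 8, dpsi = c(0.22, -0.4))
  tb$records$fdr[1] <- NA  # missing FDR must survive the trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_knockdown_table(tb, path)
  back <- read_knockdown_table(path, "canonical", rbp_name = "SRSF1",
                               cell_line = "toy")
  int_cols <- c("exon_start", "exon_end", "upstream_exon_start",
                "upstream_exon_end", "downstream_exon_start",
                "downstream_exon_end")
  for (f in int_cols) expect_identical(back$records[[f]], tb$records[[f]])
  for (f in c("psi_control", "psi_knockdown", "delta_psi", "fdr"))
    expect_equal(back$records[[f]], tb$records[[f]], tolerance = 1e-9)
})

test_that("percent-scale PSI values are auto-normalised to fractions", {
  tb <- toy_table("X", affected = 1, universe_n = 3, dpsi = 0.22)
  # re-express everything in percent
  for (f in c("psi_control", "psi_knockdown", "delta_psi"))
    tb$records[[f]] <- tb$records[[f]] * 100
  path <- withr::local_tempfile(fileext = ".tsv")
  write_knockdown_table(tb, path)
  back <- read_knockdown_table(path, "canonical")
  expect_equal(back$records$delta_psi[1], 0.22, tolerance = 1e-9)
  expect_true(all(abs(back$records$psi_control) <= 1))
})

test_that("control-minus-knockdown dialects get their sign flipped", {
  # a source reporting control - kd = -0.22 means inclusion ROSE by 0.22
  raw <- data.frame(
    gid = "G1", sym = "Gene1", chrom = "chr1", std = "+",
    es = 1000L, ee = 1100L, ues = 500L, uee = 600L, des = 1400L, dee = 1500L,
    ctrl = 0.50, kd = 0.72, diff = -0.22, q = 0.01
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- dialect("flipped", columns = c(
    gene_id = "gid", gene_symbol = "sym", chrom = "chrom", strand = "std",
    exon_start = "es", exon_end = "ee",
    upstream_exon_start = "ues", upstream_exon_end = "uee",
    downstream_exon_start = "des", downstream_exon_end = "dee",
    psi_control = "ctrl", psi_knockdown = "kd", delta_psi = "diff", fdr = "q"),
    sign = "control_minus_kd")
  back <- read_knockdown_table(path, d)
  expect_equal(back$records$delta_psi, 0.22)
  # sign-normalisation invariant: delta = psi_kd - psi_control
  expect_equal(back$records$delta_psi,
               back$records$psi_knockdown - back$records$psi_control,
               tolerance = 1e-6)
})

test_that("dialects can be declared in a YAML column-mapping file", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: custom_percent",
    "psi_units: percent",
    "columns:",
    "  gene_id: gid", "  gene_symbol: sym", "  chrom: chrom",
    "  strand: std", "  exon_start: es", "  exon_end: ee",
    "  upstream_exon_start: ues", "  upstream_exon_end: uee",
    "  downstream_exon_start: des", "  downstream_exon_end: dee",
    "  delta_psi: diff"), yml)
  d <- get_dialect(yml)
  expect_s3_class(d, "sd_dialect")
  expect_equal(d$name, "custom_percent")

  raw <- data.frame(gid = "G1", sym = "S1", chrom = "chr2", std = "+",
                    es = 10L, ee = 90L, ues = 1L, uee = 5L,
                    des = 95L, dee = 99L, diff = 22)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_knockdown_table(tsv, yml, rbp_name = "X")
  expect_equal(back$records$delta_psi, 0.22)  # percent -> fraction
  expect_true(is.na(back$records$fdr))

  expect_error(get_dialect("no_such_dialect"), "registered dialects")
})

test_that("rMATS-style replicate inclusion levels are averaged", {
  raw <- data.frame(
    GeneID = "G1", geneSymbol = "Gene1", chr = "chr1", strand = "-",
    exonStart_0base = 100L, exonEnd = 200L,
    upstreamES = 10L, upstreamEE = 50L, downstreamES = 300L, downstreamEE = 350L,
    IncLevel1 = "0.2,0.4", IncLevel2 = "0.6,0.8", IncLevelDifference = -0.4,
    FDR = 0.001, check.names = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_knockdown_table(path, "rmats_se_jc")
  expect_equal(back$records$psi_knockdown, 0.3)
  expect_equal(back$records$psi_control, 0.7)
  expect_equal(back$records$delta_psi, -0.4)
})

test_that("format errors name the offending column or line", {
  tb <- toy_table("X", universe_n = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_knockdown_table(tb, path)
  txt <- readLines(path)
  txt[1] <- sub("IncLevelDifference", "wrongName", txt[1])
  writeLines(txt, path)
  expect_error(read_knockdown_table(path, "canonical"), "IncLevelDifference")

  write_knockdown_table(tb, path)
  txt <- readLines(path)
  txt[2] <- sub("^(\\S+\t\\S+\t\\S+\t)\\+", "\\1*", txt[2])
  writeLines(txt, path)
  expect_error(read_knockdown_table(path, "canonical"), "strand")
})

test_that("deduplicate keeps the strongest record and is idempotent", {
  tb <- toy_table("X", universe_n = 5)
  # duplicate exon 2 with |dPSI| 0.10 vs 0.30 (different flanking exons:
  # identity must ignore them)
  dup <- tb$records[2, ]
  dup$upstream_exon_start <- 1L
  tb$records$delta_psi[2] <- 0.10
  dup$delta_psi <- 0.30
  tb$records <- rbind(tb$records, dup)
  out <- deduplicate(tb)
  expect_equal(nrow(out$records), 5L)
  k <- exon_key("chr1", "+", 2000L, 2100L)
  kept <- out$records[exon_key(out$records$chrom, out$records$strand,
                               out$records$exon_start,
                               out$records$exon_end) == k, ]
  expect_equal(kept$delta_psi, 0.30)
  expect_identical(deduplicate(out)$records, out$records)

  # ties on |dPSI| break by smaller FDR
  tb2 <- toy_table("Y", universe_n = 2)
  dup2 <- tb2$records[1, ]
  tb2$records$delta_psi[1] <- 0.3; tb2$records$fdr[1] <- 0.2
  dup2$delta_psi <- -0.3; dup2$fdr <- 0.05
  tb2$records <- rbind(tb2$records, dup2)
  out2 <- deduplicate(tb2)
  expect_equal(nrow(out2$records), 2L)
  expect_equal(out2$records$fdr[out2$records$exon_start == 1000L], 0.05)
})

test_that("deduplicate leaves unique and empty tables unchanged", {
  tb <- toy_table("X", universe_n = 4)
  expect_identical(deduplicate(tb)$records, tb$records)
  empty <- tb
  empty$records <- tb$records[0, ]
  expect_equal(nrow(deduplicate(empty)$records), 0L)
})

test_that("feature tables reject duplicates and non-positive lengths", {
  feats <- data.frame(
    chr = "chr1", strand = "+", exonStart_0base = c(100L, 200L, 300L),
    exonEnd = c(150L, 260L, 390L), exon_len = c(50L, 60L, 90L),
    up_intron_len = 500L, down_intron_len = 700L,
    ss5_maxent = c(8.1, 7.2, 9.0), ss3_maxent = 6.5, phylop = 1.2,
    check.names = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(feats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_feature_table(path)
  expect_equal(nrow(out), 3L)
  expect_equal(out$ss5_score, c(8.1, 7.2, 9.0))

  feats$exon_len[2] <- 0L
  write.table(feats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(path), "exon_len")

  feats$exon_len[2] <- 60L
  feats$exonStart_0base[3] <- 100L; feats$exonEnd[3] <- 150L
  write.table(feats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(path), "chr1:\\+:100:150")
})
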