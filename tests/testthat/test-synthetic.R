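test_that("generation is deterministic given the config", {
  cfg <- synthetic_config(seed = 123, n_rbps = 5, universe_size = 400)
  d1 <- generate_synthetic(cfg)
  d2 <- generate_synthetic(cfg)
  expect_identical(d1$tables_by_line, d2$tables_by_line)
  expect_identical(d1$features, d2$features)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_synthetic(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("planted pairwise overlaps are reproduced exactly", {
  cfg <- synthetic_config(
    seed = 9, n_rbps = 4, universe_size = 5000,
    regulon_sizes = c(100L, 100L, 60L, 40L),
    planted_pairs = list(list(rbp_a = 1, rbp_b = 2, shared = 40),
                         list(rbp_a = 3, rbp_b = 4, shared = 12)))
  ds <- generate_synthetic(cfg)
  regs <- synthetic_regulons(ds)
  expect_equal(length(intersect(regs$RBP01$affected, regs$RBP02$affected)), 40L)
  expect_equal(length(intersect(regs$RBP03$affected, regs$RBP04$affected)), 12L)
  pr <- all_pairs(regs)
  planted <- paste(pr$rbp_a, pr$rbp_b) %in% c("RBP01 RBP02", "RBP03 RBP04")
  expect_true(all(pr$significant[planted]))
})

test_that("infeasible planted overlaps are rejected at config time", {
  expect_error(generate_synthetic(synthetic_config(
    seed = 1, n_rbps = 2, universe_size = 100, regulon_sizes = c(10L, 5L),
    planted_pairs = list(list(rbp_a = 1, rbp_b = 2, shared = 8)))),
    "exceeds regulon size")
  expect_error(synthetic_config(seed = 1, n_rbps = 3, universe_size = 10,
                                regulon_sizes = c(3L, 5L, 50L)),
               "universe_size")
})

test_that("filters recover the planted truth under both stock policies", {
  cfg <- synthetic_config(seed = 31, n_rbps = 6, universe_size = 800)
  ds <- generate_synthetic(cfg)
  truth <- ds$truth$lines[[1]]$affected
  for (policy in list(hela_policy(), encode_policy())) {
    regs <- synthetic_regulons(ds, policy = policy)
    for (nm in names(regs)) {
      expect_setequal(regs[[nm]]$affected, truth[[nm]])
      expect_equal(regs[[nm]]$directions[sort(names(regs[[nm]]$directions))],
                   ds$truth$lines[[1]]$directions[[nm]][
                     sort(names(ds$truth$lines[[1]]$directions[[nm]]))])
    }
  }
})

test_that("emitted records satisfy the record invariants", {
  cfg <- synthetic_config(seed = 77, n_rbps = 4, universe_size = 300)
  ds <- generate_synthetic(cfg)
  for (tb in ds$tables_by_line[[1]]) {
    r <- tb$records
    expect_true(all(r$exon_start < r$exon_end))
    expect_true(all(r$psi_control >= 0 & r$psi_control <= 1))
    expect_true(all(r$psi_knockdown >= 0 & r$psi_knockdown <= 1))
    expect_equal(r$delta_psi, r$psi_knockdown - r$psi_control,
                 tolerance = 1e-9)
    expect_true(all(abs(r$delta_psi) <= 1))
    expect_false(anyDuplicated(exon_key(r$chrom, r$strand, r$exon_start,
                                        r$exon_end)) > 0)
  }
})

test_that("written datasets read back to the same regulons", {
  cfg <- synthetic_config(seed = 13, n_rbps = 3, universe_size = 200)
  ds <- generate_synthetic(cfg)
  dir <- withr::local_tempdir()
  write_synthetic(ds, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  files <- list.files(file.path(dir, "HeLa"), full.names = TRUE)
  expect_length(files, 3L)
  regs_disk <- lapply(files, function(p)
    apply_filter(deduplicate(read_knockdown_table(p, "canonical")),
                 hela_policy()))
  regs_mem <- synthetic_regulons(ds)
  for (i in seq_along(regs_disk))
    expect_setequal(regs_disk[[i]]$affected,
                    regs_mem[[regs_disk[[i]]$rbp_name]]$affected)
  feats <- read_feature_table(file.path(dir, "features.tsv"))
  expect_equal(nrow(feats), 200L)
})

test_that("null resampling matches the chance-overlap expectation M*n/N", {
  cfg <- synthetic_config(seed = 55, n_rbps = 2, universe_size = 1000,
                          regulon_sizes = c(50L, 60L), planted_pairs = list())
  reps <- null_resample(cfg, 1000)
  m <- vapply(reps, function(regs)
    length(intersect(regs[[1]]$affected, regs[[2]]$affected)), 1L)
  expected <- 50 * 60 / 1000
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - expected), 3 * se)
  # zero-size regulons never overlap and give p = 1
  cfg0 <- synthetic_config(seed = 56, n_rbps = 2, universe_size = 100,
                           regulon_sizes = c(0L, 10L), planted_pairs = list())
  reps0 <- null_resample(cfg0, 3)
  for (regs in reps0) {
    res <- test_pair(regs[[1]], regs[[2]])
    expect_equal(res$m, 0L)
    expect_equal(res$p_value, 1)
  }
})
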