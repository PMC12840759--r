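test_that("multiplicity counts how many regulons hit each exon", {
  regs <- list(toy_regulon("A", c(1, 2, 3), universe_n = 20),
               toy_regulon("B", c(1, 4), universe_n = 20),
               toy_regulon("C", c(1, 4, 5), universe_n = 20))
  prof <- build_multiplicity(regs)
  counts <- setNames(prof$per_exon$count, prof$per_exon$key)
  expect_equal(unname(counts[toy_key(1)]), 3L)
  expect_equal(unname(counts[toy_key(4)]), 2L)
  expect_equal(unname(counts[toy_key(5)]), 1L)
  # conservation: bins sum to the union of affected sets
  expect_equal(sum(lengths(prof$bins)), 5L)
  # disjoint regulons are all multiplicity 1
  prof1 <- build_multiplicity(list(toy_regulon("A", 1:3),
                                   toy_regulon("B", 4:6)))
  expect_true(all(prof1$per_exon$count == 1L))

  # nine regulons sharing one exon: bins extend to multiplicity 9
  nine <- lapply(1:9, function(i)
    toy_regulon(sprintf("R%02d", i), affected = c(1, i + 10), universe_n = 30))
  prof9 <- build_multiplicity(nine)
  expect_equal(max(prof9$per_exon$count), 9L)
  expect_equal(names(prof9$bins)[length(prof9$bins)], "9")
})

test_that("direction classes split exclusive from mixed regulation", {
  regs <- list(
    toy_regulon("A", 1:3, universe_n = 20, dpsi = c(0.5, -0.5, 0.5)),
    toy_regulon("B", 1:2, universe_n = 20, dpsi = c(0.5, 0.5))
  )
  prof <- build_multiplicity(regs)
  cls <- direction_consistency(prof)
  two <- cls[cls$count == 2, ]
  expect_equal(two$n_exons, 2L)
  expect_equal(two$pct_increase_only, 50)  # exon 1: inc+inc
  expect_equal(two$pct_both, 50)           # exon 2: dec+inc
  one <- cls[cls$count == 1, ]
  expect_equal(one$pct_both, 0)            # single regulator can't mix
  expect_equal(one$pct_increase_only + one$pct_decrease_only + one$pct_both, 100)
})

test_that("mixed-direction fraction follows 1 - 2(1/2)^k under unbiased signs", {
  cfg <- synthetic_config(seed = 99, n_rbps = 12, universe_size = 1000,
                          regulon_sizes = rep(150L, 12),
                          enhancer_bias = 0.5)
  regs <- synthetic_regulons(generate_synthetic(cfg))
  cls <- direction_consistency(build_multiplicity(regs))
  for (k in cls$count[cls$n_exons >= 50]) {
    expected <- 100 * (1 - 2 * 0.5^k)
    n <- cls$n_exons[cls$count == k]
    se <- 100 * sqrt(0.25 / n)  # conservative binomial SE
    expect_lt(abs(cls$pct_both[cls$count == k] - expected), 4 * se + 1e-9)
  }
})

test_that("interdependent exons sit at intermediate inclusion more often", {
  cfg <- synthetic_config(seed = 17, n_rbps = 10, universe_size = 1500)
  prof <- build_multiplicity(synthetic_regulons(generate_synthetic(cfg)))
  incl <- inclusion_distributions(prof)
  f <- incl$intermediate_fraction
  # independent exons: bimodal Beta(1,9)/Beta(9,1) mixture keeps the
  # [0.35, 0.65] window nearly empty (closed-form mass ~2%)
  expect_lt(f[["independent"]], 0.10)
  expect_gt(f[["interdependent"]], f[["independent"]])
  expect_equal(sum(incl$histogram$n[incl$histogram$population == "independent"]),
               sum(prof$per_exon$count == 1))
})

test_that("degenerate all-intermediate input gives fraction 1", {
  regs <- list(toy_regulon("A", 1:5, universe_n = 10),
               toy_regulon("B", 1:5, universe_n = 10))
  prof <- build_multiplicity(regs)  # toy psi_control is 0.5 everywhere
  incl <- inclusion_distributions(prof)
  expect_equal(unname(incl$intermediate_fraction["interdependent"]), 1)
})

test_that("feature trends recover a planted slope and flatten on constants", {
  cfg <- synthetic_config(seed = 5, n_rbps = 12, universe_size = 1500,
                          regulon_sizes = rep(120L, 12))
  ds <- generate_synthetic(cfg)
  prof <- build_multiplicity(synthetic_regulons(ds))
  ft <- feature_trend(prof, ds$features)
  ss5 <- ft$trends[ft$trends$feature == "ss5_score", ]
  ci <- ss5$slope + c(-1, 1) * qt(0.975, ss5$n_bins - 2) * ss5$slope_se
  expect_true(ci[1] <= -0.4 && -0.4 <= ci[2])

  flat <- ds$features
  flat$phylop <- 2.5
  ft2 <- feature_trend(prof, flat)
  ph <- ft2$trends[ft2$trends$feature == "phylop", ]
  expect_equal(ph$slope, 0)
  expect_equal(ph$r_squared, 0)
})

test_that("exons missing from the feature table are excluded and counted", {
  cfg <- synthetic_config(seed = 6, n_rbps = 8, universe_size = 800,
                          regulon_sizes = rep(80L, 8))
  ds <- generate_synthetic(cfg)
  prof <- build_multiplicity(synthetic_regulons(ds))
  partial <- ds$features[seq_len(nrow(ds$features) %/% 2), ]
  ft <- feature_trend(prof, partial)
  expect_gt(ft$n_missing_features, 0)
  expect_equal(ft$n_missing_features,
               sum(!prof$per_exon$key %in% partial$key))
  tiny <- ds$features[0, ]
  expect_error(feature_trend(prof, tiny), "bins")
})
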