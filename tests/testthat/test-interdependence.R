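test_that("survival function matches hand-checked values", {
  expect_identical(hypergeom_sf(0, 100, 10, 10), 1)
  # P(X >= 1) for two size-5 sets in a universe of 10: 1 - C(5,5)/C(10,5)
  expect_equal(hypergeom_sf(1, 10, 5, 5), 251 / 252, tolerance = 1e-12)
  expect_identical(hypergeom_sf(6, 10, 5, 5), 0)
  expect_error(hypergeom_sf(1, 10, 11, 5), "M <= N")
  expect_error(hypergeom_sf(-1, 10, 5, 5), "non-negative")
})

test_that("survival function agrees with subset enumeration on small universes", {
  for (N in c(6, 8, 10)) for (M in c(0, 2, N %/% 2, N)) for (n in c(1, N %/% 2)) {
    for (m in 0:(min(M, n) + 1)) {
      expect_equal(hypergeom_sf(m, N, M, n), sf_enumerate(m, N, M, n),
                   tolerance = 1e-12,
                   label = sprintf("sf(%d; %d, %d, %d)", m, N, M, n))
    }
  }
})

test_that("upper tail is monotone in m and complements the lower CDF", {
  cases <- list(c(50, 10, 20), c(200, 40, 15), c(25, 12, 12), c(1000, 300, 50))
  for (cs in cases) {
    N <- cs[1]; M <- cs[2]; n <- cs[3]
    sf <- vapply(0:(min(M, n) + 1), hypergeom_sf, numeric(1), N = N, M = M, n = n)
    expect_true(all(diff(sf) <= 1e-15))
    for (m in 1:min(M, n)) {
      lower <- sum(exp(lchoose(M, 0:(m - 1)) + lchoose(N - M, n - (0:(m - 1))) -
                         lchoose(N, n)))
      expect_equal(hypergeom_sf(m, N, M, n) + lower, 1, tolerance = 1e-12)
    }
  }
})

test_that("log-space evaluation survives extreme tails without underflow", {
  # naive arithmetic overflows here: choose(400, 200) alone exceeds 1e119
  p <- hypergeom_sf(200, 20000, 400, 400)
  expect_gt(p, 0)
  expect_lt(p, 1e-200)
  expect_equal(log(p),
               phyper(199, 400, 19600, 400, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-10)
})

test_that("pair tests count overlap, union universe, and flag no-overlap", {
  a <- toy_regulon("A", 1:6, universe_n = 30)
  b <- toy_regulon("B", 4:12, universe_n = 30)
  res <- test_pair(a, b)
  expect_equal(res$m, 3L)
  expect_equal(res$N, 30L)
  expect_equal(res$M, 6L)
  expect_equal(res$n, 9L)
  expect_equal(res$p_value, sf_oracle(3, 30, 6, 9), tolerance = 1e-12)
  expect_equal(res$status, "tested")

  # symmetry: m, N, p identical; M and n swap
  rev <- test_pair(b, a)
  expect_equal(rev[c("m", "N", "p_value")], res[c("m", "N", "p_value")])
  expect_equal(c(rev$M, rev$n), c(res$n, res$M))

  disjoint <- test_pair(toy_regulon("C", 1:3), toy_regulon("D", 10:12))
  expect_equal(disjoint$p_value, 1)
  expect_equal(disjoint$status, "no_overlap")
  expect_false(disjoint$significant)
})

test_that("degenerate full overlap is certain, hence never significant", {
  a <- toy_regulon("A", 1:20, universe_n = 20)
  b <- toy_regulon("B", 1:20, universe_n = 20)
  res <- test_pair(a, b, alpha = 0.05)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_true(test_pair(a, b, alpha = 1)$significant)
})

test_that("the sum-universe variant inflates N but not the counts", {
  a <- toy_regulon("A", 1:6, universe_n = 30)
  b <- toy_regulon("B", 4:12, universe_n = 30)
  res <- test_pair(a, b, universe = "sum")
  expect_equal(res$N, 60L)
  expect_equal(res$m, 3L)
})

test_that("all_pairs enumerates each unordered pair once, in name order", {
  regs <- lapply(paste0("R", sprintf("%02d", 1:5)), toy_regulon,
                 affected = 1:4, universe_n = 50)
  res <- all_pairs(regs)
  expect_equal(nrow(res), 10L)
  expect_true(all(res$rbp_a < res$rbp_b))
  expect_false(any(duplicated(paste(res$rbp_a, res$rbp_b))))
  expect_equal(all_pairs(regs[1:2])$m, 4L)
  dup <- c(regs, regs[1])
  expect_error(all_pairs(dup), "duplicate")
})

test_that("planted dependent pairs are detected, null pairs are not", {
  # 5 RBPs in a universe of 5000; two pairs share 40 of their 100 exons
  u <- 5000
  sets <- list(A = 1:100, B = c(1:40, 201:260), C = 301:400,
               D = c(321:360, 501:560), E = 1001:1100)
  regs <- mapply(function(nm, ix) toy_regulon(nm, ix, universe_n = u),
                 names(sets), sets, SIMPLIFY = FALSE)
  res <- all_pairs(regs, alpha = 0.05)
  sig <- res[res$significant, c("rbp_a", "rbp_b")]
  expect_setequal(paste(sig$rbp_a, sig$rbp_b), c("A B", "C D"))
})

test_that("BH adjustment only ever reduces the significant set", {
  set.seed(11)
  regs <- lapply(sprintf("R%02d", 1:8), function(nm)
    toy_regulon(nm, sample(200, 30), universe_n = 200))
  raw <- all_pairs(regs, alpha = 0.05)
  adj <- all_pairs(regs, alpha = 0.05, adjust = "BH")
  expect_true(all(adj$p_adjusted >= adj$p_value))
  expect_true(all(which(adj$significant) %in% which(raw$significant)))
})

test_that("matrix cells are percentages of the row's interdependent exons", {
  # row RBP with 9 affected exons, all interdependent, 4 shared with one
  # partner: that partner's cell reads 44%
  regs <- list(
    toy_regulon("hR", 1:9, universe_n = 300),
    toy_regulon("hC", c(1:4, 101:140), universe_n = 300),
    toy_regulon("hZ", c(5:9, 201:240), universe_n = 300)
  )
  m <- build_matrix(regs)
  expect_equal(m$row_totals[["hR"]], 9L)
  expect_equal(round(m$cells["hR", "hC"]), 44)
  expect_equal(m$per_rbp_interdependent_fraction[["hR"]], 100)
  expect_true(all(m$cells <= 100 + 1e-9))
  expect_true(all(m$row_totals <= m$n_affected))
})

test_that("a row with no interdependent exon has an all-zero row", {
  regs <- list(toy_regulon("A", 1:5, universe_n = 50),
               toy_regulon("B", 10:14, universe_n = 50),
               toy_regulon("C", 10:12, universe_n = 50))
  m <- build_matrix(regs)
  expect_equal(m$row_totals[["A"]], 0L)
  expect_true(all(m$cells["A", ] == 0))
  expect_equal(m$per_rbp_interdependent_fraction[["A"]], 0)
})

test_that("complete linkage merges tight pairs first and at the full diameter", {
  # rows at 0, 1 and 2.1 on a line: complete linkage joins {0,1} at
  # height 1, then absorbs 2.1 at height 2.1 (single linkage would use 1.1)
  m <- matrix(c(0, 1, 2.1, 0, 0, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  cl <- cluster_matrix(m)
  expect_equal(cl$rows$height, c(1, 2.1))
  expect_equal(sort(cl$rows$merge[1, ]), c(-2, -1))

  same <- matrix(0, nrow = 2, ncol = 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  cl2 <- cluster_matrix(same)
  expect_equal(cl2$rows$height, 0)
  expect_error(cluster_matrix(m[1, , drop = FALSE]), "2 rows")
})
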