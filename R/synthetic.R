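# Synthetic knockdown datasets with planted ground truth.
#
# The generator emulates the statistical shape of SR/hnRNP knockdown
# differential-splicing tables: ~30 RBPs with regulon sizes spanning
# roughly 3-300 exons, planted pairwise regulon overlaps, a per-RBP
# enhancer bias in the sign of dPSI, bimodal wildtype PSI with an
# intermediate component that grows with regulator multiplicity, and exon
# feature covariates with a negative 5' splice-site trend against
# multiplicity. Every planted affected row passes the |dPSI| > 0.15
# filter (and FDR <= 0.05), every background row fails both, so filters
# recover the planted truth exactly.

#' Configure a synthetic knockdown dataset
#'
#' @param seed integer seed; generation is deterministic given the config.
#' @param n_rbps number of simulated RBPs.
#' @param universe_size number of candidate cassette exons shared by all
#'   knockdown tables.
#' @param regulon_sizes integer vector of per-RBP affected-set sizes, or
#'   `NULL` to sample log-uniformly over `regulon_size_range`.
#' @param regulon_size_range length-2 range for log-uniform size sampling.
#' @param planted_pairs list of `list(rbp_a=, rbp_b=, shared=)` giving
#'   exact pairwise overlaps to plant (RBPs referenced by index or name),
#'   or `NULL` to auto-plant: each pair independently chosen with
#'   probability `planted_pair_prob`, sharing
#'   `round(planted_overlap_frac * min(size_a, size_b))` exons (>= 1).
#' @param planted_pair_prob,planted_overlap_frac auto-planting parameters.
#' @param enhancer_bias per-RBP probability that an affected exon shows
#'   *decreased* inclusion upon knockdown (the RBP enhances in wildtype);
#'   recycled across RBPs.
#' @param delta_psi_shape Beta shape parameters for affected |dPSI|
#'   magnitudes, drawn as `0.15 + 0.85 * Beta(a, b)` (right-skewed effect
#'   sizes typical of knockdown differential-splicing output).
#' @param psi_intermediate_weight_max,psi_intermediate_full_at wildtype-PSI
#'   mixture: weight of the intermediate `Beta(5, 5)` component is 0 for
#'   multiplicity-1 exons and rises linearly to the maximum at the given
#'   multiplicity; the rest is split evenly between `Beta(1, 9)` and
#'   `Beta(9, 1)` (bimodal inclusion).
#' @param feature_model named list of `c(intercept, slope, noise_sd)` per
#'   feature; defaults plant a negative 5' splice-site and PhyloP trend
#'   against multiplicity and weaker trends for exon/upstream-intron
#'   length.
#' @param cell_lines named numeric vector: cell-line label -> fraction of
#'   the first line's regulon retained in that line (the remainder is
#'   resampled). The first entry is the reference line and must be 1.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_rbps = 30L,
                             universe_size = 5000L,
                             regulon_sizes = NULL,
                             regulon_size_range = c(3L, 300L),
                             planted_pairs = NULL,
                             planted_pair_prob = 0.15,
                             planted_overlap_frac = 0.25,
                             enhancer_bias = 0.65,
                             delta_psi_shape = c(2, 5),
                             psi_intermediate_weight_max = 0.4,
                             psi_intermediate_full_at = 4L,
                             feature_model = NULL,
                             cell_lines = c(HeLa = 1)) {
  if (is.null(feature_model)) {
    feature_model <- list(
      ss5_score = c(intercept = 8.5, slope = -0.4, noise_sd = 1.5),
      ss3_score = c(intercept = 8.0, slope = 0.0, noise_sd = 1.5),
      phylop = c(intercept = 1.5, slope = -0.08, noise_sd = 0.5),
      exon_length = c(intercept = 130, slope = -3, noise_sd = 40),
      upstream_intron_length = c(intercept = 5000, slope = -150, noise_sd = 2000),
      downstream_intron_length = c(intercept = 5000, slope = 0, noise_sd = 2000)
    )
  }
  cfg <- list(seed = as.integer(seed), n_rbps = as.integer(n_rbps),
              universe_size = as.integer(universe_size),
              regulon_sizes = regulon_sizes,
              regulon_size_range = as.integer(regulon_size_range),
              planted_pairs = planted_pairs,
              planted_pair_prob = planted_pair_prob,
              planted_overlap_frac = planted_overlap_frac,
              enhancer_bias = enhancer_bias,
              delta_psi_shape = delta_psi_shape,
              psi_intermediate_weight_max = psi_intermediate_weight_max,
              psi_intermediate_full_at = as.integer(psi_intermediate_full_at),
              feature_model = feature_model,
              cell_lines = cell_lines)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_rbps < 1L) stopf("n_rbps must be >= 1")
  if (!is.null(cfg$regulon_sizes)) {
    if (length(cfg$regulon_sizes) != cfg$n_rbps)
      stopf("regulon_sizes must have length n_rbps")
    if (cfg$universe_size < max(cfg$regulon_sizes))
      stopf("universe_size must be >= the largest regulon")
  } else if (cfg$universe_size < min(cfg$regulon_size_range)) {
    stopf("universe_size must be >= the smallest possible regulon")
  }
  for (p in c("planted_pair_prob", "planted_overlap_frac",
              "psi_intermediate_weight_max"))
    assert_scalar_number(cfg[[p]], p, 0, 1)
  if (any(cfg$enhancer_bias < 0 | cfg$enhancer_bias > 1))
    stopf("enhancer_bias must lie in [0, 1]")
  if (length(cfg$cell_lines) < 1L || abs(cfg$cell_lines[1] - 1) > 1e-12)
    stopf("the first cell line is the reference and must have fraction 1")
  invisible(cfg)
}

# RNG discipline: a fixed algorithm (Mersenne-Twister / Inversion /
# Rejection), not the session default, so streams match across platforms;
# the caller's RNG state is restored on exit.
with_fixed_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  force(code)
}

rbp_names_for <- function(n) sprintf("RBP%02d", seq_len(n))

# sample() treats a scalar x as 1:x; this never does
safe_sample <- function(x, k) x[sample.int(length(x), k)]

resolve_sizes <- function(cfg) {
  if (!is.null(cfg$regulon_sizes)) return(as.integer(cfg$regulon_sizes))
  r <- cfg$regulon_size_range
  # regulons cannot outgrow the universe in small simulated studies
  r[2] <- min(r[2], cfg$universe_size)
  as.integer(round(exp(stats::runif(cfg$n_rbps, log(r[1]), log(r[2])))))
}

resolve_planted_pairs <- function(cfg, sizes) {
  n <- cfg$n_rbps
  nm <- rbp_names_for(n)
  if (!is.null(cfg$planted_pairs)) {
    out <- lapply(cfg$planted_pairs, function(p) {
      ia <- if (is.character(p$rbp_a)) match(p$rbp_a, nm) else as.integer(p$rbp_a)
      ib <- if (is.character(p$rbp_b)) match(p$rbp_b, nm) else as.integer(p$rbp_b)
      if (is.na(ia) || is.na(ib) || ia == ib)
        stopf("invalid planted pair (%s, %s)", p$rbp_a, p$rbp_b)
      list(a = min(ia, ib), b = max(ia, ib), shared = as.integer(p$shared))
    })
  } else {
    # auto mode: each pair planted with fixed probability, but never let a
    # regulon's total planted load exceed 60% of its size (feasibility)
    out <- list()
    load <- integer(n)
    cap <- pmax(1L, as.integer(floor(0.6 * sizes)))
    if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < cfg$planted_pair_prob) {
        s <- max(1L, as.integer(round(cfg$planted_overlap_frac * min(sizes[i], sizes[j]))))
        if (load[i] + s > cap[i] || load[j] + s > cap[j]) next
        load[i] <- load[i] + s
        load[j] <- load[j] + s
        out[[length(out) + 1L]] <- list(a = i, b = j, shared = s)
      }
    }
  }
  for (p in out)
    if (p$shared > min(sizes[p$a], sizes[p$b]))
      stopf("planted overlap %d exceeds regulon size for pair (%s, %s)",
            p$shared, nm[p$a], nm[p$b])
  out
}

# Sample wildtype PSI from the multiplicity-dependent Beta mixture,
# truncated to [lo, hi] by rejection (uniform fallback after 200 tries).
sample_psi_control <- function(w_int, lo, hi) {
  n <- length(w_int)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:200) {
      u <- stats::runif(1)
      w <- w_int[i]
      x <- if (u < w) stats::rbeta(1, 5, 5)
      else if (u < w + (1 - w) / 2) stats::rbeta(1, 1, 9)
      else stats::rbeta(1, 9, 1)
      if (x >= lo[i] && x <= hi[i]) { out[i] <- x; ok <- TRUE; break }
    }
    if (!ok) out[i] <- stats::runif(1, lo[i], hi[i])
  }
  out
}

#' Generate a synthetic knockdown dataset
#'
#' Produces one `knockdown_table` per RBP per cell line, a feature table
#' covering the full exon universe, and the planted ground truth. Exon
#' coordinates are synthesised as non-overlapping intervals on synthetic
#' chromosomes. Deterministic given the config (seed included).
#'
#' @param config a `synthetic_config`.
#' @return a `synthetic_dataset`: list with `tables_by_line` (cell line ->
#'   named list of `knockdown_table`s), `features` (tibble), `truth`
#'   (per-line affected key sets, directions, planted pairs, per-exon
#'   multiplicity, feature model), and `config`.
#' @export
generate_synthetic <- function(config) {
  validate_synthetic_config(config)
  with_fixed_rng(config$seed, {
    n <- config$n_rbps
    U <- config$universe_size
    rbps <- rbp_names_for(n)
    families <- rep(c("SR", "hnRNP"), length.out = n)

    # non-overlapping exon coordinates on synthetic chromosomes
    chroms <- paste0("chrS", ((seq_len(U) - 1L) %% 4L) + 1L)
    slot <- (seq_len(U) - 1L) %/% 4L
    exon_len <- sample(50:300, U, replace = TRUE)
    exon_start <- 10000L + slot * 10000L
    exon_end <- exon_start + exon_len
    strand <- sample(c("+", "-"), U, replace = TRUE)
    keys <- exon_key(chroms, strand, exon_start, exon_end)
    gene_id <- sprintf("SYNG%05d", seq_len(U))
    gene_symbol <- sprintf("Gene%05d", seq_len(U))

    sizes <- resolve_sizes(config)
    planted <- resolve_planted_pairs(config, sizes)
    bias <- rep(config$enhancer_bias, length.out = n)

    # --- plant reference-line regulons with exact pairwise overlaps ---
    affected <- replicate(n, integer(0), simplify = FALSE)
    partners <- replicate(n, integer(0), simplify = FALSE)
    for (p in planted) {
      pool <- setdiff(seq_len(U), union(affected[[p$a]], affected[[p$b]]))
      if (length(pool) < p$shared)
        stopf("universe too small for planted overlaps")
      s <- safe_sample(pool, p$shared)
      affected[[p$a]] <- c(affected[[p$a]], s)
      affected[[p$b]] <- c(affected[[p$b]], s)
      partners[[p$a]] <- union(partners[[p$a]], p$b)
      partners[[p$b]] <- union(partners[[p$b]], p$a)
    }
    for (i in seq_len(n)) {
      if (length(affected[[i]]) > sizes[i])
        stopf("planted overlaps exceed regulon size for %s", rbps[i])
      need <- sizes[i] - length(affected[[i]])
      if (need > 0L) {
        # avoid incidental overlap with planted partners so their
        # pairwise intersections stay exactly as planted
        excl <- unique(c(affected[[i]], unlist(affected[partners[[i]]])))
        pool <- setdiff(seq_len(U), excl)
        if (length(pool) < need) stopf("universe too small to pad %s", rbps[i])
        affected[[i]] <- c(affected[[i]], safe_sample(pool, need))
      }
      affected[[i]] <- sort(affected[[i]])
    }

    # derived lines: keep a fraction of each reference regulon, resample
    # the rest (still avoiding planted-partner collisions is not needed
    # off-reference; overlap there is incidental by design)
    lines <- names(config$cell_lines)
    affected_by_line <- list()
    affected_by_line[[lines[1]]] <- affected
    if (length(lines) > 1L) for (li in 2:length(lines)) {
      f <- config$cell_lines[li]
      aff <- lapply(seq_len(n), function(i) {
        keep_n <- round(f * sizes[i])
        keep <- if (keep_n > 0) safe_sample(affected[[i]], keep_n) else integer(0)
        pool <- setdiff(seq_len(U), affected[[i]])
        fresh <- safe_sample(pool, sizes[i] - keep_n)
        sort(c(keep, fresh))
      })
      affected_by_line[[lines[li]]] <- aff
    }

    # --- per-line signs, magnitudes, PSI, and record tables ---
    dshape <- config$delta_psi_shape
    tables_by_line <- list()
    truth_lines <- list()
    mult1 <- NULL
    for (line in lines) {
      aff <- affected_by_line[[line]]
      long <- data.frame(
        rbp = rep(seq_len(n), lengths(aff)),
        exon = unlist(aff)
      )
      long$decrease <- stats::runif(nrow(long)) < bias[long$rbp]
      mag <- 0.15 + 0.85 * stats::rbeta(nrow(long), dshape[1], dshape[2])
      mag <- pmin(mag, 0.98)

      count <- tabulate(long$exon, nbins = U)
      n_dec <- tabulate(long$exon[long$decrease], nbins = U)
      both_dir <- n_dec > 0L & (count - n_dec) > 0L
      mag[both_dir[long$exon]] <- pmin(mag[both_dir[long$exon]], 0.49)
      long$mag <- mag

      max_dec <- rep(0, U); max_inc <- rep(0, U)
      dec_rows <- long[long$decrease, ]; inc_rows <- long[!long$decrease, ]
      if (nrow(dec_rows)) {
        agg <- tapply(dec_rows$mag, dec_rows$exon, max)
        max_dec[as.integer(names(agg))] <- agg
      }
      if (nrow(inc_rows)) {
        agg <- tapply(inc_rows$mag, inc_rows$exon, max)
        max_inc[as.integer(names(agg))] <- agg
      }
      lo <- pmin(max_dec + 0.005, 0.995)
      hi <- pmax(1 - max_inc - 0.005, lo + 0.001)
      w_full <- config$psi_intermediate_full_at
      w_int <- config$psi_intermediate_weight_max *
        pmin(1, pmax(0, (count - 1) / max(1, w_full - 1)))
      psi_control <- sample_psi_control(w_int, lo, hi)

      tables <- vector("list", n)
      for (i in seq_len(n)) {
        # background: small, headroom-respecting |dPSI| <= 0.149
        d_lo <- pmax(-0.149, -psi_control)
        d_hi <- pmin(0.149, 1 - psi_control)
        delta <- stats::runif(U, d_lo, d_hi)
        fdr <- stats::runif(U, 0.051, 1)
        sub <- long[long$rbp == i, ]
        delta[sub$exon] <- ifelse(sub$decrease, -sub$mag, sub$mag)
        fdr[sub$exon] <- stats::runif(nrow(sub), 0, 0.05)
        psi_kd <- pmin(pmax(psi_control + delta, 0), 1)
        rec <- tibble::tibble(
          gene_id = gene_id, gene_symbol = gene_symbol,
          chrom = chroms, strand = strand,
          exon_start = exon_start, exon_end = exon_end,
          upstream_exon_start = exon_start - 2000L,
          upstream_exon_end = exon_start - 1800L,
          downstream_exon_start = exon_end + 1800L,
          downstream_exon_end = exon_end + 2000L,
          psi_control = psi_control, psi_knockdown = psi_kd,
          delta_psi = delta, fdr = fdr
        )
        tables[[i]] <- knockdown_table(rbps[i], rec, cell_line = line,
                                       rbp_family = families[i])
      }
      names(tables) <- rbps
      tables_by_line[[line]] <- tables
      dir_by_rbp <- lapply(seq_len(n), function(i) {
        sub <- long[long$rbp == i, ]
        stats::setNames(ifelse(sub$decrease, "decrease", "increase"),
                        keys[sub$exon])
      })
      names(dir_by_rbp) <- rbps
      truth_lines[[line]] <- list(
        affected = stats::setNames(lapply(aff, function(ix) keys[ix]), rbps),
        directions = dir_by_rbp,
        multiplicity = tibble::tibble(key = keys[count > 0],
                                      count = count[count > 0])
      )
      if (line == lines[1]) mult1 <- count
    }

    # --- features, with planted trends against reference multiplicity ---
    fm <- config$feature_model
    fgen <- function(f, minimum = -Inf, integer = FALSE) {
      p <- fm[[f]]
      x <- p[["intercept"]] + p[["slope"]] * mult1 +
        stats::rnorm(U, 0, p[["noise_sd"]])
      x <- pmax(x, minimum)
      if (integer) as.integer(round(x)) else x
    }
    features <- tibble::tibble(
      key = keys,
      exon_length = fgen("exon_length", 20, TRUE),
      upstream_intron_length = fgen("upstream_intron_length", 80, TRUE),
      downstream_intron_length = fgen("downstream_intron_length", 80, TRUE),
      ss5_score = fgen("ss5_score"),
      ss3_score = fgen("ss3_score"),
      phylop = fgen("phylop")
    )

    planted_tbl <- if (length(planted))
      tibble::tibble(rbp_a = rbps[vapply(planted, `[[`, 1L, "a")],
                     rbp_b = rbps[vapply(planted, `[[`, 1L, "b")],
                     shared = vapply(planted, `[[`, 1L, "shared"))
    else tibble::tibble(rbp_a = character(), rbp_b = character(),
                        shared = integer())

    structure(list(
      tables_by_line = tables_by_line,
      features = features,
      truth = list(lines = truth_lines, planted_pairs = planted_tbl,
                   regulon_sizes = stats::setNames(sizes, rbps),
                   enhancer_bias = stats::setNames(bias, rbps),
                   feature_model = fm,
                   universe_keys = keys),
      config = config
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d RBPs x %d cell line(s), universe %d exons\n",
              x$config$n_rbps, length(x$tables_by_line),
              x$config$universe_size))
  invisible(x)
}

#' Filter a synthetic dataset into regulons
#'
#' Convenience wrapper: deduplicates and filters every knockdown table of
#' one cell line.
#'
#' @param dataset a `synthetic_dataset`.
#' @param policy a `filter_policy` (default HeLa-style).
#' @param line cell line label (default: the reference line).
#' @return named list of `regulon`s.
#' @export
synthetic_regulons <- function(dataset, policy = hela_policy(), line = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  line <- line %||% names(dataset$tables_by_line)[1]
  lapply(dataset$tables_by_line[[line]],
         function(tb) apply_filter(deduplicate(tb), policy))
}

#' Write a synthetic dataset to disk
#'
#' Writes one canonical TSV per RBP per cell line, the feature table, and
#' the ground truth as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (line in names(dataset$tables_by_line)) {
    ld <- file.path(dir, line)
    dir.create(ld, showWarnings = FALSE)
    for (tb in dataset$tables_by_line[[line]])
      write_knockdown_table(tb, file.path(ld, paste0(tb$rbp_name, ".tsv")))
  }
  write_feature_table(dataset$features, file.path(dir, "features.tsv"))
  truth <- dataset$truth
  truth$lines <- lapply(truth$lines, function(tl)
    list(affected = tl$affected,
         directions = lapply(tl$directions, as.list),
         multiplicity = tl$multiplicity))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Null datasets for calibration
#'
#' Draws regulon collections with the marginal regulon sizes of a config
#' but no planted structure: each RBP's affected set is an independent
#' uniform draw from the universe, so any overlap arises by chance. These
#' lightweight regulons are intended for calibrating the pair test, not
#' for table-level I/O.
#'
#' @param config a `synthetic_config`.
#' @param n_replicates number of independent null datasets.
#' @return list of length `n_replicates`; each element a named list of
#'   `regulon`s sharing one universe.
#' @export
null_resample <- function(config, n_replicates) {
  validate_synthetic_config(config)
  with_fixed_rng(config$seed, {
    U <- config$universe_size
    keys <- sprintf("chrS1:+:%d:%d", 10000L + (seq_len(U) - 1L) * 1000L,
                    10000L + (seq_len(U) - 1L) * 1000L + 100L)
    sizes <- resolve_sizes(config)
    rbps <- rbp_names_for(config$n_rbps)
    pol <- hela_policy()
    lapply(seq_len(n_replicates), function(rep) {
      regs <- lapply(seq_len(config$n_rbps), function(i) {
        aff <- if (sizes[i] > 0) sort(safe_sample(keys, sizes[i])) else character(0)
        structure(list(
          rbp_name = rbps[i], rbp_family = "other", cell_line = "null",
          policy = pol, affected = aff,
          directions = stats::setNames(rep("decrease", length(aff)), aff),
          delta_psi = stats::setNames(rep(-0.5, length(aff)), aff),
          psi_control = stats::setNames(rep(0.5, length(aff)), aff),
          fdr = stats::setNames(rep(0.01, length(aff)), aff),
          universe = keys, n_dropped_missing_dpsi = 0L
        ), class = "regulon")
      })
      names(regs) <- rbps
      regs
    })
  })
}
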