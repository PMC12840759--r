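# In-code fixtures: small knockdown tables built on a shared toy universe
# of exons chr1:+:1000i-1000i+100, i = 1..n.

toy_key <- function(i) exon_key("chr1", "+", 1000L * i, 1000L * i + 100L)

toy_records <- function(n, psi_control = 0.5) {
  i <- seq_len(n)
  tibble::tibble(
    gene_id = sprintf("G%04d", i),
    gene_symbol = sprintf("Gene%04d", i),
    chrom = "chr1", strand = "+",
    exon_start = 1000L * i, exon_end = 1000L * i + 100L,
    upstream_exon_start = 1000L * i - 500L,
    upstream_exon_end = 1000L * i - 400L,
    downstream_exon_start = 1000L * i + 400L,
    downstream_exon_end = 1000L * i + 500L,
    psi_control = psi_control,
    psi_knockdown = psi_control + 0.01,
    delta_psi = 0.01,
    fdr = 0.5
  )
}

# A table over `universe_n` exons in which exons `affected` carry
# delta PSI `dpsi` (recycled, signed) and FDR 0.01; everything else is
# sub-threshold background.
toy_table <- function(rbp, affected = integer(0), universe_n = 20,
                      dpsi = 0.5, cell_line = "toy") {
  rec <- toy_records(universe_n)
  if (length(affected) > 0) {
    d <- rep_len(dpsi, length(affected))
    rec$delta_psi[affected] <- d
    rec$psi_knockdown[affected] <- pmin(pmax(0.5 + d, 0), 1)
    rec$fdr[affected] <- 0.01
  }
  knockdown_table(rbp, rec, cell_line = cell_line)
}

toy_regulon <- function(rbp, affected = integer(0), universe_n = 20,
                        dpsi = 0.5, policy = hela_policy(),
                        cell_line = "toy") {
  apply_filter(deduplicate(toy_table(rbp, affected, universe_n, dpsi,
                                     cell_line)), policy)
}

# Independent closed-form oracle for the hypergeometric upper tail:
# direct binomial-coefficient arithmetic, no logs.
sf_oracle <- function(m, N, M, n) {
  if (m <= 0) return(1)
  hi <- min(M, n)
  if (m > hi) return(0)
  i <- m:hi
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Brute-force oracle: enumerate every size-n subset of 1:N and count how
# often its overlap with {1..M} reaches m. Only feasible for small N.
sf_enumerate <- function(m, N, M, n) {
  if (n == 0) return(as.numeric(m <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= m)
}
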