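# shared fixture builders and independent oracles

# methylome tibble from parallel vectors (defaults: CpG, plus strand)
mk_methylome <- function(pos, meth, unmeth, chrom = "chr1", strand = "+",
                         context = "CpG", name = NULL) {
  as_methylome(tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context = context, meth = as.integer(meth), unmeth = as.integer(unmeth)
  ), name = name)
}

# brute-force membership of 1-based positions in BED half-open intervals
brute_sites_in_intervals <- function(sites, intervals) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(intervals$chrom == sites$chrom[i] &
          intervals$start < sites$pos[i] &
          sites$pos[i] <= intervals$end)
  }, logical(1))
}

# brute-force TOM by explicit triple loop
brute_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

# two planted co-methylation blocks across n_samp methylomes, levels in [0,1]
mk_block_matrix <- function(seed, n_per = 100, n_samp = 20, rho = 0.9) {
  set.seed(seed)
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  rows <- rbind(
    t(vapply(seq_len(n_per),
             function(i) sqrt(rho) * f1 + sqrt(1 - rho) * rnorm(n_samp),
             numeric(n_samp))),
    t(vapply(seq_len(n_per),
             function(i) sqrt(rho) * f2 + sqrt(1 - rho) * rnorm(n_samp),
             numeric(n_samp)))
  )
  m <- pnorm(rows)
  rownames(m) <- paste0("chr1:", seq_len(nrow(m)) * 1000L, "-",
                        seq_len(nrow(m)) * 1000L + 200L)
  colnames(m) <- paste0("s", seq_len(n_samp))
  m
}

# a MEF2-like 9-bp PWM and a GC-rich decoy
mk_mef2_pwm <- function() {
  new_pwm("MEF2A", matrix(c(8, 0, 90, 2, 2, 2, 2, 94, 90, 2, 4, 4,
                            80, 2, 2, 16, 85, 1, 1, 13, 88, 2, 2, 8,
                            2, 2, 2, 94, 2, 2, 94, 2, 40, 20, 20, 20),
                          nrow = 4))
}

mk_decoy_pwm <- function() {
  G <- c(2, 2, 94, 2); C <- c(2, 94, 2, 2)
  new_pwm("EGR1", matrix(c(G, C, G, G, C, G, C, C), nrow = 4))
}

# random ACGT sequences
rand_seqs <- function(n, len, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n),
           function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
           character(1))
  })
}

# recall/precision of called DMRs against truth intervals by overlap
dmr_overlap_stats <- function(dmrs, truth) {
  recall <- if (nrow(truth) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(truth)), function(i) {
      any(dmrs$chrom == truth$chrom[i] & dmrs$start < truth$end[i] &
            dmrs$end > truth$start[i])
    }, logical(1)))
  }
  precision <- if (nrow(dmrs) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(dmrs)), function(i) {
      any(truth$chrom == dmrs$chrom[i] & truth$start < dmrs$end[i] &
            truth$end > dmrs$start[i])
    }, logical(1)))
  }
  list(recall = recall, precision = precision)
}

# adjusted Rand index (agreement of two partitions corrected for chance)
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_a <- b * cc / n2
  max_a <- (b + cc) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

# deterministic mini-panel: high-coverage counts so pairwise significance is
# certain, exercising the >= 75% of pairwise comparisons rule exactly
mk_boundary_panel <- function(n_bg = 30) {
  pos_bg <- seq(1000L, by = 100L, length.out = n_bg)
  base <- function(extra_meth, extra_unmeth) {
    mk_methylome(pos = c(pos_bg, 10L),
                 meth = c(rep(50L, n_bg), extra_meth),
                 unmeth = c(rep(50L, n_bg), extra_unmeth))
  }
  list(
    tt = base(100L, 0L),   # focal type: fully methylated at site 10
    o1 = base(0L, 100L),
    o2 = base(0L, 100L),
    o3 = base(0L, 100L),
    o4 = base(100L, 0L)    # matches the focal type: comparison not significant
  )
}

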