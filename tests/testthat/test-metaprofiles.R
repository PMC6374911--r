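mk_anchor_row <- function(start, end, strand = ".") {
  tibble::tibble(chrom = "chr1", start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

test_that("a constant methylome gives a flat anchored profile with zero SEM", {
  pos <- seq(1000L, 99000L, by = 100L)
  m <- mk_methylome(pos, meth = rep(7L, length(pos)), unmeth = rep(3L, length(pos)))
  anchors <- mk_anchor_row(seq(10000, 90000, by = 10000),
                           seq(10000, 90000, by = 10000) + 1000)
  pc <- anchored_methylation_profile(m, anchors, flank = 5000, n_bins = 20,
                                     min_cov = 5)
  expect_true(all(abs(pc$mean[pc$n_sites > 0] - 0.7) < 1e-12))
  expect_true(all(pc$sem[pc$n_sites > 1] < 1e-12))
  # empty bins carry an undefined mean and zero count
  m2 <- mk_methylome(10000L, 7L, 3L)
  pc2 <- anchored_methylation_profile(m2, mk_anchor_row(9000, 11000),
                                      flank = 5000, n_bins = 10)
  expect_true(any(is.na(pc2$mean) & pc2$n_sites == 0))
  expect_error(anchored_methylation_profile(m, anchors[0, ]), "empty")
})

test_that("a planted hypomethylation dip appears at the anchor centre", {
  cfg <- sim_config(seed = 51, chrom_length = 2e5)
  g <- simulate_genome(cfg)
  anchors <- mk_anchor_row(seq(10000, 180000, by = 20000),
                           seq(10000, 180000, by = 20000) + 1000)
  lv <- ifelse(sites_in_intervals(g$cpg_map, anchors), 0.2, 0.8)
  m <- merge_symmetric_cpg(simulate_methylome(g$cpg_map, lv, 30, seed = 2))
  pc <- anchored_methylation_profile(m, anchors, flank = 5000, n_bins = 20,
                                     min_cov = 5)
  center <- mean(pc$mean[abs(pc$offset_mid) < 500], na.rm = TRUE)
  edge <- mean(pc$mean[abs(pc$offset_mid) > 4000], na.rm = TRUE)
  expect_lt(center, 0.3)
  expect_gt(edge, 0.7)
})

test_that("per-bin SEM matches a brute-force recomputation", {
  withr::with_seed(52, {
    pos <- sort(sample(1000:20000, 200))
    meth <- rbinom(200, 20, 0.5)
    m <- mk_methylome(pos, meth, 20L - meth)
    anchors <- mk_anchor_row(c(5000, 12000), c(5400, 12400))
    pc <- anchored_methylation_profile(m, anchors, flank = 2000, n_bins = 8,
                                       min_cov = 1)
    centers <- floor((anchors$start + anchors$end) / 2)
    edges <- seq(-2000, 2000, length.out = 9)
    for (b in which(pc$n_sites > 1)) {
      lv <- c()
      for (i in seq_along(pos)) {
        for (ctr in centers) {
          off <- (pos[i] - 1) - ctr
          hit <- off >= edges[b] &&
            (off < edges[b + 1] || (b == 8 && off == edges[9]))
          if (hit) lv <- c(lv, meth[i] / 20)
        }
      }
      expect_equal(pc$n_sites[b], length(lv))
      expect_equal(pc$sem[b], sd(lv) / sqrt(length(lv)), tolerance = 1e-10)
    }
  })
})

test_that("anchored profiles are additive over disjoint anchor sets", {
  cfg <- sim_config(seed = 53, chrom_length = 1e5)
  g <- simulate_genome(cfg)
  m <- merge_symmetric_cpg(simulate_methylome(
    g$cpg_map, methdyn:::draw_baseline_levels(nrow(g$cpg_map), cfg), seed = 3))
  a1 <- mk_anchor_row(c(20000, 40000), c(20400, 40400))
  a2 <- mk_anchor_row(c(60000, 80000), c(60400, 80400))
  p1 <- anchored_methylation_profile(m, a1, flank = 3000, n_bins = 10)
  p2 <- anchored_methylation_profile(m, a2, flank = 3000, n_bins = 10)
  pu <- anchored_methylation_profile(m, dplyr::bind_rows(a1, a2),
                                     flank = 3000, n_bins = 10)
  expect_equal(pu$n_sites, p1$n_sites + p2$n_sites)
  s1 <- ifelse(p1$n_sites > 0, p1$mean * p1$n_sites, 0)
  s2 <- ifelse(p2$n_sites > 0, p2$mean * p2$n_sites, 0)
  su <- ifelse(pu$n_sites > 0, pu$mean * pu$n_sites, 0)
  expect_equal(su, s1 + s2, tolerance = 1e-10)
})

test_that("DMS frequency curves normalise to ~1 under a uniform scatter", {
  cfg <- sim_config(seed = 54, chrom_length = 4e6)
  g <- simulate_genome(cfg)
  anchors <- mk_anchor_row(seq(5000, 3985000, by = 10000),
                           seq(5000, 3985000, by = 10000) + 500)
  tested <- g$cpg_map
  for (seed in 1:3) {
    withr::with_seed(seed, {
      dms <- tested[sample.int(nrow(tested), round(0.1 * nrow(tested))), ]
    })
    fc <- dms_frequency_profile(dms, tested, anchors, flank = 5000, n_bins = 20)
    busy <- fc$n_tested >= 200
    expect_gt(sum(busy), 0)
    expect_true(all(fc$normalized[busy] >= 0.8 & fc$normalized[busy] <= 1.2))
  }
  # DMSs concentrated at anchor centres dominate the centre bins
  ctr <- sites_in_intervals(tested, anchors)
  fc2 <- dms_frequency_profile(tested[ctr, ], tested, anchors,
                               flank = 5000, n_bins = 20)
  expect_gt(max(fc2$normalized, na.rm = TRUE), 3)
  expect_lt(min(fc2$normalized[fc2$n_tested > 50], na.rm = TRUE), 1)
  expect_error(dms_frequency_profile(tested[0, ], tested, anchors), "DMS")
})

test_that("gene-scaled profiles are strand-oriented and flat for constant input", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
    tss = c(20000L, 90000L), tes = c(30000L, 80000L), exons = list(NULL, NULL)
  )
  pos <- seq(1000L, 99000L, by = 50L)
  m <- mk_methylome(pos, rep(7L, length(pos)), rep(3L, length(pos)))
  pc <- scaled_gene_profile(m, genes, context = "CpG", flank = 10000,
                            body_bins = 10, flank_bins = 5)
  expect_true(all(abs(pc$mean[pc$n_sites > 0] - 0.7) < 1e-12))

  # methylation rising from TSS to TES must rise in transcription order
  # for both strands once oriented
  lv_plus <- pmin(1, pmax(0, (pos - 20000) / 10000))
  lv_minus <- pmin(1, pmax(0, (90000 - pos) / 10000))
  m_grad <- function(lv) {
    meth <- round(lv * 20)
    mk_methylome(pos, as.integer(meth), as.integer(20 - meth))
  }
  for (gid in c("gp", "gm")) {
    lv <- if (gid == "gp") lv_plus else lv_minus
    pg <- scaled_gene_profile(m_grad(lv), genes[genes$gene_id == gid, ],
                              context = "CpG", flank = 5000,
                              body_bins = 10, flank_bins = 2)
    body <- pg[pg$region == "body", ]
    expect_gt(body$mean[body$bin == max(body$bin)],
              body$mean[body$bin == min(body$bin)])
  }
})

test_that("CH-context profiles pick up a planted TES-proximal signal", {
  withr::with_seed(55, {
    genes <- tibble::tibble(gene_id = c("hi", "lo"), chrom = "chr1",
                            strand = "+", tss = c(20000L, 60000L),
                            tes = c(30000L, 70000L), exons = list(NULL, NULL))
    pos <- seq(15000L, 75000L, by = 25L)
    near_hi_tes <- pos > 27000 & pos <= 30000
    lv <- ifelse(near_hi_tes, 0.30, 0.02)
    meth <- rbinom(length(pos), 30, lv)
    m <- mk_methylome(pos, meth, 30L - meth, context = "CHH")
    groups <- c(hi = "high", lo = "low")
    pg <- scaled_gene_profile(m, genes, context = "CH", flank = 2000,
                              body_bins = 10, flank_bins = 2, groups = groups)
    tes_bin <- pg[pg$region == "body" & pg$bin == 12, ]
    expect_gt(tes_bin$mean[tes_bin$group == "high"],
              tes_bin$mean[tes_bin$group == "low"] + 0.1)
  })
})

test_that("expression grouping follows the tercile and remainder rules", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:350),
                         tpm = c(rep(0, 50), seq(1, 300)))
  eg <- expression_groups(expr)
  expect_equal(as.vector(table(eg$group)), c(50, 100, 100, 100))
  # 301 expressed genes: remainder goes to the low tercile
  expr2 <- tibble::tibble(gene_id = paste0("g", 1:301), tpm = seq(1, 301))
  expect_equal(as.vector(table(expression_groups(expr2)$group)),
               c(0, 101, 100, 100))
  # groups are ordered by expression
  agg <- dplyr::summarise(dplyr::group_by(eg[eg$group != "none", ], group),
                          m = mean(tpm), .groups = "drop")
  expect_true(all(diff(agg$m[match(c("low", "mid", "high"), agg$group)]) > 0))
  expect_true(all(expression_groups(
    tibble::tibble(gene_id = "g", tpm = 0))$group == "none"))
})

test_that("fold-change filtering keeps the boundary and drops null genes", {
  expr <- tibble::tibble(gene_id = c("up", "flat", "zero", "down"),
                         a = c(10, 8, 0, 30), b = c(15, 8, 0, 10))
  # the 1.5x boundary is inclusive (no pseudocount)
  expect_setequal(fold_change_filter(expr, pseudocount = 0),
                  c("up", "down"))
  # with the default pseudocount the boundary case moves below threshold
  expect_setequal(fold_change_filter(expr), "down")
})
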