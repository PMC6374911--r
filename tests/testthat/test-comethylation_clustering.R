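mk_panel_for_matrix <- function(seed = 61) {
  # three methylomes over a shared set of CpGs, one with a masked site
  pos <- c(1000L, 1120L, 5000L, 30000L, 52000L)
  withr::with_seed(seed, {
    panel <- lapply(1:3, function(i) {
      meth <- rbinom(length(pos), 30, c(0.9, 0.85, 0.2, 0.5, 0.7))
      mk_methylome(pos, meth, 30L - meth, name = paste0("m", i))
    })
  })
  names(panel) <- paste0("m", 1:3)
  # site 52000 missing in methylome 3
  panel$m3$meth[panel$m3$pos == 52000] <- 0L
  panel$m3$unmeth[panel$m3$pos == 52000] <- 0L
  panel
}

test_that("DMS matrix preprocessing filters, merges and logs provenance", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          tss = 12000L, tes = 60000L, exons = list(NULL))
  dms <- tibble::tibble(chrom = "chr1",
                        pos = c(1000L, 1120L, 5000L, 30000L, 52000L))
  panel <- mk_panel_for_matrix()
  # 1000/1120 are ~11 kb upstream of the TSS: removed by the window filter;
  # 52000 is missing in one methylome: dropped by the completeness filter
  dm <- preprocess_dms_matrix(dms, genes, panel, merge_gap = 200)
  expect_equal(dm$provenance$n_loci, c(5L, 3L, 3L, 2L))
  expect_setequal(dm$loci$start, c(4999L, 29999L))
  expect_true(all(!is.na(dm$levels)))

  # two DMSs 150 bp apart merge into one coverage-weighted locus
  genes2 <- tibble::tibble(gene_id = "g2", chrom = "chr1", strand = "+",
                           tss = 500L, tes = 60000L, exons = list(NULL))
  dm2 <- preprocess_dms_matrix(dms, genes2, panel, merge_gap = 200)
  merged <- dm2$loci[dm2$loci$start == 999L, ]
  expect_equal(merged$end, 1120L)
  m1 <- panel$m1[panel$m1$pos %in% c(1000L, 1120L), ]
  expect_equal(dm2$levels[merged$locus, "m1"],
               sum(m1$meth) / sum(m1$meth + m1$unmeth))
  expect_error(preprocess_dms_matrix(dms[dms$pos == 1000, ], genes, panel),
               "gene-window")
})

test_that("adjacency is the soft-thresholded absolute correlation", {
  m <- rbind(a = c(0.1, 0.5, 0.9, 0.3), b = c(0.1, 0.5, 0.9, 0.3),
             c = c(0.9, 0.5, 0.1, 0.7))
  a <- correlation_adjacency(m, power = 6)
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 1)  # perfectly anticorrelated, unsigned network
  m2 <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  a2 <- correlation_adjacency(m2, power = 6)
  expect_equal(a2["x", "y"], abs(cor(c(1, 2, 3, 4), c(1, 3, 2, 4)))^6)
  # the documented reference point: correlation 0.5 at power 6
  expect_equal(0.5^6, 0.015625)
  m3 <- rbind(const = rep(0.5, 4), v = c(0.1, 0.2, 0.3, 0.4))
  expect_error(correlation_adjacency(m3), "constant")
})

test_that("topological overlap matches its definition and the brute force", {
  # two nodes: no shared neighbours, TOM reduces to the adjacency
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.3)
  # complete unit graph: TOM is 1 everywhere
  a1 <- matrix(1, 5, 5)
  expect_true(all(abs(topological_overlap(a1) - 1) < 1e-12))
  # random instances up to 30 nodes against the triple loop
  withr::with_seed(62, {
    for (n in c(5, 12, 20, 30)) {
      a <- abs(cor(matrix(rnorm(n * 10), 10, n)))^6
      diag(a) <- 1
      expect_lt(max(abs(topological_overlap(a) - brute_tom(a))), 1e-10)
    }
  })
})

test_that("planted blocks are recovered and noise stays unassigned", {
  m <- mk_block_matrix(seed = 63)
  adj <- correlation_adjacency(m)
  asg <- detect_modules(topological_overlap(adj), m)
  expect_equal(length(asg$sizes), 2)
  expect_gte(ari(asg$assignment$module, rep(1:2, each = 100)), 0.8)
  # eigen-profiles are unit vectors explaining the top variance share
  withr::with_seed(64, {
    for (mm in 1:2) {
      v <- asg$eigen[, mm]
      expect_equal(sum(v^2), 1, tolerance = 1e-10)
      idx <- asg$assignment$module == mm
      xs <- t(scale(t(m[idx, ])))
      var_eigen <- sum((xs %*% v)^2)
      for (probe in 1:100) {
        r <- rnorm(ncol(m)); r <- r / sqrt(sum(r^2))
        expect_lte(sum((xs %*% r)^2), var_eigen + 1e-8)
      }
    }
  })
  # pure noise: everything unassigned at the default parameters
  withr::with_seed(65, {
    noise <- pnorm(matrix(rnorm(200 * 20), 200, 20))
  })
  rownames(noise) <- rownames(m)
  asg0 <- detect_modules(topological_overlap(correlation_adjacency(noise)), noise)
  expect_equal(length(asg0$sizes), 0)
  expect_true(all(asg0$assignment$module == 0L))
  # fewer rows than the minimum module size: warn, all label 0
  small <- m[1:10, ]
  expect_warning(
    asg_s <- detect_modules(topological_overlap(correlation_adjacency(small)),
                            small),
    "min_module_size")
  expect_true(all(asg_s$assignment$module == 0L))
})

test_that("module merging joins correlated eigen-profiles and never splits", {
  m <- mk_block_matrix(seed = 66)
  # duplicate block 1 as a third block with the same underlying profile
  m3 <- rbind(m, m[1:50, ] + matrix(rnorm(50 * 20, sd = 0.01), 50))
  m3 <- pmin(pmax(m3, 0), 1)
  rownames(m3) <- paste0("chr1:", seq_len(nrow(m3)) * 1000L, "-",
                         seq_len(nrow(m3)) * 1000L + 200L)
  fake <- tibble::tibble(locus = rownames(m3),
                         module = c(rep(1L, 100), rep(2L, 100), rep(3L, 50)))
  asg <- methdyn:::new_module_assignment(fake, m3)
  merged <- merge_close_modules(asg, m3, merge_corr = 0.75)
  expect_equal(length(merged$sizes), 2)          # 1 and 3 collapse
  expect_equal(sort(unname(merged$sizes)), c(100, 150))
  expect_lte(length(merged$sizes), length(asg$sizes))
  # uncorrelated modules stay apart
  asg2 <- methdyn:::new_module_assignment(
    tibble::tibble(locus = rownames(m), module = rep(1:2, each = 100)), m)
  expect_equal(length(merge_close_modules(asg2, m)$sizes), 2)
})

test_that("the blockwise pipeline is deterministic and matches single-block", {
  m <- mk_block_matrix(seed = 67)
  a1 <- comethylation_modules(m)
  a2 <- comethylation_modules(m)
  expect_identical(a1$assignment, a2$assignment)
  ab <- comethylation_modules(m, max_block = 80)
  expect_gte(ari(ab$assignment$module, a1$assignment$module), 0.8)
})

test_that("module summaries are tidy, bounded and exact for uniform modules", {
  m <- matrix(rep(c(0.2, 0.4, 0.9), each = 40), nrow = 40)
  rownames(m) <- paste0("chr1:", 1:40 * 100, "-", 1:40 * 100 + 50)
  colnames(m) <- c("s1", "s2", "s3")
  asg <- methdyn:::new_module_assignment(
    tibble::tibble(locus = rownames(m), module = 1L), m)
  sm <- module_profile_summary(asg, m)
  expect_equal(sm$mean, c(0.2, 0.4, 0.9))
  expect_equal(sm$sd, rep(0, 3))
  expect_true(all(sm$mean >= 0 & sm$mean <= 1))
  expect_s3_class(tidy(asg), "tbl_df")
  expect_equal(glance(asg)$n_modules, 1L)
})
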