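test_that("cytosine report parsing, filtering and validation work", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t100\t+\t7\t3\tCpG\tCGG",
               "chr1\t150\t+\t2\t2\tCHH\tCAT",
               "chr1\t200\t-\t0\t5\tCpG\tCGA"), f)
  m <- read_cytosine_report(f, context_filter = "CpG")
  expect_equal(nrow(m), 2)
  expect_equal(methylation_level(m)[m$pos == 100], 0.7)
  mh <- read_cytosine_report(f, context_filter = "CHH")
  expect_equal(mh$context, "CHH")

  # unsorted within chromosome names the offending line
  writeLines(c("chr1\t200\t+\t1\t1\tCpG\tCGG",
               "chr1\t100\t+\t1\t1\tCpG\tCGG"), f)
  expect_error(read_cytosine_report(f), "line 2")
  # negative counts rejected
  writeLines("chr1\t100\t+\t-1\t3\tCpG\tCGG", f)
  expect_error(read_cytosine_report(f), "negative|malformed")
  # malformed strand reported
  writeLines("chr1\t100\t*\t1\t3\tCpG\tCGG", f)
  expect_error(read_cytosine_report(f), "malformed")
})

test_that("cytosine report round-trips through write and read", {
  cfg <- sim_config(seed = 42, chrom_length = 2e4)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g$cpg_map, rep(0.5, nrow(g$cpg_map)), seed = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_cytosine_report(m, f)
  m2 <- read_cytosine_report(f)
  expect_equal(as.data.frame(m2), as.data.frame(m), ignore_attr = TRUE)
})

test_that("symmetric CpG dyads collapse onto the plus strand", {
  m <- mk_methylome(pos = c(100, 101, 300),
                    meth = c(3, 2, 4), unmeth = c(1, 2, 0),
                    strand = c("+", "-", "+"))
  out <- merge_symmetric_cpg(m)
  expect_equal(nrow(out), 2)
  merged <- out[out$pos == 100, ]
  expect_equal(merged$meth, 5L)
  expect_equal(merged$unmeth, 3L)
  expect_equal(merged$strand, "+")
  # plus-only site unchanged
  expect_equal(out[out$pos == 300, ]$meth, 4L)
  # unpaired minus site passes through; CH contexts untouched
  m2 <- mk_methylome(pos = c(51, 60), meth = c(1, 2), unmeth = c(1, 0),
                     strand = c("-", "-"), context = c("CpG", "CHH"))
  out2 <- merge_symmetric_cpg(m2)
  expect_equal(nrow(out2), 2)
  expect_setequal(out2$strand, "-")
  # empty methylome stays empty
  empty <- mk_methylome(integer(0), integer(0), integer(0))
  expect_equal(nrow(merge_symmetric_cpg(empty)), 0)
})

test_that("BED reading validates and round-trips with labels", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tCGI", f)
  iv <- read_bed(f)
  expect_equal(iv$start, 0L)
  expect_equal(iv$end, 100L)
  expect_equal(iv$label, "CGI")
  writeLines("chr1\t100\t100\tbad", f)
  expect_error(read_bed(f), "line 1")

  x <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0L, 50L),
                      end = c(10L, 800L), label = c("Con", "Inc"),
                      score = c(1, 2), strand = c("+", "."))
  write_bed(x, f)
  expect_equal(as.data.frame(read_bed(f)), as.data.frame(x))
})

test_that("enhancer class counts survive a BED round trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  x <- tibble::tibble(chrom = "chr1",
                      start = seq(0L, by = 1000L, length.out = 800L),
                      end = seq(500L, by = 1000L, length.out = 800L),
                      label = "Con")
  write_bed(x, f)
  iv <- read_bed(f)
  expect_equal(sum(iv$label == "Con"), 800L)
})

test_that("gene models store TSS/TES in transcription order", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tgplus\t0\t+\t999\t2000\t0\t2\t100,200\t0,801", f)
  f6 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t4999\t6000\tgminus\t0\t-", f6)
  gn <- dplyr::bind_rows(read_gene_models(f), read_gene_models(f6))
  gp <- gn[gn$gene_id == "gplus", ]
  gm <- gn[gn$gene_id == "gminus", ]
  expect_equal(gp$tss, 1000L); expect_equal(gp$tes, 2000L)
  expect_equal(gm$tss, 6000L); expect_equal(gm$tes, 5000L)  # minus: tss > tes
  expect_equal(gp$exons[[1]]$start, c(999L, 1800L))
  sp <- gene_span(gn)
  expect_equal(sp$start, c(999L, 4999L))
  expect_equal(sp$end, c(2000L, 6000L))

  g <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr2\tsrc\tgene\t500\t900\t.\t-\t.\tgene_id \"gx\";",
               "chr2\tsrc\texon\t500\t600\t.\t-\t.\tgene_id \"gx\";"), g)
  gg <- read_gene_models(g)
  expect_equal(gg$gene_id, "gx")
  expect_equal(gg$tss, 900L)
  expect_equal(gg$tes, 500L)
})

test_that("JASPAR PFMs parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TEST",
               "A [ 0  3 79 40 66 48 65 11 ]",
               "C [94 75  4  3  1  2  5  2 ]",
               "G [ 1  0  3  4  1  0  5  3 ]",
               "T [ 2 19 11 50 29 47 22 81 ]"), f)
  pwms <- read_pfm(f)
  p <- pwms[["MA0001.1"]]
  expect_equal(ncol(p$counts), 8)
  expect_true(all(abs(colSums(pwm_prob(p)) - 1) < 1e-12))
  f2 <- withr::local_tempfile(fileext = ".jaspar")
  write_pfm(pwms, f2)
  p2 <- read_pfm(f2)[["MA0001.1"]]
  expect_equal(p2$counts, p$counts)

  writeLines(c(">BAD", "A 1 2 3 4", "C 1 2 3", "G 1 2 3 4", "T 1 2 3 4"), f)
  expect_error(read_pfm(f), "unequal")
})

test_that("DMS table and DMR BED writers round-trip", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L), level_a = c(0.1, 0.9),
    level_b = c(0.6, 0.4), delta = c(0.5, -0.5), p = c(1e-4, 2e-3),
    p_adj = c(1e-3, 2e-2), cov_a = c(20L, 30L), cov_b = c(25L, 15L)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dms_table(sites, f)
  expect_equal(as.data.frame(read_dms_table(f)), as.data.frame(sites))

  dmrs <- tibble::tibble(
    chrom = "chr1", start = c(100L, 900L), end = c(550L, 1400L),
    n_dms = c(5L, 6L), direction = c("hyper", "hypo"),
    frac_dms_consistent = c(1, 0.83), frac_cpg_consistent = c(0.9, 0.85),
    mean_delta = c(0.25, -0.3)
  )
  write_dmr_bed(dmrs, f)
  expect_equal(as.data.frame(read_dmr_bed(f)), as.data.frame(dmrs))
})

test_that("coordinate convention holds exhaustively on a 100 bp toy", {
  grid <- expand.grid(s = 0:99, e = 1:100)
  grid <- grid[grid$s < grid$e, ]
  for (p in c(1L, 2L, 50L, 99L, 100L)) {
    expect_equal(pos_in_interval(p, grid$s, grid$e), grid$s < p & p <= grid$e)
  }
  # full exhaustive sweep via the interval-overlap machinery on one interval
  sites <- tibble::tibble(chrom = "chr1", pos = 1:100)
  for (s in c(0L, 10L, 57L)) {
    for (e in c(s + 1L, s + 5L, 100L)) {
      iv <- tibble::tibble(chrom = "chr1", start = s, end = e)
      expect_equal(sites_in_intervals(sites, iv),
                   s < sites$pos & sites$pos <= e)
    }
  }
})

test_that("interval membership matches a brute-force linear scan", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      sites <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 500, TRUE),
        pos = sample.int(10000, 500, TRUE)
      )
      st <- sample.int(9900, 30, TRUE)
      iv <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                           start = st, end = st + sample.int(500, 30, TRUE))
      expect_equal(sites_in_intervals(sites, iv),
                   brute_sites_in_intervals(sites, iv))
    }
  })
})

test_that("tidy and glance summarise a dms_result", {
  a <- mk_methylome(pos = c(10, 20, 30), meth = c(20, 0, 10),
                    unmeth = c(0, 20, 10))
  b <- mk_methylome(pos = c(10, 20, 30), meth = c(0, 20, 10),
                    unmeth = c(20, 0, 10))
  res <- call_dms(a, b, min_cov = 10, fdr = "bh")
  expect_s3_class(tidy(res), "tbl_df")
  expect_named(glance(res), c("m", "m0", "n_dms", "alpha", "method"))
  expect_equal(glance(res)$m, 3L)
})
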