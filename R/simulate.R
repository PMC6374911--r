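#' Default simulation configuration
#'
#' Collects the generator parameters in one list. Defaults emulate the
#' statistical structure the analysis assumes: a strongly bimodal
#' baseline of CpG methylation levels (most sites near 0 or 1, little
#' intermediate mass), negative-binomial read coverage around the ~10x
#' usable-coverage regime of deep WGBS (mean 20, size 5), and spiked
#' differential regions placed only where enough CpGs fall inside the
#' window so the ground truth is detectable by construction.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_chrom,chrom_length synthetic genome shape.
#' @param cpg_density CpG dinucleotides per bp.
#' @param baseline_weights mixture weights (hyper, hypo, intermediate)
#'   of the baseline level distribution.
#' @param baseline_shapes list of Beta(alpha, beta) parameters for the
#'   three mixture components.
#' @param coverage_mean,coverage_size negative-binomial coverage model.
#' @param dmr_width,n_dmr,dmr_min_cpg,dmr_delta,dmr_direction spiked
#'   differential-region specification; `dmr_direction` is `"hyper"`,
#'   `"hypo"` or `"both"` (alternating).
#' @param dmr_margin minimum separation between spiked regions (bp).
#' @param celltype_delta,celltype_n_sites per-cell-type specification of
#'   designated hypo/hyper sites.
#' @param missing_rate fraction of panel entries masked as missing.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L, chrom_length = 1e6,
                       cpg_density = 0.01,
                       baseline_weights = c(hyper = 0.70, hypo = 0.25, mid = 0.05),
                       baseline_shapes = list(hyper = c(30, 2), hypo = c(2, 30), mid = c(2, 2)),
                       coverage_mean = 20, coverage_size = 5,
                       dmr_width = 1000L, n_dmr = 20L, dmr_min_cpg = 10L,
                       dmr_delta = 0.3, dmr_direction = "both",
                       dmr_margin = 2000L,
                       celltype_delta = 0.4, celltype_n_sites = 100L,
                       missing_rate = 0) {
  stopifnot(cpg_density > 0, chrom_length > 0, n_chrom >= 1,
            dmr_delta > 0, dmr_delta <= 1, coverage_mean >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome with a controlled CpG density
#'
#' Draws a random background sequence, removes incidental CG
#' dinucleotides, then plants CG dyads at `cpg_density` per bp. The
#' returned CpG map lists every CG occurrence in the final sequence
#' (1-based position of the plus-strand C).
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character vector of sequences) and
#'   `cpg_map` (tibble: `chrom`, `pos`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$chrom_length <= 0) abort("chrom_length must be positive")
  withr::with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    genome <- setNames(vector("character", cfg$n_chrom), chroms)
    maps <- vector("list", cfg$n_chrom)
    for (ci in seq_len(cfg$n_chrom)) {
      L <- as.integer(cfg$chrom_length)
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      # break incidental CG dyads so density is governed by planting
      cg <- which(s[-L] == "C" & s[-1] == "G")
      if (length(cg) > 0) s[cg + 1L] <- "A"
      starts <- which(runif(L - 1L) < cfg$cpg_density)
      if (length(starts) > 1) {
        keep <- c(TRUE, diff(starts) >= 2L)
        starts <- starts[keep]
      }
      s[starts] <- "C"; s[starts + 1L] <- "G"
      seq <- paste(s, collapse = "")
      pos <- which(s[-L] == "C" & s[-1] == "G")
      genome[ci] <- seq
      maps[[ci]] <- tibble(chrom = chroms[ci], pos = as.integer(pos))
    }
    list(genome = genome, cpg_map = bind_rows(maps))
  })
}

#' Write a genome as FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

# draw baseline true levels from the bimodal mixture
draw_baseline_levels <- function(n, cfg) {
  w <- cfg$baseline_weights / sum(cfg$baseline_weights)
  comp <- sample(seq_along(w), n, replace = TRUE, prob = w)
  shapes <- cfg$baseline_shapes
  lv <- numeric(n)
  for (k in seq_along(shapes)) {
    idx <- comp == k
    lv[idx] <- rbeta(sum(idx), shapes[[k]][1], shapes[[k]][2])
  }
  lv
}

#' Simulate a methylome from true per-site levels
#'
#' Beta-binomial-style WGBS sampling: per-record coverage is negative
#' binomial, methylated counts binomial at the true level (the level
#' dispersion comes from the Beta baseline). With `stranded = TRUE`
#' (the default) each CpG dyad is reported the way a per-cytosine
#' report does: a plus-strand record at the C position and a
#' minus-strand record at position + 1, each with its own coverage
#' draw and the shared true level (CpG methylation is symmetric).
#' Records drawing coverage 0 are retained as missing
#' (meth = unmeth = 0).
#'
#' @param cpg_map tibble with `chrom`, `pos` (plus-strand C positions).
#' @param true_levels numeric vector in `[0, 1]`, one per site.
#' @param coverage_mean,coverage_size negative-binomial parameters of
#'   the per-record (per-strand) coverage.
#' @param seed integer seed.
#' @param name,genome_id methylome metadata.
#' @param stranded emit both strands of each dyad (see above); set
#'   `FALSE` for a single plus-strand record per CpG.
#' @return a methylome tibble.
#' @export
simulate_methylome <- function(cpg_map, true_levels, coverage_mean = 20,
                               coverage_size = 5, seed = 1L,
                               name = "sim", genome_id = "simgenome",
                               stranded = TRUE) {
  stopifnot(length(true_levels) == nrow(cpg_map),
            all(true_levels >= 0 & true_levels <= 1))
  withr::with_seed(seed, {
    n <- nrow(cpg_map)
    draw <- function() {
      cov <- if (coverage_mean <= 0) integer(n) else {
        rnbinom(n, mu = coverage_mean, size = coverage_size)
      }
      meth <- rbinom(n, cov, true_levels)
      list(meth = as.integer(meth), unmeth = as.integer(cov - meth))
    }
    plus <- draw()
    rows <- tibble(chrom = cpg_map$chrom, pos = cpg_map$pos, strand = "+",
                   context = "CpG", meth = plus$meth, unmeth = plus$unmeth)
    if (stranded) {
      minus <- draw()
      rows <- bind_rows(
        rows,
        tibble(chrom = cpg_map$chrom, pos = cpg_map$pos + 1L, strand = "-",
               context = "CpG", meth = minus$meth, unmeth = minus$unmeth)
      )
    }
    as_methylome(rows, name = name, genome_id = genome_id)
  })
}

# place n windows of `width` each containing >= min_cpg CpGs, pairwise
# separated by at least `margin` bp so neighbouring truth regions stay
# resolvable by gap-based clustering
place_spike_regions <- function(cpg_map, width, n, min_cpg, margin = 2000L) {
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  by_chrom <- split(cpg_map$pos, cpg_map$chrom)
  cand <- bind_rows(map(names(by_chrom), function(ch) {
    pos <- sort(by_chrom[[ch]])
    if (length(pos) < min_cpg) return(NULL)
    # windows anchored at CpGs: [pos_i - 1, pos_i - 1 + width)
    hi <- findInterval(pos + width - 1L, pos)
    ok <- which(hi - seq_along(pos) + 1L >= min_cpg)
    if (length(ok) == 0) return(NULL)
    tibble(chrom = ch, start = pos[ok] - 1L, end = pos[ok] - 1L + as.integer(width))
  }))
  if (nrow(cand) == 0) abort("no candidate windows hold the requested CpG count")
  cand <- cand[sample.int(nrow(cand)), ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(placed) >= n) break
    row <- cand[i, ]
    grown <- mutate(row, start = pmax(0L, .data$start - as.integer(margin)),
                    end = .data$end + as.integer(margin))
    if (!any(intervals_overlap_any(grown, placed))) {
      placed <- bind_rows(placed, row)
    }
  }
  if (nrow(placed) < n) {
    warn(paste0("placed only ", nrow(placed), " of ", n, " spiked regions"))
  }
  arrange(placed, .data$chrom, .data$start)
}

#' Simulate a two-condition methylome pair with spiked DMRs
#'
#' Outside the spiked regions both conditions share identical true
#' levels drawn from the bimodal baseline. Inside each spiked region
#' condition B is shifted by `dmr_delta` in the region's direction and
#' clipped to `[0, 1]`; so that the shift survives clipping, hyper
#' regions are seeded with hypomethylated baseline and hypo regions
#' with hypermethylated baseline.
#'
#' @param cfg a [sim_config()]; set `n_dmr = 0` for a fully null pair.
#' @param genome optional pre-built output of [simulate_genome()]
#'   (rebuilt from `cfg` when missing).
#' @return list with `meth_a`, `meth_b`, `truth` (list: `dmr_intervals`
#'   tibble with `direction`, `dms_positions` tibble, `true_levels_a/b`),
#'   and `cpg_map`.
#' @export
spike_condition_pair <- function(cfg, genome = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(genome)) genome <- simulate_genome(cfg)
  cpg <- genome$cpg_map
  withr::with_seed(cfg$seed + 1L, {
    lv_a <- draw_baseline_levels(nrow(cpg), cfg)
    if (cfg$n_dmr > 0) {
      regions <- place_spike_regions(cpg, cfg$dmr_width, cfg$n_dmr,
                                     cfg$dmr_min_cpg, cfg$dmr_margin)
      regions$direction <- switch(
        cfg$dmr_direction,
        hyper = rep("hyper", nrow(regions)),
        hypo = rep("hypo", nrow(regions)),
        both = rep(c("hyper", "hypo"), length.out = nrow(regions))
      )
    } else {
      regions <- tibble(chrom = character(), start = integer(),
                        end = integer(), direction = character())
    }
    lv_b <- lv_a
    shifted <- rep(FALSE, nrow(cpg))
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      idx <- which(cpg$chrom == r$chrom & pos_in_interval(cpg$pos, r$start, r$end))
      base <- if (r$direction == "hyper") {
        rbeta(length(idx), cfg$baseline_shapes$hypo[1], cfg$baseline_shapes$hypo[2])
      } else {
        rbeta(length(idx), cfg$baseline_shapes$hyper[1], cfg$baseline_shapes$hyper[2])
      }
      lv_a[idx] <- base
      lv_b[idx] <- pmin(1, pmax(0, base + if (r$direction == "hyper") cfg$dmr_delta else -cfg$dmr_delta))
      shifted[idx] <- TRUE
    }
    truth <- list(
      dmr_intervals = regions,
      dms_positions = cpg[shifted, ],
      true_levels_a = lv_a,
      true_levels_b = lv_b
    )
    list(
      meth_a = merge_symmetric_cpg(
        simulate_methylome(cpg, lv_a, cfg$coverage_mean, cfg$coverage_size,
                           seed = cfg$seed + 2L, name = "condA")),
      meth_b = merge_symmetric_cpg(
        simulate_methylome(cpg, lv_b, cfg$coverage_mean, cfg$coverage_size,
                           seed = cfg$seed + 3L, name = "condB")),
      truth = truth,
      cpg_map = cpg
    )
  })
}

#' Simulate a multi-cell-type methylome panel
#'
#' Five named methylomes (excitatory, PV, VIP, astrocyte,
#' oligodendrocyte by default). For each type, `celltype_n_sites`
#' designated hypo sites are hypomethylated by `celltype_delta`
#' relative to every other type (and likewise hyper sites
#' hypermethylated); remaining sites share the bimodal baseline.
#' A `missing_rate` fraction of (site, methylome) entries is masked
#' as coverage 0.
#'
#' @param cfg a [sim_config()].
#' @param cell_types names of the panel methylomes.
#' @param coverage_mean panel coverage (defaults to `cfg$coverage_mean`).
#' @return list with `panel` (named list of methylomes), `truth`
#'   (tibble: `cell_type`, `chrom`, `pos`, `direction`), `cpg_map`.
#' @export
simulate_celltype_panel <- function(cfg,
                                    cell_types = c("excitatory", "PV", "VIP",
                                                   "astrocyte", "oligodendrocyte"),
                                    coverage_mean = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(coverage_mean)) coverage_mean <- cfg$coverage_mean
  genome <- simulate_genome(cfg)
  cpg <- genome$cpg_map
  k <- length(cell_types)
  n_per <- cfg$celltype_n_sites
  n_need <- 2L * k * n_per
  if (nrow(cpg) < n_need) abort("not enough CpGs for the requested designated sites")
  withr::with_seed(cfg$seed + 10L, {
    base <- draw_baseline_levels(nrow(cpg), cfg)
    levels <- matrix(rep(base, k), ncol = k, dimnames = list(NULL, cell_types))
    desig_idx <- if (n_per > 0) sample.int(nrow(cpg), n_need) else integer(0)
    truth <- NULL
    if (n_per > 0) {
      slots <- split(desig_idx, rep(seq_len(2L * k), each = n_per))
      rows <- list()
      for (t in seq_len(k)) {
        hypo_i <- slots[[2L * t - 1L]]
        hyper_i <- slots[[2L * t]]
        # others pinned high, target low (hypo) and vice versa
        hi <- 0.9 + runif(length(hypo_i), 0, 0.08)
        levels[hypo_i, ] <- matrix(rep(hi, k), ncol = k)
        levels[hypo_i, t] <- pmax(0, hi - cfg$celltype_delta)
        lo <- 0.02 + runif(length(hyper_i), 0, 0.08)
        levels[hyper_i, ] <- matrix(rep(lo, k), ncol = k)
        levels[hyper_i, t] <- pmin(1, lo + cfg$celltype_delta)
        rows[[t]] <- bind_rows(
          tibble(cell_type = cell_types[t], chrom = cpg$chrom[hypo_i],
                 pos = cpg$pos[hypo_i], direction = "hypo"),
          tibble(cell_type = cell_types[t], chrom = cpg$chrom[hyper_i],
                 pos = cpg$pos[hyper_i], direction = "hyper")
        )
      }
      truth <- bind_rows(rows)
    } else {
      truth <- tibble(cell_type = character(), chrom = character(),
                      pos = integer(), direction = character())
    }
    panel <- setNames(vector("list", k), cell_types)
    for (t in seq_len(k)) {
      m <- merge_symmetric_cpg(
        simulate_methylome(cpg, levels[, t], coverage_mean, cfg$coverage_size,
                           seed = cfg$seed + 20L + t, name = cell_types[t]))
      if (cfg$missing_rate > 0) {
        drop <- runif(nrow(m)) < cfg$missing_rate
        m$meth[drop] <- 0L
        m$unmeth[drop] <- 0L
      }
      panel[[t]] <- m
    }
    list(panel = panel, truth = arrange(truth, .data$chrom, .data$pos),
         cpg_map = cpg)
  })
}

#' Embed motif instances into target/background sequences
#'
#' A fraction `rate_t` of the target sequences (and `rate_b` of the
#' background) receive one consensus motif instance at a random offset.
#'
#' @param targets,background character vectors of sequences.
#' @param pwm a `pwm` object; its per-column consensus is embedded.
#' @param rate_t,rate_b embedding rates.
#' @param seed integer seed.
#' @return list with modified `targets`, `background`, and `truth`
#'   (list of embedded indices per set).
#' @export
embed_motif <- function(targets, background, pwm, rate_t, rate_b, seed = 1L) {
  cons <- pwm_consensus(pwm)
  withr::with_seed(seed, {
    emb <- function(seqs, rate) {
      n <- length(seqs)
      pick <- which(runif(n) < rate)
      for (i in pick) {
        L <- nchar(seqs[i]); w <- nchar(cons)
        if (L < w) next
        off <- sample.int(L - w + 1L, 1)
        substr(seqs[i], off, off + w - 1L) <- cons
      }
      list(seqs = seqs, idx = pick)
    }
    tg <- emb(targets, rate_t)
    bg <- emb(background, rate_b)
    list(targets = tg$seqs, background = bg$seqs,
         truth = list(target_idx = tg$idx, background_idx = bg$idx))
  })
}

#' Simulate a gene expression table
#'
#' Zero-inflated lognormal TPM values: a `prop_zero` fraction of genes
#' is not expressed (TPM 0), the rest draws from a lognormal.
#'
#' @param genes gene-model tibble (or character vector of gene ids).
#' @param seed integer seed.
#' @param prop_zero fraction of unexpressed genes.
#' @param meanlog,sdlog lognormal parameters of the expressed fraction.
#' @return tibble with `gene_id`, `tpm`.
#' @export
simulate_expression <- function(genes, seed = 1L, prop_zero = 0.25,
                                meanlog = 2, sdlog = 1.5) {
  ids <- if (is.character(genes)) genes else genes$gene_id
  withr::with_seed(seed, {
    n <- length(ids)
    zero <- runif(n) < prop_zero
    tpm <- ifelse(zero, 0, rlnorm(n, meanlog, sdlog))
    tibble(gene_id = ids, tpm = tpm)
  })
}
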