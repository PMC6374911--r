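#' PWM construction and scoring primitives
#'
#' A `pwm` holds a 4 x L count (or probability) matrix with rows
#' A, C, G, T and the background base frequencies. Scoring is log2
#' odds of the pseudocounted probability matrix over the background.
#'
#' @param motif_id,name identifiers.
#' @param counts 4 x L non-negative matrix, rows A/C/G/T.
#' @param background base frequencies summing to 1.
#' @return a `pwm` object.
#' @export
new_pwm <- function(motif_id, counts, name = motif_id,
                    background = rep(0.25, 4)) {
  stopifnot(nrow(counts) == 4, all(counts >= 0),
            length(background) == 4, abs(sum(background) - 1) < 1e-6)
  if (ncol(counts) < 4) abort("motif length must be at least 4")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 background = background),
            class = "pwm")
}

#' @rdname new_pwm
#' @param pwm a `pwm` object.
#' @param pseudocount added per cell before normalisation.
#' @export
pwm_prob <- function(pwm, pseudocount = 0.01) {
  cs <- colSums(pwm$counts)
  p <- sweep(pwm$counts, 2, ifelse(cs > 0, cs, 1), "/")
  sweep(p + pseudocount, 2, colSums(p + pseudocount), "/")
}

#' @rdname new_pwm
#' @export
pwm_logodds <- function(pwm, pseudocount = 0.01) {
  log2(pwm_prob(pwm, pseudocount) / pwm$background)
}

#' @rdname new_pwm
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' @rdname new_pwm
#' @export
pwm_max_score <- function(pwm, pseudocount = 0.01) {
  sum(apply(pwm_logodds(pwm, pseudocount), 2, max))
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$motif_id, paste0("(", x$name, ")"),
      "L =", ncol(x$counts), " consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(s, NULL), function(v) paste(rev(v), collapse = ""), ""))
}

#' Scan sequences with a PWM
#'
#' Log-odds scoring at every offset on both strands with per-cell
#' pseudocount; `N` (and any non-ACGT) positions contribute 0. A
#' sequence is a hit when its best score reaches `score_fraction`
#' times the maximum achievable score.
#'
#' @param sequences character vector (or `DNAStringSet`) over ACGTN.
#' @param pwm a `pwm` object.
#' @param score_fraction hit threshold as a fraction of the maximum
#'   achievable score.
#' @param pseudocount per-cell pseudocount.
#' @return tibble: `seq_id`, `length`, `best_score`, `hit`, `too_short`.
#'   The score threshold and maximum are attached as attributes.
#' @export
scan_pwm <- function(sequences, pwm, score_fraction = 0.8, pseudocount = 0.01) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq_", seq_along(sequences))
  }
  lo <- pwm_logodds(pwm, pseudocount)
  lo5 <- rbind(lo, 0)  # row 5: N / unknown base
  L <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- score_fraction * max_score
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  best_one <- function(s) {
    v <- code[strsplit(toupper(s), NULL)[[1]]]
    v[is.na(v)] <- 5L
    n <- length(v)
    if (n < L) return(NA_real_)
    no <- n - L + 1L
    idx <- rep(seq_len(no), L) + rep(0:(L - 1L), each = no)
    sc <- matrix(lo5[cbind(v[idx], rep(seq_len(L), each = no))], nrow = no)
    max(rowSums(sc))
  }
  fwd <- vapply(sequences, best_one, numeric(1))
  rev <- vapply(revcomp(sequences), best_one, numeric(1))
  best <- pmax(fwd, rev, na.rm = FALSE)
  out <- tibble(
    seq_id = names(sequences),
    length = nchar(sequences),
    best_score = unname(best),
    hit = !is.na(best) & best >= thr - 1e-9,
    too_short = is.na(best)
  )
  structure(out, threshold = thr, max_score = max_score)
}

#' Flank-derived background regions for motif enrichment
#'
#' For each target `[s, e)` of width `w`, emits two same-width regions
#' at `[s - offset - w, s - offset)` and `[e + offset, e + offset + w)`,
#' i.e. upstream and downstream regions situated `offset` bp away, so
#' the background doubles the target set. Regions running off the
#' chromosome or overlapping any target are dropped; the drop counts
#' are attached as attributes.
#'
#' @param targets interval tibble.
#' @param offset distance between a target and its flank regions (bp).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return interval tibble of background regions with attributes
#'   `n_dropped_bounds` and `n_dropped_overlap`.
#' @export
build_flank_background <- function(targets, offset = 2000, chrom_sizes = NULL) {
  w <- targets$end - targets$start
  cand <- bind_rows(
    tibble(chrom = targets$chrom, start = targets$start - offset - w,
           end = targets$start - offset, label = "flank_up"),
    tibble(chrom = targets$chrom, start = targets$end + offset,
           end = targets$end + offset + w, label = "flank_down")
  )
  in_bounds <- cand$start >= 0
  if (!is.null(chrom_sizes)) {
    in_bounds <- in_bounds & cand$end <= unname(chrom_sizes[cand$chrom])
  }
  n_bounds <- sum(!in_bounds)
  cand <- cand[in_bounds, ]
  ovl <- intervals_overlap_any(cand, targets)
  n_ovl <- sum(ovl)
  out <- cand[!ovl, ]
  structure(out, n_dropped_bounds = n_bounds, n_dropped_overlap = n_ovl)
}

#' Binomial motif enrichment test
#'
#' The background hit fraction is the null probability; the p-value is
#' the upper binomial tail of the target hit count. A zero background
#' hit rate is floored at `1 / (2 * n_bg)`.
#'
#' @param n_target,n_target_hit,n_bg,n_bg_hit hit counts.
#' @param cutoff significance cutoff for the `enriched` call.
#' @param motif_id carried into the output.
#' @return one-row tibble: `motif_id`, counts, `p_binomial`, `enriched`.
#' @export
motif_enrichment_test <- function(n_target, n_target_hit, n_bg, n_bg_hit,
                                  cutoff = 1e-10, motif_id = NA_character_) {
  stopifnot(n_target_hit <= n_target, n_bg_hit <= n_bg)
  p0 <- if (n_bg > 0) n_bg_hit / n_bg else 0
  if (p0 == 0 && n_target_hit > 0) p0 <- 1 / (2 * max(n_bg, 1))
  p <- if (n_target_hit == 0) 1 else {
    pbinom(n_target_hit - 1, n_target, p0, lower.tail = FALSE)
  }
  tibble(motif_id = motif_id, n_target = n_target, n_target_hit = n_target_hit,
         n_bg = n_bg, n_bg_hit = n_bg_hit, p_binomial = p,
         enriched = p <= cutoff)
}

# extract sequences for intervals from a named genome (character vector
# or DNAStringSet); intervals are BED half-open
extract_interval_sequences <- function(genome, intervals) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  vapply(seq_len(nrow(intervals)), function(i) {
    substr(genome[[intervals$chrom[i]]], intervals$start[i] + 1L, intervals$end[i])
  }, character(1))
}

#' Per-module known-motif enrichment report
#'
#' For each module: target regions are the module's loci extended to a
#' fixed width around their centres; background regions come from
#' [build_flank_background()]; every PWM is scanned over both sets and
#' tested with [motif_enrichment_test()]. Motif families are grouped by
#' the letter prefix of the motif id so family members with similar
#' motifs are reported together.
#'
#' @param modules a `module_assignment` whose loci are
#'   `"chrom:start-end"` strings (module 0 is skipped).
#' @param genome named character vector or `DNAStringSet`.
#' @param pwms list of `pwm` objects.
#' @param offset flank-background offset (bp).
#' @param width fixed target width centred on each locus (bp).
#' @param cutoff enrichment significance cutoff.
#' @param score_fraction scan threshold (see [scan_pwm()]).
#' @return tibble sorted by p within module: `module`, `motif_id`,
#'   `family`, counts, `p_binomial`, `enriched`.
#' @export
cluster_motif_report <- function(modules, genome, pwms, offset = 2000,
                                 width = 200, cutoff = 1e-10,
                                 score_fraction = 0.8) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  chrom_sizes <- setNames(nchar(genome), names(genome))
  loci <- parse_locus(modules$assignment$locus)
  mods <- sort(setdiff(unique(modules$assignment$module), 0L))
  out <- map(mods, function(mm) {
    idx <- which(modules$assignment$module == mm)
    if (length(idx) == 0) return(NULL)
    ctr <- floor((loci$start[idx] + loci$end[idx]) / 2)
    targets <- tibble(chrom = loci$chrom[idx],
                      start = pmax(0L, as.integer(ctr - width %/% 2)),
                      end = as.integer(ctr - width %/% 2 + width)) |>
      mutate(end = pmin(.data$end, unname(chrom_sizes[.data$chrom]))) |>
      filter(.data$end > .data$start)
    bg <- build_flank_background(targets, offset = offset,
                                 chrom_sizes = chrom_sizes)
    tseq <- extract_interval_sequences(genome, targets)
    bseq <- extract_interval_sequences(genome, bg)
    map(pwms, function(p) {
      th <- scan_pwm(tseq, p, score_fraction = score_fraction)
      bh <- scan_pwm(bseq, p, score_fraction = score_fraction)
      motif_enrichment_test(nrow(th), sum(th$hit), nrow(bh), sum(bh$hit),
                            cutoff = cutoff, motif_id = p$motif_id) |>
        mutate(module = mm, .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(module = integer(), motif_id = character(),
                  family = character(), n_target = integer(),
                  n_target_hit = integer(), n_bg = integer(),
                  n_bg_hit = integer(), p_binomial = double(),
                  enriched = logical()))
  }
  out |>
    mutate(family = toupper(sub("^([A-Za-z]+).*", "\\1", .data$motif_id))) |>
    arrange(.data$module, .data$p_binomial) |>
    select("module", "motif_id", "family", everything())
}

parse_locus <- function(locus) {
  m <- regmatches(locus, regexec("^(.+):([0-9]+)-([0-9]+)$", locus))
  tibble(
    chrom = vapply(m, `[`, "", 2),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4))
  )
}
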