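#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The table rows are the two conditions, the columns methylated /
#' unmethylated read counts. The two-sided p-value is the sum of
#' hypergeometric probabilities (margins fixed) of all tables at most as
#' probable as the observed one; tables within a relative tolerance of
#' the observed probability count as ties (the dominant convention).
#'
#' @param a,b,c,d non-negative integer cell counts: `a` methylated and
#'   `b` unmethylated in condition A, `c`/`d` likewise in condition B.
#' @param tie_tol relative tolerance for probability ties.
#' @return list with `p` and `odds_ratio` (`ad/bc`; `Inf` when `bc == 0`
#'   and `ad > 0`, `NaN` when both products are 0).
#' @export
fisher_exact_two_sided <- function(a, b, c, d, tie_tol = 1e-7) {
  if (any(c(a, b, c, d) < 0)) abort("negative cell counts")
  n <- a + b + c + d
  if (n == 0) abort("all-zero contingency table")
  list(
    p = fisher_p(a, b, c, d, tie_tol),
    odds_ratio = fisher_or(a, b, c, d)
  )
}

fisher_or <- function(a, b, c, d) {
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c
  if (den == 0 && num == 0) NaN else num / den
}

# scalar two-sided p by hypergeometric enumeration over the table support
fisher_p <- function(a, b, c, d, tie_tol = 1e-7) {
  m1 <- a + c          # methylated margin
  m2 <- b + d          # unmethylated margin
  r1 <- a + b          # condition-A margin
  lo <- max(0L, r1 - m2)
  hi <- min(r1, m1)
  k <- lo:hi
  logp <- dhyper(k, m1, m2, r1, log = TRUE)
  lp_obs <- logp[k == a]
  min(1, sum(exp(logp[logp <= lp_obs + log1p(tie_tol)])))
}

# vectorised p over columns of a table tibble; shared tables computed once
fisher_p_vec <- function(a, b, c, d, tie_tol = 1e-7) {
  key <- paste(a, b, c, d)
  uk <- !duplicated(key)
  pu <- mapply(fisher_p, a[uk], b[uk], c[uk], d[uk],
               MoreArgs = list(tie_tol = tie_tol))
  unname(pu[match(key, key[uk])])
}

#' Sequential permutation p-value for one contingency table
#'
#' Monte-Carlo calibration of the exact test: tables are redrawn from
#' the hypergeometric null with the observed margins fixed (equivalent
#' to permuting read labels), the statistic is the exact-test p-value,
#' and sampling stops early once `h` permuted statistics at most as
#' large as the observed one have been seen (Besag-Clifford rule).
#'
#' @inheritParams fisher_exact_two_sided
#' @param max_perm permutation cap.
#' @param h exceedance count triggering early stopping.
#' @return list with `p_perm` (in `(0, 1]`) and `n_used`.
#' @export
sequential_permutation_pvalue <- function(a, b, c, d, max_perm = 1000, h = 10) {
  if (h > max_perm) abort("h must not exceed max_perm")
  m1 <- a + c; m2 <- b + d; r1 <- a + b
  p_obs <- fisher_p(a, b, c, d)
  # precompute the exact p for every achievable table, then draw indices
  lo <- max(0L, r1 - m2); hi <- min(r1, m1)
  p_by_k <- vapply(lo:hi, function(k) {
    fisher_p(k, r1 - k, m1 - k, m2 - (r1 - k))
  }, numeric(1))
  exceed <- 0L
  for (i in seq_len(max_perm)) {
    k <- rhyper(1, m1, m2, r1)
    if (p_by_k[k - lo + 1L] <= p_obs * (1 + 1e-12)) {
      exceed <- exceed + 1L
      if (exceed >= h) {
        return(list(p_perm = h / i, n_used = i))
      }
    }
  }
  list(p_perm = (exceed + 1) / (max_perm + 1), n_used = max_perm)
}

#' Histogram estimate of the number of true null hypotheses
#'
#' Tail-averaging rule on `n_bins` equal-width bins of the p-values:
#' find the smallest bin index `i` whose count does not exceed the mean
#' count of bins `i..B`, then `m0 = (B / (B - i + 1)) * sum(counts[i:B])`,
#' capped at `m`. Uniform p-values give `m0 ~ m`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param n_bins number of histogram bins (requires `length(pvals) >= n_bins`).
#' @return estimated `m0` (scalar), with the bin counts attached as the
#'   `"bins"` attribute.
#' @export
estimate_m0_histogram <- function(pvals, n_bins = 20) {
  m <- length(pvals)
  if (m == 0) abort("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < n_bins) abort("need at least n_bins p-values")
  bin <- pmin(n_bins, floor(pvals * n_bins) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  tail_mean <- rev(cumsum(rev(counts))) / (n_bins - seq_len(n_bins) + 1)
  i <- which(counts <= tail_mean)[1]
  m0 <- min(m, (n_bins / (n_bins - i + 1)) * sum(counts[i:n_bins]))
  structure(m0, bins = counts)
}

#' Adaptive Benjamini-Hochberg adjustment with a plug-in m0
#'
#' Step-up adjustment `p_adj(i) = min over p(j) >= p(i) of
#' min(1, m0 * p(j) / rank(j))`. With `m0 = m` this is exactly the
#' textbook BH adjustment.
#'
#' @param pvals p-values.
#' @param m0 estimated number of true nulls, in `[0, m]`.
#' @return adjusted p-values in the input order.
#' @export
adjust_adaptive_bh <- function(pvals, m0) {
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  if (is.na(m0) || m0 < 0 || m0 > m) abort("m0 must lie in [0, m]")
  ord <- order(pvals)
  adj <- m0 * pvals[ord] / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(adj))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Classify a methylation level as hypo/intermediate/hyper
#'
#' Hypermethylated at level >= 0.8, hypomethylated at level <= 0.2.
#'
#' @param level numeric vector in `[0, 1]`.
#' @return character vector of `"hypo"`, `"intermediate"`, `"hyper"`.
#' @export
classify_level <- function(level) {
  dplyr::case_when(
    level >= 0.8 ~ "hyper",
    level <= 0.2 ~ "hypo",
    is.na(level) ~ NA_character_,
    TRUE ~ "intermediate"
  )
}

#' Call differentially methylated sites between two methylomes
#'
#' Sites covered by at least `min_cov` reads in *both* samples are
#' tested with a per-site two-sided Fisher's exact test on the
#' methylated/unmethylated counts. False discovery is controlled with
#' an adaptive BH adjustment whose plug-in m0 comes from the histogram
#' estimator; sites with adjusted p <= `alpha` are flagged as DMSs.
#'
#' @param meth_a,meth_b methylome tibbles (CpG-context sites are used;
#'   dyad-merge with [merge_symmetric_cpg()] first if strands are split).
#' @param min_cov minimum read coverage in each sample.
#' @param alpha adjusted-p threshold for the DMS call.
#' @param fdr `"adaptive"` (exact p + histogram m0, the default),
#'   `"bh"` (m0 = m), or `"permutation"` (sequential permutation p-values
#'   with 1000-permutation cap, then adaptive adjustment).
#' @param max_perm,h sequential permutation parameters (permutation mode).
#' @param n_bins histogram bins for the m0 estimate.
#' @return object of class `dms_result`: list with `sites` (tibble:
#'   chrom, pos, strand, level_a, level_b, delta, cov_a, cov_b, p,
#'   p_adj, is_dms), `fdr` (m, m0, bins, alpha, method) and `params`.
#' @export
call_dms <- function(meth_a, meth_b, min_cov = 10, alpha = 0.05,
                     fdr = c("adaptive", "bh", "permutation"),
                     max_perm = 1000, h = 10, n_bins = 20) {
  fdr <- match.arg(fdr)
  ga <- attr(meth_a, "genome_id"); gb <- attr(meth_b, "genome_id")
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    abort("methylomes come from different genomes")
  }
  joined <- inner_join(
    meth_a |> select("chrom", "pos", "strand", meth_a = "meth", unmeth_a = "unmeth"),
    meth_b |> select("chrom", "pos", "strand", meth_b = "meth", unmeth_b = "unmeth"),
    by = c("chrom", "pos", "strand")
  ) |>
    mutate(cov_a = .data$meth_a + .data$unmeth_a,
           cov_b = .data$meth_b + .data$unmeth_b) |>
    filter(.data$cov_a >= min_cov, .data$cov_b >= min_cov)
  if (nrow(joined) == 0) {
    warn("no sites testable at the requested coverage")
    empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                    level_a = double(), level_b = double(), delta = double(),
                    cov_a = integer(), cov_b = integer(), p = double(),
                    p_adj = double(), is_dms = logical())
    return(new_dms_result(empty, m = 0L, m0 = 0, bins = integer(n_bins),
                          alpha = alpha, method = fdr,
                          params = list(min_cov = min_cov)))
  }
  p_exact <- fisher_p_vec(joined$meth_a, joined$unmeth_a,
                          joined$meth_b, joined$unmeth_b)
  p_use <- if (fdr == "permutation") {
    pmap_dbl(list(joined$meth_a, joined$unmeth_a, joined$meth_b, joined$unmeth_b),
             function(a, b, c, d) {
               sequential_permutation_pvalue(a, b, c, d, max_perm = max_perm, h = h)$p_perm
             })
  } else {
    p_exact
  }
  m <- length(p_use)
  if (fdr == "bh" || m < n_bins) {
    m0 <- m
    bins <- integer(n_bins)
  } else {
    m0 <- estimate_m0_histogram(p_use, n_bins = n_bins)
    bins <- attr(m0, "bins")
    m0 <- as.numeric(m0)
  }
  p_adj <- adjust_adaptive_bh(p_use, m0)
  sites <- joined |>
    mutate(
      level_a = .data$meth_a / .data$cov_a,
      level_b = .data$meth_b / .data$cov_b,
      delta = .data$level_b - .data$level_a,
      p = p_use,
      p_adj = p_adj,
      is_dms = p_adj <= alpha
    ) |>
    select("chrom", "pos", "strand", "level_a", "level_b", "delta",
           "cov_a", "cov_b", "p", "p_adj", "is_dms")
  new_dms_result(sites, m = m, m0 = m0, bins = bins, alpha = alpha,
                 method = fdr,
                 params = list(min_cov = min_cov, max_perm = max_perm, h = h))
}

new_dms_result <- function(sites, m, m0, bins, alpha, method, params) {
  structure(
    list(sites = sites,
         fdr = list(m = m, m0 = m0, bins = bins, alpha = alpha, method = method),
         params = params),
    class = "dms_result"
  )
}

#' @export
print.dms_result <- function(x, ...) {
  cat("<dms_result>\n")
  cat("  tested sites:", x$fdr$m, "\n")
  cat("  estimated m0:", round(x$fdr$m0, 1), "\n")
  cat("  DMSs (p_adj <=", x$fdr$alpha, "):", sum(x$sites$is_dms), "\n")
  cat("  fdr method:", x$fdr$method, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dms_result <- function(x, ...) x$sites

#' @exportS3Method generics::glance
glance.dms_result <- function(x, ...) {
  tibble(m = x$fdr$m, m0 = x$fdr$m0, n_dms = sum(x$sites$is_dms),
         alpha = x$fdr$alpha, method = x$fdr$method)
}
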