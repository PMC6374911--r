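#' Chain adjacent DMSs into candidate clusters
#'
#' Single-linkage chaining: consecutive DMSs at most `max_gap` bp apart
#' (on the same chromosome) join one cluster.
#'
#' @param dms tibble of DMS rows with `chrom` and `pos` columns.
#' @param max_gap maximum distance between adjacent member DMSs (bp).
#' @return the input rows, sorted, with an integer `cluster` column.
#' @export
cluster_dms <- function(dms, max_gap = 500) {
  if (nrow(dms) == 0) return(mutate(dms, cluster = integer(0)))
  dms |>
    arrange(.data$chrom, .data$pos) |>
    mutate(
      new_cluster = .data$chrom != coalesce(lag(.data$chrom), "") |
        .data$pos - coalesce(lag(.data$pos), .data$pos) > max_gap,
      cluster = cumsum(.data$new_cluster)
    ) |>
    select(-"new_cluster")
}

#' Filter DMS clusters to differentially methylated regions
#'
#' A candidate cluster becomes a DMR iff (i) it contains at least
#' `min_dms` DMSs, (ii) at least `min_frac` of its DMSs change in the
#' majority direction, and (iii) at least `min_frac` of *all* covered
#' CpG sites in its hull change by at least `min_delta` in that
#' direction. CpGs without an observed level in either sample are
#' excluded from the criterion (iii) denominator (delta is undefined
#' without both levels). A 50/50 direction tie cannot reach `min_frac`
#' and is rejected.
#'
#' @param clusters output of [cluster_dms()].
#' @param all_sites tibble with `chrom`, `pos`, `delta` for every covered
#'   CpG (DMS or not), e.g. the `sites` table of a [call_dms()] result.
#' @param min_dms minimum DMS count per region (the headline definition
#'   uses 5; 4 is the documented alternative).
#' @param min_frac consistency fraction for criteria (ii) and (iii).
#' @param min_delta minimum |methylation change| for criterion (iii).
#' @return DMR tibble: `chrom`, `start`, `end` (0-based half-open hull),
#'   `n_dms`, `direction`, `frac_dms_consistent`, `frac_cpg_consistent`,
#'   `mean_delta`, `member_positions` (list-column).
#' @export
filter_clusters_to_dmrs <- function(clusters, all_sites, min_dms = 5,
                                    min_frac = 0.8, min_delta = 0.1) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_dms = integer(), direction = character(),
                  frac_dms_consistent = double(), frac_cpg_consistent = double(),
                  mean_delta = double(), member_positions = list())
  if (nrow(clusters) == 0) return(empty)
  eps <- 1e-12
  out <- clusters |>
    group_by(.data$cluster) |>
    group_map(function(g, key) {
      n_dms <- nrow(g)
      if (n_dms < min_dms) return(NULL)
      n_up <- sum(g$delta > 0); n_dn <- sum(g$delta < 0)
      if (n_up == n_dn) return(NULL)
      maj <- if (n_up > n_dn) 1 else -1
      frac_dms <- max(n_up, n_dn) / n_dms
      if (frac_dms < min_frac - eps) return(NULL)
      hull_lo <- min(g$pos); hull_hi <- max(g$pos)
      cov <- all_sites |>
        filter(.data$chrom == g$chrom[1],
               .data$pos >= hull_lo, .data$pos <= hull_hi,
               !is.na(.data$delta))
      if (nrow(cov) == 0) return(NULL)
      ok <- sign(cov$delta) == maj & abs(cov$delta) >= min_delta - eps
      frac_cpg <- sum(ok) / nrow(cov)
      if (frac_cpg < min_frac - eps) return(NULL)
      tibble(
        chrom = g$chrom[1],
        start = hull_lo - 1L,
        end = hull_hi,
        n_dms = n_dms,
        direction = if (maj > 0) "hyper" else "hypo",
        frac_dms_consistent = frac_dms,
        frac_cpg_consistent = frac_cpg,
        mean_delta = mean(g$delta),
        member_positions = list(g$pos)
      )
    }) |>
    list_rbind()
  if (is.null(out) || nrow(out) == 0) empty else out
}

#' Call DMRs from a DMS result
#'
#' Convenience wrapper: clusters the flagged DMSs with [cluster_dms()]
#' and applies the region filters of [filter_clusters_to_dmrs()] using
#' all tested sites for the CpG-consistency criterion.
#'
#' @param x a `dms_result` from [call_dms()].
#' @inheritParams cluster_dms
#' @inheritParams filter_clusters_to_dmrs
#' @return DMR tibble (see [filter_clusters_to_dmrs()]).
#' @export
call_dmrs <- function(x, max_gap = 500, min_dms = 5, min_frac = 0.8,
                      min_delta = 0.1) {
  stopifnot(inherits(x, "dms_result"))
  dms <- filter(x$sites, .data$is_dms)
  clusters <- cluster_dms(dms, max_gap = max_gap)
  filter_clusters_to_dmrs(clusters, x$sites, min_dms = min_dms,
                          min_frac = min_frac, min_delta = min_delta)
}

# strand-aware interval covering the gene body plus `upstream` bp before the TSS
gene_window <- function(genes, upstream) {
  tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(ifelse(genes$strand == "+",
                                       genes$tss - 1L - upstream,
                                       pmin(genes$tss, genes$tes) - 1L))),
    end = as.integer(ifelse(genes$strand == "+",
                            pmax(genes$tss, genes$tes),
                            genes$tss + upstream)),
    gene_id = genes$gene_id,
    strand = genes$strand
  )
}

# strand-aware promoter: the 2 kb window ending at (and including) the TSS
promoter_window <- function(genes, upstream = 2000) {
  tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(ifelse(genes$strand == "+",
                                       genes$tss - 1L - upstream,
                                       genes$tss - 1L))),
    end = as.integer(ifelse(genes$strand == "+",
                            genes$tss,
                            genes$tss + upstream)),
    gene_id = genes$gene_id,
    strand = genes$strand
  )
}

#' Associate DMRs with genes
#'
#' A DMR is associated with a gene when it overlaps the gene body
#' (TSS..TES) or the strand-aware window `upstream` bp before the TSS.
#'
#' @param dmrs DMR tibble.
#' @param genes gene-model tibble.
#' @param upstream window size upstream of the TSS (bp).
#' @return tibble with one row per (gene, DMR) association: `gene_id`,
#'   `chrom`, `dmr_start`, `dmr_end`, `direction`.
#' @export
associate_dmrs_with_genes <- function(dmrs, genes, upstream = 10000) {
  win <- gene_window(genes, upstream)
  if (nrow(dmrs) == 0 || nrow(win) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  dmr_start = integer(), dmr_end = integer(),
                  direction = character()))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_granges(dmrs), intervals_granges(win), ignore.strand = TRUE
  ))
  qi <- S4Vectors_from(hits, "query"); si <- S4Vectors_from(hits, "subject")
  tibble(
    gene_id = win$gene_id[si],
    chrom = dmrs$chrom[qi],
    dmr_start = dmrs$start[qi],
    dmr_end = dmrs$end[qi],
    direction = dmrs$direction[qi]
  ) |> distinct()
}

#' Genes whose promoter overlaps a DMR
#'
#' The promoter is the strand-aware 2 kb window from 2 kb upstream of
#' the TSS to the TSS.
#'
#' @param dmrs DMR tibble.
#' @param genes gene-model tibble.
#' @param direction optional filter: only DMRs of this direction
#'   (`"hyper"` or `"hypo"`) count.
#' @param upstream promoter size (bp).
#' @return character vector of gene ids.
#' @export
promoter_dmr_genes <- function(dmrs, genes, direction = NULL, upstream = 2000) {
  if (!is.null(direction)) dmrs <- filter(dmrs, .data$direction == !!direction)
  win <- promoter_window(genes, upstream)
  if (nrow(dmrs) == 0) return(character(0))
  hit <- intervals_overlap_any(win, dmrs)
  unique(win$gene_id[hit])
}
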