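#' Anchor-centred methylation profile
#'
#' Bins cytosine sites by signed offset from the centre of each anchor
#' interval (strand-aware for `+`/`-` anchors, unoriented for `.`) and
#' averages the observed methylation level per bin with its SEM over
#' sites. A site near several anchors contributes once per anchor.
#'
#' @param m methylome tibble.
#' @param anchors interval tibble (e.g. enhancers).
#' @param flank half-window around the anchor centre (bp).
#' @param n_bins number of offset bins.
#' @param min_cov minimum site coverage to contribute a level.
#' @return a `profile_curve` tibble: `bin`, `offset_mid` (bp), `mean`,
#'   `sem`, `n_sites`. Empty bins carry `mean = NA`, `n_sites = 0`.
#' @export
anchored_methylation_profile <- function(m, anchors, flank = 5000,
                                         n_bins = 50, min_cov = 5) {
  if (nrow(anchors) == 0) abort("empty anchor set")
  sites <- m |>
    mutate(cov = .data$meth + .data$unmeth,
           level = ifelse(.data$cov > 0, .data$meth / .data$cov, NA_real_)) |>
    filter(.data$cov >= min_cov)
  offs <- anchor_offsets(sites, anchors, flank)
  edges <- seq(-flank, flank, length.out = n_bins + 1)
  curve <- offs |>
    mutate(level = sites$level[.data$site],
           bin = offset_bin(.data$offset, flank, n_bins)) |>
    group_by(.data$bin) |>
    summarise(mean = mean(.data$level),
              sem = sd(.data$level) / sqrt(dplyr::n()),
              n_sites = dplyr::n(), .groups = "drop") |>
    complete(bin = seq_len(n_bins),
             fill = list(n_sites = 0L)) |>
    mutate(offset_mid = (edges[.data$bin] + edges[.data$bin + 1]) / 2) |>
    select("bin", "offset_mid", "mean", "sem", "n_sites")
  structure(curve, class = c("profile_curve", class(curve)),
            anchor_mode = "center", flank = flank)
}

# (site, anchor) pairs with the strand-aware signed offset from the centre
anchor_offsets <- function(sites, anchors, flank) {
  centers <- anchors |>
    mutate(center = floor((.data$start + .data$end) / 2),
           start = .data$center - flank,
           end = .data$center + flank)
  pairs <- site_interval_pairs(sites, centers)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep(".", nrow(anchors))
  pairs |>
    mutate(
      offset = (sites$pos[.data$site] - 1) - centers$center[.data$interval],
      offset = ifelse(strand[.data$interval] == "-", -.data$offset, .data$offset)
    ) |>
    filter(abs(.data$offset) <= flank)
}

offset_bin <- function(offset, flank, n_bins) {
  pmin(n_bins, pmax(1L, floor((offset + flank) / (2 * flank) * n_bins) + 1L))
}

#' DMS frequency profile around anchors, normalised to the genome average
#'
#' Per offset bin, the DMS fraction is the number of DMSs over the
#' number of tested sites in the bin; the curve is divided by the
#' genome-wide average fraction `|DMS| / |tested|`, so a uniform
#' scatter of DMSs gives ~1 everywhere.
#'
#' @param dms_sites tibble with `chrom`, `pos` of DMSs.
#' @param tested_sites tibble with `chrom`, `pos` of all tested sites.
#' @param anchors interval tibble.
#' @param flank,n_bins binning as in [anchored_methylation_profile()].
#' @return a `frequency_curve` tibble: `bin`, `offset_mid`, `n_dms`,
#'   `n_tested`, `fraction`, `normalized`; the genome average is the
#'   `"genome_average"` attribute (and a column).
#' @export
dms_frequency_profile <- function(dms_sites, tested_sites, anchors,
                                  flank = 5000, n_bins = 50) {
  if (nrow(dms_sites) == 0) abort("no DMSs: normalisation undefined")
  if (nrow(tested_sites) == 0) abort("no tested sites")
  if (nrow(anchors) == 0) abort("empty anchor set")
  genome_average <- nrow(dms_sites) / nrow(tested_sites)
  bin_counts <- function(sites) {
    anchor_offsets(sites |> mutate(site = dplyr::row_number()), anchors, flank) |>
      mutate(bin = offset_bin(.data$offset, flank, n_bins)) |>
      count(.data$bin)
  }
  edges <- seq(-flank, flank, length.out = n_bins + 1)
  dc <- bin_counts(dms_sites) |> rename(n_dms = "n")
  tc <- bin_counts(tested_sites) |> rename(n_tested = "n")
  curve <- tibble(bin = seq_len(n_bins)) |>
    left_join(dc, by = "bin") |>
    left_join(tc, by = "bin") |>
    mutate(
      n_dms = coalesce(.data$n_dms, 0L),
      n_tested = coalesce(.data$n_tested, 0L),
      fraction = ifelse(.data$n_tested > 0, .data$n_dms / .data$n_tested, NA_real_),
      genome_average = genome_average,
      normalized = .data$fraction / genome_average,
      offset_mid = (edges[.data$bin] + edges[.data$bin + 1]) / 2
    ) |>
    select("bin", "offset_mid", "n_dms", "n_tested", "fraction",
           "genome_average", "normalized")
  structure(curve, class = c("frequency_curve", class(curve)),
            genome_average = genome_average, flank = flank)
}

#' Gene-scaled methylation metaprofile
#'
#' The gene body (TSS..TES, strand-aware so the TSS is always on the
#' left) is linearly rescaled to `body_bins`; flanks of `flank` bp on
#' either side are binned in absolute coordinates (`flank_bins` each).
#' Per bin the read-weighted level `sum(meth) / sum(meth + unmeth)` is
#' reported, the appropriate summary for pooled counts.
#'
#' @param m methylome tibble.
#' @param genes gene-model tibble.
#' @param context `"CpG"` or `"CH"` (CHG + CHH, both strands).
#' @param flank flank width (bp).
#' @param body_bins,flank_bins bin counts.
#' @param min_cov minimum site coverage.
#' @param groups optional named vector gene_id -> group label; the
#'   profile is computed per group.
#' @return a `profile_curve` tibble: `group` (if given), `bin`,
#'   `region` (upstream/body/downstream), `mean`, `sem`, `n_sites`.
#' @export
scaled_gene_profile <- function(m, genes, context = c("CpG", "CH"),
                                flank = 100000, body_bins = 60,
                                flank_bins = 50, min_cov = 1,
                                groups = NULL) {
  context <- match.arg(context)
  ctx <- if (context == "CpG") "CpG" else c("CHG", "CHH")
  sites <- m |>
    filter(.data$context %in% ctx) |>
    mutate(cov = .data$meth + .data$unmeth) |>
    filter(.data$cov >= min_cov)
  span <- gene_span(genes) |>
    mutate(start = pmax(0L, .data$start - as.integer(flank)),
           end = .data$end + as.integer(flank))
  pairs <- site_interval_pairs(sites, span)
  if (nrow(pairs) == 0) abort("no sites near any gene")
  g <- genes[pairs$interval, ]
  pos <- sites$pos[pairs$site]
  body_len <- abs(g$tes - g$tss)
  td <- ifelse(g$strand == "+", pos - g$tss, g$tss - pos)  # transcription coords
  n_total <- flank_bins + body_bins + flank_bins
  bin <- integer(length(td))
  up <- td < 0
  body <- td >= 0 & td <= body_len
  down <- td > body_len
  bw <- flank / flank_bins
  bin[up] <- pmax(1L, flank_bins - floor((-td[up] - 1) / bw))
  bin[body] <- flank_bins +
    pmin(body_bins, floor(td[body] / pmax(body_len[body], 1) * body_bins) + 1L)
  bin[down] <- flank_bins + body_bins +
    pmin(flank_bins, floor((td[down] - body_len[down] - 1) / bw) + 1L)
  df <- tibble(
    bin = bin,
    meth = sites$meth[pairs$site],
    cov = sites$cov[pairs$site],
    level = sites$meth[pairs$site] / sites$cov[pairs$site],
    group = if (is.null(groups)) "all" else unname(groups[g$gene_id])
  ) |> filter(!is.na(.data$group))
  curve <- df |>
    group_by(.data$group, .data$bin) |>
    summarise(mean = sum(.data$meth) / sum(.data$cov),
              sem = sd(.data$level) / sqrt(dplyr::n()),
              n_sites = dplyr::n(), .groups = "drop") |>
    complete(group = unique(df$group), bin = seq_len(n_total),
             fill = list(n_sites = 0L)) |>
    mutate(region = case_when(
      .data$bin <= flank_bins ~ "upstream",
      .data$bin <= flank_bins + body_bins ~ "body",
      TRUE ~ "downstream"
    ))
  structure(curve, class = c("profile_curve", class(curve)),
            anchor_mode = "tss_tes_scaled",
            flank = flank, body_bins = body_bins, flank_bins = flank_bins)
}

#' Partition genes into expression groups
#'
#' Genes below the `not_expressed_below` TPM threshold are `"none"`;
#' the rest are ranked (ties broken by gene id for determinism) and
#' split into three groups of near-equal size -- `"low"`, `"mid"`,
#' `"high"` -- with remainders assigned to the lower groups first
#' (301 expressed genes give 101/100/100).
#'
#' @param expr tibble with `gene_id` and one or more numeric TPM
#'   columns (averaged when several).
#' @param not_expressed_below TPM threshold for `"none"`.
#' @return tibble: `gene_id`, `tpm`, `group` (factor
#'   none < low < mid < high).
#' @export
expression_groups <- function(expr, not_expressed_below = 1.0) {
  is_num <- vapply(expr, is.numeric, logical(1)) & names(expr) != "gene_id"
  if (!any(is_num)) abort("no numeric expression columns")
  tpm <- rowMeans(as.matrix(expr[is_num]))
  out <- tibble(gene_id = expr$gene_id, tpm = tpm,
                group = "none")
  idx <- which(tpm >= not_expressed_below)
  n <- length(idx)
  if (n > 0) {
    ord <- idx[order(tpm[idx], expr$gene_id[idx])]
    base <- n %/% 3L; rem <- n %% 3L
    sizes <- c(base + (rem >= 1), base + (rem >= 2), base)
    out$group[ord] <- rep(c("low", "mid", "high"), times = sizes)
  }
  out$group <- factor(out$group, levels = c("none", "low", "mid", "high"))
  out
}

#' Fold-change filter for expression tables
#'
#' Keeps genes whose pseudocounted fold change between two conditions
#' is at least `min_fc` in either direction:
#' `|log((b + pc) / (a + pc))| >= log(min_fc)`.
#'
#' @param expr tibble with `gene_id` and two numeric columns, or the
#'   columns given by `a` / `b`.
#' @param a,b column names of the two conditions.
#' @param min_fc minimum fold change.
#' @param pseudocount added to both sides before the ratio.
#' @return character vector of gene ids passing the filter.
#' @export
fold_change_filter <- function(expr, a = "a", b = "b", min_fc = 1.5,
                               pseudocount = 1) {
  va <- expr[[a]]; vb <- expr[[b]]
  lfc <- log(vb + pseudocount) - log(va + pseudocount)
  keep <- abs(lfc) >= log(min_fc) - 1e-9
  expr$gene_id[keep & !is.na(keep)]
}
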