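#' Compartment enrichment of foreground sites
#'
#' For each labelled compartment, builds the 2x2 table (foreground
#' in/out x background in/out) and reports the odds ratio and two-sided
#' Fisher p. A site overlapping several compartments counts in each.
#' The natural background is the set of all tested CpG sites minus the
#' foreground (coverage-matched, so enrichment is not confounded by
#' coverage).
#'
#' @param fg_sites tibble with `chrom`, `pos` (e.g. DMS positions).
#' @param compartments interval tibble with a `label` column.
#' @param bg_sites tibble with `chrom`, `pos` (control sites).
#' @return tibble per label: `label`, `n_hit_fg`, `n_fg`, `n_hit_bg`,
#'   `n_bg`, `odds_ratio`, `p`, `q` (BH across labels).
#' @export
compartment_enrichment <- function(fg_sites, compartments, bg_sites) {
  if (nrow(fg_sites) == 0) abort("empty foreground site set")
  labels <- unique(compartments$label)
  res <- map(labels, function(lb) {
    iv <- filter(compartments, .data$label == lb)
    hit_fg <- sum(sites_in_intervals(fg_sites, iv))
    hit_bg <- sum(sites_in_intervals(bg_sites, iv))
    n_fg <- nrow(fg_sites); n_bg <- nrow(bg_sites)
    ft <- fisher_exact_two_sided(hit_fg, n_fg - hit_fg, hit_bg, n_bg - hit_bg)
    tibble(label = lb, n_hit_fg = hit_fg, n_fg = n_fg,
           n_hit_bg = hit_bg, n_bg = n_bg,
           odds_ratio = ft$odds_ratio, p = ft$p)
  }) |> list_rbind()
  mutate(res, q = p.adjust(.data$p, method = "BH"))
}

#' Cell-type-specific methylation sites from a panel
#'
#' Runs every pairwise DMS comparison in the panel with [call_dms()]
#' (each with its own FDR calibration). A site is hyper-specific for
#' cell type T when it is a significant DMS with T-higher methylation
#' in at least `min_frac` of the pairwise comparisons involving T in
#' which the site was testable; hypo-specific analogously.
#'
#' @param panel named list of >= 3 methylome tibbles.
#' @param min_cov,alpha,fdr,n_bins passed to [call_dms()].
#' @param min_frac required fraction of supporting comparisons
#'   (0.75: at least 3 of 4 in a five-methylome panel).
#' @return tibble: `cell_type`, `chrom`, `pos`, `direction`
#'   (`hyper`/`hypo`), `n_support`, `n_tested`.
#' @export
celltype_specific_sites <- function(panel, min_cov = 10, alpha = 0.05,
                                    min_frac = 0.75, fdr = "adaptive",
                                    n_bins = 20) {
  k <- length(panel)
  if (k < 3) abort("panel needs at least 3 methylomes")
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    abort("panel methylomes must be named")
  }
  types <- names(panel)
  pairs <- utils::combn(k, 2)
  evid <- vector("list", 2L * ncol(pairs))
  e <- 0L
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- call_dms(panel[[i1]], panel[[i2]], min_cov = min_cov,
                    alpha = alpha, fdr = fdr, n_bins = n_bins)
    s <- res$sites
    # delta = level_2 - level_1
    e <- e + 1L
    evid[[e]] <- tibble(cell_type = types[i1], chrom = s$chrom, pos = s$pos,
                        hyper = s$is_dms & s$delta < 0,
                        hypo = s$is_dms & s$delta > 0)
    e <- e + 1L
    evid[[e]] <- tibble(cell_type = types[i2], chrom = s$chrom, pos = s$pos,
                        hyper = s$is_dms & s$delta > 0,
                        hypo = s$is_dms & s$delta < 0)
  }
  eps <- 1e-12
  bind_rows(evid) |>
    group_by(.data$cell_type, .data$chrom, .data$pos) |>
    summarise(n_tested = dplyr::n(), n_hyper = sum(.data$hyper),
              n_hypo = sum(.data$hypo), .groups = "drop") |>
    mutate(
      direction = case_when(
        .data$n_hyper / .data$n_tested >= min_frac - eps ~ "hyper",
        .data$n_hypo / .data$n_tested >= min_frac - eps ~ "hypo",
        TRUE ~ NA_character_
      ),
      n_support = pmax(.data$n_hyper, .data$n_hypo)
    ) |>
    filter(!is.na(.data$direction)) |>
    select("cell_type", "chrom", "pos", "direction", "n_support", "n_tested") |>
    arrange(.data$cell_type, .data$chrom, .data$pos)
}

#' DMR enrichment on cell-type-specific sites
#'
#' For each (cell type, direction) site set, counts how many sites lie
#' inside at least one DMR; the control is the entire pool of
#' cell-type-specific sites. Reports the fold enrichment (hit rate in
#' the set over hit rate in the pool) and a Fisher odds ratio / p
#' comparing the set against the rest of the pool.
#'
#' @param dmrs DMR tibble.
#' @param site_sets output of [celltype_specific_sites()].
#' @return tibble per (cell type, direction): counts, `fold`,
#'   `odds_ratio`, `p`, `q`.
#' @export
dmr_enrichment_on_celltype_sites <- function(dmrs, site_sets) {
  pool <- distinct(site_sets, .data$chrom, .data$pos)
  if (nrow(pool) == 0) abort("empty cell-type-specific site pool")
  pool$in_dmr <- sites_in_intervals(pool, dmrs)
  n_bg <- nrow(pool); hit_bg <- sum(pool$in_dmr)
  groups <- distinct(site_sets, .data$cell_type, .data$direction)
  res <- pmap(groups, function(cell_type, direction) {
    fg <- site_sets |>
      filter(.data$cell_type == !!cell_type, .data$direction == !!direction) |>
      distinct(.data$chrom, .data$pos) |>
      left_join(pool, by = c("chrom", "pos"))
    n_fg <- nrow(fg); hit_fg <- sum(fg$in_dmr)
    if (n_fg == 0 || hit_bg == 0) {
      return(tibble(cell_type = cell_type, direction = direction,
                    n_hit_fg = hit_fg, n_fg = n_fg,
                    n_hit_bg = hit_bg, n_bg = n_bg,
                    fold = NA_real_, odds_ratio = NA_real_, p = NA_real_))
    }
    rest_hit <- hit_bg - hit_fg
    rest_n <- n_bg - n_fg
    ft <- fisher_exact_two_sided(hit_fg, n_fg - hit_fg,
                                 rest_hit, rest_n - rest_hit)
    tibble(cell_type = cell_type, direction = direction,
           n_hit_fg = hit_fg, n_fg = n_fg, n_hit_bg = hit_bg, n_bg = n_bg,
           fold = (hit_fg / n_fg) / (hit_bg / n_bg),
           odds_ratio = ft$odds_ratio, p = ft$p)
  }) |> list_rbind()
  mutate(res, q = p.adjust(.data$p, method = "BH"))
}

#' Binomial test of DMS overlap with TF binding sites
#'
#' The null overlap probability `p0` is the fraction of control sites
#' (covered but not differentially methylated) inside the TF interval
#' set; the p-value is the upper binomial tail at the observed DMS
#' overlap count. A degenerate `p0 = 0` with observed hits is floored
#' at `1 / (2 * n_control)`.
#'
#' @param dms_sites tibble with `chrom`, `pos` of DMSs.
#' @param tf_sites interval tibble of TF binding sites.
#' @param control_sites tibble with `chrom`, `pos` of control CpGs.
#' @return one-row tibble: counts, `p0`, `p`.
#' @export
tf_overlap_binomial <- function(dms_sites, tf_sites, control_sites) {
  if (nrow(control_sites) == 0) abort("empty control site set")
  n <- nrow(dms_sites)
  k <- sum(sites_in_intervals(dms_sites, tf_sites))
  hit_ctrl <- sum(sites_in_intervals(control_sites, tf_sites))
  p0 <- hit_ctrl / nrow(control_sites)
  if (p0 == 0 && k > 0) p0 <- 1 / (2 * nrow(control_sites))
  p <- if (k == 0) 1 else pbinom(k - 1, n, p0, lower.tail = FALSE)
  tibble(n_hit_fg = k, n_fg = n, n_hit_bg = hit_ctrl,
         n_bg = nrow(control_sites), p0 = p0, p = p)
}
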