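#' Build the DMS level matrix for co-methylation analysis
#'
#' Preprocessing before module discovery: (1) keep DMS loci inside the
#' strand-aware window from 10 kb upstream of a TSS to the TES of at
#' least one gene; (2) chain-merge loci at most `merge_gap` bp apart,
#' the merged locus level per methylome being the coverage-weighted
#' mean (total meth / total coverage); (3) drop loci with a missing
#' level in any methylome. A provenance log records the locus count
#' after each step.
#'
#' @param dms_sites tibble with `chrom`, `pos` of DMS loci.
#' @param genes gene-model tibble.
#' @param panel named list of methylome tibbles.
#' @param merge_gap maximum distance for merging neighbouring loci (bp).
#' @param upstream upstream window before the TSS (bp).
#' @return a `dms_matrix` object: list with `levels` (numeric matrix,
#'   loci x methylomes), `loci` (tibble: `locus`, `chrom`, `start`,
#'   `end`), `provenance` (tibble: `step`, `n_loci`).
#' @export
preprocess_dms_matrix <- function(dms_sites, genes, panel, merge_gap = 200,
                                  upstream = 10000) {
  if (is.null(names(panel))) abort("panel methylomes must be named")
  prov <- tibble(step = "input", n_loci = nrow(dms_sites))
  win <- gene_window(genes, upstream)
  keep <- sites_in_intervals(dms_sites, win)
  sel <- dms_sites[keep, ]
  prov <- add_row(prov, step = "within TSS-10kb..TES", n_loci = nrow(sel))
  if (nrow(sel) == 0) abort("no DMS loci remain after the gene-window filter")
  merged <- sel |>
    arrange(.data$chrom, .data$pos) |>
    mutate(grp = cumsum(.data$chrom != coalesce(lag(.data$chrom), "") |
                          .data$pos - coalesce(lag(.data$pos), .data$pos) > merge_gap)) |>
    group_by(.data$grp) |>
    summarise(chrom = .data$chrom[1], start = min(.data$pos) - 1L,
              end = max(.data$pos), .groups = "drop") |>
    mutate(locus = paste0(.data$chrom, ":", .data$start, "-", .data$end)) |>
    select("locus", "chrom", "start", "end")
  prov <- add_row(prov, step = paste0("merged within ", merge_gap, " bp"),
                  n_loci = nrow(merged))
  lvl <- vapply(panel, function(m) {
    pr <- site_interval_pairs(m, merged)
    agg <- tibble(interval = pr$interval,
                  meth = m$meth[pr$site],
                  cov = m$meth[pr$site] + m$unmeth[pr$site]) |>
      group_by(.data$interval) |>
      summarise(level = ifelse(sum(.data$cov) > 0,
                               sum(.data$meth) / sum(.data$cov), NA_real_),
                .groups = "drop")
    out <- rep(NA_real_, nrow(merged))
    out[agg$interval] <- agg$level
    out
  }, numeric(nrow(merged)))
  lvl <- matrix(lvl, nrow = nrow(merged),
                dimnames = list(merged$locus, names(panel)))
  ok <- complete.cases(lvl)
  lvl <- lvl[ok, , drop = FALSE]
  merged <- merged[ok, ]
  prov <- add_row(prov, step = "complete across methylomes", n_loci = nrow(merged))
  if (nrow(merged) < 2) abort("fewer than 2 loci remain after the missing-data filter")
  if (ncol(lvl) < 3) abort("need at least 3 methylomes")
  structure(list(levels = lvl, loci = merged, provenance = prov),
            class = "dms_matrix")
}

#' Soft-threshold correlation adjacency
#'
#' Unsigned weighted-network adjacency `|cor(row_i, row_j)|^power`
#' between locus level profiles across methylomes.
#'
#' @param mat numeric matrix (loci x methylomes) or a `dms_matrix`.
#' @param power soft-threshold exponent.
#' @return symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
correlation_adjacency <- function(mat, power = 6) {
  if (inherits(mat, "dms_matrix")) mat <- mat$levels
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant level rows (undefined correlation): ",
                 paste(head(rownames(mat)[sds == 0], 5), collapse = ", ")))
  }
  a <- abs(cor(t(mat)))^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM(i,j) = (sum_u a(i,u) a(u,j) + a(i,j)) / (min(k_i, k_j) + 1 - a(i,j))`
#' with connectivities `k` = adjacency row sums excluding the diagonal.
#' Shared-neighbourhood smoothing of the adjacency; `TOM(i,i) = 1`.
#'
#' @param adjacency symmetric adjacency matrix in `[0, 1]`.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-methylation modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut statically at `cut_height`; clusters smaller than
#' `min_module_size` are left unassigned (module 0). Each module's
#' eigen-profile is the first principal component of its
#' row-standardised level submatrix (a unit vector over methylomes),
#' sign-oriented to correlate positively with the module's mean level
#' profile.
#'
#' @param tom TOM matrix (rownames = loci).
#' @param mat level matrix used for eigen-profiles (loci x methylomes);
#'   a `dms_matrix` is accepted.
#' @param min_module_size smallest admissible module.
#' @param cut_height static tree-cut height on `1 - TOM`.
#' @return a `module_assignment`: list with `assignment` (tibble:
#'   `locus`, `module`; 0 = unassigned), `eigen` (methylomes x modules
#'   matrix), `sizes`.
#' @export
detect_modules <- function(tom, mat, min_module_size = 30, cut_height = 0.75) {
  if (inherits(mat, "dms_matrix")) mat <- mat$levels
  loci <- rownames(mat)
  if (nrow(mat) < min_module_size) {
    warn("fewer loci than min_module_size: nothing assignable")
    return(new_module_assignment(tibble(locus = loci, module = 0L), mat))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  lab <- ifelse(raw %in% keep, raw, 0L)
  lab <- relabel_by_size(lab)
  new_module_assignment(tibble(locus = loci, module = lab), mat)
}

relabel_by_size <- function(lab) {
  mods <- setdiff(unique(lab), 0L)
  if (length(mods) == 0) return(lab)
  sizes <- vapply(mods, function(m) sum(lab == m), integer(1))
  new_ids <- setNames(seq_along(mods), mods[order(-sizes, mods)])
  ifelse(lab == 0L, 0L, as.integer(new_ids[as.character(lab)]))
}

module_eigenprofile <- function(mat, idx) {
  x <- mat[idx, , drop = FALSE]
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  v <- drop(sv$v)
  mp <- colMeans(x)
  if (stats::var(mp) > 0 && cor(v, mp) < 0) v <- -v
  v
}

new_module_assignment <- function(assignment, mat) {
  mods <- sort(setdiff(unique(assignment$module), 0L))
  eig <- if (length(mods) > 0) {
    vapply(mods, function(mm) {
      module_eigenprofile(mat, which(assignment$module == mm))
    }, numeric(ncol(mat)))
  } else {
    matrix(numeric(0), nrow = ncol(mat), ncol = 0)
  }
  eig <- matrix(eig, nrow = ncol(mat),
                dimnames = list(colnames(mat), as.character(mods)))
  sizes <- vapply(mods, function(mm) sum(assignment$module == mm), integer(1))
  structure(list(assignment = assignment, eigen = eig,
                 sizes = setNames(sizes, as.character(mods))),
            class = "module_assignment")
}

#' Merge modules with highly correlated eigen-profiles
#'
#' Iteratively merges the module pair with the largest eigen-profile
#' correlation at or above `merge_corr` (ties broken towards smaller
#' module ids), recomputing eigen-profiles after each merge, until no
#' pair qualifies.
#'
#' @param x a `module_assignment`.
#' @param mat level matrix (or `dms_matrix`) the assignment refers to.
#' @param merge_corr correlation threshold for merging.
#' @return updated `module_assignment` (ids relabelled by size).
#' @export
merge_close_modules <- function(x, mat, merge_corr = 0.75) {
  if (inherits(mat, "dms_matrix")) mat <- mat$levels
  lab <- x$assignment$module
  repeat {
    mods <- sort(setdiff(unique(lab), 0L))
    if (length(mods) < 2) break
    eig <- vapply(mods, function(mm) module_eigenprofile(mat, which(lab == mm)),
                  numeric(ncol(mat)))
    cc <- cor(eig)
    diag(cc) <- -Inf
    best <- -Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(mods)) {
      for (j in seq_along(mods)) {
        if (j <= i) next
        if (cc[i, j] > best + 1e-12) { best <- cc[i, j]; bi <- i; bj <- j }
      }
    }
    if (best < merge_corr) break
    lab[lab == mods[bj]] <- mods[bi]
  }
  lab <- relabel_by_size(lab)
  new_module_assignment(tibble(locus = x$assignment$locus, module = lab), mat)
}

#' Full co-methylation module pipeline
#'
#' Adjacency, TOM, average-linkage modules, eigen-profile merging.
#' For inputs larger than `max_block` loci, a two-level scheme
#' pre-partitions loci into blocks (k-means on level profiles with
#' deterministic seeding along the leading principal component),
#' detects modules per block, and merges correlated modules across
#' blocks; module discovery itself involves no randomness.
#'
#' @param dmat a `dms_matrix` (or plain loci x methylomes matrix).
#' @param power soft-threshold exponent.
#' @param min_module_size,cut_height,merge_corr see
#'   [detect_modules()] / [merge_close_modules()].
#' @param max_block largest block clustered in one piece.
#' @return a `module_assignment`.
#' @export
comethylation_modules <- function(dmat, power = 6, min_module_size = 30,
                                  cut_height = 0.75, merge_corr = 0.75,
                                  max_block = 5000) {
  mat <- if (inherits(dmat, "dms_matrix")) dmat$levels else dmat
  n <- nrow(mat)
  blocks <- if (n <= max_block) {
    list(seq_len(n))
  } else {
    nb <- ceiling(n / max_block)
    pc1 <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = 1)$x[, 1]
    ord <- order(pc1)
    centers <- mat[ord[round(seq(1, n, length.out = nb + 2))[2:(nb + 1)]], , drop = FALSE]
    km <- kmeans(mat, centers = centers, iter.max = 50, nstart = 1)
    split(seq_len(n), km$cluster)
  }
  lab <- integer(n)
  offset <- 0L
  for (b in blocks) {
    sub <- mat[b, , drop = FALSE]
    if (nrow(sub) < 2) next
    adj <- correlation_adjacency(sub, power = power)
    tom <- topological_overlap(adj)
    asg <- detect_modules(tom, sub, min_module_size = min_module_size,
                          cut_height = cut_height)
    bl <- asg$assignment$module
    lab[b] <- ifelse(bl == 0L, 0L, bl + offset)
    offset <- offset + max(0L, max(bl))
  }
  asg <- new_module_assignment(tibble(locus = rownames(mat),
                                      module = relabel_by_size(lab)), mat)
  merge_close_modules(asg, mat, merge_corr = merge_corr)
}

#' Per-module methylation summary across methylomes
#'
#' @param x a `module_assignment`.
#' @param mat level matrix (or `dms_matrix`).
#' @return tidy tibble: `module`, `methylome`, `mean`, `sd`, `n_loci`.
#' @export
module_profile_summary <- function(x, mat) {
  if (inherits(mat, "dms_matrix")) mat <- mat$levels
  mods <- sort(setdiff(unique(x$assignment$module), 0L))
  map(mods, function(mm) {
    sub <- mat[x$assignment$module == mm, , drop = FALSE]
    tibble(module = mm, methylome = colnames(mat),
           mean = unname(colMeans(sub)),
           sd = unname(apply(sub, 2, sd)),
           n_loci = nrow(sub))
  }) |> list_rbind()
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("<module_assignment>\n")
  cat("  loci:", nrow(x$assignment), "\n")
  cat("  modules:", length(x$sizes),
      if (length(x$sizes) > 0) paste0("(sizes ", paste(x$sizes, collapse = ", "), ")") else "", "\n")
  cat("  unassigned:", sum(x$assignment$module == 0L), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.module_assignment <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
glance.module_assignment <- function(x, ...) {
  tibble(n_loci = nrow(x$assignment),
         n_modules = length(x$sizes),
         n_unassigned = sum(x$assignment$module == 0L))
}
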