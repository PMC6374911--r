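#' Construct and validate a methylome table
#'
#' A methylome is a tibble of cytosine sites with columns `chrom`,
#' `pos` (1-based), `strand` (`+`/`-`), `context` (`CpG`, `CHG`, `CHH`),
#' `meth` and `unmeth` (read counts). Sites with `meth + unmeth == 0`
#' are present but *missing* (no observed methylation level), which is
#' distinct from a level of 0. Rows are sorted by `(chrom, pos, strand)`
#' and unique on that key.
#'
#' @param sites tibble (or data frame) with the columns above.
#' @param name sample name, stored as the `"name"` attribute.
#' @param genome_id identifier of the reference the positions refer to.
#' @return a validated methylome tibble.
#' @export
as_methylome <- function(sites, name = NULL, genome_id = NULL) {
  sites <- as_tibble(sites)
  need <- c("chrom", "pos", "strand", "context", "meth", "unmeth")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("methylome is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(sites$meth < 0 | sites$unmeth < 0)) {
    abort("negative read counts in methylome")
  }
  if (!all(sites$strand %in% c("+", "-"))) {
    abort("methylome strand must be '+' or '-'")
  }
  sites <- arrange(sites, .data$chrom, .data$pos, .data$strand)
  if (anyDuplicated(sites[c("chrom", "pos", "strand")]) > 0) {
    abort("duplicate (chrom, pos, strand) in methylome")
  }
  if (!is.null(name)) attr(sites, "name") <- name
  if (!is.null(genome_id)) attr(sites, "genome_id") <- genome_id
  sites
}

#' Observed methylation level of each site
#'
#' `meth / (meth + unmeth)`, `NA` for uncovered (missing) sites.
#'
#' @param m methylome tibble.
#' @return numeric vector in `[0, 1]` (or `NA`).
#' @export
methylation_level <- function(m) {
  cov <- m$meth + m$unmeth
  ifelse(cov > 0, m$meth / cov, NA_real_)
}

#' Read a Bismark-style per-cytosine report
#'
#' Expects tab-separated columns: chrom, pos (1-based), strand,
#' count methylated, count unmethylated, context, trinucleotide.
#'
#' @param path file path.
#' @param context_filter contexts to retain (subset of CpG/CHG/CHH).
#' @param name,genome_id passed to [as_methylome()].
#' @return a methylome tibble.
#' @export
read_cytosine_report <- function(path, context_filter = c("CpG", "CHG", "CHH"),
                                 name = NULL, genome_id = NULL) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(as_methylome(
      tibble(chrom = character(), pos = integer(), strand = character(),
             context = character(), meth = integer(), unmeth = integer()),
      name = name, genome_id = genome_id
    ))
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  meth <- suppressWarnings(as.integer(raw$meth))
  unmeth <- suppressWarnings(as.integer(raw$unmeth))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth) |
                 !(raw$strand %in% c("+", "-")) |
                 !(raw$context %in% c("CpG", "CHG", "CHH")))
  if (length(bad) > 0) {
    abort(paste0("malformed cytosine-report lines: ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""))
  }
  if (any(meth < 0 | unmeth < 0)) {
    abort(paste0("negative counts at line ",
                 which(meth < 0 | unmeth < 0)[1]))
  }
  # positions must be non-decreasing within each chromosome block
  off <- which(raw$chrom == dplyr::lag(raw$chrom) & pos < dplyr::lag(pos))
  if (length(off) > 0) {
    abort(paste0("cytosine report unsorted within chromosome at line ", off[1]))
  }
  out <- tibble(chrom = raw$chrom, pos = pos, strand = raw$strand,
                context = raw$context, meth = meth, unmeth = unmeth) |>
    filter(.data$context %in% context_filter)
  as_methylome(out, name = name, genome_id = genome_id)
}

#' Write a per-cytosine report
#'
#' Inverse of [read_cytosine_report()] (trinucleotide column is written
#' as the context's canonical representative when not supplied).
#'
#' @param m methylome tibble.
#' @param path output file.
#' @export
write_cytosine_report <- function(m, path) {
  tri <- c(CpG = "CGG", CHG = "CAG", CHH = "CAT")[m$context]
  readr::write_tsv(
    tibble(m$chrom, m$pos, m$strand, m$meth, m$unmeth, m$context, tri),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Collapse symmetric CpG dyads onto the plus strand
#'
#' A plus-strand CpG at position `p` and the minus-strand CpG of the same
#' dyad at `p + 1` are summed into one plus-strand record at `p`.
#' Unpaired sites pass through unchanged. CpG methylation is symmetric,
#' so both strands measure the same epiallele; CH sites should be left
#' stranded and are not touched.
#'
#' @param m methylome tibble.
#' @return methylome tibble with merged CpG dyads.
#' @export
merge_symmetric_cpg <- function(m) {
  name <- attr(m, "name"); genome_id <- attr(m, "genome_id")
  cpg <- filter(m, .data$context == "CpG")
  other <- filter(m, .data$context != "CpG")
  plus <- filter(cpg, .data$strand == "+")
  minus <- filter(cpg, .data$strand == "-")
  j <- minus |>
    mutate(plus_pos = .data$pos - 1L) |>
    select("chrom", "plus_pos", minus_meth = "meth", minus_unmeth = "unmeth")
  merged <- plus |>
    left_join(j, by = c("chrom", pos = "plus_pos")) |>
    mutate(
      meth = .data$meth + coalesce(.data$minus_meth, 0L),
      unmeth = .data$unmeth + coalesce(.data$minus_unmeth, 0L),
      paired = !is.na(.data$minus_meth) | !is.na(.data$minus_unmeth)
    )
  paired_minus_pos <- merged |>
    filter(.data$paired) |>
    transmute(.data$chrom, pos = .data$pos + 1L)
  minus_left <- minus |> anti_join(paired_minus_pos, by = c("chrom", "pos"))
  out <- bind_rows(
    merged |> select("chrom", "pos", "strand", "context", "meth", "unmeth"),
    minus_left, other
  )
  as_methylome(out, name = name, genome_id = genome_id)
}

#' Read a BED file of labelled intervals
#'
#' BED3 or more; 0-based half-open. Column 4 (name), if present, becomes
#' `label`; columns 5 and 6 become `score` and `strand`.
#'
#' @param path file path.
#' @return tibble with `chrom`, `start`, `end`, `label`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  start <- suppressWarnings(as.double(raw[[2]]))
  end <- suppressWarnings(as.double(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0) {
    abort(paste0("invalid BED interval (start >= end or non-numeric) at line ", bad[1]))
  }
  tibble(
    chrom = raw[[1]],
    start = as.integer(start),
    end = as.integer(end),
    label = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
    score = if (ncol(raw) >= 5) suppressWarnings(as.double(raw[[5]])) else NA_real_,
    strand = if (ncol(raw) >= 6) ifelse(raw[[6]] %in% c("+", "-"), raw[[6]], ".") else "."
  )
}

#' Write intervals as BED
#'
#' @param intervals tibble with at least `chrom`, `start`, `end`; `label`,
#'   `score` and `strand` are written when present.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  out <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    label = if ("label" %in% names(intervals)) intervals$label else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or minimal GTF
#'
#' Genes are stored in transcription order: `tss` and `tes` are 1-based
#' genomic positions of the transcription start and end; for minus-strand
#' genes `tss > tes`. This makes strand-aware windows ("10 kb upstream of
#' the TSS") unambiguous; genomic min/max are recovered with
#' [gene_span()].
#'
#' @param path file path; format guessed from content (`.gtf`-style lines
#'   with a `gene_id` attribute, otherwise BED).
#' @return tibble with `gene_id`, `chrom`, `strand`, `tss`, `tes` and an
#'   `exons` list-column of 0-based half-open intervals (BED12 only).
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\tgene\t", first) || grepl("gene_id", first)) {
    read_genes_gtf(path)
  } else {
    read_genes_bed12(path)
  }
}

read_genes_bed12 <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(bed) < 6) abort("gene BED needs at least 6 columns (name and strand)")
  start <- as.integer(bed[[2]]); end <- as.integer(bed[[3]])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) abort(paste0("invalid gene interval at line ", bad[1]))
  strand <- bed[[6]]
  if (!all(strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  exons <- if (ncol(bed) >= 12) {
    pmap(list(start, bed[[11]], bed[[12]]), function(s, sizes, offs) {
      sz <- as.integer(strsplit(sizes, ",")[[1]])
      of <- as.integer(strsplit(offs, ",")[[1]])
      tibble(start = s + of, end = s + of + sz)
    })
  } else {
    rep(list(NULL), nrow(bed))
  }
  tibble(
    gene_id = bed[[4]],
    chrom = bed[[1]],
    strand = strand,
    tss = ifelse(strand == "+", start + 1L, end),
    tes = ifelse(strand == "+", end, start + 1L),
    exons = exons
  )
}

read_genes_gtf <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  genes <- raw[raw[[3]] == "gene", ]
  if (nrow(genes) == 0) abort("no 'gene' feature lines in GTF")
  gid <- sub('.*gene_id[ ="]+([^";]+).*', "\\1", genes[[9]])
  start <- as.integer(genes[[4]]); end <- as.integer(genes[[5]])
  strand <- genes[[7]]
  if (!all(strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  tibble(
    gene_id = gid,
    chrom = genes[[1]],
    strand = strand,
    tss = ifelse(strand == "+", start, end),
    tes = ifelse(strand == "+", end, start),
    exons = rep(list(NULL), nrow(genes))
  )
}

#' Genomic span of gene models
#'
#' @param genes gene-model tibble from [read_gene_models()].
#' @return interval tibble (`chrom`, `start`, `end`, `label`, `strand`),
#'   0-based half-open from leftmost to rightmost transcribed base.
#' @export
gene_span <- function(genes) {
  tibble(
    chrom = genes$chrom,
    start = pmin(genes$tss, genes$tes) - 1L,
    end = pmax(genes$tss, genes$tes),
    label = genes$gene_id,
    strand = genes$strand
  )
}

#' Write gene models as BED6
#' @param genes gene-model tibble.
#' @param path output file.
#' @export
write_gene_bed <- function(genes, path) {
  sp <- gene_span(genes)
  write_bed(mutate(sp, score = 0), path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Each record is a `>ID name` header followed by four rows (A, C, G, T)
#' of non-negative counts, with or without the `A [ ... ]` decoration.
#'
#' @param path file path.
#' @param background base frequencies (A, C, G, T) attached to each PWM.
#' @return list of `pwm` objects (`motif_id`, `name`, `counts` 4xL matrix,
#'   `background`).
#' @export
read_pfm <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort("no '>' headers in PFM file")
  ends <- c(hdr[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(hdr), function(ri) {
    h <- hdr[ri]; e <- ends[ri]
    body <- lines[(h + 1):e]
    if (length(body) != 4) {
      abort(paste0("PFM record at line ", h, " must have 4 matrix rows"))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
      if (anyNA(vals)) abort(paste0("non-numeric PFM row after line ", h))
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      abort(paste0("PFM rows of unequal length in record at line ", h))
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    if (any(mat < 0)) abort("negative PFM entries")
    tok <- strsplit(sub("^>", "", lines[h]), "[ \t]+")[[1]]
    new_pwm(motif_id = tok[1],
            name = if (length(tok) > 1) paste(tok[-1], collapse = " ") else tok[1],
            counts = mat, background = background)
  })
  names(pwms) <- map_chr(pwms, "motif_id")
  pwms
}

#' Write PWMs in JASPAR text format
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @export
write_pfm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  txt <- unlist(map(pwms, function(p) {
    c(paste0(">", p$motif_id, " ", p$name),
      map_chr(1:4, function(i) {
        paste0(c("A", "C", "G", "T")[i], " [ ",
               paste(format(p$counts[i, ], trim = TRUE), collapse = " "), " ]")
      }))
  }))
  writeLines(txt, path)
  invisible(path)
}

#' Write and read the DMS table
#'
#' TSV layout: chrom, pos, levelA, levelB, delta, p, p_adj, covA, covB.
#'
#' @param records DMS tibble (from [call_dms()], `$sites`).
#' @param path output file.
#' @export
write_dms_table <- function(records, path) {
  out <- tibble(
    chrom = records$chrom, pos = records$pos,
    levelA = records$level_a, levelB = records$level_b,
    delta = records$delta, p = records$p, p_adj = records$p_adj,
    covA = records$cov_a, covB = records$cov_b
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dms_table
#' @export
read_dms_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cidddddii", progress = FALSE)
  tibble(
    chrom = raw$chrom, pos = raw$pos,
    level_a = raw$levelA, level_b = raw$levelB, delta = raw$delta,
    p = raw$p, p_adj = raw$p_adj, cov_a = raw$covA, cov_b = raw$covB
  )
}

#' Write and read DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (mean |delta|), strand (`.`),
#' then n_dms, direction, frac_dms_consistent, frac_cpg_consistent.
#'
#' @param records DMR tibble (from [call_dmrs()]).
#' @param path output file.
#' @export
write_dmr_bed <- function(records, path) {
  out <- tibble(
    chrom = records$chrom, start = records$start, end = records$end,
    name = paste0("dmr_", seq_len(nrow(records))),
    score = abs(records$mean_delta),
    strand = ".",
    n_dms = records$n_dms,
    direction = records$direction,
    frac_dms_consistent = records$frac_dms_consistent,
    frac_cpg_consistent = records$frac_cpg_consistent
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "n_dms", "direction", "frac_dms_consistent", "frac_cpg_consistent"),
    col_types = "ciicdcicdd", progress = FALSE
  )
  tibble(
    chrom = raw$chrom, start = raw$start, end = raw$end,
    n_dms = raw$n_dms, direction = raw$direction,
    frac_dms_consistent = raw$frac_dms_consistent,
    frac_cpg_consistent = raw$frac_cpg_consistent,
    mean_delta = ifelse(raw$direction == "hyper", raw$score, -raw$score)
  )
}
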