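# CNVR assembly: per-tool regions with call-density trimming, >=2-tool
# consensus, breed-sharing / region-completeness rules, exclusive regions,
# and summary statistics.

.cnvr_df <- function(chrom = character(0), start = numeric(0), end = numeric(0),
                     cnvr_type = character(0), tools = character(0),
                     samples = character(0), n_calls = integer(0)) {
  df <- data.frame(cnvr_id = seq_along(chrom), chrom = chrom, start = start,
                   end = end, cnvr_type = cnvr_type, tools = tools,
                   samples = samples, n_calls = as.integer(n_calls),
                   stringsAsFactors = FALSE)
  class(df) <- c("cnvr", "data.frame")
  df
}

.renumber_cnvrs <- function(df) {
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start, df$end, df$cnvr_type), , drop = FALSE]
    df$cnvr_id <- seq_len(nrow(df))
    rownames(df) <- NULL
  }
  class(df) <- c("cnvr", "data.frame")
  df
}

.join_ids <- function(x) paste(sort(unique(x)), collapse = ",")
.split_ids <- function(x) strsplit(x, ",", fixed = TRUE)

#' Assemble one tool's calls into density-trimmed CNVRs
#'
#' Per CNV type, calls overlapping by at least one base are merged into
#' candidate regions. Within each candidate region the per-base support
#' profile is computed and maximal segments supported by fewer than
#' `density_min` of the region's contributing calls are removed, splitting
#' the region wherever an interior segment falls below threshold. Post-trim
#' loss and gain regions that still overlap by >= 1 bp are fused into a
#' single region typed `both`.
#'
#' @param calls `cnv_calls` from exactly one tool, already filtered.
#' @param density_min Minimum support fraction (default 0.10); bases with
#'   support strictly below `density_min * n_contributing_calls` are removed.
#' @return A `cnvr` data frame (columns `cnvr_id`, `chrom`, `start`, `end`,
#'   `cnvr_type`, `tools`, `samples`, `n_calls`).
#' @export
build_tool_cnvrs <- function(calls, density_min = 0.10) {
  calls <- as.data.frame(calls)
  if (nrow(calls) && length(unique(calls$tool)) > 1) {
    stop("build_tool_cnvrs: calls must come from exactly one tool; got ",
         paste(unique(calls$tool), collapse = ", "))
  }
  tool <- if (nrow(calls)) calls$tool[1] else NA_character_
  trimmed <- list()
  for (type in c("loss", "gain")) {
    sub <- calls[calls$cnv_type == type, , drop = FALSE]
    if (!nrow(sub)) next
    cand <- merge_adjacent(sub)
    for (i in seq_len(nrow(cand))) {
      region <- cand[i, , drop = FALSE]
      inreg <- sub$chrom == region$chrom & sub$start <= region$end & sub$end >= region$start
      contrib <- sub[inreg, , drop = FALSE]
      prof <- support_profile(region, contrib)
      thr <- density_min * nrow(contrib)
      keep <- prof$support >= thr
      if (!any(keep)) next
      runs <- rle(keep)
      seg_hi <- cumsum(runs$lengths); seg_lo <- seg_hi - runs$lengths + 1
      for (r in which(runs$values)) {
        s <- prof$start[seg_lo[r]]; e <- prof$end[seg_hi[r]]
        trimmed[[length(trimmed) + 1]] <- data.frame(
          chrom = region$chrom, start = s, end = e, cnvr_type = type,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(trimmed)) return(.cnvr_df())
  regions <- do.call(rbind, trimmed)
  # fuse cross-type overlaps into 'both' regions
  red <- merge_adjacent(regions)
  gr_red <- .as_granges(red); gr_reg <- .as_granges(regions)
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_red, ignore.strand = TRUE)
  comp <- rep(NA_integer_, nrow(regions))
  comp[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  type_by_comp <- tapply(regions$cnvr_type, comp, function(t) {
    if (length(unique(t)) > 1) "both" else t[1]
  })
  out_type <- as.character(type_by_comp[as.character(seq_len(nrow(red)))])
  samples <- character(nrow(red)); ncall <- integer(nrow(red))
  gr_calls <- .as_granges(calls)
  chits <- GenomicRanges::findOverlaps(gr_calls, gr_red, ignore.strand = TRUE)
  cq <- S4Vectors::queryHits(chits); cs <- S4Vectors::subjectHits(chits)
  for (i in seq_len(nrow(red))) {
    rows <- cq[cs == i]
    samples[i] <- .join_ids(calls$sample_id[rows])
    ncall[i] <- length(rows)
  }
  .renumber_cnvrs(.cnvr_df(red$chrom, red$start, red$end, out_type,
                           tools = rep(tool, nrow(red)), samples = samples,
                           n_calls = ncall))
}

#' Combine per-tool CNVRs into multi-tool consensus regions
#'
#' CNVRs of the same type coming from different tools are combined when they
#' overlap by at least one base (chained); `both`-typed regions combine with
#' either type. Combined regions supported by fewer than `min_tools` distinct
#' tools are discarded. Each combined region spans the union of its members
#' and is retyped from its full contributing set (`both` when losses and
#' gains both contribute).
#'
#' @param tool_sets List of `cnvr` data frames, one per tool.
#' @param min_tools Minimum number of distinct supporting tools (default 2).
#' @return A `cnvr` data frame.
#' @export
consensus_cnvrs <- function(tool_sets, min_tools = 2) {
  if (length(tool_sets) < min_tools) {
    stop("consensus_cnvrs: need at least ", min_tools, " tool CNVR sets, got ",
         length(tool_sets))
  }
  all_cnvrs <- do.call(rbind, lapply(tool_sets, as.data.frame))
  if (is.null(all_cnvrs) || !nrow(all_cnvrs)) return(.cnvr_df())
  rownames(all_cnvrs) <- NULL
  n <- nrow(all_cnvrs)
  gr <- .as_granges(all_cnvrs)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  ta <- all_cnvrs$cnvr_type[qi]; tb <- all_cnvrs$cnvr_type[si]
  compatible <- ta == tb | ta == "both" | tb == "both"
  comp <- .union_find(n, qi[compatible], si[compatible])
  out <- list()
  for (cid in unique(comp)) {
    rows <- which(comp == cid)
    tools <- unique(unlist(.split_ids(all_cnvrs$tools[rows])))
    if (length(tools) < min_tools) next
    types <- unique(all_cnvrs$cnvr_type[rows])
    newtype <- if ("both" %in% types || all(c("loss", "gain") %in% types)) "both" else types[1]
    out[[length(out) + 1]] <- data.frame(
      chrom = all_cnvrs$chrom[rows[1]],
      start = min(all_cnvrs$start[rows]), end = max(all_cnvrs$end[rows]),
      cnvr_type = newtype,
      tools = paste(sort(tools), collapse = ","),
      samples = .join_ids(unlist(.split_ids(all_cnvrs$samples[rows]))),
      n_calls = sum(all_cnvrs$n_calls[rows]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.cnvr_df())
  df <- do.call(rbind, out)
  .renumber_cnvrs(.cnvr_df(df$chrom, df$start, df$end, df$cnvr_type, df$tools,
                           df$samples, df$n_calls))
}

# individuals supporting each CNVR: >= 1 bp overlap by any of the
# individual's filtered calls, regardless of tool or call type
.supporters <- function(cnvrs, calls) {
  calls <- as.data.frame(calls)
  res <- vector("list", nrow(cnvrs))
  if (!nrow(cnvrs)) return(res)
  gr_cnvr <- .as_granges(cnvrs)
  if (nrow(calls)) {
    gr_calls <- .as_granges(calls)
    hits <- GenomicRanges::findOverlaps(gr_calls, gr_cnvr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    for (i in seq_len(nrow(cnvrs))) {
      res[[i]] <- sort(unique(calls$sample_id[qi[si == i]]))
    }
  } else {
    res[] <- list(character(0))
  }
  res
}

#' Filter consensus CNVRs by breed sharing or regional completeness
#'
#' An individual supports a CNVR iff at least one of its filtered calls
#' overlaps the CNVR span by >= 1 bp, regardless of tool. Two modes:
#' \describe{
#'   \item{`per_breed_min2`}{keep CNVRs supported by at least two individuals
#'     in every breed of the sheet (the strict all-breeds rule).}
#'   \item{`region_all`}{keep CNVRs supported by every individual of the
#'     given geographic `region`.}
#'   \item{`overall_min`}{laxer variant: keep CNVRs supported by at least
#'     `min_individuals` individuals overall (default 3, so singletons and
#'     doubletons stay excluded).}
#' }
#' Singletons (one supporting individual) and doubletons (two) are recorded
#' in attributes `singletons` and `doubletons` and never enter shared sets.
#'
#' @param consensus A `cnvr` data frame from [consensus_cnvrs()].
#' @param calls The pooled filtered `cnv_calls` of all samples and tools.
#' @param sheet A `sample_sheet`.
#' @param mode Sharing rule (see above).
#' @param region Region name, required for `region_all`.
#' @param min_individuals Threshold for `overall_min`.
#' @return A `cnvr` data frame whose `samples` column lists the supporting
#'   individuals; attributes `singletons` and `doubletons` hold the excluded
#'   low-support CNVRs.
#' @export
shared_cnvrs <- function(consensus, calls, sheet,
                         mode = c("per_breed_min2", "region_all", "overall_min"),
                         region = NULL, min_individuals = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(sheet, "sample_sheet"))
  consensus <- as.data.frame(consensus)
  supp <- .supporters(consensus, calls)
  n_supp <- lengths(supp)
  singles <- consensus[n_supp == 1, , drop = FALSE]
  doubles <- consensus[n_supp == 2, , drop = FALSE]
  if (mode == "per_breed_min2") {
    bc <- table(sheet$breed)
    thin <- names(bc)[bc < 2]
    if (length(thin)) {
      stop("shared_cnvrs: breed(s) with fewer than 2 sampled individuals cannot ",
           "satisfy the >=2-per-breed rule: ", paste(thin, collapse = ", "))
    }
    breeds <- unique(sheet$breed)
    keep <- vapply(supp, function(s) {
      b <- sheet$breed[match(s, sheet$sample_id)]
      all(vapply(breeds, function(x) sum(b == x, na.rm = TRUE) >= 2, logical(1)))
    }, logical(1))
  } else if (mode == "region_all") {
    if (is.null(region) || !region %in% sheet$region) {
      stop("shared_cnvrs: mode 'region_all' needs a region present in the sheet")
    }
    members <- sheet$sample_id[sheet$region == region]
    keep <- vapply(supp, function(s) all(members %in% s), logical(1))
  } else {
    keep <- n_supp >= min_individuals
  }
  out <- consensus[keep, , drop = FALSE]
  out$samples <- vapply(supp[keep], paste, character(1), collapse = ",")
  out <- .renumber_cnvrs(out)
  attr(out, "singletons") <- .renumber_cnvrs(singles)
  attr(out, "doubletons") <- .renumber_cnvrs(doubles)
  out
}

#' Region-exclusive CNVRs
#'
#' Keeps the target CNVRs having zero base-pair overlap with every CNVR in
#' every other region's shared set. CNVRs are kept or dropped whole; spans
#' are never trimmed.
#'
#' @param target `cnvr` data frame of one region's shared set.
#' @param others List of `cnvr` data frames from the other regions.
#' @return A `cnvr` data frame.
#' @export
exclusive_cnvrs <- function(target, others) {
  target <- as.data.frame(target)
  if (!nrow(target)) return(.renumber_cnvrs(target))
  other_df <- do.call(rbind, lapply(others, function(x) as.data.frame(x)[, c("chrom", "start", "end")]))
  if (is.null(other_df) || !nrow(other_df)) return(.renumber_cnvrs(target))
  hits <- GenomicRanges::findOverlaps(.as_granges(target), .as_granges(other_df),
                                      ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- target[setdiff(seq_len(nrow(target)), drop), , drop = FALSE]
  .renumber_cnvrs(out)
}

#' Summary statistics of a CNVR set
#'
#' @param cnvrs A `cnvr` data frame.
#' @param build A [genome_build()] providing the autosomal length for the
#'   genome fraction.
#' @return A `cnvr_summary` list: counts by type (`n_total`, `n_loss`,
#'   `n_gain`, `n_both`), `per_chrom` counts, `total_bp`,
#'   `genome_fraction_pct` (percent of the autosomal genome, 2 decimals),
#'   and `min`/`mean`/`median`/`max` lengths (mean/median to 2 decimals).
#' @export
summarize_cnvrs <- function(cnvrs, build) {
  stopifnot(inherits(build, "genome_build"))
  cnvrs <- as.data.frame(cnvrs)
  if (!nrow(cnvrs)) {
    out <- list(n_total = 0L, n_loss = 0L, n_gain = 0L, n_both = 0L,
                per_chrom = table(character(0)), total_bp = 0,
                genome_fraction_pct = 0, min_len = 0, mean_len = 0,
                median_len = 0, max_len = 0)
    class(out) <- "cnvr_summary"
    return(out)
  }
  w <- cnvrs$end - cnvrs$start + 1
  total <- sum(w)
  out <- list(
    n_total = nrow(cnvrs),
    n_loss = sum(cnvrs$cnvr_type == "loss"),
    n_gain = sum(cnvrs$cnvr_type == "gain"),
    n_both = sum(cnvrs$cnvr_type == "both"),
    per_chrom = table(cnvrs$chrom),
    total_bp = total,
    genome_fraction_pct = round(100 * total / autosomal_length(build), 2),
    min_len = min(w),
    mean_len = round(total / nrow(cnvrs), 2),
    median_len = round(stats::median(w), 2),
    max_len = max(w)
  )
  class(out) <- "cnvr_summary"
  out
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat("CNVR summary\n")
  cat(sprintf("  regions: %d (loss %d, gain %d, both %d)\n",
              x$n_total, x$n_loss, x$n_gain, x$n_both))
  cat(sprintf("  total length: %s bp (%.2f%% of autosomal genome)\n",
              format(x$total_bp, big.mark = ","), x$genome_fraction_pct))
  cat(sprintf("  length range: %s - %s bp, mean %.2f, median %.2f\n",
              format(x$min_len, big.mark = ","), format(x$max_len, big.mark = ","),
              x$mean_len, x$median_len))
  invisible(x)
}
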