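# Filtering and classification of raw calls, pooled cross-tool union loci,
# and the homozygous/multicopy exon-overlapping call set.

#' Call filter configuration
#'
#' Defaults follow the standard CNV-study conventions: minimum variant size
#' 50 bp, calls larger than 5 Mb excluded (false-positive control in
#' repetitive/assembly-uncertain regions), autosomes only (sex-bias control).
#'
#' @param min_len_bp Minimum call length in bp.
#' @param max_len_bp Maximum call length in bp.
#' @param autosomes_only Keep only autosomal calls.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_len_bp = 50, max_len_bp = 5e6, autosomes_only = TRUE) {
  if (!(min_len_bp > 0 && min_len_bp < max_len_bp)) {
    stop("filter_config: need 0 < min_len_bp < max_len_bp")
  }
  structure(list(min_len_bp = min_len_bp, max_len_bp = max_len_bp,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "filter_config")
}

#' Filter CNV calls by size and chromosome
#'
#' @param calls A `cnv_calls` data frame.
#' @param build A [genome_build()].
#' @param cfg A [filter_config()].
#' @return Filtered calls; attribute `removed` counts removals per reason
#'   (`too_short`, `too_long`, `non_autosomal`), applied in that order.
#' @export
filter_calls <- function(calls, build, cfg = filter_config()) {
  stopifnot(inherits(build, "genome_build"), inherits(cfg, "filter_config"))
  len <- calls$end - calls$start + 1
  too_short <- len < cfg$min_len_bp
  too_long <- !too_short & len > cfg$max_len_bp
  non_auto <- rep(FALSE, nrow(calls))
  if (cfg$autosomes_only) {
    non_auto <- !too_short & !too_long & !(calls$chrom %in% autosome_names(build))
  }
  keep <- !(too_short | too_long | non_auto)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(too_short = sum(too_short), too_long = sum(too_long),
                            non_autosomal = sum(non_auto))
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Classify a CNV as loss or gain
#'
#' @param copy_number Integer copy number (diploid baseline 2), or NULL.
#' @param svtype `"DEL"` or `"DUP"`, used when `copy_number` is NULL/NA.
#' @return `"loss"` or `"gain"`. A copy number of exactly 2 is not a CNV and
#'   raises an error.
#' @export
classify_call_type <- function(copy_number = NULL, svtype = NULL) {
  if (!is.null(copy_number) && length(copy_number) && !is.na(copy_number)) {
    if (copy_number == 2) stop("classify_call_type: copy number 2 is not a CNV")
    return(if (copy_number < 2) "loss" else "gain")
  }
  if (!is.null(svtype) && svtype %in% c("DEL", "DUP")) {
    return(if (svtype == "DEL") "loss" else "gain")
  }
  stop("classify_call_type: need a copy number != 2 or SVTYPE DEL/DUP")
}

#' Build pooled cross-tool union loci
#'
#' All calls (across samples and tools) of the same type are clustered by
#' chained reciprocal overlap at `ro_threshold`; each cluster becomes one
#' union locus spanning `[min start, max end]` of its members. Losses and
#' gains never co-cluster, so loci of different types may overlap spatially.
#' Every input call belongs to exactly one locus.
#'
#' @param calls Filtered `cnv_calls`.
#' @param ro_threshold Reciprocal-overlap threshold (default 0.5).
#' @return List with `loci` (data frame `locus_id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `n_members`, `n_samples`) and `members` (data frame
#'   `locus_id`, `call_row`, `sample_id`, `tool`) mapping calls to loci by
#'   row index into `calls`.
#' @export
build_union_loci <- function(calls, ro_threshold = 0.5) {
  calls <- as.data.frame(calls)
  if (!nrow(calls)) {
    return(list(loci = data.frame(locus_id = integer(0), chrom = character(0),
                                  start = numeric(0), end = numeric(0),
                                  cnv_type = character(0), n_members = integer(0),
                                  n_samples = integer(0)),
                members = data.frame(locus_id = integer(0), call_row = integer(0),
                                     sample_id = character(0), tool = character(0))))
  }
  loci_list <- list(); members_list <- list(); offset <- 0L
  for (type in c("loss", "gain")) {
    idx <- which(calls$cnv_type == type)
    if (!length(idx)) next
    cl <- cluster_reciprocal(calls[idx, , drop = FALSE], threshold = ro_threshold)
    spans <- attr(cl, "spans")
    loci_list[[type]] <- data.frame(
      locus_id = spans$cluster + offset, chrom = spans$chrom,
      start = spans$start, end = spans$end, cnv_type = type,
      n_members = spans$n, stringsAsFactors = FALSE)
    members_list[[type]] <- data.frame(
      locus_id = cl$cluster + offset, call_row = idx,
      sample_id = calls$sample_id[idx], tool = calls$tool[idx],
      stringsAsFactors = FALSE)
    offset <- offset + nrow(spans)
  }
  loci <- do.call(rbind, loci_list)
  members <- do.call(rbind, members_list)
  ns <- tapply(members$sample_id, members$locus_id, function(s) length(unique(s)))
  loci$n_samples <- as.integer(ns[as.character(loci$locus_id)])
  ord <- order(loci$chrom, loci$start, loci$end, loci$cnv_type)
  loci <- loci[ord, , drop = FALSE]
  # renumber loci in genomic order for stable downstream ids
  relab <- stats::setNames(seq_len(nrow(loci)), loci$locus_id)
  loci$locus_id <- unname(relab[as.character(loci$locus_id)])
  members$locus_id <- unname(relab[as.character(members$locus_id)])
  members <- members[order(members$locus_id, members$call_row), , drop = FALSE]
  rownames(loci) <- rownames(members) <- NULL
  list(loci = loci, members = members)
}

#' Extract extreme-copy-number loci present in every sample
#'
#' Keeps only calls with copy number 0 (homozygous deletion, potential gene
#' disruption) or >= 4 (homozygous duplication, gene dosage imbalance),
#' clusters them at `ro_threshold` reciprocal overlap, and retains loci with
#' at least one member call from every sample in `samples`.
#'
#' @param calls Filtered `cnv_calls` carrying `copy_number`.
#' @param samples Character vector of all sample ids that must be covered.
#' @param ro_threshold Reciprocal-overlap threshold (default 0.5).
#' @return As [build_union_loci()], restricted to universally supported loci.
#' @export
extract_extreme_cn_shared <- function(calls, samples, ro_threshold = 0.5) {
  if (!length(samples)) stop("extract_extreme_cn_shared: empty sample list")
  calls <- as.data.frame(calls)
  extreme <- !is.na(calls$copy_number) & (calls$copy_number == 0 | calls$copy_number >= 4)
  ul <- build_union_loci(calls[extreme, , drop = FALSE], ro_threshold = ro_threshold)
  by_locus <- split(ul$members$sample_id, ul$members$locus_id)
  universal <- vapply(by_locus, function(s) all(samples %in% s), logical(1))
  keep_ids <- as.integer(names(by_locus))[universal]
  loci <- ul$loci[ul$loci$locus_id %in% keep_ids, , drop = FALSE]
  members <- ul$members[ul$members$locus_id %in% keep_ids, , drop = FALSE]
  # call_row indices refer to the extreme-call subset's origin rows
  members$call_row <- which(extreme)[members$call_row]
  rownames(loci) <- rownames(members) <- NULL
  list(loci = loci, members = members)
}

#' Select loci overlapping exons by at least a fraction of their length
#'
#' A locus is retained iff the bases it shares with some single gene's exonic
#' union cover at least `min_frac` of the locus length (inclusive threshold).
#' For retained loci, every gene whose exons overlap the locus by >= 1 bp is
#' reported once.
#'
#' @param loci Data frame of loci (`locus_id`, `chrom`, `start`, `end`, ...).
#' @param genes A `gene_models` object (see [read_gene_models()]).
#' @param min_frac Minimum exonic fraction of the locus length (default 0.5).
#' @return Data frame `locus_id`, `chrom`, `start`, `end`, `cnv_type` (when
#'   present), `exon_frac` (best per-gene fraction), `genes` (comma-separated
#'   deduplicated gene ids with >= 1 bp exon overlap).
#' @export
exon_overlap_select <- function(loci, genes, min_frac = 0.5) {
  stopifnot(inherits(genes, "gene_models"))
  eu <- genes$exonic_union
  if (!nrow(loci)) {
    out <- loci; out$exon_frac <- numeric(0); out$genes <- character(0)
    return(out)
  }
  gr_loci <- .as_granges(loci)
  gr_eu <- .as_granges(eu)
  hits <- GenomicRanges::findOverlaps(gr_loci, gr_eu, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    out <- loci[0, , drop = FALSE]; out$exon_frac <- numeric(0); out$genes <- character(0)
    return(out)
  }
  ovl <- pmin(loci$end[qi], eu$end[si]) - pmax(loci$start[qi], eu$start[si]) + 1
  len <- (loci$end - loci$start + 1)[qi]
  # exonic bases per (locus, gene): union pieces are disjoint, so they sum
  key <- paste(qi, eu$gene_id[si], sep = "\r")
  per_gene <- tapply(ovl, key, sum)
  k <- strsplit(names(per_gene), "\r", fixed = TRUE)
  li <- as.integer(vapply(k, `[`, character(1), 1))
  gid <- vapply(k, `[`, character(1), 2)
  frac <- as.numeric(per_gene) / (loci$end - loci$start + 1)[li]
  best <- tapply(frac, li, max)
  keep_rows <- as.integer(names(best))[as.numeric(best) >= min_frac]
  if (!length(keep_rows)) {
    out <- loci[0, , drop = FALSE]; out$exon_frac <- numeric(0); out$genes <- character(0)
    return(out)
  }
  gene_lists <- vapply(keep_rows, function(r) {
    paste(sort(unique(gid[li == r])), collapse = ",")
  }, character(1))
  out <- loci[keep_rows, , drop = FALSE]
  out$exon_frac <- as.numeric(best[as.character(keep_rows)])
  out$genes <- gene_lists
  rownames(out) <- NULL
  out
}
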