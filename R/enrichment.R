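# Gene/QTL overlap of CNVRs, per-trait over-representation against the full
# QTL background, local gene-set over-representation, and 1-Mb gene density.

#' Overlap CNVRs with genomic features
#'
#' An association requires >= 1 bp overlap. Works for gene tables (column
#' `gene_id`) and QTL tables (column `qtl_id`/`trait`); any interval data
#' frame with an id column is accepted.
#'
#' @param cnvrs A `cnvr` data frame.
#' @param features Interval data frame with an id column (`gene_id`,
#'   `qtl_id`, or the first non-coordinate column).
#' @return List with `pairs` (data frame `cnvr_id` + feature columns, one
#'   row per association) and `feature_ids` (deduplicated ids of all
#'   associated features).
#' @export
overlap_features <- function(cnvrs, features) {
  cnvrs <- as.data.frame(cnvrs)
  .check_intervals(features, "features")
  id_col <- intersect(c("gene_id", "qtl_id"), names(features))
  if (!length(id_col)) id_col <- setdiff(names(features), c("chrom", "start", "end"))[1]
  id_col <- id_col[1]
  if (!nrow(cnvrs) || !nrow(features)) {
    pairs <- cbind(data.frame(cnvr_id = integer(0)), features[0, , drop = FALSE])
    return(list(pairs = pairs, feature_ids = character(0)))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(cnvrs), .as_granges(features),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pairs <- cbind(data.frame(cnvr_id = cnvrs$cnvr_id[qi]),
                 features[si, , drop = FALSE])
  rownames(pairs) <- NULL
  list(pairs = pairs, feature_ids = sort(unique(as.character(features[[id_col]][si]))))
}

# one-sided (greater) hypergeometric tail for a 2x2 table
# a = in-category & selected, K = category total, n = selected total, N = all
.hyper_tail <- function(a, K, n, N) {
  if (a <= 0) return(1)
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-trait QTL over-representation in CNVRs (one-sided Fisher)
#'
#' For each trait the 2x2 table counts QTL records (not traits): `a` = QTL of
#' the trait overlapping >= 1 CNVR, `b` = QTL of the trait not overlapping,
#' `c` = QTL of other traits overlapping, `d` = the rest. The one-sided
#' (greater) Fisher p-value is the hypergeometric tail; the full QTL table is
#' the background. No multiple-testing correction drives the significance
#' flag; a Benjamini-Hochberg column is emitted for transparency.
#'
#' @param cnvrs A `cnvr` data frame.
#' @param qtl QTL data frame (`qtl_id`, `trait`, `chrom`, `start`, `end`).
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @return Data frame `trait`, `a`, `b`, `c`, `d`, `p_value`, `p_bh`,
#'   `significant`, sorted by p-value.
#' @export
qtl_fisher_enrichment <- function(cnvrs, qtl, alpha = 0.05) {
  if (!nrow(qtl)) stop("qtl_fisher_enrichment: empty QTL background")
  empty_trait <- is.na(qtl$trait) | !nzchar(trimws(qtl$trait))
  if (any(empty_trait)) {
    warning(sum(empty_trait), " QTL record(s) without trait skipped")
    qtl <- qtl[!empty_trait, , drop = FALSE]
  }
  cnvrs <- as.data.frame(cnvrs)
  overlapping <- rep(FALSE, nrow(qtl))
  if (nrow(cnvrs)) {
    hits <- GenomicRanges::findOverlaps(.as_granges(qtl), .as_granges(cnvrs),
                                        ignore.strand = TRUE)
    overlapping[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  N <- nrow(qtl)
  n_sel <- sum(overlapping)
  traits <- sort(unique(qtl$trait))
  res <- lapply(traits, function(tr) {
    in_tr <- qtl$trait == tr
    a <- sum(in_tr & overlapping)
    b <- sum(in_tr & !overlapping)
    c_ <- n_sel - a
    d <- N - a - b - c_
    data.frame(trait = tr, a = a, b = b, c = c_, d = d,
               p_value = .hyper_tail(a, a + b, n_sel, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation from local GMT sets
#'
#' Hypergeometric over-representation of a deduplicated gene list in each
#' set, against a stated background universe. Set members outside the
#' background are ignored.
#'
#' @param genes Character vector of selected gene ids (deduplicated
#'   internally).
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @param background Character vector, the gene universe; must contain every
#'   selected gene.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `set`, `a`, `b`, `c`, `d`, `gene_ratio`, `p_value`,
#'   `p_bh`, `significant`, sorted by p-value; empty input gives an empty
#'   result.
#' @export
gene_set_ora <- function(genes, gene_sets, background, alpha = 0.05) {
  genes <- unique(as.character(genes))
  background <- unique(as.character(background))
  if (!length(genes)) {
    return(data.frame(set = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), gene_ratio = numeric(0),
                      p_value = numeric(0), p_bh = numeric(0),
                      significant = logical(0)))
  }
  missing <- setdiff(genes, background)
  if (length(missing)) {
    stop("gene_set_ora: gene(s) absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  N <- length(background)
  n_sel <- length(genes)
  res <- lapply(sort(names(gene_sets)), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    a <- length(intersect(genes, set))
    data.frame(set = nm, a = a, b = K - a, c = n_sel - a,
               d = N - K - (n_sel - a),
               gene_ratio = if (n_sel) a / n_sel else 0,
               p_value = .hyper_tail(a, K, n_sel, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene density in fixed windows
#'
#' Tiles every chromosome of the build with `window_bp` windows (the last
#' window of a chromosome may be short) and counts, for each window, the
#' genes overlapping it by >= 1 bp; a gene spanning a boundary is counted in
#' both windows.
#'
#' @param genes A `gene_models` object or a data frame with `chrom`,
#'   `start`, `end`.
#' @param build A [genome_build()].
#' @param window_bp Window size (default 1 Mb).
#' @return Data frame `chrom`, `start`, `end`, `n_genes`.
#' @export
gene_density <- function(genes, build, window_bp = 1e6) {
  stopifnot(inherits(build, "genome_build"))
  if (inherits(genes, "gene_models")) {
    gdf <- merge(genes$genes,
                 do.call(rbind, lapply(split(genes$exons, genes$exons$gene_id), function(e) {
                   data.frame(gene_id = e$gene_id[1], start = min(e$start), end = max(e$end))
                 })), by = "gene_id")
    gdf <- gdf[, c("chrom", "start", "end")]
  } else {
    .check_intervals(genes, "genes")
    gdf <- genes[, c("chrom", "start", "end")]
  }
  wins <- do.call(rbind, lapply(seq_len(nrow(build)), function(i) {
    len <- build$length_bp[i]
    starts <- seq(1, len, by = window_bp)
    data.frame(chrom = build$chrom[i], start = starts,
               end = pmin(starts + window_bp - 1, len), stringsAsFactors = FALSE)
  }))
  wins$n_genes <- 0L
  if (nrow(gdf)) {
    hits <- GenomicRanges::findOverlaps(.as_granges(wins), .as_granges(gdf),
                                        ignore.strand = TRUE)
    tab <- table(S4Vectors::queryHits(hits))
    wins$n_genes[as.integer(names(tab))] <- as.integer(tab)
  }
  rownames(wins) <- NULL
  wins
}
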