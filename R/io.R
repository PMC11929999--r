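# Readers and writers for every external format the pipeline touches.
# Internal convention everywhere: 1-based fully-closed coordinates
# (VCF/GFF3-native). BED's 0-based half-open convention is converted at this
# boundary and nowhere else.

.CNV_TYPES <- c("loss", "gain")
.REGIONS <- c("America", "AsiaOceania", "Europe")

.empty_calls <- function() {
  data.frame(sample_id = character(0), tool = character(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             cnv_type = character(0), copy_number = integer(0),
             genotype = character(0), stringsAsFactors = FALSE)
}

.gt_class <- function(gt) {
  gt <- sub(":.*", "", gt)
  ifelse(gt %in% c("1/1", "1|1"), "hom",
         ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"), "het", "unknown"))
}

#' Read one caller's CNV calls for one sample
#'
#' Ingests deletion/duplication calls from one of three dialects and
#' normalizes them to 1-based inclusive coordinates:
#' \describe{
#'   \item{`vcf_svtype`}{SV VCF with `SVTYPE`/`END` INFO fields and a GT
#'     column. `SVTYPE=DEL` maps to loss, `SVTYPE=DUP` to gain; a diploid
#'     `1/1` genotype on a DEL implies copy number 0 (homozygous deletion),
#'     `0/1` implies copy number 1.}
#'   \item{`vcf_cn`}{SV VCF whose FORMAT carries an integer `CN` field
#'     (read-depth caller style); type is taken from `SVTYPE` when present,
#'     otherwise from `CN` (< 2 loss, > 2 gain).}
#'   \item{`tsv_regions`}{Headerless whitespace-separated region list:
#'     `type chrom:start-end CN=k`, with type one of
#'     deletion/duplication/loss/gain/DEL/DUP.}
#' }
#' Records whose `SVTYPE` is neither DEL nor DUP (breakends, inversions,
#' insertions) are skipped with a counted warning; records with `END < POS`
#' are dropped as record-level errors; records on chromosomes absent from the
#' build are rejected with a warning count. Ingest statistics are attached as
#' attribute `ingest_stats`.
#'
#' @param path Input file.
#' @param tool Tool name recorded on every call (free text; dialects, not
#'   tool identities, drive parsing).
#' @param dialect One of `"vcf_svtype"`, `"vcf_cn"`, `"tsv_regions"`.
#' @param build A [genome_build()] used to validate chromosome names.
#' @param sample_id Sample the calls belong to; for VCF dialects defaults to
#'   the VCF sample column name.
#' @return A `cnv_calls` data frame with columns `sample_id`, `tool`,
#'   `chrom`, `start`, `end`, `cnv_type`, `copy_number` (NA when the caller
#'   reports none), `genotype`.
#' @export
read_cnv_calls <- function(path, tool, dialect = c("vcf_svtype", "vcf_cn", "tsv_regions"),
                           build, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_cnv_calls: cannot read ", path)
  stopifnot(inherits(build, "genome_build"))
  if (dialect == "tsv_regions") {
    calls <- .read_tsv_regions(path, tool, sample_id)
  } else {
    calls <- .read_sv_vcf(path, tool, sample_id, with_cn = (dialect == "vcf_cn"))
  }
  stats <- attr(calls, "ingest_stats")
  bad_chrom <- !(calls$chrom %in% build$chrom)
  if (any(bad_chrom)) {
    warning(sum(bad_chrom), " record(s) on chromosomes absent from build '",
            attr(build, "name"), "' rejected")
  }
  stats$unknown_chrom <- sum(bad_chrom)
  calls <- calls[!bad_chrom, , drop = FALSE]
  rownames(calls) <- NULL
  stats$n_kept <- nrow(calls)
  attr(calls, "ingest_stats") <- stats
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

.read_sv_vcf <- function(path, tool, sample_id, with_cn) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  stats <- list(n_read = n, skipped_svtype = 0L, bad_coords = 0L)
  if (n == 0) {
    out <- .empty_calls(); attr(out, "ingest_stats") <- stats; return(out)
  }
  info <- fix[, "INFO"]
  grab <- function(key) {
    vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]+"), info)),
           function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[[1]]) else NA_character_,
           character(1))
  }
  svtype <- grab("SVTYPE")
  endv <- suppressWarnings(as.numeric(grab("END")))
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  gt_col <- NULL
  cn <- rep(NA_integer_, n)
  geno <- rep("unknown", n)
  if (ncol(v@gt) >= 2) {
    vcf_sample <- colnames(v@gt)[2]
    if (is.null(sample_id)) sample_id <- vcf_sample
    gt <- tryCatch(vcfR::extract.gt(v, element = "GT")[, 1],
                   error = function(e) rep(NA_character_, n))
    geno <- .gt_class(ifelse(is.na(gt), "", gt))
    if (with_cn) {
      cnv <- tryCatch(vcfR::extract.gt(v, element = "CN")[, 1],
                      error = function(e) rep(NA_character_, n))
      cn <- suppressWarnings(as.integer(cnv))
    }
  }
  if (is.null(sample_id)) stop("read_cnv_calls: sample_id required for VCF without sample column")
  type <- ifelse(svtype %in% "DEL", "loss", ifelse(svtype %in% "DUP", "gain", NA))
  if (with_cn) {
    # CN is authoritative where SVTYPE is absent
    type[is.na(type) & !is.na(cn) & cn < 2] <- "loss"
    type[is.na(type) & !is.na(cn) & cn > 2] <- "gain"
  }
  skip <- is.na(type)
  if (any(skip)) {
    stats$skipped_svtype <- sum(skip)
    warning(sum(skip), " record(s) with unsupported SVTYPE skipped in ", basename(path))
  }
  bad <- !skip & (!is.finite(endv) | !is.finite(pos) | endv < pos)
  if (any(bad)) {
    stats$bad_coords <- sum(bad)
    warning("record error (END < POS or missing END) at VCF record(s) ",
            paste(utils::head(which(bad), 10), collapse = ", "), " in ", basename(path),
            "; dropped")
  }
  keep <- !skip & !bad
  cn_out <- cn
  no_cn <- is.na(cn_out)
  cn_out[no_cn & type == "loss" & geno == "hom"] <- 0L
  cn_out[no_cn & type == "loss" & geno == "het"] <- 1L
  out <- data.frame(sample_id = sample_id, tool = tool,
                    chrom = as.character(fix[keep, "CHROM"]),
                    start = pos[keep], end = endv[keep],
                    cnv_type = type[keep], copy_number = cn_out[keep],
                    genotype = geno[keep], stringsAsFactors = FALSE)
  attr(out, "ingest_stats") <- stats
  out
}

.read_tsv_regions <- function(path, tool, sample_id) {
  if (is.null(sample_id)) {
    stop("read_cnv_calls: sample_id is required for the tsv_regions dialect")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  stats <- list(n_read = length(lines), skipped_svtype = 0L, bad_coords = 0L)
  if (!length(lines)) {
    out <- .empty_calls(); attr(out, "ingest_stats") <- stats; return(out)
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  type_raw <- tolower(vapply(parts, `[`, character(1), 1))
  type <- ifelse(type_raw %in% c("deletion", "loss", "del"), "loss",
                 ifelse(type_raw %in% c("duplication", "gain", "dup"), "gain", NA))
  coords <- vapply(parts, `[`, character(1), 2)
  m <- regexec("^([^:]+):([0-9]+)-([0-9]+)$", coords)
  mm <- regmatches(coords, m)
  okfmt <- lengths(mm) == 4
  chrom <- ifelse(okfmt, vapply(mm, function(x) if (length(x) == 4) x[2] else NA_character_, character(1)), NA)
  start <- suppressWarnings(as.numeric(vapply(mm, function(x) if (length(x) == 4) x[3] else NA_character_, character(1))))
  end <- suppressWarnings(as.numeric(vapply(mm, function(x) if (length(x) == 4) x[4] else NA_character_, character(1))))
  cn_field <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, character(1))
  cn <- suppressWarnings(as.integer(sub("^CN=", "", cn_field)))
  skip <- is.na(type)
  if (any(skip)) {
    stats$skipped_svtype <- sum(skip)
    warning(sum(skip), " region line(s) with unrecognised type skipped in ", basename(path))
  }
  bad <- !skip & (!okfmt | !is.finite(start) | !is.finite(end) | end < start)
  if (any(bad)) {
    stats$bad_coords <- sum(bad)
    warning("record error (malformed coordinates) at line(s) ",
            paste(utils::head(which(bad), 10), collapse = ", "), " in ", basename(path),
            "; dropped")
  }
  keep <- !skip & !bad
  geno <- rep("unknown", length(lines))
  geno[!is.na(cn) & cn == 0] <- "hom"
  out <- data.frame(sample_id = sample_id, tool = tool, chrom = chrom[keep],
                    start = start[keep], end = end[keep], cnv_type = type[keep],
                    copy_number = cn[keep], genotype = geno[keep],
                    stringsAsFactors = FALSE)
  attr(out, "ingest_stats") <- stats
  out
}

#' Read a sample sheet mapping samples to breeds and geographic regions
#'
#' Delimited file with columns `sample_id` (or `sample`), `breed`, `region`.
#' Regions form the closed set America / AsiaOceania / Europe. Duplicate
#' sample ids, breeds mapped to two regions, and unknown region labels are
#' fatal.
#'
#' @param path Input TSV/CSV path.
#' @return A `sample_sheet` data frame with columns `sample_id`, `breed`,
#'   `region`; attributes `breed_counts` and `region_counts`.
#' @export
read_sample_sheet <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  nm <- names(tab)
  if ("sample" %in% nm && !"sample_id" %in% nm) names(tab)[nm == "sample"] <- "sample_id"
  req <- c("sample_id", "breed", "region")
  if (!all(req %in% names(tab))) {
    stop("read_sample_sheet: missing columns: ", paste(setdiff(req, names(tab)), collapse = ", "))
  }
  as_sample_sheet(tab[, req])
}

#' Validate a data frame as a sample sheet
#' @param df Data frame with columns `sample_id`, `breed`, `region`.
#' @return A validated `sample_sheet` object.
#' @export
as_sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$breed <- as.character(df$breed)
  df$region <- as.character(df$region)
  if (anyDuplicated(df$sample_id)) {
    stop("sample sheet: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_region <- setdiff(unique(df$region), .REGIONS)
  if (length(bad_region)) {
    stop("sample sheet: unknown region label(s): ", paste(bad_region, collapse = ", "),
         " (expected ", paste(.REGIONS, collapse = "/"), ")")
  }
  b2r <- unique(df[, c("breed", "region")])
  if (anyDuplicated(b2r$breed)) {
    stop("sample sheet: breed mapped to two regions: ",
         paste(unique(b2r$breed[duplicated(b2r$breed)]), collapse = ", "))
  }
  attr(df, "breed_counts") <- table(df$breed)
  attr(df, "region_counts") <- table(df$region)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read gene models from GFF3
#'
#' Genes and their exons are linked through `Parent` attributes (directly, or
#' via an mRNA/transcript feature). Exons with a dangling parent are dropped
#' with a warning. The per-gene exonic union (overlapping exons counted once)
#' is precomputed.
#'
#' @param gff3_path GFF3 file with gene/exon features.
#' @param build A [genome_build()]; genes on unknown chromosomes are rejected
#'   with a warning count.
#' @return A `gene_models` list with data frames `genes` (`gene_id`,
#'   `symbol`, `chrom`, `strand`), `exons` and `exonic_union` (both
#'   `gene_id`, `chrom`, `start`, `end`).
#' @export
read_gene_models <- function(gff3_path, build) {
  stopifnot(inherits(build, "genome_build"))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  typ <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- vapply(as.list(meta$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  is_gene <- typ == "gene"
  gene_ids <- ids[is_gene]
  symbol <- if ("Name" %in% names(meta)) as.character(meta$Name)[is_gene] else rep(NA_character_, sum(is_gene))
  genes <- data.frame(gene_id = gene_ids, symbol = symbol,
                      chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
                      strand = as.character(GenomicRanges::strand(gr))[is_gene],
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "unknown"
  bad_chrom <- !(genes$chrom %in% build$chrom)
  if (any(bad_chrom)) {
    warning(sum(bad_chrom), " gene(s) on chromosomes absent from build rejected")
    genes <- genes[!bad_chrom, , drop = FALSE]
  }
  # transcript-level features route exon parents to their gene
  is_tx <- typ %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(parents[is_tx], ids[is_tx])
  is_exon <- typ == "exon"
  exon_parent <- parents[is_exon]
  exon_gene <- ifelse(exon_parent %in% genes$gene_id, exon_parent,
                      unname(tx2gene[exon_parent]))
  orphan <- is.na(exon_gene) | !(exon_gene %in% genes$gene_id)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) with dangling Parent dropped")
  }
  exons <- data.frame(gene_id = exon_gene[!orphan],
                      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon][!orphan],
                      start = GenomicRanges::start(gr)[is_exon][!orphan],
                      end = GenomicRanges::end(gr)[is_exon][!orphan],
                      stringsAsFactors = FALSE)
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon)) {
    warning(length(no_exon), " gene(s) without exons dropped: ",
            paste(utils::head(no_exon, 5), collapse = ", "))
    genes <- genes[genes$gene_id %in% exons$gene_id, , drop = FALSE]
  }
  rownames(genes) <- NULL
  out <- list(genes = genes, exons = exons,
              exonic_union = exonic_union(exons))
  class(out) <- "gene_models"
  out
}

#' Per-gene exonic union
#'
#' Merges each gene's exons so overlapping exons are not double-counted.
#'
#' @param exons Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return Data frame of disjoint per-gene intervals.
#' @export
exonic_union <- function(exons) {
  if (!nrow(exons)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  }
  pieces <- lapply(split(exons, exons$gene_id), function(e) {
    m <- merge_adjacent(e[, c("chrom", "start", "end")])
    # exonic bases are counted once even for bookended exons
    gr <- GenomicRanges::reduce(.as_granges(m))
    m <- .from_granges(GenomicRanges::sort(gr))
    m$gene_id <- e$gene_id[1]
    m
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("gene_id", "chrom", "start", "end")]
}

#' Read QTL records (Animal-QTLdb-style GFF dialect or plain TSV)
#'
#' TSV input needs columns `qtl_id`, `trait`, `chrom`, `start`, `end`. The
#' GFF dialect is detected from 9-column tab layout with `QTL_ID=` in the
#' attribute field; trait names are taken verbatim from the `Name` attribute.
#' Records without a trait name or with `end < start` are record errors and
#' dropped with a warning.
#'
#' @param path Input path.
#' @param build A [genome_build()] for chromosome validation.
#' @param format `"auto"`, `"tsv"` or `"gff"`.
#' @return Data frame `qtl_id`, `trait`, `chrom`, `start`, `end`.
#' @export
read_qtl <- function(path, build, format = c("auto", "tsv", "gff")) {
  format <- match.arg(format)
  stopifnot(inherits(build, "genome_build"))
  if (format == "auto") {
    first <- readLines(path, n = 50)
    body <- first[!startsWith(first, "#")]
    format <- if (length(body) && grepl("QTL_ID=", body[1])) "gff" else "tsv"
  }
  if (format == "gff") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t")
    ok9 <- lengths(f) >= 9
    if (any(!ok9)) warning(sum(!ok9), " malformed QTL GFF line(s) dropped")
    f <- f[ok9]
    chrom <- sub("^[Cc]hr\\.?", "", vapply(f, `[`, character(1), 1))
    start <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 4)))
    end <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 5)))
    attrs <- vapply(f, `[`, character(1), 9)
    getattr <- function(key) {
      m <- regmatches(attrs, regexpr(paste0(key, "=(\"[^\"]*\"|[^;]*)"), attrs))
      out <- rep(NA_character_, length(attrs))
      hit <- regmatches(attrs, gregexpr(paste0(key, "=(\"[^\"]*\"|[^;]*)"), attrs))
      vapply(hit, function(x) {
        if (!length(x)) return(NA_character_)
        gsub("\"", "", sub(paste0("^", key, "="), "", x[[1]]))
      }, character(1))
    }
    qtl <- data.frame(qtl_id = getattr("QTL_ID"), trait = getattr("Name"),
                      chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if ("trait_name" %in% names(tab) && !"trait" %in% names(tab)) {
      names(tab)[names(tab) == "trait_name"] <- "trait"
    }
    req <- c("qtl_id", "trait", "chrom", "start", "end")
    if (!all(req %in% names(tab))) {
      stop("read_qtl: missing columns: ", paste(setdiff(req, names(tab)), collapse = ", "))
    }
    qtl <- tab[, req]
    qtl$chrom <- as.character(qtl$chrom)
    qtl$qtl_id <- as.character(qtl$qtl_id)
    qtl$trait <- as.character(qtl$trait)
  }
  no_trait <- is.na(qtl$trait) | !nzchar(trimws(qtl$trait))
  bad_coord <- !is.finite(qtl$start) | !is.finite(qtl$end) | qtl$end < qtl$start
  if (any(no_trait)) warning(sum(no_trait), " QTL record(s) without trait name dropped")
  if (any(bad_coord)) warning(sum(bad_coord), " QTL record(s) with malformed coordinates dropped")
  qtl <- qtl[!no_trait & !bad_coord, , drop = FALSE]
  bad_chrom <- !(qtl$chrom %in% build$chrom)
  if (any(bad_chrom)) {
    warning(sum(bad_chrom), " QTL record(s) on chromosomes absent from build rejected")
    qtl <- qtl[!bad_chrom, , drop = FALSE]
  }
  rownames(qtl) <- NULL
  qtl
}

#' Read gene models and QTL together
#' @param gff3_path Gene-model GFF3 path.
#' @param qtl_path QTL table path (GFF dialect or TSV).
#' @param build A [genome_build()].
#' @return List with elements `genes` (a `gene_models` object) and `qtl`.
#' @export
read_annotations <- function(gff3_path, qtl_path, build) {
  list(genes = read_gene_models(gff3_path, build),
       qtl = read_qtl(qtl_path, build))
}

#' Read gene sets from a GMT file
#' @param path GMT path (tab-separated: set name, description, gene ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read qPCR Ct triplicates
#'
#' TSV with columns `sample_id`, `assay_id`, `ct_t1..ct_t3`, `ct_r1..ct_r3`
#' and optional `predicted_type` (loss/gain). Ct values must be finite and
#' positive; incomplete triplicates are fatal.
#'
#' @param path Input TSV.
#' @return Data frame of measurements.
#' @export
read_qpcr <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  req <- c("sample_id", "assay_id", paste0("ct_t", 1:3), paste0("ct_r", 1:3))
  if (!all(req %in% names(tab))) {
    stop("read_qpcr: missing columns: ", paste(setdiff(req, names(tab)), collapse = ", "))
  }
  if (!"predicted_type" %in% names(tab)) tab$predicted_type <- NA_character_
  ct <- as.matrix(tab[, c(paste0("ct_t", 1:3), paste0("ct_r", 1:3))])
  if (anyNA(ct)) stop("read_qpcr: incomplete triplicate (missing Ct value)")
  if (any(!is.finite(ct)) || any(ct <= 0)) stop("read_qpcr: Ct values must be finite and positive")
  tab[, c(req, "predicted_type")]
}

# ---- table writers / readers (round-trip safe) ------------------------------

.fmt_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Write CNVRs as TSV (1-based inclusive)
#' @param cnvrs A `cnvr` data frame (see [build_tool_cnvrs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvr_tsv <- function(cnvrs, path) {
  cols <- c("cnvr_id", "chrom", "start", "end", "cnvr_type", "tools", "samples", "n_calls")
  .fmt_write(as.data.frame(cnvrs)[, cols, drop = FALSE], path)
}

#' Read CNVRs written by [write_cnvr_tsv()]
#' @param path Input path.
#' @return A `cnvr` data frame.
#' @export
read_cnvr_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("chrom", "cnvr_type", "tools", "samples")))
  df$chrom <- as.character(df$chrom)
  class(df) <- c("cnvr", "data.frame")
  df
}

#' Write CNVRs (or any interval table) as BED
#'
#' BED is 0-based half-open: start is decremented by 1, end is kept. The name
#' column carries the region type where available.
#'
#' @param x Interval data frame (optionally with a `cnvr_type` or `cnv_type`
#'   column used as the BED name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  .check_intervals(x)
  name <- if ("cnvr_type" %in% names(x)) x$cnvr_type
          else if ("cnv_type" %in% names(x)) x$cnv_type
          else rep(".", nrow(x))
  bed <- data.frame(chrom = x$chrom, start = x$start - 1, end = x$end, name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write CNV calls as TSV
#' @param calls A `cnv_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("sample_id", "tool", "chrom", "start", "end", "cnv_type",
            "copy_number", "genotype")
  .fmt_write(as.data.frame(calls)[, cols, drop = FALSE], path)
}

#' Read CNV calls written by [write_calls_tsv()]
#' @param path Input path.
#' @return A `cnv_calls` data frame.
#' @export
read_calls_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("sample_id", "tool", "chrom",
                                                          "cnv_type", "genotype")))
  df$copy_number <- as.integer(df$copy_number)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' Write a numeric matrix as TSV with row labels
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  .fmt_write(df, path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Matrix with row names from the `id` column.
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a phylogenetic tree as Newick
#' @param tree An `ape::phylo` object or the list returned by
#'   [neighbor_joining()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo") && !is.null(tree$phylo)) tree <- tree$phylo
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Persist a set of pipeline objects to a directory
#'
#' CNVR tables are written both as TSV (1-based inclusive, with type/support
#' columns) and BED (0-based half-open); call tables as TSV; matrices as TSV;
#' trees as Newick. Reading back any emitted TSV reproduces the in-memory
#' object.
#'
#' @param objects Named list; element classes decide the format (`cnvr`,
#'   `cnv_calls`, `matrix`, `phylo`/NJ result, plain data frames fall back to
#'   TSV).
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of files written, invisibly.
#' @export
write_tables <- function(objects, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("write_tables: cannot create ", out_dir)
  written <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (inherits(obj, "cnvr")) {
      p1 <- file.path(out_dir, paste0(nm, ".tsv")); write_cnvr_tsv(obj, p1)
      p2 <- file.path(out_dir, paste0(nm, ".bed")); write_bed(obj, p2)
      written <- c(written, p1, p2)
    } else if (inherits(obj, "cnv_calls")) {
      p <- file.path(out_dir, paste0(nm, ".tsv")); write_calls_tsv(obj, p)
      written <- c(written, p)
    } else if (is.matrix(obj)) {
      p <- file.path(out_dir, paste0(nm, ".tsv")); write_matrix_tsv(obj, p)
      written <- c(written, p)
    } else if (inherits(obj, "phylo") || (is.list(obj) && !is.null(obj$phylo))) {
      p <- file.path(out_dir, paste0(nm, ".nwk")); write_tree_newick(obj, p)
      written <- c(written, p)
    } else if (is.data.frame(obj)) {
      p <- file.path(out_dir, paste0(nm, ".tsv")); .fmt_write(obj, p)
      written <- c(written, p)
    } else {
      stop("write_tables: unsupported object class for '", nm, "'")
    }
  }
  invisible(written)
}
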