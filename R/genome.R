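#' Construct a genome build table
#'
#' A genome build is the coordinate authority for the whole pipeline: every
#' reader validates chromosome names against it, and all genome fractions are
#' computed over its autosomal length.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length_bp Positive integer chromosome lengths in base pairs.
#' @param is_autosome Logical flags marking autosomes.
#' @param name Name of the build (free text).
#'
#' @return A `genome_build` object: a data frame with columns `chrom`,
#'   `length_bp`, `is_autosome` and attributes `name` and `autosomal_length`.
#' @examples
#' gb <- genome_build(c("1", "2", "X"), c(1e6, 8e5, 5e5), c(TRUE, TRUE, FALSE))
#' autosomal_length(gb)
#' @export
genome_build <- function(chrom, length_bp, is_autosome, name = "custom") {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) {
    stop("genome_build: duplicated chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("genome_build: chromosome lengths must be positive")
  }
  is_autosome <- as.logical(is_autosome)
  if (anyNA(is_autosome)) stop("genome_build: is_autosome must be TRUE/FALSE")
  auto_len <- sum(length_bp[is_autosome])
  if (auto_len <= 0) stop("genome_build: build must contain at least one autosome")
  out <- data.frame(chrom = chrom, length_bp = length_bp,
                    is_autosome = is_autosome, stringsAsFactors = FALSE)
  attr(out, "name") <- name
  attr(out, "autosomal_length") <- auto_len
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Summed length of all autosomes in a build
#'
#' @param build A [genome_build()] object.
#' @return Numeric scalar, base pairs.
#' @export
autosomal_length <- function(build) {
  stopifnot(inherits(build, "genome_build"))
  attr(build, "autosomal_length")
}

#' Chromosome names of the autosomes in a build
#' @param build A [genome_build()] object.
#' @return Character vector.
#' @export
autosome_names <- function(build) {
  stopifnot(inherits(build, "genome_build"))
  build$chrom[build$is_autosome]
}

#' The Sus scrofa 11.1 genome build
#'
#' Chromosome lengths of the pig reference assembly Sscrofa11.1 (Ensembl
#' assembly metadata): autosomes 1-18 plus the X chromosome. Autosomes 1-18
#' sum to 2,265,774,640 bp, the denominator for all autosomal genome
#' fractions.
#'
#' @return A [genome_build()] object.
#' @examples
#' autosomal_length(sus_scrofa_11_1())
#' @export
sus_scrofa_11_1 <- function() {
  genome_build(
    chrom = c(as.character(1:18), "X"),
    length_bp = c(274330532, 151935994, 132848913, 130910915, 104526007,
                  170843587, 121844099, 138966237, 139512083, 69359453,
                  79169978, 61602749, 208334590, 141755446, 140412725,
                  79944280, 63494081, 55982971, 125939595),
    is_autosome = c(rep(TRUE, 18), FALSE),
    name = "Sscrofa11.1"
  )
}

#' Read a genome build from a tab-separated table
#'
#' Expects columns `chrom`, `length_bp`, `is_autosome` (logical or 0/1).
#'
#' @param path Path to a TSV file.
#' @param name Build name; defaults to the file name.
#' @return A [genome_build()] object.
#' @export
read_genome_build <- function(path, name = basename(path)) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("chrom", "length_bp", "is_autosome")
  if (!all(req %in% names(tab))) {
    stop("read_genome_build: missing columns: ",
         paste(setdiff(req, names(tab)), collapse = ", "))
  }
  genome_build(tab$chrom, tab$length_bp, as.logical(tab$is_autosome), name = name)
}

#' Write a genome build as a tab-separated table
#' @param build A [genome_build()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_build <- function(build, path) {
  stopifnot(inherits(build, "genome_build"))
  df <- as.data.frame(build)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
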