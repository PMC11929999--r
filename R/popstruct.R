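# Population structure from the binary CNV presence/absence matrix:
# distance matrices, classical multidimensional scaling, and a
# neighbour-joining tree.

#' Binary CNV presence/absence matrix
#'
#' One row per sample of the sheet, one column per union locus; a cell is 1
#' iff the sample contributed at least one member call to the locus.
#'
#' @param loci Result of [build_union_loci()] (list with `loci`, `members`).
#' @param sheet A `sample_sheet`.
#' @return Integer matrix `samples x loci` with dimnames; every column has at
#'   least one presence by construction.
#' @export
binary_matrix <- function(loci, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  members <- loci$members
  unknown <- setdiff(unique(members$sample_id), sheet$sample_id)
  if (length(unknown)) {
    stop("binary_matrix: sample(s) in loci absent from sheet: ",
         paste(unknown, collapse = ", "))
  }
  ids <- loci$loci$locus_id
  m <- matrix(0L, nrow = nrow(sheet), ncol = length(ids),
              dimnames = list(sheet$sample_id, paste0("locus_", ids)))
  if (nrow(members)) {
    m[cbind(match(members$sample_id, sheet$sample_id),
            match(members$locus_id, ids))] <- 1L
  }
  if (ncol(m) && any(colSums(m) == 0)) {
    stop("binary_matrix: locus without members (violates construction invariant)")
  }
  m
}

#' Pairwise distances between samples from a binary matrix
#'
#' Jaccard distance (default): 1 minus the ratio of shared to pooled presence
#' loci of a sample pair. Simple matching distance: fraction of loci at which
#' the two samples disagree. A pair with an empty union has distance 0 by
#' convention (with a warning).
#'
#' @param m Binary matrix from [binary_matrix()].
#' @param metric `"jaccard"` or `"simple_matching"`.
#' @return A `dist_matrix` object: symmetric numeric matrix with zero
#'   diagonal and values in `[0, 1]`.
#' @export
cnv_distance <- function(m, metric = c("jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2) stop("cnv_distance: need at least 2 samples")
  n <- nrow(m)
  mm <- matrix(as.numeric(m), nrow = n)
  inter <- mm %*% t(mm)
  rs <- rowSums(mm)
  uni <- outer(rs, rs, "+") - inter
  if (metric == "jaccard") {
    empty <- uni == 0
    if (any(empty[upper.tri(empty)])) {
      warning("sample pair(s) with empty presence union; distance set to 0")
    }
    d <- ifelse(uni > 0, 1 - inter / uni, 0)
  } else {
    agree <- inter + ((1 - mm) %*% t(1 - mm))
    d <- 1 - agree / ncol(mm)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  class(d) <- c("dist_matrix", class(d))
  d
}

.check_dist <- function(d) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(d < -1e-12)) stop("distance matrix must be nonnegative")
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Squares the distances, double-centres, eigendecomposes, and returns the
#' top-`k` coordinates scaled by the square root of the eigenvalues. Axes
#' with nonpositive eigenvalues are excluded (their count is reported in
#' attribute `n_negative_eig`). Each axis's sign is fixed deterministically
#' by making its largest-magnitude coordinate positive.
#'
#' @param d Distance matrix (object from [cnv_distance()] or any symmetric
#'   matrix with zero diagonal).
#' @param k Number of dimensions (default 2).
#' @return Numeric matrix `samples x k'` (`k' <= k` if fewer positive
#'   eigenvalues exist) with attributes `eigenvalues` and `n_negative_eig`.
#' @export
classical_mds <- function(d, k = 2) {
  if (k <= 0) stop("classical_mds: k must be positive")
  d <- .check_dist(d)
  n <- nrow(d)
  if (n <= k) stop("classical_mds: need more samples than dimensions")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- eig$values > max(1e-12, 1e-9 * abs(eig$values[1]))
  n_use <- min(k, sum(pos))
  if (n_use == 0) stop("classical_mds: no positive eigenvalue; degenerate configuration")
  coords <- eig$vectors[, seq_len(n_use), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(n_use)]), n_use)
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  attr(coords, "eigenvalues") <- eig$values
  attr(coords, "n_negative_eig") <- sum(eig$values < -1e-12)
  coords
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard agglomeration: at each step the pair minimising the Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined; branch
#' lengths come from the canonical closed forms. Ties are broken by the
#' lexicographically smallest label pair (internal nodes carry the smallest
#' leaf label beneath them), making the result deterministic. Negative
#' branch-length estimates are clamped to zero with the deficit moved to the
#' sister branch; the number of clamped branches is reported. Exact on
#' additive distance matrices.
#'
#' @param d Symmetric nonnegative distance matrix with labels; >= 2 taxa
#'   (2 taxa give a single edge of the given length).
#' @return List with `phylo` (an `ape` tree re-parsed from the emitted
#'   Newick), `newick` (character) and `n_clamped`.
#' @export
neighbor_joining <- function(d) {
  d <- .check_dist(d)
  n <- nrow(d)
  if (n < 2) stop("neighbor_joining: need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels          # growing newick fragment per active node
  key <- labels           # smallest leaf label beneath, for tie-breaking
  D <- d
  n_clamped <- 0L
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- cbind(pmin(key[cand[, 1]], key[cand[, 2]]),
                       pmax(key[cand[, 1]], key[cand[, 2]]))
    best <- order(pair_keys[, 1], pair_keys[, 2])[1]
    i <- cand[best, 1]; j <- cand[best, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0; n_clamped <- n_clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; n_clamped <- n_clamped + 1L }
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":", fmt(bj), ")")
    newkey <- min(key[i], key[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  if (nrow(D) == 3) {
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    bl <- c(a, b, c3)
    for (i in seq_along(bl)) if (bl[i] < 0) {
      bl[i] <- 0; n_clamped <- n_clamped + 1L
    }
    ord <- order(key)
    newick <- paste0("(", paste0(frag[ord], ":", fmt(bl[ord]), collapse = ","), ");")
  } else {
    half <- D[1, 2] / 2
    ord <- order(key)
    newick <- paste0("(", frag[ord[1]], ":", fmt(half), ",",
                     frag[ord[2]], ":", fmt(half), ");")
  }
  phylo <- ape::read.tree(text = newick)
  list(phylo = phylo, newick = newick, n_clamped = n_clamped)
}

#' MDS coordinates annotated with breed and region
#'
#' Convenience wrapper joining [classical_mds()] output with the sample
#' sheet for export.
#'
#' @param coords Matrix from [classical_mds()].
#' @param sheet A `sample_sheet`.
#' @return Data frame `sample_id`, `dim...`, `breed`, `region`.
#' @export
mds_table <- function(coords, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  df <- data.frame(sample_id = rownames(coords), coords, row.names = NULL,
                   check.names = FALSE)
  idx <- match(df$sample_id, sheet$sample_id)
  df$breed <- sheet$breed[idx]
  df$region <- sheet$region[idx]
  df
}
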