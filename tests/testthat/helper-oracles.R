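# Independent brute-force oracles. These recompute expected results by
# direct enumeration / per-base arithmetic and deliberately share no code
# with the package implementation.

# pairwise reciprocal overlap by plain arithmetic
oracle_ro <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  ov / max(e1 - s1 + 1, e2 - s2 + 1)
}

# transitive closure clustering via boolean matrix powering
oracle_ro_clusters <- function(df, threshold) {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && oracle_ro(df$chrom[i], df$start[i], df$end[i],
                            df$chrom[j], df$start[j], df$end[j]) >= threshold) {
      adj[i, j] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  for (i in seq_len(n)) comp[i] <- min(which(adj[i, ]))
  comp
}

# per-base density trimming of one merged candidate region
oracle_trim <- function(calls, density_min) {
  stopifnot(length(unique(calls$chrom)) == 1)
  lo <- min(calls$start); hi <- max(calls$end)
  cov <- integer(hi - lo + 1)
  for (i in seq_len(nrow(calls))) {
    idx <- (calls$start[i] - lo + 1):(calls$end[i] - lo + 1)
    cov[idx] <- cov[idx] + 1L
  }
  keep <- cov >= density_min * nrow(calls)
  if (!any(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(keep)
  hi_i <- cumsum(r$lengths); lo_i <- hi_i - r$lengths + 1
  out <- data.frame(start = lo + lo_i[r$values] - 1, end = lo + hi_i[r$values] - 1)
  rownames(out) <- NULL
  out
}

# one-sided hypergeometric tail by explicit summation of choose() terms
oracle_hyper_tail <- function(a, K, n, N) {
  if (a <= 0) return(1)
  ks <- max(a, max(0, n - (N - K))):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random interval set on a small genome
random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len - 1, stringsAsFactors = FALSE)
}

# Procrustes residual after optimal rotation/reflection + translation
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$v %*% t(s$u)
  sum((Yc %*% R - Xc)^2)
}

# tiny sample sheet factories
toy_sheet <- function() {
  as_sample_sheet(data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c2"),
    breed = c("A", "A", "A", "B", "B", "C", "C"),
    region = c("America", "America", "America", "AsiaOceania", "AsiaOceania",
               "Europe", "Europe")))
}

toy_build <- function() genome_build(c("1", "2", "X"), c(1e7, 1e7, 1e6),
                                     c(TRUE, TRUE, FALSE), name = "toy")

make_calls <- function(chrom, start, end, type = "loss", sample = "s1",
                       tool = "t1", cn = NA_integer_, geno = "unknown") {
  df <- data.frame(sample_id = sample, tool = tool, chrom = as.character(chrom),
                   start = start, end = end, cnv_type = type,
                   copy_number = as.integer(cn), genotype = geno,
                   stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}
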