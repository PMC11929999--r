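test_that("size and chromosome filters follow the 50 bp / 5 Mb / autosome rules", {
  build <- toy_build()
  calls <- make_calls(
    chrom = c("1", "1", "1", "X"),
    start = c(1000, 2000, 10000, 5000),
    end = c(1048, 2000 + 5e6, 10999, 6000),
    sample = "s1")
  # lengths: 49 (too short), 5,000,001 (too long), 1000 (ok), X (non-autosomal)
  out <- filter_calls(calls, build)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 10000)
  removed <- attr(out, "removed")
  expect_equal(unname(removed["too_short"]), 1L)
  expect_equal(unname(removed["too_long"]), 1L)
  expect_equal(unname(removed["non_autosomal"]), 1L)
  expect_equal(sum(removed), nrow(calls) - nrow(out))
  # boundary: exactly 50 bp and exactly 5 Mb survive
  edge <- make_calls("1", c(100, 10000), c(149, 10000 + 5e6 - 1))
  expect_equal(nrow(filter_calls(edge, build)), 2)
})

test_that("copy number classification rejects the diploid state", {
  expect_equal(classify_call_type(0), "loss")
  expect_equal(classify_call_type(1), "loss")
  expect_equal(classify_call_type(5), "gain")
  expect_error(classify_call_type(2), "not a CNV")
  expect_equal(classify_call_type(svtype = "DEL"), "loss")
  expect_equal(classify_call_type(svtype = "DUP"), "gain")
})

test_that("union loci pool same-type calls across tools and samples", {
  calls <- rbind(
    make_calls("1", 1000, 1999, sample = "s1", tool = "a"),
    make_calls("1", 1000, 1999, sample = "s1", tool = "b"),
    make_calls("1", 1100, 2099, sample = "s2", tool = "a"))
  ul <- build_union_loci(calls, 0.5)
  expect_equal(nrow(ul$loci), 1)
  expect_equal(ul$loci$n_members, 3L)
  expect_equal(ul$loci$n_samples, 2L)
  expect_equal(ul$loci$start, 1000)
  expect_equal(ul$loci$end, 2099)
  # same coordinates but opposite types never merge
  mixed <- rbind(make_calls("1", 5000, 6000, type = "loss"),
                 make_calls("1", 5000, 6000, type = "gain"))
  ul2 <- build_union_loci(mixed)
  expect_equal(nrow(ul2$loci), 2)
  expect_setequal(ul2$loci$cnv_type, c("loss", "gain"))
})

test_that("every call lands in exactly one union locus", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- random_intervals(n, max_pos = 2000, max_len = 500)
    calls <- make_calls(x$chrom, x$start, x$end,
                        type = sample(c("loss", "gain"), n, replace = TRUE),
                        sample = sample(paste0("s", 1:4), n, replace = TRUE),
                        tool = sample(c("a", "b"), n, replace = TRUE))
    ul <- build_union_loci(calls)
    expect_setequal(ul$members$call_row, seq_len(n))
    expect_equal(anyDuplicated(ul$members$call_row), 0L)
    # locus count matches the per-type brute-force closure oracle
    n_oracle <- sum(vapply(c("loss", "gain"), function(ty) {
      sub <- calls[calls$cnv_type == ty, , drop = FALSE]
      if (!nrow(sub)) return(0L)
      length(unique(oracle_ro_clusters(sub, 0.5)))
    }, integer(1)))
    expect_equal(nrow(ul$loci), n_oracle)
  }
})

test_that("extreme-copy-number extraction requires universal support", {
  samples <- c("s1", "s2", "s3")
  base <- rbind(
    make_calls("1", 1000, 2000, sample = "s1", cn = 0, geno = "hom"),
    make_calls("1", 1005, 2004, sample = "s2", cn = 0, geno = "hom"),
    make_calls("1", 995, 1998, sample = "s3", cn = 0, geno = "hom"),
    make_calls("1", 50000, 60000, sample = "s1", cn = 5),
    make_calls("1", 50000, 60000, sample = "s2", cn = 4))
  res <- extract_extreme_cn_shared(base, samples)
  # the cn=0 locus is in all three samples; the gain locus misses s3
  expect_equal(nrow(res$loci), 1)
  expect_equal(res$loci$cnv_type, "loss")
  # heterozygous deletions (cn 1) never enter the input
  het <- rbind(base, make_calls("1", 1000, 2000, sample = "s3", cn = 1, geno = "het"))
  res2 <- extract_extreme_cn_shared(het, samples)
  expect_equal(nrow(res2$loci), 1)
  expect_error(extract_extreme_cn_shared(base, character(0)), "empty sample list")
})

test_that("adding required samples never grows the universal locus set", {
  run <- noiseless_dataset()
  calls <- do.call(rbind, lapply(run$data$tool_calls, as.data.frame))
  class(calls) <- c("cnv_calls", "data.frame")
  sheet <- run$data$sheet
  subsets <- list(sheet$sample_id[1:6], sheet$sample_id[1:18], sheet$sample_id)
  counts <- vapply(subsets, function(s) {
    sub <- calls[calls$sample_id %in% s, , drop = FALSE]
    nrow(extract_extreme_cn_shared(sub, s)$loci)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("exon overlap selection is inclusive at the 50 percent boundary", {
  gm <- list(
    genes = data.frame(gene_id = c("g1", "g2"), symbol = NA, chrom = "1",
                       strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("g1", "g2"), chrom = "1",
                       start = c(1000, 9000), end = c(1499, 9099)),
    exonic_union = data.frame(gene_id = c("g1", "g2"), chrom = "1",
                              start = c(1000, 9000), end = c(1499, 9099)))
  class(gm) <- "gene_models"
  loci <- data.frame(locus_id = 1:3, chrom = "1",
                     start = c(1000, 1001, 20000),
                     end = c(1999, 2000, 20999), cnv_type = "loss")
  # locus 1: 500/1000 exonic bases -> retained; locus 2: 499/1000 -> dropped;
  # locus 3: entirely intergenic -> dropped
  sel <- exon_overlap_select(loci, gm, 0.5)
  expect_equal(sel$locus_id, 1L)
  expect_equal(sel$exon_frac, 0.5)
  expect_equal(sel$genes, "g1")
})
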