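test_that("per-tool CNVRs merge same-type calls and trim low-density flanks", {
  # 10 overlapping losses, no gain: one loss CNVR
  calls <- make_calls("1", 1000 + (0:9) * 10, 5000 + (0:9) * 10,
                      sample = paste0("s", 1:10))
  cnvrs <- build_tool_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1)
  expect_equal(cnvrs$cnvr_type, "loss")
  expect_equal(cnvrs$n_calls, 10L)

  # 20 calls sharing a core plus one call extending a 1-kb flank:
  # flank support 1/20 = 0.05 < 0.10 -> trimmed off
  core <- make_calls("1", rep(10000, 19), rep(20000, 19),
                     sample = paste0("s", 1:19))
  flank <- make_calls("1", 9000, 20000, sample = "s20")
  trimmed <- build_tool_cnvrs(rbind(core, flank))
  expect_equal(trimmed$start, 10000)
  expect_equal(trimmed$end, 20000)
  # oracle agreement on the same candidate region
  want <- oracle_trim(rbind(core, flank), 0.10)
  expect_equal(as.data.frame(trimmed)[, c("start", "end")], want)

  expect_error(build_tool_cnvrs(rbind(
    make_calls("1", 1, 100, tool = "a"), make_calls("1", 1, 100, tool = "b"))),
    "exactly one tool")
})

test_that("density trimming splits regions at interior low-support segments", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    start <- sample.int(500, n, replace = TRUE)
    len <- sample.int(400, n, replace = TRUE)
    calls <- make_calls("1", start, start + len - 1, sample = paste0("s", 1:n))
    got <- build_tool_cnvrs(calls)
    # oracle: merge candidates per base, then trim each independently
    cand <- merge_adjacent(calls)
    want <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      inside <- calls$start <= cand$end[i] & calls$end >= cand$start[i]
      oracle_trim(calls[inside, , drop = FALSE], 0.10)
    }))
    want <- want[order(want$start), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(as.data.frame(got)[, c("start", "end")], want)
    # trimming never expands the candidate span
    expect_true(all(got$start >= min(calls$start)))
    expect_true(all(got$end <= max(calls$end)))
  }
})

test_that("rebuilding CNVRs from their own spans is a fixed point", {
  set.seed(78)
  x <- random_intervals(30, chroms = "1", max_pos = 3000, max_len = 600)
  calls <- make_calls(x$chrom, x$start, x$end, sample = paste0("s", 1:30))
  once <- build_tool_cnvrs(calls)
  again <- build_tool_cnvrs(make_calls(once$chrom, once$start, once$end,
                                       sample = paste0("r", seq_len(nrow(once)))))
  expect_equal(again[, c("chrom", "start", "end")],
               once[, c("chrom", "start", "end")])
})

test_that("overlapping post-trim loss and gain regions fuse into 'both'", {
  calls <- rbind(
    make_calls("1", rep(1, 3), rep(500, 3), type = "loss", sample = paste0("s", 1:3)),
    make_calls("1", rep(400, 3), rep(900, 3), type = "gain", sample = paste0("s", 4:6)))
  cnvrs <- build_tool_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1)
  expect_equal(cnvrs$cnvr_type, "both")
  expect_equal(cnvrs$start, 1)
  expect_equal(cnvrs$end, 900)
  expect_equal(cnvrs$n_calls, 6L)
})

test_that("consensus requires one-bp overlap from at least two tools", {
  mk <- function(tool, start, end, type = "loss", samples = "s1") {
    cnvpool:::.cnvr_df(chrom = "1", start = start, end = end, cnvr_type = type,
                       tools = tool, samples = samples,
                       n_calls = rep(1L, length(start)))
  }
  # one-bp overlap between tools a and b
  cons <- consensus_cnvrs(list(mk("a", 1000, 2000), mk("b", 2000, 3000)))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$tools, "a,b")
  expect_equal(cons$start, 1000)
  expect_equal(cons$end, 3000)
  # single-tool regions are discarded
  cons2 <- consensus_cnvrs(list(mk("a", 1000, 2000), mk("b", 50000, 60000)))
  expect_equal(nrow(cons2), 0)
  # a gain meeting only a loss: no same-type partner, both discarded
  cons3 <- consensus_cnvrs(list(mk("a", 1000, 2000, type = "gain"),
                                mk("b", 1500, 2500, type = "loss")))
  expect_equal(nrow(cons3), 0)
  # 'both' regions combine with either type and the fusion is retyped
  cons4 <- consensus_cnvrs(list(mk("a", 1000, 2000, type = "both"),
                                mk("b", 1500, 2500, type = "loss")))
  expect_equal(nrow(cons4), 1)
  expect_equal(cons4$cnvr_type, "both")
  expect_error(consensus_cnvrs(list(mk("a", 1, 10))), "at least 2")
})

test_that("every consensus CNVR is supported by at least min_tools tools", {
  run <- default_pipeline_run()
  cons <- read_cnvr_tsv(file.path(run$out_dir, "shared_all_breeds.tsv"))
  if (nrow(cons)) {
    n_tools <- lengths(strsplit(cons$tools, ","))
    expect_true(all(n_tools >= 2))
  }
})

test_that("sharing rules count supporting individuals, not calls", {
  sheet <- toy_sheet()
  cnvrs <- cnvpool:::.cnvr_df(chrom = "1", start = c(1000, 50000, 90000),
                              end = c(2000, 60000, 91000),
                              cnvr_type = "loss", tools = "a,b",
                              samples = "", n_calls = c(10L, 10L, 10L))
  # region 1: >=2 supporters in every breed; region 2: only breed A;
  # region 3: a single supporter (singleton)
  sup <- c(sheet$sample_id,                     # all 7 on region 1
           c("a1", "a2"),                       # region 2
           "c1")                                # region 3
  calls <- make_calls("1",
                      c(rep(1000, 7), rep(50000, 2), 90000),
                      c(rep(2000, 7), rep(60000, 2), 91000),
                      sample = sup)
  shared <- shared_cnvrs(cnvrs, calls, sheet, mode = "per_breed_min2")
  expect_equal(shared$start, 1000)
  expect_equal(shared$samples, paste(sort(sheet$sample_id), collapse = ","))
  expect_equal(nrow(attr(shared, "singletons")), 1)
  expect_equal(attr(shared, "singletons")$start, 90000)
  expect_equal(nrow(attr(shared, "doubletons")), 1)
  # region_all: 2 of 3 American animals is not enough
  reg <- shared_cnvrs(cnvrs, calls, sheet, mode = "region_all", region = "America")
  expect_equal(reg$start, 1000)
  calls_all_am <- rbind(calls, make_calls("1", 50000, 60000, sample = "a3"))
  reg2 <- shared_cnvrs(cnvrs, calls_all_am, sheet, mode = "region_all",
                       region = "America")
  expect_setequal(reg2$start, c(1000, 50000))
  # a breed with one sampled animal cannot satisfy the >=2 rule
  thin <- as_sample_sheet(data.frame(sample_id = c("x1", "y1", "y2"),
                                     breed = c("X", "Y", "Y"),
                                     region = c("Europe", "Europe", "Europe")))
  expect_error(shared_cnvrs(cnvrs, calls, thin, mode = "per_breed_min2"),
               "fewer than 2")
})

test_that("exclusive CNVRs tolerate zero overlap with other regions", {
  mk <- function(start, end) cnvpool:::.cnvr_df("1", start, end, "loss", "a,b",
                                                "s", rep(1L, length(start)))
  target <- mk(c(1000, 5000), c(2000, 6000))
  # 1-bp contact with another region's CNVR disqualifies
  other <- mk(2000, 3000)
  excl <- exclusive_cnvrs(target, list(other))
  expect_equal(excl$start, 5000)
  # fully disjoint target survives whole
  excl2 <- exclusive_cnvrs(target, list(mk(90000, 95000)))
  expect_equal(nrow(excl2), 2)
  # identical sets annihilate
  expect_equal(nrow(exclusive_cnvrs(target, list(target))), 0)
})

test_that("summary statistics satisfy the partition and mean identities", {
  build <- toy_build()
  cnvrs <- cnvpool:::.cnvr_df(chrom = rep("1", 4), start = c(1, 1000, 5000, 9000),
                              end = c(180, 1999, 5999, 9999),
                              cnvr_type = c("loss", "loss", "gain", "both"),
                              tools = "a,b", samples = "s1",
                              n_calls = rep(2L, 4))
  s <- summarize_cnvrs(cnvrs, build)
  expect_equal(s$n_total, s$n_loss + s$n_gain + s$n_both)
  expect_equal(sum(s$per_chrom), s$n_total)
  expect_equal(s$total_bp, 180 + 1000 + 1000 + 1000)
  expect_equal(s$mean_len, round(s$total_bp / 4, 2))
  expect_equal(s$min_len, 180)
  expect_equal(s$genome_fraction_pct, round(100 * s$total_bp / autosomal_length(build), 2))
  empty <- summarize_cnvrs(cnvrs[0, ], build)
  expect_equal(empty$n_total, 0L)
  expect_equal(empty$genome_fraction_pct, 0)
})
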