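test_that("the planted truth table honours class structure and disjointness", {
  cfg <- synthetic_config(seed = 5)
  truth <- plant_truth(cfg)
  sheet <- synthetic_sample_sheet(cfg)
  expect_equal(nrow(sheet), 36)
  expect_equal(length(unique(sheet$breed)), 9)
  expect_equal(length(unique(sheet$region)), 3)
  # class counts as configured
  expect_equal(sum(truth$class == "common"), cfg$n_common)
  expect_equal(sum(truth$class == "region_exclusive"), 3 * cfg$n_region_exclusive)
  expect_equal(sum(truth$class == "singleton"), cfg$n_singleton)
  expect_equal(sum(truth$class == "doubleton"), cfg$n_doubleton)
  # planted intervals are pairwise disjoint in genomic space
  m <- merge_adjacent(truth[, c("chrom", "start", "end")])
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(truth$end <= 1e7) && all(truth$start >= 1))
  # carriers per class
  carriers <- strsplit(truth$carriers, ",")
  expect_true(all(lengths(carriers[truth$class == "common"]) == 36))
  expect_true(all(lengths(carriers[truth$class == "singleton"]) == 1))
  expect_true(all(lengths(carriers[truth$class == "doubleton"]) == 2))
  for (i in which(truth$class == "region_exclusive")) {
    members <- sheet$sample_id[sheet$region == truth$region[i]]
    expect_setequal(carriers[[i]], members)
  }
  for (i in which(truth$class == "breed")) {
    members <- sheet$sample_id[sheet$breed == truth$breed[i]]
    expect_gte(length(carriers[[i]]), 2)
    expect_true(all(carriers[[i]] %in% members))
  }
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 9)
  t1 <- plant_truth(cfg); t2 <- plant_truth(cfg)
  expect_identical(t1, t2)
  c1 <- emit_tool_calls(t1, cfg); c2 <- emit_tool_calls(t2, cfg)
  expect_identical(c1, c2)
  a1 <- emit_annotations(t1, cfg); a2 <- emit_annotations(t2, cfg)
  expect_identical(a1, a2)
})

test_that("the loss fraction lands inside its binomial bounds", {
  # pool several seeds for ~200 planted CNVRs at loss_fraction 0.9
  n_loss <- 0; n_tot <- 0
  for (s in 21:25) {
    truth <- plant_truth(synthetic_config(seed = s))
    n_loss <- n_loss + sum(truth$cnv_type == "loss")
    n_tot <- n_tot + nrow(truth)
  }
  ci <- qbinom(c(0.005, 0.995), n_tot, 0.9)
  expect_gte(n_loss, ci[1])
  expect_lte(n_loss, ci[2])
})

test_that("the noiseless configuration reproduces truth exactly", {
  run <- noiseless_dataset()
  truth <- run$data$truth
  for (tool in names(run$data$tool_calls)) {
    calls <- run$data$tool_calls[[tool]]
    # no false positive: every call maps to a truth record
    expect_false(anyNA(calls$truth_id))
    m <- merge(as.data.frame(calls), truth[, c("truth_id", "start", "end")],
               by = "truth_id", suffixes = c("", "_t"))
    expect_true(all(m$start == m$start_t & m$end == m$end_t))
    # detection probability 1: one call per carrier per truth region
    expected <- sum(lengths(strsplit(truth$carriers, ",")))
    expect_equal(nrow(calls), expected)
  }
})

test_that("detection probability is honoured within binomial bounds", {
  cfg <- synthetic_config(
    seed = 31,
    tools = cnvpool:::.default_tool_profiles(detection_prob = 0.8,
                                             jitter_sd = 0, fp_per_mb = 0))
  truth <- plant_truth(cfg)
  calls <- emit_tool_calls(truth, cfg)
  n_pairs <- sum(lengths(strsplit(truth$carriers, ",")))
  for (tool in names(calls)) {
    got <- nrow(calls[[tool]])
    ci <- qbinom(c(0.005, 0.995), n_pairs, 0.8)
    expect_gte(got, ci[1])
    expect_lte(got, ci[2])
  }
})

test_that("jittered calls never invert and stay on the chromosome", {
  cfg <- synthetic_config(seed = 33)
  truth <- plant_truth(cfg)
  calls <- do.call(rbind, lapply(emit_tool_calls(truth, cfg), as.data.frame))
  expect_true(all(calls$start <= calls$end))
  expect_true(all(calls$start >= 1))
  expect_true(all(calls$end <= 1e7))
})

test_that("planted annotations carry the designed signals", {
  run <- noiseless_dataset()
  truth <- run$data$truth
  ann <- run$data$annotations
  # covered truth CNVRs are >= 50% exonic in the emitted gene models
  for (tid in names(ann$truth_gene_map)) {
    g <- ann$truth_gene_map[[tid]]
    tr <- truth[truth$truth_id == tid, ]
    ex <- ann$exons[ann$exons$gene_id == g, ]
    exonic <- sum(pmin(ex$end, tr$end) - pmax(ex$start, tr$start) + 1)
    expect_gte(exonic / (tr$end - tr$start + 1), 0.5)
  }
  # enriched-trait QTL hit common truth CNVRs far more often than background
  common <- truth[truth$class == "common", ]
  on_common <- function(q) {
    any(common$chrom == q["chrom"] &
          common$start <= as.numeric(q["end"]) &
          common$end >= as.numeric(q["start"]))
  }
  qtl <- ann$qtl
  hits <- apply(qtl[, c("chrom", "start", "end")], 1, on_common)
  enriched <- qtl$trait == run$cfg$enriched_trait
  expect_gt(mean(hits[enriched]), 0.6)
  expect_equal(mean(hits[!enriched]), 0)
  # qPCR: noise-free delta-Ct inverts the copy-number model
  cfg0 <- synthetic_config(seed = 12, ct_noise_sd = 0)
  ann0 <- emit_annotations(plant_truth(cfg0), cfg0)
  est <- estimate_copy_number(ann0$qpcr)
  nonzero <- ann0$qpcr$true_cn > 0
  expect_equal(est$copy_number[nonzero], ann0$qpcr$true_cn[nonzero],
               tolerance = 1e-9)
})

test_that("an undersized genome fails with an actionable error", {
  tiny <- synthetic_config(seed = 1,
                           genome = genome_build("1", 2e5, TRUE, "tiny"))
  expect_error(plant_truth(tiny), "genome too small")
})

test_that("written datasets are byte-identical across runs of one seed", {
  cfg <- synthetic_config(seed = 77)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  write_synthetic_dataset(cfg, d1)
  write_synthetic_dataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})
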