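# Seeded synthetic cohort generator: genome, truth CNVRs with population
# structure, per-tool noisy call files, gene/QTL/gene-set annotation, and
# qPCR measurements. The generator emits exactly the dialects the readers
# ingest, so every pipeline stage is testable without external data.

.default_breed_table <- function() {
  data.frame(
    breed = c("AM_Breed1", "AM_Breed2",
              "AS_Breed1", "AS_Breed2", "AS_Breed3",
              "EU_Breed1", "EU_Breed2", "EU_Breed3", "EU_Breed4"),
    region = c("America", "America",
               "AsiaOceania", "AsiaOceania", "AsiaOceania",
               "Europe", "Europe", "Europe", "Europe"),
    n = c(5, 5, 3, 3, 3, 4, 4, 4, 5),
    stringsAsFactors = FALSE)
}

.default_tool_profiles <- function(detection_prob = 0.9, jitter_sd = 200,
                                   fp_per_mb = 0.5) {
  list(
    list(name = "readdepth_a", dialect = "tsv_regions",
         detection_prob = detection_prob, jitter_sd = jitter_sd, fp_per_mb = fp_per_mb),
    list(name = "readdepth_b", dialect = "vcf_cn",
         detection_prob = detection_prob, jitter_sd = jitter_sd, fp_per_mb = fp_per_mb),
    list(name = "pairedsplit", dialect = "vcf_svtype",
         detection_prob = detection_prob, jitter_sd = jitter_sd, fp_per_mb = fp_per_mb),
    list(name = "splitread", dialect = "vcf_svtype",
         detection_prob = detection_prob, jitter_sd = jitter_sd, fp_per_mb = fp_per_mb)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror a nine-breed, three-region miniature pig resequencing
#' design: 36 samples (America 10, Asia/Oceania 9, Europe 17, 3-5 animals per
#' breed), three 10-Mb autosomes, planted truth CNVRs of five classes
#' (common to all samples, breed-restricted, region-exclusive, singleton,
#' doubleton), a 0.9 loss fraction reflecting the strong loss bias of
#' short-read CNV calling, log-uniform sizes between 200 bp and 1.4 Mb, and
#' four caller profiles (two read-depth style, one paired/split, one
#' split-read) each with 0.9 detection probability, 200 bp breakpoint jitter
#' SD and 0.5 false positives per Mb per sample.
#'
#' @param seed Integer master seed; fixed seed implies byte-identical output.
#' @param genome A [genome_build()] to plant variants on.
#' @param breeds Data frame `breed`, `region`, `n` defining the cohort.
#' @param n_common Common-to-all-samples CNVRs.
#' @param n_extreme How many of the common CNVRs carry extreme copy numbers
#'   (0 for losses, >= 4 for gains) in every carrier.
#' @param n_per_breed Breed-restricted CNVRs per breed (carried by >= 2
#'   members of one breed only).
#' @param n_region_exclusive Region-exclusive CNVRs per region (carried by
#'   every member of one region, nobody else).
#' @param n_singleton,n_doubleton CNVRs carried by exactly one / two samples.
#' @param loss_fraction Probability a planted CNVR is a loss.
#' @param size_range Log-uniform size range in bp.
#' @param tools List of caller profiles (`name`, `dialect`,
#'   `detection_prob`, `jitter_sd`, `fp_per_mb`).
#' @param min_gap Minimum spacing between planted CNVRs in bp.
#' @param exon_cover_frac Fraction of truth CNVRs that receive a gene whose
#'   exons cover >= 50 percent of the CNVR.
#' @param n_background_genes Genes placed away from any truth CNVR.
#' @param n_traits Number of QTL traits (one of them planted as enriched).
#' @param n_qtl_per_trait QTL records per trait.
#' @param enriched_trait Name of the planted enriched trait.
#' @param enrichment_odds Odds that an enriched-trait QTL lands on a common
#'   truth CNVR rather than background.
#' @param n_assays,n_discordant_gains qPCR assay counts; discordant assays
#'   predict a gain while the underlying state is diploid.
#' @param ct_base,ct_noise_sd qPCR cycle-threshold baseline and noise SD.
#' @param cn_floor Effective copy number used in place of 0 when simulating
#'   Ct values (a true zero never amplifies).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             genome = genome_build(c("1", "2", "3"), rep(1e7, 3),
                                                   rep(TRUE, 3), name = "synthetic"),
                             breeds = .default_breed_table(),
                             n_common = 12, n_extreme = 4,
                             n_per_breed = 1, n_region_exclusive = 3,
                             n_singleton = 6, n_doubleton = 4,
                             loss_fraction = 0.9,
                             size_range = c(200, 1.4e6),
                             tools = .default_tool_profiles(),
                             min_gap = 1e4,
                             exon_cover_frac = 0.7, n_background_genes = 60,
                             n_traits = 8, n_qtl_per_trait = 50,
                             enriched_trait = "Body height",
                             enrichment_odds = 10,
                             n_assays = 7, n_discordant_gains = 2,
                             ct_base = 25, ct_noise_sd = 0.15,
                             cn_floor = 0.05) {
  stopifnot(inherits(genome, "genome_build"),
            all(c("breed", "region", "n") %in% names(breeds)),
            length(size_range) == 2, size_range[1] > 0,
            size_range[1] < size_range[2],
            loss_fraction >= 0, loss_fraction <= 1,
            n_extreme <= n_common)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= 2^31 - 10) stop("synthetic_config: seed must be a 32-bit integer")
  structure(list(seed = seed, genome = genome, breeds = breeds,
                 n_common = n_common, n_extreme = n_extreme,
                 n_per_breed = n_per_breed,
                 n_region_exclusive = n_region_exclusive,
                 n_singleton = n_singleton, n_doubleton = n_doubleton,
                 loss_fraction = loss_fraction, size_range = size_range,
                 tools = tools, min_gap = min_gap,
                 exon_cover_frac = exon_cover_frac,
                 n_background_genes = n_background_genes,
                 n_traits = n_traits, n_qtl_per_trait = n_qtl_per_trait,
                 enriched_trait = enriched_trait,
                 enrichment_odds = enrichment_odds,
                 n_assays = n_assays, n_discordant_gains = n_discordant_gains,
                 ct_base = ct_base, ct_noise_sd = ct_noise_sd,
                 cn_floor = cn_floor),
            class = "synthetic_config")
}

#' Sample sheet implied by a synthetic configuration
#' @param cfg A [synthetic_config()].
#' @return A `sample_sheet` with samples `S01`, `S02`, ... in breed order.
#' @export
synthetic_sample_sheet <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  b <- cfg$breeds
  n_tot <- sum(b$n)
  as_sample_sheet(data.frame(
    sample_id = sprintf("S%02d", seq_len(n_tot)),
    breed = rep(b$breed, b$n),
    region = rep(b$region, b$n), stringsAsFactors = FALSE))
}

# place one interval of given size, >= min_gap away from already placed ones
.place_interval <- function(genome, size, placed, min_gap, max_attempts = 2000) {
  ok_chr <- genome$chrom[genome$length_bp >= size + 2 * min_gap]
  if (!length(ok_chr)) return(NULL)
  w <- genome$length_bp[match(ok_chr, genome$chrom)]
  for (a in seq_len(max_attempts)) {
    chrom <- sample(ok_chr, 1, prob = w)
    len <- genome$length_bp[genome$chrom == chrom]
    start <- floor(stats::runif(1, min_gap, len - size - min_gap))
    end <- start + size - 1
    if (nrow(placed)) {
      same <- placed$chrom == chrom
      if (any(same & placed$start - min_gap <= end & placed$end + min_gap >= start)) next
    }
    return(data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE))
  }
  NULL
}

.draw_size <- function(n, size_range) {
  round(exp(stats::runif(n, log(size_range[1]), log(size_range[2]))))
}

#' Plant the ground-truth CNVR table
#'
#' Places all truth classes at mutually disjoint genomic positions (spaced by
#' `min_gap`), draws loss/gain types at `loss_fraction`, and assigns carrier
#' samples per class: common CNVRs to every sample, breed CNVRs to >= 2
#' members of one breed, region-exclusive CNVRs to all members of one region
#' and nobody else, singletons/doubletons to one/two samples.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame `truth_id`, `class`, `chrom`, `start`, `end`,
#'   `cnv_type`, `extreme`, `breed`, `region`, `carriers` (comma-separated).
#' @export
plant_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  sheet <- synthetic_sample_sheet(cfg)
  spec <- list()
  add <- function(class, k, breed = NA, region = NA) {
    if (k > 0) {
      for (i in seq_len(k)) spec[[length(spec) + 1]] <<-
          list(class = class, breed = breed, region = region)
    }
  }
  add("common", cfg$n_common)
  for (b in cfg$breeds$breed) add("breed", cfg$n_per_breed, breed = b)
  for (r in unique(cfg$breeds$region)) add("region_exclusive", cfg$n_region_exclusive, region = r)
  add("singleton", cfg$n_singleton)
  add("doubleton", cfg$n_doubleton)
  sizes <- .draw_size(length(spec), cfg$size_range)
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rows <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    loc <- .place_interval(cfg$genome, sizes[i], placed, cfg$min_gap)
    if (is.null(loc)) {
      stop("plant_truth: genome too small to place ", length(spec),
           " disjoint CNVRs at the requested sizes; increase chromosome ",
           "lengths or reduce counts/sizes")
    }
    placed <- rbind(placed, loc)
    s <- spec[[i]]
    carriers <- switch(s$class,
      common = sheet$sample_id,
      breed = {
        members <- sheet$sample_id[sheet$breed == s$breed]
        k <- sample(2:length(members), 1)
        sort(sample(members, k))
      },
      region_exclusive = sheet$sample_id[sheet$region == s$region],
      singleton = sample(sheet$sample_id, 1),
      doubleton = sort(sample(sheet$sample_id, 2)))
    rows[[i]] <- data.frame(
      truth_id = sprintf("T%03d", i), class = s$class,
      chrom = loc$chrom, start = loc$start, end = loc$end,
      cnv_type = if (stats::runif(1) < cfg$loss_fraction) "loss" else "gain",
      extreme = FALSE, breed = s$breed, region = s$region,
      carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  common_idx <- which(truth$class == "common")
  if (cfg$n_extreme > 0 && length(common_idx)) {
    truth$extreme[common_idx[seq_len(min(cfg$n_extreme, length(common_idx)))]] <- TRUE
  }
  rownames(truth) <- NULL
  truth
}

# copy number draw given type and extremeness
.draw_cn <- function(type, extreme) {
  if (type == "loss") {
    if (extreme) 0L else sample(c(0L, 1L), 1, prob = c(0.15, 0.85))
  } else {
    if (extreme) sample(4:6, 1, prob = c(0.7, 0.2, 0.1))
    else sample(3:6, 1, prob = c(0.55, 0.25, 0.15, 0.05))
  }
}

.jitter_interval <- function(start, end, sd, chrom_len) {
  if (sd <= 0) return(c(start, end))
  for (a in 1:20) {
    s <- round(start + stats::rnorm(1, 0, sd))
    e <- round(end + stats::rnorm(1, 0, sd))
    if (s >= 1 && e <= chrom_len && s <= e) return(c(s, e))
  }
  c(start, end)
}

#' Emit noisy per-tool call sets from a truth table
#'
#' For every carrier x truth CNVR x tool, a call is emitted with the tool's
#' detection probability; endpoints are jittered by a truncated normal (the
#' interval is never inverted and never leaves the chromosome). Copy numbers
#' are drawn per call (extreme truth CNVRs always emit 0 / >= 4). False
#' positive calls are placed uniformly outside all truth regions at the
#' tool's per-Mb rate, independently per sample.
#'
#' @param truth Output of [plant_truth()].
#' @param cfg The same [synthetic_config()].
#' @return Named list (per tool) of `cnv_calls` data frames with an extra
#'   `truth_id` column (`NA` for false positives).
#' @export
emit_tool_calls <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  sheet <- synthetic_sample_sheet(cfg)
  genome <- cfg$genome
  genome_mb <- sum(genome$length_bp) / 1e6
  out <- list()
  for (tp in cfg$tools) {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      carriers <- strsplit(truth$carriers[i], ",", fixed = TRUE)[[1]]
      chrom_len <- genome$length_bp[genome$chrom == truth$chrom[i]]
      for (smp in carriers) {
        if (stats::runif(1) > tp$detection_prob) next
        se <- .jitter_interval(truth$start[i], truth$end[i], tp$jitter_sd, chrom_len)
        cn <- .draw_cn(truth$cnv_type[i], truth$extreme[i])
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = smp, tool = tp$name, chrom = truth$chrom[i],
          start = se[1], end = se[2], cnv_type = truth$cnv_type[i],
          copy_number = cn,
          genotype = if (cn == 0 || cn >= 4) "hom" else if (cn %in% c(1L, 3L)) "het" else "unknown",
          truth_id = truth$truth_id[i], stringsAsFactors = FALSE)
      }
    }
    # false positives, uniform outside truth space
    for (smp in sheet$sample_id) {
      n_fp <- stats::rpois(1, tp$fp_per_mb * genome_mb)
      if (n_fp == 0) next
      fp_sizes <- round(exp(stats::runif(n_fp, log(200), log(2e4))))
      for (k in seq_len(n_fp)) {
        loc <- .place_interval(genome, fp_sizes[k],
                               truth[, c("chrom", "start", "end")], 1)
        if (is.null(loc)) next
        type <- if (stats::runif(1) < cfg$loss_fraction) "loss" else "gain"
        cn <- .draw_cn(type, FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = smp, tool = tp$name, chrom = loc$chrom,
          start = loc$start, end = loc$end, cnv_type = type, copy_number = cn,
          genotype = if (cn == 0 || cn >= 4) "hom" else if (cn %in% c(1L, 3L)) "het" else "unknown",
          truth_id = NA_character_, stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(rows)) do.call(rbind, rows) else {
      df <- .empty_calls(); df$truth_id <- character(0); df
    }
    calls <- calls[order(calls$sample_id, calls$chrom, calls$start, calls$end), , drop = FALSE]
    rownames(calls) <- NULL
    class(calls) <- c("cnv_calls", "data.frame")
    out[[tp$name]] <- calls
  }
  out
}

#' Emit annotation inputs (genes, QTL, gene sets, qPCR) from a truth table
#'
#' Genes are placed so that a configured fraction of truth CNVRs overlap
#' exons at >= 50 percent of the CNVR length (three exons covering 60 percent
#' of the span); background genes go elsewhere. QTL of the designated
#' enriched trait land on common truth CNVRs with odds
#' `enrichment_odds : 1`; all other placements avoid truth regions so the
#' Fisher stage has a clean planted signal. One GMT set collects the genes
#' planted on truth CNVRs. qPCR Ct triplicates are generated from the true
#' copy number via `Ct_target = base - log2(CN/2) + noise`; discordant
#' assays predict a gain over a diploid state.
#'
#' @param truth Output of [plant_truth()].
#' @param cfg The same [synthetic_config()].
#' @return List with `genes` (data frame for GFF3 emission), `exons`,
#'   `qtl`, `gene_sets` (named list), `qpcr` (measurement table), and
#'   `truth_gene_map` (gene id per covered truth CNVR).
#' @export
emit_annotations <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  genome <- cfg$genome
  sheet <- synthetic_sample_sheet(cfg)
  # --- genes on truth CNVRs
  covered <- which(stats::runif(nrow(truth)) < cfg$exon_cover_frac)
  genes <- list(); exons <- list(); truth_gene <- character(0)
  gid <- 0
  for (i in covered) {
    gid <- gid + 1
    g <- sprintf("GENE%04d", gid)
    truth_gene[truth$truth_id[i]] <- g
    L <- truth$end[i] - truth$start[i] + 1
    chrom_len <- genome$length_bp[genome$chrom == truth$chrom[i]]
    genes[[g]] <- data.frame(
      gene_id = g, symbol = paste0("SYM", gid), chrom = truth$chrom[i],
      start = max(1, truth$start[i] - 1000),
      end = min(chrom_len, truth$end[i] + 1000), strand = "+",
      stringsAsFactors = FALSE)
    e_len <- ceiling(0.2 * L)
    e_starts <- truth$start[i] + floor((0:2) * L / 3)
    exons[[g]] <- data.frame(
      gene_id = g, chrom = truth$chrom[i], start = e_starts,
      end = pmin(e_starts + e_len - 1, truth$end[i]), stringsAsFactors = FALSE)
  }
  # --- background genes away from truth
  avoid <- truth[, c("chrom", "start", "end")]
  for (k in seq_len(cfg$n_background_genes)) {
    gid <- gid + 1
    g <- sprintf("GENE%04d", gid)
    loc <- .place_interval(genome, 5000, avoid, cfg$min_gap)
    if (is.null(loc)) break
    avoid <- rbind(avoid, loc)
    genes[[g]] <- data.frame(gene_id = g, symbol = paste0("SYM", gid),
                             chrom = loc$chrom, start = loc$start, end = loc$end,
                             strand = "+", stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = g, chrom = loc$chrom,
                             start = c(loc$start, loc$start + 3000),
                             end = c(loc$start + 999, loc$start + 3999),
                             stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, genes); rownames(genes_df) <- NULL
  exons_df <- do.call(rbind, exons); rownames(exons_df) <- NULL
  # --- QTL
  common <- truth[truth$class == "common", , drop = FALSE]
  bg_traits <- c("Average daily gain", "Teat number", "Backfat thickness",
                 "Litter size", "Muscle pH", "Hematocrit", "Drip loss",
                 "Loin muscle area", "Feed conversion ratio")
  traits <- c(cfg$enriched_trait,
              rep_len(bg_traits, max(0, cfg$n_traits - 1)))
  p_on <- cfg$enrichment_odds / (cfg$enrichment_odds + 1)
  qtl <- list(); qid <- 0
  for (tr in traits) {
    for (k in seq_len(cfg$n_qtl_per_trait)) {
      qid <- qid + 1
      on_cnvr <- tr == cfg$enriched_trait && nrow(common) > 0 && stats::runif(1) < p_on
      if (on_cnvr) {
        row <- common[sample(nrow(common), 1), ]
        L <- row$end - row$start + 1
        size <- min(L, round(stats::runif(1, 1000, 50000)))
        qs <- row$start + sample.int(max(1, L - size + 1), 1) - 1
        qe <- min(qs + size - 1, row$end)
      } else {
        size <- round(stats::runif(1, 10000, 100000))
        loc <- .place_interval(genome, size, truth[, c("chrom", "start", "end")], 1)
        if (is.null(loc)) next
        row <- loc; qs <- loc$start; qe <- loc$end
      }
      qtl[[qid]] <- data.frame(qtl_id = sprintf("QTL%05d", qid), trait = tr,
                               chrom = row$chrom, start = qs, end = qe,
                               stringsAsFactors = FALSE)
    }
  }
  qtl_df <- do.call(rbind, qtl); rownames(qtl_df) <- NULL
  # --- gene sets
  planted_genes <- unname(truth_gene[truth$truth_id %in% truth$truth_id[covered]])
  planted_genes <- planted_genes[!is.na(planted_genes)]
  universe <- genes_df$gene_id
  sets <- list(planted_cnvr_genes = sort(planted_genes))
  for (s in 1:5) {
    sets[[sprintf("random_set_%02d", s)]] <- sort(sample(universe, min(20, length(universe))))
  }
  # --- qPCR assays
  qpcr <- list()
  pickable <- truth[order(!truth$extreme, truth$class != "common"), , drop = FALSE]
  n_conc <- max(0, cfg$n_assays - cfg$n_discordant_gains)
  for (a in seq_len(cfg$n_assays)) {
    discordant <- a > n_conc
    if (discordant) {
      smp <- sample(sheet$sample_id, 1)
      true_cn <- 2; pred <- "gain"; tid <- NA_character_
    } else {
      row <- pickable[1 + (a - 1) %% nrow(pickable), ]
      smp <- strsplit(row$carriers, ",", fixed = TRUE)[[1]][1]
      true_cn <- if (row$cnv_type == "loss") {
        if (row$extreme) 0 else 1
      } else {
        if (row$extreme) 4 else 3
      }
      pred <- row$cnv_type; tid <- row$truth_id
    }
    mu_t <- cfg$ct_base - log2(max(true_cn, cfg$cn_floor) / 2)
    qpcr[[a]] <- data.frame(
      sample_id = smp, assay_id = sprintf("ASSAY%02d", a),
      ct_t1 = stats::rnorm(1, mu_t, cfg$ct_noise_sd),
      ct_t2 = stats::rnorm(1, mu_t, cfg$ct_noise_sd),
      ct_t3 = stats::rnorm(1, mu_t, cfg$ct_noise_sd),
      ct_r1 = stats::rnorm(1, cfg$ct_base, cfg$ct_noise_sd),
      ct_r2 = stats::rnorm(1, cfg$ct_base, cfg$ct_noise_sd),
      ct_r3 = stats::rnorm(1, cfg$ct_base, cfg$ct_noise_sd),
      predicted_type = pred, truth_id = tid, true_cn = true_cn,
      stringsAsFactors = FALSE)
  }
  qpcr_df <- do.call(rbind, qpcr); rownames(qpcr_df) <- NULL
  list(genes = genes_df, exons = exons_df, qtl = qtl_df, gene_sets = sets,
       qpcr = qpcr_df, truth_gene_map = truth_gene)
}

# ---- file emission ----------------------------------------------------------

.write_vcf <- function(calls, path, sample_id, genome, with_cn) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", genome$chrom,
                   as.integer(genome$length_bp)),
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (with_cn) {
    hdr <- c(hdr, '##FORMAT=<ID=CN,Number=1,Type=Integer,Description="Copy number">')
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    svtype <- ifelse(calls$cnv_type == "loss", "DEL", "DUP")
    gt <- ifelse(calls$genotype == "hom", "1/1",
                 ifelse(calls$genotype == "het", "0/1", "./."))
    fmt <- if (with_cn) "GT:CN" else "GT"
    smp <- if (with_cn) paste0(gt, ":", calls$copy_number) else gt
    body <- paste(calls$chrom, as.integer(calls$start), ".", "N",
                  paste0("<", svtype, ">"), ".", "PASS",
                  paste0("SVTYPE=", svtype, ";END=", as.integer(calls$end)),
                  fmt, smp, sep = "\t")
  }
  writeLines(c(hdr, body), path)
}

.write_tsv_regions <- function(calls, path) {
  lines <- character(0)
  if (nrow(calls)) {
    type <- ifelse(calls$cnv_type == "loss", "deletion", "duplication")
    lines <- paste0(type, "\t", calls$chrom, ":", as.integer(calls$start), "-",
                    as.integer(calls$end), "\tCN=", calls$copy_number)
  }
  writeLines(lines, path)
}

.write_gff3 <- function(genes, exons, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(g$chrom, "synthetic", "gene", as.integer(g$start),
                            as.integer(g$end), ".", g$strand, ".",
                            sprintf("ID=%s;Name=%s", g$gene_id, g$symbol),
                            sep = "\t"))
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[j], "synthetic", "exon",
                              as.integer(ex$start[j]), as.integer(ex$end[j]),
                              ".", g$strand, ".",
                              sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, j, g$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs [plant_truth()], [emit_tool_calls()] and [emit_annotations()] under
#' the config seed and writes every input the pipeline readers consume:
#' genome table, sample sheet, per-tool per-sample call files in the tool's
#' dialect, gene GFF3, QTL TSV, GMT gene sets, qPCR TSV, plus a `truth.json`
#' oracle for tests. Output is byte-identical for a fixed config.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created).
#' @return List with `paths` (named files/dirs), `truth`, `sheet`,
#'   `tool_calls` and `annotations` (in-memory copies), invisibly.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- plant_truth(cfg)
  tool_calls <- emit_tool_calls(truth, cfg)
  ann <- emit_annotations(truth, cfg)
  sheet <- synthetic_sample_sheet(cfg)
  paths <- list()
  paths$genome <- file.path(dir, "genome.tsv")
  write_genome_build(cfg$genome, paths$genome)
  paths$sample_sheet <- file.path(dir, "samples.tsv")
  .fmt_write(as.data.frame(sheet), paths$sample_sheet)
  calls_dir <- file.path(dir, "calls")
  for (tp in cfg$tools) {
    tdir <- file.path(calls_dir, tp$name)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    calls <- tool_calls[[tp$name]]
    for (smp in sheet$sample_id) {
      sub <- calls[calls$sample_id == smp, , drop = FALSE]
      if (tp$dialect == "tsv_regions") {
        .write_tsv_regions(sub, file.path(tdir, paste0(smp, ".tsv")))
      } else {
        .write_vcf(sub, file.path(tdir, paste0(smp, ".vcf")), smp, cfg$genome,
                   with_cn = tp$dialect == "vcf_cn")
      }
    }
    paths[[paste0("calls_", tp$name)]] <- tdir
  }
  paths$gff3 <- file.path(dir, "annotation.gff3")
  .write_gff3(ann$genes, ann$exons, paths$gff3)
  paths$qtl <- file.path(dir, "qtl.tsv")
  .fmt_write(ann$qtl, paths$qtl)
  paths$gmt <- file.path(dir, "genesets.gmt")
  write_gmt(ann$gene_sets, paths$gmt)
  paths$qpcr <- file.path(dir, "qpcr.tsv")
  .fmt_write(ann$qpcr, paths$qpcr)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, sheet = sheet,
                 tool_calls = tool_calls, annotations = ann))
}
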