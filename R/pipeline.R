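# End-to-end orchestration: ingest -> filter -> union loci -> population
# structure -> extreme-CN exon set -> per-tool CNVRs -> consensus -> shared
# (all breeds, per region) -> exclusive -> summaries -> gene/QTL overlap ->
# Fisher -> gene-set ORA -> qPCR. Deterministic for a fixed config and seed.

#' Assemble a pipeline run configuration
#'
#' Either pass input paths (per-tool call directories with one file per
#' sample, a sample sheet, a genome table, GFF3/QTL/GMT/qPCR paths), or a
#' `synthetic` block, in which case the dataset is generated under
#' `<out_dir>/input` first and then read back through the normal readers.
#'
#' @param tools List of `list(name, dialect, path)` entries; `path` is a
#'   directory holding `<sample_id>.vcf` / `<sample_id>.tsv` files.
#' @param sample_sheet,genome,gff3,qtl,gmt,qpcr Input paths (`genome` may be
#'   the string `"sus_scrofa_11_1"` for the built-in build); `gff3`, `qtl`,
#'   `gmt` and `qpcr` are optional stages.
#' @param synthetic Optional [synthetic_config()]; replaces all input paths.
#' @param ro_threshold,min_len_bp,max_len_bp,density_min,min_tools,exon_frac,alpha
#'   Numeric thresholds (defaults 0.5, 50, 5e6, 0.10, 2, 0.5, 0.05).
#' @param sharing_mode `"per_breed_min2"` (strict) or `"overall_min"`.
#' @param distance_metric `"jaccard"` or `"simple_matching"`.
#' @param seed Integer seed (used by the synthetic block).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(tools = NULL, sample_sheet = NULL, genome = NULL,
                            gff3 = NULL, qtl = NULL, gmt = NULL, qpcr = NULL,
                            synthetic = NULL,
                            ro_threshold = 0.5, min_len_bp = 50,
                            max_len_bp = 5e6, density_min = 0.10,
                            min_tools = 2, exon_frac = 0.5, alpha = 0.05,
                            sharing_mode = c("per_breed_min2", "overall_min"),
                            distance_metric = c("jaccard", "simple_matching"),
                            seed = 1) {
  sharing_mode <- match.arg(sharing_mode)
  distance_metric <- match.arg(distance_metric)
  stopifnot(ro_threshold > 0, ro_threshold <= 1,
            min_len_bp > 0, min_len_bp < max_len_bp,
            density_min >= 0, density_min <= 1,
            min_tools >= 1, exon_frac >= 0, exon_frac <= 1,
            alpha > 0, alpha < 1)
  if (is.null(synthetic)) {
    if (is.null(tools) || is.null(sample_sheet) || is.null(genome)) {
      stop("pipeline_config: need tools, sample_sheet and genome paths (or a synthetic block)")
    }
  } else {
    stopifnot(inherits(synthetic, "synthetic_config"))
  }
  structure(list(tools = tools, sample_sheet = sample_sheet, genome = genome,
                 gff3 = gff3, qtl = qtl, gmt = gmt, qpcr = qpcr,
                 synthetic = synthetic, ro_threshold = ro_threshold,
                 min_len_bp = min_len_bp, max_len_bp = max_len_bp,
                 density_min = density_min, min_tools = min_tools,
                 exon_frac = exon_frac, alpha = alpha,
                 sharing_mode = sharing_mode,
                 distance_metric = distance_metric, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown keys
#' are rejected. A `synthetic: {seed: ..., ...}` block is converted through
#' [synthetic_config()] (only scalar fields are settable from YAML).
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("read_pipeline_config: unknown key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$synthetic)) {
    syn_known <- names(formals(synthetic_config))
    syn_bad <- setdiff(names(y$synthetic), syn_known)
    if (length(syn_bad)) stop("read_pipeline_config: unknown synthetic key(s): ",
                              paste(syn_bad, collapse = ", "))
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  do.call(pipeline_config, y)
}

.read_tool_dir <- function(tool, dialect, dir, build, samples) {
  ext <- if (dialect == "tsv_regions") ".tsv" else ".vcf"
  pieces <- lapply(samples, function(smp) {
    f <- file.path(dir, paste0(smp, ext))
    if (!file.exists(f)) stop("missing call file for sample ", smp, ": ", f)
    read_cnv_calls(f, tool = tool, dialect = dialect, build = build,
                   sample_id = smp)
  })
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Run the full CNVR consensus pipeline
#'
#' Executes every stage in order and writes all tables, trees and summaries
#' plus a machine-readable `manifest.json` (config hash, seed, package
#' version, per-stage record counts) to `out_dir`. Identical config and seed
#' give byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param config A `run_config` from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "cnvpool",
                   version = as.character(utils::packageVersion("cnvpool")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  # -- stage: inputs
  if (!is.null(config$synthetic)) {
    syn <- stage("simulate", {
      cfg <- config$synthetic
      write_synthetic_dataset(cfg, file.path(out_dir, "input"))
    })
    config$tools <- lapply(config$synthetic$tools, function(tp) {
      list(name = tp$name, dialect = tp$dialect,
           path = syn$paths[[paste0("calls_", tp$name)]])
    })
    config$sample_sheet <- syn$paths$sample_sheet
    config$genome <- syn$paths$genome
    config$gff3 <- syn$paths$gff3
    config$qtl <- syn$paths$qtl
    config$gmt <- syn$paths$gmt
    config$qpcr <- syn$paths$qpcr
  }
  build <- stage("genome", {
    if (identical(config$genome, "sus_scrofa_11_1")) sus_scrofa_11_1()
    else read_genome_build(config$genome)
  })
  sheet <- stage("sample_sheet", read_sample_sheet(config$sample_sheet))
  raw <- stage("ingest", {
    lapply(stats::setNames(config$tools, vapply(config$tools, `[[`, "", "name")),
           function(tp) .read_tool_dir(tp$name, tp$dialect, tp$path, build,
                                       sheet$sample_id))
  })
  manifest$stages$ingest <- lapply(raw, nrow)
  # -- stage: filter
  fcfg <- filter_config(config$min_len_bp, config$max_len_bp, autosomes_only = TRUE)
  filtered <- stage("filter", lapply(raw, filter_calls, build = build, cfg = fcfg))
  pooled <- do.call(rbind, lapply(filtered, as.data.frame))
  rownames(pooled) <- NULL
  class(pooled) <- c("cnv_calls", "data.frame")
  manifest$stages$filter <- lapply(filtered, nrow)
  # -- stage: union loci + population structure
  ul <- stage("union_loci", build_union_loci(pooled, config$ro_threshold))
  manifest$stages$union_loci <- nrow(ul$loci)
  bm <- stage("binary_matrix", binary_matrix(ul, sheet))
  d <- stage("distance", cnv_distance(bm, config$distance_metric))
  mds <- stage("mds", classical_mds(d, k = 2))
  nj <- stage("nj", neighbor_joining(d))
  # -- stage: extreme-CN exon-overlapping set
  genes <- NULL
  if (!is.null(config$gff3)) genes <- stage("gene_models", read_gene_models(config$gff3, build))
  extreme <- stage("extreme_cn", extract_extreme_cn_shared(pooled, sheet$sample_id,
                                                           config$ro_threshold))
  manifest$stages$extreme_cn_loci <- nrow(extreme$loci)
  extreme_exonic <- NULL
  if (!is.null(genes)) {
    extreme_exonic <- stage("extreme_exonic",
                            exon_overlap_select(extreme$loci, genes, config$exon_frac))
    manifest$stages$extreme_exonic <- nrow(extreme_exonic)
  }
  # -- stage: CNVR assembly
  tool_cnvrs <- stage("tool_cnvrs",
                      lapply(filtered, build_tool_cnvrs, density_min = config$density_min))
  manifest$stages$tool_cnvrs <- lapply(tool_cnvrs, nrow)
  consensus <- stage("consensus", consensus_cnvrs(tool_cnvrs, config$min_tools))
  manifest$stages$consensus <- nrow(consensus)
  shared_all <- stage("shared_all_breeds",
                      shared_cnvrs(consensus, pooled, sheet, mode = config$sharing_mode))
  regions <- unique(sheet$region)
  shared_region <- stage("shared_regions", {
    stats::setNames(lapply(regions, function(r) {
      shared_cnvrs(consensus, pooled, sheet, mode = "region_all", region = r)
    }), regions)
  })
  exclusive <- stage("exclusive", {
    stats::setNames(lapply(regions, function(r) {
      exclusive_cnvrs(shared_region[[r]], shared_region[setdiff(regions, r)])
    }), regions)
  })
  manifest$stages$shared_all_breeds <- nrow(shared_all)
  manifest$stages$shared_regions <- lapply(shared_region, nrow)
  manifest$stages$exclusive <- lapply(exclusive, nrow)
  # -- stage: summaries
  summaries <- stage("summaries", {
    c(list(all_breeds = summarize_cnvrs(shared_all, build)),
      lapply(shared_region, summarize_cnvrs, build = build),
      stats::setNames(lapply(exclusive, summarize_cnvrs, build = build),
                      paste0("exclusive_", names(exclusive))))
  })
  # -- stage: annotation & enrichment
  qtl_enrich <- NULL; gene_overlap <- NULL; ora <- NULL
  if (!is.null(config$qtl)) {
    qtl <- stage("qtl", read_qtl(config$qtl, build))
    qtl_enrich <- stage("qtl_fisher", {
      c(list(all_breeds = qtl_fisher_enrichment(shared_all, qtl, config$alpha)),
        stats::setNames(lapply(shared_region, qtl_fisher_enrichment, qtl = qtl,
                               alpha = config$alpha), names(shared_region)))
    })
  }
  if (!is.null(genes)) {
    gb <- stage("gene_bodies", {
      do.call(rbind, lapply(split(genes$exons, genes$exons$gene_id), function(e) {
        data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                   start = min(e$start), end = max(e$end),
                   stringsAsFactors = FALSE)
      }))
    })
    gene_overlap <- stage("gene_overlap", overlap_features(shared_all, gb))
    if (!is.null(config$gmt)) {
      sets <- stage("gmt", read_gmt(config$gmt))
      ora <- stage("gene_set_ora",
                   gene_set_ora(gene_overlap$feature_ids, sets,
                                background = genes$genes$gene_id,
                                alpha = config$alpha))
    }
  }
  qpcr_out <- NULL
  if (!is.null(config$qpcr)) {
    qpcr_out <- stage("qpcr", {
      est <- estimate_copy_number(read_qpcr(config$qpcr))
      qpcr_concordance(est)
    })
  }
  # -- stage: outputs
  stage("write_outputs", {
    objs <- list(shared_all_breeds = shared_all,
                 mds_coordinates = mds_table(mds, sheet),
                 nj_tree = nj,
                 union_binary_matrix = bm)
    for (r in names(shared_region)) objs[[paste0("shared_", r)]] <- shared_region[[r]]
    for (r in names(exclusive)) objs[[paste0("exclusive_", r)]] <- exclusive[[r]]
    if (!is.null(extreme_exonic)) objs$extreme_cn_exonic <- extreme_exonic
    if (!is.null(qtl_enrich)) {
      for (nm in names(qtl_enrich)) objs[[paste0("qtl_enrichment_", nm)]] <- qtl_enrich[[nm]]
    }
    if (!is.null(ora)) objs$gene_set_ora <- ora
    if (!is.null(qpcr_out)) objs$qpcr_copy_number <- as.data.frame(qpcr_out)
    write_tables(objs, out_dir)
    sm <- do.call(rbind, lapply(names(summaries), function(nm) {
      s <- summaries[[nm]]
      data.frame(set = nm, n_total = s$n_total, n_loss = s$n_loss,
                 n_gain = s$n_gain, n_both = s$n_both, total_bp = s$total_bp,
                 genome_fraction_pct = s$genome_fraction_pct,
                 min_len = s$min_len, mean_len = s$mean_len,
                 median_len = s$median_len, max_len = s$max_len,
                 stringsAsFactors = FALSE)
    }))
    .fmt_write(sm, file.path(out_dir, "cnvr_summaries.tsv"))
  })
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(.serializable(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", force = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_json))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

# strip non-serializable pieces (paths stay; synthetic config flattened)
.serializable <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    syn <- unclass(out$synthetic)
    syn$genome <- list(chrom = syn$genome$chrom, length_bp = syn$genome$length_bp,
                       is_autosome = syn$genome$is_autosome)
    out$synthetic <- syn
  }
  # paths differ between runs/dirs; the hash covers scientific parameters only
  out[c("tools", "sample_sheet", "genome", "gff3", "qtl", "gmt", "qpcr")] <- NULL
  out
}
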