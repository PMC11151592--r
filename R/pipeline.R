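#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects the per-stage parameter blocks of [run_pipeline()]. The
#' defaults describe the package's reference synthetic study: a 40-sample
#' association cohort (50 taxa, 200 loci, 20 planted pairs) and a 13-pairs
#' tumor/normal methylome with 40 planted DML.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Global seed.
#' @param sim Named list of overrides for [sim_config()] (association
#'   cohort). The default spaces loci 1000 bp apart so that each CpG is
#'   smoothed independently.
#' @param dml_group_n Samples per group of the tumor/normal methylome.
#' @param n_dml,dml_delta Planted differential loci and their difference.
#' @param filter,dml,associate,enrich Per-stage parameter lists; see
#'   [filter_taxa()], [test_dml()]/[call_dml()]/[call_dmr()],
#'   [run_association_screen()], [region_enrichment()].
#' @param meta `NULL` to skip the meta-analysis stage, or a list with
#'   `n_studies`, `true_effect`, `tau2`, `per_study_n`, `n_null`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = list(spacing_bp = 1000L),
                            dml_group_n = 13L,
                            n_dml = 40L,
                            dml_delta = 0.3,
                            filter = list(min_abund = 1e-4, min_prev = 0.10),
                            dml = list(min_depth = 10L, window_bp = 500L,
                                       min_delta = 0.20, max_q = 0.05),
                            associate = list(fdr_cut = 0.10, cutoff = 0.75,
                                             B = 50L, family = "global"),
                            enrich = list(n_genes = 40L),
                            meta = list(n_studies = 8L, true_effect = 0.5,
                                        tau2 = 0, per_study_n = 40L,
                                        n_null = 7L)) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         dml_group_n = as.integer(dml_group_n), n_dml = as.integer(n_dml),
         dml_delta = dml_delta, filter = filter, dml = dml,
         associate = associate, enrich = enrich, meta = meta),
    class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic cohort with planted truth, writes the raw inputs
#' (taxa TSV, per-sample bisulfite call files, truth JSON), then executes
#' the stages in order: taxa filtering, DML/DMR calling on the
#' tumor/normal methylome, the locus-wise association screen on the
#' association cohort, promoter-region enrichment of the retained loci
#' against the tested-locus background, and (optionally) the cross-cohort
#' pathway meta-analysis. Every stage writes a TSV/BED artifact and the
#' run ends with a manifest recording parameters, seed and the checksum of
#' every input and output, so a rerun with the same configuration is
#' byte-reproducible.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the stage results (`taxa`, `dml_stats`,
#'   `dml`, `dmr`, `screen`, `annotations`, `enrichment`, `meta`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[mbmeth] ", ...)
  out <- config$out_dir
  dir.create(file.path(out, "inputs"), showWarnings = FALSE, recursive = TRUE)

  say("simulate: association cohort + paired methylome")
  cfg_assoc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  truth_assoc <- planted_truth(cfg_assoc)
  taxa <- simulate_taxa_table(cfg_assoc)
  meth_assoc <- simulate_methylome(cfg_assoc, taxa, truth_assoc)
  sim_dml <- config$sim
  sim_dml$n_samples <- config$dml_group_n
  sim_dml$n_assoc <- 0L
  cfg_dml <- do.call(sim_config, c(sim_dml, list(seed = config$seed + 1L)))
  truth_dml <- planted_truth(cfg_dml, n_dml = config$n_dml,
                             dml_delta = config$dml_delta)
  groups <- simulate_group_methylome(cfg_dml, truth_dml)

  taxa_path <- file.path(out, "inputs", "taxa.tsv")
  write_taxa_tsv(taxa, taxa_path)
  call_paths <- c(
    write_dss_calls(meth_assoc, file.path(out, "inputs", "calls_assoc")),
    write_dss_calls(groups$tumor, file.path(out, "inputs", "calls_tumor")),
    write_dss_calls(groups$normal, file.path(out, "inputs", "calls_normal")))
  truth_paths <- c(
    write_truth_json(truth_assoc, file.path(out, "inputs", "truth_assoc.json")),
    write_truth_json(truth_dml, file.path(out, "inputs", "truth_dml.json")))

  say("filter: taxa retention")
  taxa_f <- filter_taxa(taxa, config$filter$min_abund, config$filter$min_prev)

  say("dml: depth filter, smoothing, beta-binomial Wald test")
  tum <- depth_filter(groups$tumor, config$dml$min_depth)
  nor <- depth_filter(groups$normal, config$dml$min_depth)
  stats <- test_dml(tum, nor, window_bp = config$dml$window_bp)
  dml <- call_dml(stats, config$dml$min_delta, config$dml$max_q)
  dmr <- call_dmr(stats, config$dml$min_delta, config$dml$max_q)
  readr::write_tsv(stats, file.path(out, "dml_stats.tsv"))
  write_dmr_bed(dmr, file.path(out, "dmr.bed"))

  say("associate: de-sparsified lasso screen + stability selection")
  calls_f <- depth_filter(meth_assoc, config$dml$min_depth)
  screen <- run_association_screen(
    calls_f, taxa_f,
    fdr_cut = config$associate$fdr_cut, cutoff = config$associate$cutoff,
    B = config$associate$B, family = config$associate$family,
    window_bp = config$dml$window_bp, seed = config$seed)
  readr::write_tsv(as_tibble(screen), file.path(out, "associations.tsv"))

  say("enrich: promoter-region annotation of retained loci")
  models <- synthetic_gene_models(config$enrich$n_genes,
                                  span = max(calls_f$loci$pos),
                                  seed = config$seed)
  write_gene_models_bed(models, file.path(out, "inputs", "genes.bed"))
  ann <- annotate_cpgs(calls_f, models)
  hits <- unique(retained_associations(screen)$locus_id)
  background <- unique(screen$locus_id)
  enr <- NULL
  if (length(hits) > 0) {
    present <- intersect(region_categories,
                         as.character(ann$category[ann$locus_id %in% background]))
    enr <- list_rbind(map(present, function(cat) {
      region_enrichment(hits, background, ann, cat)
    }))
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"))
  } else {
    say("enrich: no retained association, stage skipped")
  }
  readr::write_tsv(ann, file.path(out, "annotations.tsv"))

  meta_res <- NULL
  if (!is.null(config$meta)) {
    say("meta: random-effects pathway meta-analysis")
    m <- config$meta
    tabs <- simulate_meta_cohorts(m$n_studies, m$true_effect, m$tau2,
                                  m$per_study_n, seed = config$seed,
                                  n_null = m$n_null)
    meta_res <- meta_screen(tabs)
    readr::write_tsv(select(meta_res, -"fit"), file.path(out, "meta.tsv"))
    readr::write_tsv(forest_data(meta_res$fit[[1]]),
                     file.path(out, "forest_top_pathway.tsv"))
  }

  say("manifest")
  manifest_path <- write_run_manifest(config, out)
  invisible(list(taxa = taxa_f, dml_stats = stats, dml = dml, dmr = dmr,
                 screen = screen, annotations = ann, enrichment = enr,
                 meta = meta_res, manifest_path = manifest_path))
}

#' Synthetic gene models along the simulated chromosome
#'
#' Lays `n_genes` single-TSS genes (2-kb bodies with first exon and both
#' UTRs, alternating strands, a mix of coding and noncoding classes) at
#' seeded random offsets across `[1, span]` of the synthetic chromosome.
#'
#' @param n_genes Number of genes.
#' @param span Rightmost coordinate to cover.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A [gene_models()] tibble.
#' @export
synthetic_gene_models <- function(n_genes, span, chrom = "chrSim",
                                  seed = 1L) {
  body_len <- 2000L
  classes <- rep_len(c("coding", "coding", "coding", "lncRNA", "snoRNA",
                       "miRNA"), n_genes)
  with_component_seed(seed, "truth", {
    anchor <- sort(sample.int(max(span, n_genes * 100L), n_genes))
    strand <- rep_len(c("+", "-"), n_genes)
    start <- pmax(1L, anchor - ifelse(strand == "-", body_len, 0L))
    end <- start + body_len - 1L
    tss <- ifelse(strand == "+", start, end)
    gene_models(tibble(
      gene_id = sprintf("G%03d", seq_len(n_genes)),
      chrom = chrom, strand = strand, tss = as.integer(tss),
      body_start = as.integer(start), body_end = as.integer(end),
      exon1_start = as.integer(ifelse(strand == "+", start, end - 199L)),
      exon1_end = as.integer(ifelse(strand == "+", start + 199L, end)),
      utr5_start = as.integer(ifelse(strand == "+", start, end - 99L)),
      utr5_end = as.integer(ifelse(strand == "+", start + 99L, end)),
      utr3_start = as.integer(ifelse(strand == "+", end - 199L, start)),
      utr3_end = as.integer(ifelse(strand == "+", end, start + 199L)),
      gene_class = classes))
  })
}

write_run_manifest <- function(config, out) {
  files <- setdiff(list.files(out, recursive = TRUE, full.names = TRUE),
                   file.path(out, "run_manifest.json"))
  sums <- tools::md5sum(files)
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # manifest must not depend on where the run lives
  manifest <- list(
    package = "mbmeth",
    version = as.character(utils::packageVersion("mbmeth")),
    seed = config$seed,
    config = cfg,
    files = lapply(seq_along(sums), function(i) {
      list(path = sub(paste0("^", out, "/?"), "", names(sums)[i]),
           md5 = unname(sums[i]))
    })
  )
  path <- file.path(out, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Verify a pipeline run against its manifest
#'
#' Recomputes the checksum of every file recorded in `run_manifest.json`
#' and aborts on the first mismatch or missing file.
#'
#' @param out_dir Directory of a completed [run_pipeline()] run.
#' @return `TRUE`, invisibly, when everything matches.
#' @export
verify_manifest <- function(out_dir) {
  path <- file.path(out_dir, "run_manifest.json")
  if (!file.exists(path)) stop("no run_manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(path)
  for (f in manifest$files) {
    full <- file.path(out_dir, f$path)
    if (!file.exists(full)) stop("manifest file missing: ", f$path)
    if (unname(tools::md5sum(full)) != f$md5) {
      stop("checksum mismatch for ", f$path)
    }
  }
  invisible(TRUE)
}
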