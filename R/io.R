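#' Read a taxa abundance table from TSV
#'
#' Expected layout: one row per taxon with columns `taxon_id`, `lineage`,
#' then one numeric column per sample (the transpose is stored: samples
#' are rows of the abundance matrix).
#'
#' @param path TSV file path.
#' @param sample_meta Optional sample metadata tibble.
#' @param is_relative Passed to [taxa_table()].
#' @return A [taxa_table()].
#' @export
read_taxa_tsv <- function(path, sample_meta = NULL, is_relative = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    taxon_id = readr::col_character(), lineage = readr::col_character(),
    .default = readr::col_character()))
  if (nrow(raw) == 0) stop("no taxa in ", path)
  if (!all(c("taxon_id", "lineage") %in% names(raw))) {
    stop("taxa TSV needs 'taxon_id' and 'lineage' columns")
  }
  dup <- raw$taxon_id[duplicated(raw$taxon_id)]
  if (length(dup)) stop("duplicated taxon: ", dup[1])
  sample_cols <- setdiff(names(raw), c("taxon_id", "lineage"))
  if (length(sample_cols) == 0) stop("no sample columns in ", path)
  num <- suppressWarnings(
    vapply(raw[sample_cols], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(raw$taxon_id, sample_cols))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric abundance at taxon '%s', sample '%s'",
                 rownames(num)[bad[1]], colnames(num)[bad[2]]))
  }
  taxa_table(t(num),
             taxonomy = tibble(taxon_id = raw$taxon_id, lineage = raw$lineage),
             sample_meta = sample_meta, is_relative = is_relative)
}

#' Write a taxa abundance table to TSV
#'
#' @param t A [taxa_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa_tsv <- function(t, path) {
  stopifnot(inherits(t, "taxa_table"))
  out <- bind_cols(t$taxonomy,
                   as_tibble(base::t(t$abundance)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read per-sample bisulfite call files (chr / pos / N / X)
#'
#' Each file is a 4-column TSV (`chr`, `pos`, `N`, `X`), header optional.
#' Loci are unified across samples by outer join; a locus missing from a
#' sample gets `N = 0`, `X = 0` there. Rows with `X > N` abort with the
#' file and line.
#'
#' @param paths Named character vector of file paths; names become sample
#'   ids (basenames without extension when unnamed).
#' @return A [meth_calls()].
#' @export
read_dss_calls <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  per_sample <- imap(paths, function(pth, sid) {
    first <- readr::read_lines(pth, n_max = 1)
    has_header <- grepl("chr", first, ignore.case = TRUE) &&
      !grepl("^\\S+\t\\d+\t\\d+\t\\d+$", first)
    d <- readr::read_tsv(pth, col_names = c("chr", "pos", "N", "X"),
                         skip = if (has_header) 1L else 0L,
                         col_types = "ciii")
    bad <- which(d$X > d$N | d$X < 0 | d$N < 0)
    if (length(bad)) {
      stop(sprintf("invalid counts (X > N) in %s at data line %d",
                   pth, bad[1]))
    }
    d$sample_id <- sid
    d
  })
  long <- list_rbind(per_sample)
  loci <- long |> distinct(.data$chr, .data$pos) |>
    arrange(.data$chr, .data$pos) |>
    mutate(locus_id = sprintf("%s:%d", .data$chr, .data$pos))
  key <- setNames(seq_len(nrow(loci)), paste(loci$chr, loci$pos))
  sids <- names(paths)
  N <- X <- matrix(0L, nrow(loci), length(sids),
                   dimnames = list(loci$locus_id, sids))
  ridx <- key[paste(long$chr, long$pos)]
  cidx <- match(long$sample_id, sids)
  N[cbind(ridx, cidx)] <- long$N
  X[cbind(ridx, cidx)] <- long$X
  meth_calls(tibble(locus_id = loci$locus_id, chrom = loci$chr,
                    pos = loci$pos), N, X)
}

#' Write a call set as per-sample DSS-style files
#'
#' @param calls A [meth_calls()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_dss_calls <- function(calls, dir) {
  stopifnot(inherits(calls, "meth_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(colnames(calls$N), ".tsv")),
                    colnames(calls$N))
  for (sid in colnames(calls$N)) {
    readr::write_tsv(
      tibble(chr = calls$loci$chrom, pos = calls$loci$pos,
             N = calls$N[, sid], X = calls$X[, sid]),
      paths[[sid]])
  }
  invisible(paths)
}

#' Write DMRs as a 6-column BED file
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention; the score is `mean_delta * 1000` clamped to
#' `[0, 1000]` and the direction is carried in the name.
#'
#' @param dmrs Tibble from [call_dmr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  out <- tibble(
    chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
    name = sprintf("dmr_%s_%d", dmrs$direction, seq_len(nrow(dmrs))),
    score = pmin(pmax(round(dmrs$mean_delta * 1000), 0), 1000),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a BED6(+1) file
#'
#' Standard BED: 0-based half-open intervals, converted to the package's
#' 1-based inclusive coordinates. Columns: chrom, start, end, name
#' (gene id), score (ignored), strand, and optionally a 7th column with
#' the gene class. The TSS is the strand-appropriate end of the interval;
#' sub-gene features (first exon, UTRs) are not representable in BED6 and
#' are left unset.
#'
#' @param path BED file path.
#' @return A [gene_models()] tibble.
#' @export
read_gene_models_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  if (ncol(d) < 6) stop("gene-model BED needs at least 6 columns")
  names(d)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  gene_models(tibble(
    gene_id = as.character(d$gene_id), chrom = as.character(d$chrom),
    strand = d$strand,
    tss = ifelse(d$strand == "+", d$start + 1L, d$end),
    body_start = d$start + 1L, body_end = d$end,
    gene_class = if (ncol(d) >= 7) as.character(d[[7]]) else "coding"
  ))
}

#' Write gene models to BED6+1
#'
#' @param models A [gene_models()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(models, path) {
  models <- gene_models(models)
  readr::write_tsv(
    tibble(chrom = models$chrom, start = models$body_start - 1L,
           end = models$body_end, name = models$gene_id, score = 0L,
           strand = models$strand, class = models$gene_class),
    path, col_names = FALSE)
  invisible(path)
}

#' Write a square distance matrix as TSV
#'
#' @param d Symmetric matrix with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  readr::write_tsv(as_tibble(as.matrix(d), rownames = "sample_id"), path)
  invisible(path)
}

#' Serialize planted truth to JSON
#'
#' @param truth A [planted_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(
    list(assoc_pairs = truth$assoc_pairs,
         covariate_betas = as.list(truth$covariate_betas),
         baseline_logit = as.list(truth$baseline_logit),
         dml = truth$dml,
         meta_true_effect = truth$meta_true_effect,
         meta_tau2 = truth$meta_tau2),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
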