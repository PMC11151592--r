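#' Gene models for CpG region annotation
#'
#' Single-TSS gene models in the 450K-array category convention. Intervals
#' are 1-based inclusive; `utr5`, `exon1` and `utr3` are optional (`NA`).
#'
#' @param models Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`, `body_start`, `body_end`, and optionally
#'   `exon1_start`, `exon1_end`, `utr5_start`, `utr5_end`, `utr3_start`,
#'   `utr3_end`, `gene_class` (e.g. `"coding"`, `"lncRNA"`, `"snoRNA"`,
#'   `"miRNA"`; defaults to `"coding"`).
#' @return A validated `gene_models` tibble.
#' @export
gene_models <- function(models) {
  m <- as_tibble(models)
  req <- c("gene_id", "chrom", "strand", "tss", "body_start", "body_end")
  if (!all(req %in% names(m))) {
    stop("gene models need columns: ", paste(req, collapse = ", "))
  }
  for (col in c("exon1_start", "exon1_end", "utr5_start", "utr5_end",
                "utr3_start", "utr3_end")) {
    if (!col %in% names(m)) m[[col]] <- NA_integer_
  }
  if (!"gene_class" %in% names(m)) m$gene_class <- "coding"
  if (anyDuplicated(m$gene_id)) stop("duplicate gene_id")
  bad <- !m$strand %in% c("+", "-")
  if (any(bad)) stop("malformed model (strand): ", m$gene_id[which(bad)[1]])
  bad <- m$body_end < m$body_start
  if (any(bad)) stop("malformed model (body): ", m$gene_id[which(bad)[1]])
  for (iv in c("exon1", "utr5", "utr3")) {
    s <- m[[paste0(iv, "_start")]]
    e <- m[[paste0(iv, "_end")]]
    if (any(xor(is.na(s), is.na(e)))) {
      stop("malformed model (", iv, " half-specified): ",
           m$gene_id[which(xor(is.na(s), is.na(e)))[1]])
    }
    bad <- !is.na(s) & (e < s | s < m$body_start | e > m$body_end)
    if (any(bad)) stop("malformed model (", iv, "): ", m$gene_id[which(bad)[1]])
  }
  class(m) <- c("gene_models", class(m))
  m
}

region_categories <- c("TSS200", "TSS1500", "5UTR", "1stExon", "Body",
                       "3UTR", "Intergenic")

#' Annotate CpG loci with genomic region categories
#'
#' Each locus is assigned to its nearest gene (distance to the TSS, ties
#' broken by lexicographic `gene_id`) and then to exactly one category of
#' that gene. TSS flanks are strand-aware: on the coding strand, TSS200 is
#' the 200 bp immediately upstream of the TSS (`[TSS-200, TSS)` for `+`
#' genes, reflected for `-` genes) and TSS1500 the 201-1500 bp band beyond
#' it. Within the gene, the precedence is 5'UTR, then first exon, then
#' 3'UTR, then the remaining gene body; loci matching no category of their
#' nearest gene are `Intergenic`, as are loci on chromosomes without genes.
#'
#' @param loci Tibble with `locus_id`, `chrom`, `pos`, or a [meth_calls()].
#' @param models A [gene_models()] tibble.
#' @return Tibble with `locus_id`, `chrom`, `pos`, `category`, `gene_id`
#'   (`NA` for intergenic loci); `category` is a factor over all seven
#'   categories.
#' @export
annotate_cpgs <- function(loci, models) {
  if (inherits(loci, "meth_calls")) loci <- loci$loci
  loci <- as_tibble(loci)
  stopifnot(all(c("locus_id", "chrom", "pos") %in% names(loci)))
  models <- gene_models(models)
  out <- loci |> mutate(category = "Intergenic", gene_id = NA_character_)
  for (i in seq_len(nrow(loci))) {
    g <- models[models$chrom == loci$chrom[i], ]
    if (nrow(g) == 0) next
    d <- abs(g$tss - loci$pos[i])
    g <- g[order(d, g$gene_id), ][1, ]
    out$category[i] <- categorize_position(loci$pos[i], g)
    if (out$category[i] != "Intergenic") out$gene_id[i] <- g$gene_id
  }
  out$category <- factor(out$category, levels = region_categories)
  out
}

categorize_position <- function(pos, g) {
  upstream <- if (g$strand == "+") g$tss - pos else pos - g$tss
  if (upstream >= 1 && upstream <= 200) return("TSS200")
  if (upstream >= 201 && upstream <= 1500) return("TSS1500")
  in_iv <- function(iv) {
    s <- g[[paste0(iv, "_start")]]
    !is.na(s) && pos >= s && pos <= g[[paste0(iv, "_end")]]
  }
  if (in_iv("utr5")) return("5UTR")
  if (in_iv("exon1")) return("1stExon")
  if (in_iv("utr3")) return("3UTR")
  if (pos >= g$body_start && pos <= g$body_end) return("Body")
  "Intergenic"
}

#' Region enrichment of hit loci against a background
#'
#' One-sided hypergeometric upper-tail test for over-representation of a
#' region category among hit loci relative to a background locus set, with
#' the odds ratio from the 2x2 table (Haldane 0.5 correction when any cell
#' is zero).
#'
#' @param hits Character vector of hit locus ids (subset of `background`).
#' @param background Character vector of background locus ids.
#' @param calls Annotation tibble from [annotate_cpgs()].
#' @param category One of the seven region categories.
#' @return Tibble with `category`, `n_hits`, `hits_in_category`,
#'   `n_background`, `background_in_category`, `odds_ratio`, `p`.
#' @export
#' @examples
#' calls <- tibble::tibble(locus_id = paste0("L", 1:10),
#'                         category = rep(c("TSS200", "Body"), c(4, 6)))
#' region_enrichment(paste0("L", 1:3), paste0("L", 1:10), calls, "TSS200")
region_enrichment <- function(hits, background, calls, category) {
  category <- match.arg(category, region_categories)
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (length(hits) == 0 || length(background) == 0) {
    stop("hits and background must be non-empty")
  }
  if (!all(hits %in% background)) stop("hits must be a subset of background")
  cat_of <- setNames(as.character(calls$category), calls$locus_id)
  if (!all(background %in% names(cat_of))) {
    stop("some background loci are not annotated")
  }
  in_cat_bg <- sum(cat_of[background] == category)
  if (in_cat_bg == 0) stop("category ", category, " absent from background")
  k <- sum(cat_of[hits] == category)
  n_h <- length(hits)
  n_b <- length(background)
  p <- phyper(k - 1, in_cat_bg, n_b - in_cat_bg, n_h, lower.tail = FALSE)
  tab <- c(a = k, b = n_h - k, c = in_cat_bg - k,
           d = n_b - in_cat_bg - (n_h - k))
  or <- if (tab["c"] + tab["d"] == 0) {
    1  # hits exhaust the background: no contrast, odds ratio is neutral
  } else {
    if (any(tab == 0)) tab <- tab + 0.5
    unname(tab["a"] * tab["d"] / (tab["b"] * tab["c"]))
  }
  tibble(category = category, n_hits = n_h, hits_in_category = k,
         n_background = n_b, background_in_category = in_cat_bg,
         odds_ratio = or, p = p)
}

#' Promoter-region view of retained associations
#'
#' Restricts retained associations to loci falling in the promoter bands
#' (TSS200/TSS1500) of genes of the requested class.
#'
#' @param results An `assoc_screen` result (or tibble with `locus_id` and
#'   `retained`).
#' @param calls Annotation tibble from [annotate_cpgs()].
#' @param models The [gene_models()] used for the annotation.
#' @param gene_class One of `"coding"`, `"lncRNA"`, `"snoRNA"`, `"miRNA"`.
#' @return Retained associations at matching promoters, with `gene_id`,
#'   `category` and `gene_class` attached.
#' @export
promoter_association_view <- function(results, calls, models,
                                      gene_class = c("coding", "lncRNA",
                                                     "snoRNA", "miRNA")) {
  gene_class <- match.arg(gene_class)
  models <- gene_models(models)
  as_tibble(results) |>
    filter(.data$retained) |>
    inner_join(select(calls, "locus_id", "category", "gene_id"),
               by = "locus_id") |>
    filter(.data$category %in% c("TSS200", "TSS1500")) |>
    inner_join(select(models, "gene_id", "gene_class"), by = "gene_id") |>
    filter(.data$gene_class == .env$gene_class) |>
    arrange(.data$gene_id, .data$locus_id)
}
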