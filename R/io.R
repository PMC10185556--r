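#' @importFrom stats approx coef cor cor.test fisher.test lm lm.fit median
#'   optimise p.adjust pbinom plogis pnorm prcomp pt qlogis quantile resid
#'   rbinom rexp rnbinom rnorm runif sd setNames var
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 0-based half-open everywhere. CG sites are
# width-1 intervals at the cytosine; 1-based TSV positions are converted on
# read, BED is consumed natively.

#' Methylation matrix container
#'
#' Bundles a site x sample matrix of beta values (fraction methylated, in
#' \[0,1\]) with per-site genomic coordinates and a per-sample sheet.
#'
#' @param betas numeric matrix, sites x samples, values in \[0,1\] or NA.
#' @param chrom character vector of chromosome names per site.
#' @param pos integer vector of 1-based cytosine positions per site.
#' @param sample_sheet data.frame with one row per sample column; must carry a
#'   `sample_id` column matching `colnames(betas)`.
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(betas, chrom, pos, sample_sheet) {
  stopifnot(is.matrix(betas), !is.null(rownames(betas)), !is.null(colnames(betas)))
  if (anyDuplicated(rownames(betas)))
    stop("duplicated site ids: ", paste(unique(rownames(betas)[duplicated(rownames(betas))])[1:3], collapse = ", "))
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at site '%s', sample '%s' (value %g)",
                 rownames(betas)[bad[1, 1]], colnames(betas)[bad[1, 2]],
                 betas[bad[1, 1], bad[1, 2]]))
  if (length(chrom) != nrow(betas) || length(pos) != nrow(betas))
    stop("chrom/pos length must equal number of sites")
  if (any(pos <= 0) || any(pos != round(pos)))
    stop("positions must be strictly positive integers")
  if (!all(colnames(betas) %in% sample_sheet$sample_id))
    stop("sample sheet missing samples: ",
         paste(setdiff(colnames(betas), sample_sheet$sample_id)[1:3], collapse = ", "))
  sample_sheet <- sample_sheet[match(colnames(betas), sample_sheet$sample_id), , drop = FALSE]
  structure(list(betas = betas, chrom = as.character(chrom), pos = as.integer(pos),
                 sample_sheet = sample_sheet),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$betas), ncol(x$betas), 100 * mean(is.na(x$betas))))
  invisible(x)
}

#' Site coordinate table of a methylation matrix
#' @param m a `meth_matrix`.
#' @return data.frame with site_id, chrom, pos (1-based).
#' @export
meth_sites <- function(m) {
  data.frame(site_id = rownames(m$betas), chrom = m$chrom, pos = m$pos,
             stringsAsFactors = FALSE)
}

#' Expression count matrix container
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param sample_sheet data.frame with `sample_id` (and usually
#'   `participant_id`, `depot`, covariates) per sample column.
#' @return Object of class `expr_matrix` with a lazily-filled `logexpr` slot.
#' @export
expr_matrix <- function(counts, sample_sheet) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  sample_sheet <- sample_sheet[match(colnames(counts), sample_sheet$sample_id), , drop = FALSE]
  structure(list(counts = counts, sample_sheet = sample_sheet, logexpr = NULL),
            class = "expr_matrix")
}

#' Genotype dosage matrix container
#'
#' @param dosages numeric matrix, SNPs x samples, values in \[0,2\].
#' @param chrom,pos SNP coordinates (1-based position).
#' @param effect_allele,other_allele single-character bases per SNP; dosage
#'   counts copies of the effect allele.
#' @return Object of class `geno_matrix` carrying per-SNP minor allele
#'   frequency computed from the dosages.
#' @export
geno_matrix <- function(dosages, chrom, pos, effect_allele, other_allele) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)))
  if (anyDuplicated(rownames(dosages))) stop("duplicated snp ids")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    bad <- which(dosages < 0 | dosages > 2, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage out of [0,2] at snp '%s', sample '%s'",
                 rownames(dosages)[bad[1]], colnames(dosages)[bad[2]]))
  }
  ok <- c("A", "C", "G", "T")
  if (!all(effect_allele %in% ok) || !all(other_allele %in% ok))
    stop("alleles must be single bases A/C/G/T")
  af <- rowMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  structure(list(dosages = dosages, chrom = as.character(chrom), pos = as.integer(pos),
                 effect_allele = effect_allele, other_allele = other_allele, maf = maf),
            class = "geno_matrix")
}

#' Read a feature matrix from TSV
#'
#' TSV layout: methylation and genotype files carry `id`, `chrom`, `pos`
#' (1-based) then one column per sample; expression files carry `id` then
#' sample columns; genotype files additionally carry `effect_allele` and
#' `other_allele` after `pos`. Sample sheets are supplied separately.
#'
#' @param path TSV file.
#' @param kind one of "methylation", "expression", "genotype".
#' @param sample_sheet data.frame (required for methylation/expression).
#' @return a `meth_matrix`, `expr_matrix` or `geno_matrix`.
#' @export
read_matrix <- function(path, kind = c("methylation", "expression", "genotype"),
                        sample_sheet = NULL) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (anyDuplicated(dt$id))
    stop(sprintf("%s: duplicated feature id '%s'", path, dt$id[duplicated(dt$id)][1]))
  if (kind == "methylation") {
    meta <- c("id", "chrom", "pos")
    vals <- as.matrix(dt[, setdiff(names(dt), meta), drop = FALSE])
    rownames(vals) <- dt$id
    meth_matrix(vals, dt$chrom, dt$pos, sample_sheet)
  } else if (kind == "expression") {
    vals <- as.matrix(dt[, setdiff(names(dt), "id"), drop = FALSE])
    rownames(vals) <- dt$id
    expr_matrix(vals, sample_sheet)
  } else {
    meta <- c("id", "chrom", "pos", "effect_allele", "other_allele")
    vals <- as.matrix(dt[, setdiff(names(dt), meta), drop = FALSE])
    rownames(vals) <- dt$id
    geno_matrix(vals, dt$chrom, dt$pos, dt$effect_allele, dt$other_allele)
  }
}

#' Write a feature matrix to TSV (inverse of [read_matrix()])
#' @param x matrix container from this package.
#' @param path output TSV path.
#' @export
write_matrix <- function(x, path) {
  # 17 significant digits so doubles survive the text round-trip bit-exactly
  fmt <- function(v) {
    out <- matrix(sprintf("%.17g", v), nrow(v), ncol(v), dimnames = dimnames(v))
    out[is.na(v)] <- NA_character_
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (inherits(x, "meth_matrix")) {
    df <- data.frame(id = rownames(x$betas), chrom = x$chrom, pos = x$pos,
                     fmt(x$betas), check.names = FALSE)
  } else if (inherits(x, "expr_matrix")) {
    df <- data.frame(id = rownames(x$counts), x$counts, check.names = FALSE)
  } else if (inherits(x, "geno_matrix")) {
    df <- data.frame(id = rownames(x$dosages), chrom = x$chrom, pos = x$pos,
                     effect_allele = x$effect_allele, other_allele = x$other_allele,
                     fmt(x$dosages), check.names = FALSE)
  } else stop("unsupported matrix type")
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an annotation interval track (BED3/BED4+)
#'
#' BED is 0-based half-open, which is also the internal convention, so
#' coordinates are taken verbatim. Records are returned sorted by
#' (chrom, start).
#'
#' @param path BED file (whitespace-delimited, no header).
#' @param dialect only "bed" is supported.
#' @return a [GenomicRanges::GRanges] (0-based half-open stored as IRanges
#'   start = BED start + 1 internally; use [intervals_to_bed()] to write).
#'   A `label` metadata column carries BED column 4 (or the chrom name).
#' @export
read_intervals <- function(path, dialect = "bed") {
  stopifnot(dialect == "bed")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("%s: malformed BED line %d (need >=3 fields)", path, which(nf < 3)[1]))
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("%s: non-integer coordinate at line %d", path,
                 which(is.na(start) | is.na(end))[1]))
  if (any(start >= end))
    stop(sprintf("%s: start >= end at line %d", path, which(start >= end)[1]))
  label <- ifelse(nf >= 4, vapply(parts, function(p) if (length(p) >= 4) p[4] else "", ""), chrom)
  strand <- ifelse(nf >= 6, vapply(parts, function(p) if (length(p) >= 6) p[6] else "*", ""), "*")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end),
                               strand = strand, label = label)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write an interval set as BED
#' @param gr GRanges with a `label` column.
#' @param path output path.
#' @export
intervals_to_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   label = if (!is.null(gr$label)) gr$label else ".")
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert 1-based point coordinates (e.g. CG sites) to width-1 GRanges
#' @param chrom,pos coordinate vectors (1-based position of the cytosine).
#' @param id optional names.
#' @return GRanges of width-1 ranges.
#' @export
points_to_granges <- function(chrom, pos, id = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
  if (!is.null(id)) names(gr) <- id
  gr
}

#' Read a distal-interval-to-gene interaction map
#'
#' BEDPE-like TSV with header `chrom start end gene_id source`; the interval is
#' 0-based half-open (the distal anchor), `gene_id` the promoter-side gene and
#' `source` a provenance tag (e.g. capture-HiC vs enhancer catalogue).
#' Duplicate rows are removed with a message.
#'
#' @param path TSV file.
#' @param genes optional `gene_models` for cross-checking gene ids; unknown ids
#'   produce a warning listing them.
#' @return data.frame of class `interaction_map`.
#' @export
read_pairs <- function(path, genes = NULL) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "source")
  if (!all(need %in% names(df))) stop(path, ": need columns ", paste(need, collapse = " "))
  if (any(df$start >= df$end)) stop(path, ": start >= end in interaction interval")
  ndup <- sum(duplicated(df[need]))
  if (ndup > 0) {
    message(ndup, " duplicate interaction rows removed")
    df <- df[!duplicated(df[need]), , drop = FALSE]
  }
  if (!is.null(genes)) {
    unknown <- setdiff(df$gene_id, genes$gene$gene_id)
    if (length(unknown) > 0)
      warning("interaction gene ids absent from gene models: ",
              paste(head(unknown, 5), collapse = ", "))
  }
  class(df) <- c("interaction_map", "data.frame")
  df
}

#' Write an interaction map (inverse of [read_pairs()])
#' @param x interaction_map.
#' @param path output TSV.
#' @export
write_pairs <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Gene model container
#'
#' @param gene data.frame: gene_id, chrom, strand ("+"/"-"), tss (1-based).
#' @param exons data.frame: gene_id, start, end (0-based half-open), with
#'   optional `kind` in {"exon","utr5","utr3"}.
#' @param promoter_halfwidth promoter window half-width around the TSS (bp).
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(gene, exons, promoter_halfwidth = 5000L) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(gene)))
  if (anyDuplicated(gene$gene_id)) stop("duplicated gene ids")
  if (!"kind" %in% names(exons)) exons$kind <- "exon"
  if (any(exons$start >= exons$end)) stop("exon start >= end")
  # within-gene exon overlap is rejected: models are expected merged
  sp <- split(exons, exons$gene_id)
  for (g in sp) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("overlapping exon records within gene ", g$gene_id[1])
  }
  structure(list(gene = gene, exons = exons,
                 promoter_halfwidth = as.integer(promoter_halfwidth)),
            class = "gene_models")
}

#' Read a gene model TSV pair
#' @param gene_path TSV gene_id/chrom/strand/tss; `exon_path` TSV
#'   gene_id/start/end/kind (0-based half-open).
#' @param exon_path see above.
#' @param promoter_halfwidth bp, default 5000.
#' @return `gene_models`.
#' @export
read_gene_models <- function(gene_path, exon_path, promoter_halfwidth = 5000L) {
  gene_models(data.table::fread(gene_path, data.table = FALSE),
              data.table::fread(exon_path, data.table = FALSE),
              promoter_halfwidth)
}

#' Read GWAS summary statistics
#'
#' TSV with columns snp, effect_allele, other_allele, beta, se, p, n. Alleles
#' are upper-cased and validated against {A,C,G,T}; non-positive standard
#' errors and p-values outside (0,1] are rejected.
#'
#' @param path TSV file.
#' @return data.frame of class `gwas_summary`.
#' @export
read_gwas_summary <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "beta", "se", "p", "n")
  if (!all(need %in% names(df))) stop(path, ": need columns ", paste(need, collapse = " "))
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  if (any(df$se <= 0))
    stop(sprintf("%s: se <= 0 for snp '%s'", path, df$snp[df$se <= 0][1]))
  if (any(df$p <= 0 | df$p > 1))
    stop(sprintf("%s: p outside (0,1] for snp '%s'", path, df$snp[df$p <= 0 | df$p > 1][1]))
  ok <- c("A", "C", "G", "T")
  bad <- !(df$effect_allele %in% ok) | !(df$other_allele %in% ok)
  if (any(bad))
    stop(sprintf("%s: invalid allele for snp '%s'", path, df$snp[bad][1]))
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, tab-separated gene ids).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}
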