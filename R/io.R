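# Readers and writers for the pipeline's on-disk formats. Tabular data is
# plain TSV; gene models travel as GTF and methylation tracks as bedGraph
# (both via rtracklayer, with the 1-based/0-based conversion handled at
# the boundary — internally everything is 0-based half-open); somatic
# sites travel as VCF with the tumor allele in ALT and the host allele in
# REF.

#' @rdname pipeline_io
#' @param counts genes x samples integer matrix.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname pipeline_io
#' @param design sample sheet data.frame.
#' @export
write_sample_sheet <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sample_sheet <- function(path) sample_design(read.delim(path))

#' Pipeline file formats
#'
#' Paired readers/writers for every format the pipeline touches: counts
#' TSV (gene_id column + one column per sample), sample sheet TSV, gene
#' models GTF, methylation bedGraph, somatic-site VCF, pileup TSV and Ct
#' TSV.
#'
#' @param gene_models exon data.frame (0-based half-open).
#' @name pipeline_io
#' @export
write_gene_models_gtf <- function(gene_models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(start = gene_models$start + 1L,
                              end = gene_models$end),
    strand = gene_models$strand,
    type = "exon",
    gene_id = gene_models$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  out <- data.frame(gene_id = gr$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' @rdname pipeline_io
#' @param track methylation track data.frame.
#' @export
write_track_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_track_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' @rdname pipeline_io
#' @param sites somatic-site data.frame (`gene_id`, `chrom`, `pos`,
#'   `tumor_allele`, `host_allele`); by convention the host allele is
#'   written as REF and the tumor allele as ALT, with the gene id carried
#'   in the ID column.
#' @export
write_sites_vcf <- function(sites, path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required for VCF output")
  vr <- VariantAnnotation::VRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    ref = sites$host_allele,
    alt = sites$tumor_allele,
    sampleNames = "TUMOR")
  v <- methods::as(vr, "VCF")
  names(v) <- paste(sites$gene_id, sites$pos, sep = "|")
  VariantAnnotation::writeVcf(v, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sites_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required for VCF input")
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  id <- names(rr)
  gene_id <- sub("\\|.*$", "", id)
  data.frame(gene_id = gene_id,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr) - 1L,
             tumor_allele = as.character(unlist(rr$ALT)),
             host_allele = as.character(rr$REF),
             row.names = NULL)
}

#' @rdname pipeline_io
#' @param df generic data.frame for the simple TSV formats (pileups, Ct
#'   tables, results).
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tsv <- function(path) read.delim(path, check.names = FALSE)
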