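#' Write synthetic dataset files
#'
#' Writes the genome (FASTA), gene models (GTF2.2), repeat track (BED6 with
#' name = SINE family and the element strand) and truth tables (TSV) of a
#' simulated dataset. Output is deterministic given the dataset.
#'
#' @param sim A `circscan_sim` from [generate_genome()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @importFrom rtracklayer export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom utils write.table
#' @export
write_genome_files <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             gtf = file.path(outdir, "genes.gtf"),
             bed = file.path(outdir, "repeats.bed"),
             genes = file.path(outdir, "truth_genes.tsv"),
             circs = file.path(outdir, "truth_circs.tsv"),
             sines = file.path(outdir, "truth_sines.tsv"))
  ss <- Biostrings::DNAStringSet(sim$genome$seq)
  Biostrings::writeXStringSet(ss, paths["fasta"])
  export_gene_models_gtf(sim$exons, paths["gtf"])
  if (nrow(sim$sines)) {
    gr <- GenomicRanges::GRanges(sim$sines$chrom,
                                 IRanges::IRanges(sim$sines$start, sim$sines$end),
                                 strand = sim$sines$strand)
    gr$name <- sim$sines$family
    gr$score <- 0L
    rtracklayer::export(gr, paths["bed"], format = "BED")
  } else {
    writeLines(character(0), paths["bed"])
  }
  tsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  tsv(sim$genes, paths["genes"])
  tsv(sim$circs, paths["circs"])
  tsv(sim$sines, paths["sines"])
  invisible(paths)
}

# GTF2.2 exon records (1-based closed per the standard).
export_gene_models_gtf <- function(exons, path) {
  if (!nrow(exons)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               strand = exons$strand)
  gr$source <- "circscan"
  gr$type <- "exon"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  gr$exon_number <- exons$exon_number
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports exon records into the plain exon table used across the package
#' (gene_id, transcript_id, chrom, start, end, strand, exon_number in
#' transcript order).
#'
#' @param path GTF file.
#' @return data.frame of exons.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(gene_id = gr$gene_id, transcript_id = gr$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  # transcript order: by coordinate, reversed for minus-strand transcripts
  df <- df[order(df$transcript_id, df$start), ]
  sp <- split(seq_len(nrow(df)), df$transcript_id)
  df$exon_number <- NA_integer_
  for (idx in sp) {
    n <- length(idx)
    df$exon_number[idx] <- if (df$strand[idx[1]] == "-") rev(seq_len(n)) else seq_len(n)
  }
  df <- df[order(df$gene_id, df$transcript_id, df$exon_number), ]
  rownames(df) <- NULL
  df
}

#' Write simulated reads as FASTQ
#'
#' All bases carry the constant Phred quality 'I'; qualities are never used
#' downstream.
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(strrep("I", nchar(reads))))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
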