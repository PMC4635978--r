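#' Build an exact k-mer anchor index over a genome
#'
#' Exhaustive exact-match index of every forward k-mer of every chromosome
#' (positions containing ambiguous bases are excluded). Minus-strand
#' occurrences of a query are found by looking up its reverse complement, so
#' the index stores forward positions only.
#'
#' @param genome A genome: FASTA path, named character vector, DNAStringSet
#'   or `circscan_genome`.
#' @param k Anchor length in nt (>= 8; default 20, the unique-exact-anchor
#'   "mapping score 40" contract).
#' @return An object of class `circscan_index`.
#' @importFrom data.table data.table setkey
#' @export
build_index <- function(genome, k = 20L) {
  k <- as.integer(k)
  stopifnot(k >= 8L)
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  if (!length(lens) || all(lens < k)) stop("genome is empty or shorter than k")
  tabs <- lapply(names(genome$seq), function(cn) {
    L <- lens[[cn]]
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    km <- substring(genome$seq[[cn]], pos, pos + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table::data.table(kmer = km[keep], chrom = cn, pos = pos[keep])
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  idx <- list(k = k, dt = dt, genome = genome, lens = lens)
  class(idx) <- "circscan_index"
  idx
}

#' Query the anchor index
#'
#' Returns all exact occurrences of each query k-mer on both strands. A
#' minus-strand hit at position p means the reverse complement of the query
#' occurs on the forward sequence at p (so the query matches the minus
#' strand there). Palindromic k-mers are reported on both strands at the
#' same locus.
#'
#' @param index A `circscan_index`.
#' @param kmers Character vector of query k-mers (length-k strings).
#' @return data.frame with columns query (index into `kmers`), chrom, pos
#'   (1-based start on the forward strand), strand.
#' @export
index_query <- function(index, kmers) {
  stopifnot(inherits(index, "circscan_index"),
            all(nchar(kmers) == index$k))
  q <- data.table::data.table(kmer = kmers, query = seq_along(kmers))
  fwd <- index$dt[q, on = "kmer", nomatch = NULL]
  rcq <- data.table::data.table(kmer = revcomp(kmers), query = seq_along(kmers))
  rev <- index$dt[rcq, on = "kmer", nomatch = NULL]
  out <- rbind(
    if (nrow(fwd)) data.frame(query = fwd$query, chrom = fwd$chrom,
                              pos = fwd$pos, strand = "+"),
    if (nrow(rev)) data.frame(query = rev$query, chrom = rev$chrom,
                              pos = rev$pos, strand = "-"))
  if (is.null(out)) out <- data.frame(query = integer(0), chrom = character(0),
                                      pos = integer(0), strand = character(0))
  out[order(out$query, out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' @export
print.circscan_index <- function(x, ...) {
  cat(sprintf("circscan k-mer index: k=%d, %d indexed forward positions over %d chromosome(s)\n",
              x$k, nrow(x$dt), length(x$lens)))
  invisible(x)
}
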