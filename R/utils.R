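# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet DNAString reverseComplement readDNAStringSet
#' @importFrom stats runif rpois setNames
NULL

# Random DNA of length n at a given GC fraction.
random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Byte-level reverse complement (fast for the per-read hot path; handles
# ACGTN and lowercase, leaves other bytes unchanged).
comp_lookup <- local({
  lk <- as.raw(0:255)
  from <- utf8ToInt("ACGTacgtNn")
  to <- utf8ToInt("TGCAtgcaNn")
  lk[from + 1L] <- as.raw(to)
  lk
})

revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(comp_lookup[as.integer(charToRaw(s)) + 1L]))
  }, character(1), USE.NAMES = FALSE)
}

# Draw one element of x (safe for length-1 x, unlike sample()).
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Log-uniform integer sampler on [lo, hi]; used for intron lengths and RPMs.
rloguniform <- function(n, lo, hi) {
  stopifnot(lo > 0, hi >= lo)
  exp(runif(n, log(lo), log(hi)))
}

# Genome container: named character vector of chromosome sequences plus
# cached raw-byte views for fast mismatch counting.
as_genome <- function(x) {
  if (inherits(x, "circscan_genome")) return(x)
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    names(ss) <- sub("\\s.*$", "", names(ss))
    x <- setNames(as.character(ss), names(ss))
  }
  stopifnot(is.character(x), !is.null(names(x)))
  g <- list(seq = x, raw = lapply(x, charToRaw))
  class(g) <- "circscan_genome"
  g
}

genome_lengths <- function(genome) vapply(genome$seq, nchar, integer(1))

# Substring of chromosome `chrom` on [start, end], 1-based closed; "+" as-is,
# "-" reverse-complemented.
genome_sub <- function(genome, chrom, start, end, strand = "+") {
  s <- substring(genome$seq[[chrom]], start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# Count mismatches between raw vectors a and b of equal length.
raw_mismatch <- function(a, b) sum(a != b)

#' @export
print.circscan_genome <- function(x, ...) {
  cat("synthetic genome:", length(x$seq), "chromosome(s),",
      sum(genome_lengths(x)), "bp total\n")
  invisible(x)
}
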