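#' Read-simulation parameters
#'
#' Single-end simulation at 100 nt (reads are treated independently by the
#' detection stage, so mate information would be ignored anyway).
#' `total_raw_reads` is the raw sequencing depth of the sample — the RPM
#' denominator and the basis for planted junction-read counts
#' (`count = round(target_rpm * total_raw_reads / 1e6)`) — while
#' `n_linear_reads` is the number of linear-transcript reads actually
#' emitted, which may be much smaller than the raw depth.
#'
#' @param read_length Read length (nt).
#' @param n_linear_reads Linear-transcript reads emitted.
#' @param total_raw_reads Raw read depth of the sample (RPM denominator).
#' @param error_rate Per-base substitution probability, in [0, 0.05].
#' @param anchor_len Anchor length: junction reads always span the
#'   back-splice with at least this many nt on both sides.
#' @param seed Integer seed.
#' @return An object of class `circscan_read_params`.
#' @export
read_sim_params <- function(read_length = 100L, n_linear_reads = 20000L,
                            total_raw_reads = 1e6, error_rate = 0,
                            anchor_len = 20L, seed = 1L) {
  p <- list(read_length = as.integer(read_length),
            n_linear_reads = as.integer(n_linear_reads),
            total_raw_reads = total_raw_reads,
            error_rate = error_rate, anchor_len = as.integer(anchor_len),
            seed = as.integer(seed))
  stopifnot(p$read_length > 2L * p$anchor_len,
            p$error_rate >= 0, p$error_rate <= 0.05,
            p$n_linear_reads >= 0L, p$total_raw_reads > 0)
  class(p) <- "circscan_read_params"
  p
}

# Apply substitution errors to a character vector of reads.
apply_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(r)
    ch <- strsplit(r, "")[[1]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate sequencing reads with planted back-splice junctions
#'
#' Emits single-end reads: linear reads drawn from spliced transcripts
#' (gene expression levels drawn log-normally), junction reads spanning each
#' planted circRNA's back-splice with at least `anchor_len` nt on both sides
#' (count = `round(target_rpm * total_raw_reads / 1e6)`), and decoy reads
#' drawn from the decoys' linear-mimic loci. Planted circRNAs whose target
#' RPM yields a count below one are omitted from the reads (with a warning)
#' but kept in the truth table.
#'
#' @param sim A `circscan_sim` from [generate_genome()].
#' @param params A [read_sim_params()].
#' @param sample_name Sample label recorded in the metadata.
#' @return A list of class `circscan_reads`: `reads` (named character
#'   vector), `meta` (data.frame read_id/origin/source_id), `sample`,
#'   `total_raw_reads`, `gene_reads` (true per-gene linear read counts).
#' @export
simulate_reads <- function(sim, params = read_sim_params(),
                           sample_name = "sample1") {
  stopifnot(inherits(sim, "circscan_sim"),
            inherits(params, "circscan_read_params"))
  with_seed(params$seed, simulate_reads_impl(sim, params, sample_name))
}

simulate_reads_impl <- function(sim, params, sample_name) {
  L <- params$read_length
  k <- params$anchor_len
  tx <- spliced_transcripts(sim)
  reads <- character(0); origin <- character(0); source_id <- character(0)
  gene_reads <- setNames(rep(0L, nrow(sim$genes)), sim$genes$gene_id)

  if (params$n_linear_reads > 0L && length(tx)) {
    tlen <- nchar(tx)
    usable <- tlen >= L
    if (any(usable)) {
      w <- rlnorm(sum(usable), meanlog = 0, sdlog = 1) * tlen[usable]
      gi <- sample(names(tx)[usable], params$n_linear_reads, replace = TRUE,
                   prob = w)
      pos <- vapply(tlen[gi] - L + 1L, function(m) sample.int(m, 1L), integer(1))
      reads <- substring(tx[gi], pos, pos + L - 1L)
      tab <- table(gi)
      gene_reads[names(tab)] <- as.integer(tab)
      origin <- rep("linear", length(reads))
      source_id <- gi
    }
  }

  if (nrow(sim$circs)) {
    for (ci in seq_len(nrow(sim$circs))) {
      cc <- sim$circs[ci, ]
      cnt <- round(cc$target_rpm * params$total_raw_reads / 1e6)
      if (cnt < 1L) {
        warning(sprintf("planted circ %s: target RPM %.3g yields no reads; kept in truth only",
                        cc$circ_id, cc$target_rpm))
        next
      }
      if (cc$is_decoy) {
        mlen <- cc$mimic_end - cc$mimic_start + 1L
        off <- sample.int(mlen - L + 1L, cnt, replace = TRUE)
        rs <- substring(genome_sub(sim$genome, cc$mimic_chrom, cc$mimic_start,
                                   cc$mimic_end), off, off + L - 1L)
      } else {
        ctx <- circ_transcript_seq(sim, ci)
        clen2 <- nchar(ctx)
        # junction offset = nt of donor-side sequence in the read, in [k, L-k]
        off <- sample(k:(L - k), cnt, replace = TRUE)
        rs <- vapply(off, function(o) {
          paste0(substring(ctx, clen2 - o + 1L, clen2),
                 substring(ctx, 1L, L - o))
        }, character(1))
      }
      reads <- c(reads, rs)
      origin <- c(origin, rep(if (cc$is_decoy) "decoy" else "junction", cnt))
      source_id <- c(source_id, rep(cc$circ_id, cnt))
    }
  }

  reads <- apply_errors(reads, params$error_rate)
  ids <- sprintf("read_%06d", seq_along(reads))
  names(reads) <- ids
  out <- list(reads = reads,
              meta = data.frame(read_id = ids, origin = origin,
                                source_id = source_id),
              sample = sample_name,
              total_raw_reads = params$total_raw_reads,
              gene_reads = gene_reads)
  class(out) <- "circscan_reads"
  out
}

# Spliced transcript sequences (transcript orientation) per gene.
spliced_transcripts <- function(sim) {
  if (!nrow(sim$exons)) return(character(0))
  sp <- split(sim$exons, sim$exons$gene_id)
  vapply(sp, function(ex) {
    ex <- ex[order(ex$exon_number), ]
    paste(vapply(seq_len(nrow(ex)), function(i)
      genome_sub(sim$genome, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[i]),
      character(1)), collapse = "")
  }, character(1))
}

# Spliced sequence of the circularized exon run of circ row ci.
circ_transcript_seq <- function(sim, ci) {
  cc <- sim$circs[ci, ]
  ex <- sim$exons[sim$exons$gene_id == cc$gene_id, ]
  ex <- ex[ex$exon_number >= cc$exon_first & ex$exon_number <= cc$exon_last, ]
  ex <- ex[order(ex$exon_number), ]
  paste(vapply(seq_len(nrow(ex)), function(i)
    genome_sub(sim$genome, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[i]),
    character(1)), collapse = "")
}

#' @export
print.circscan_reads <- function(x, ...) {
  cat(sprintf("circscan reads: %d emitted (%s), raw depth %s\n",
              length(x$reads),
              paste(sprintf("%s=%d", names(table(x$meta$origin)),
                            as.integer(table(x$meta$origin))), collapse = ", "),
              format(x$total_raw_reads, big.mark = ",")))
  invisible(x)
}
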