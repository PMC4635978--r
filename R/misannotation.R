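#' Build a back-splice junction probe
#'
#' Concatenates the last J exonic nt before the back-splice donor with the
#' first J exonic nt after the acceptor, in transcript orientation. When gene
#' models are supplied and a transcript's exon boundaries coincide with the
#' circ ends, the internal splice structure is respected (the probe follows
#' the spliced circular sequence); otherwise raw genomic flanks inside the
#' circ span are used. Sides are truncated to half the circularized sequence
#' length when J exceeds it (flagged).
#'
#' @param circ One-row data.frame (or list) with chrom, start, end, strand
#'   and optionally circ_id.
#' @param genome A genome acceptable to [build_index()].
#' @param gene_models Optional exon table (see [read_gene_models()]).
#' @param J Context length per side (default from config, 80 nt).
#' @return List of class `circscan_probe`: circ_id, sequence, side_len,
#'   truncated, donor_span, acceptor_span (genomic source spans).
#' @export
build_junction_probe <- function(circ, genome, gene_models = NULL, J = 80L) {
  genome <- as_genome(genome)
  chrom <- circ$chrom; start <- circ$start; end <- circ$end
  strand <- circ$strand
  span <- end - start + 1L
  if (span < 40L) stop("span too short: circ spans fewer than 2 x 20 nt")
  circ_seq <- NULL
  if (!is.null(gene_models)) circ_seq <- spliced_circ_seq(circ, genome, gene_models)
  if (is.null(circ_seq)) {
    circ_seq <- genome_sub(genome, chrom, start, end, strand)
  }
  n <- nchar(circ_seq)
  side <- min(as.integer(J), n %/% 2L)
  truncated <- side < J
  probe <- paste0(substring(circ_seq, n - side + 1L, n),
                  substring(circ_seq, 1L, side))
  # genomic source spans (outer circ ends; used to mask self-hits)
  if (strand == "+") {
    donor_span <- c(end - side + 1L, end); acceptor_span <- c(start, start + side - 1L)
  } else {
    donor_span <- c(start, start + side - 1L); acceptor_span <- c(end - side + 1L, end)
  }
  out <- list(circ_id = if (!is.null(circ$circ_id)) circ$circ_id
              else sprintf("%s:%d-%d:%s", chrom, start, end, strand),
              sequence = probe, side_len = side, truncated = truncated,
              chrom = chrom,
              donor_span = donor_span, acceptor_span = acceptor_span)
  class(out) <- "circscan_probe"
  out
}

# Spliced sequence of the circularized exon run, or NULL when no transcript's
# exon boundaries match the circ ends.
spliced_circ_seq <- function(circ, genome, gene_models) {
  ex <- gene_models[gene_models$chrom == circ$chrom &
                      gene_models$strand == circ$strand &
                      gene_models$start >= circ$start &
                      gene_models$end <= circ$end, , drop = FALSE]
  if (!nrow(ex)) return(NULL)
  for (tx in unique(ex$transcript_id)) {
    et <- ex[ex$transcript_id == tx, , drop = FALSE]
    if (min(et$start) != circ$start || max(et$end) != circ$end) next
    if (any(diff(sort(et$exon_number)) != 1L)) next
    et <- et[order(et$exon_number), ]
    return(paste(vapply(seq_len(nrow(et)), function(i)
      genome_sub(as_genome(genome), et$chrom[i], et$start[i], et$end[i],
                 et$strand[i]), character(1)), collapse = ""))
  }
  NULL
}

#' Seed-and-extend linear mapper
#'
#' Precomputes the seed index used by [linear_map_check()] (11-mer seeds by
#' default, emulating BLAT's untranslated seeding).
#'
#' @param genome A genome acceptable to [build_index()].
#' @param seed_k Seed length in nt.
#' @return A `circscan_index` with the genome attached.
#' @export
linear_mapper <- function(genome, seed_k = 11L) build_index(genome, k = seed_k)

#' Check whether a junction probe maps linearly to the genome
#'
#' Seed-and-extend ungapped local alignment of the probe against both genome
#' strands. The probe is deemed linearly mappable when one contiguous block
#' (one alignment diagonal), or two colinear blocks separated by a plausible
#' intron (>= 20 nt, genomic order matching probe order), cover at least
#' `min_coverage` of the probe at `min_identity` identity. Diagonals
#' dominated by the back-splice locus itself (the two probe source spans in
#' back-spliced order) are excluded.
#'
#' @param probe A `circscan_probe`.
#' @param mapper A [linear_mapper()] index.
#' @param config A [pipeline_config()].
#' @return One-row data.frame (LinearMapVerdict): circ_id, is_linear, and the
#'   best hit's chrom, hit_start, hit_end, identity, coverage, n_blocks,
#'   colinear.
#' @export
linear_map_check <- function(probe, mapper, config = pipeline_config()) {
  stopifnot(inherits(probe, "circscan_probe"), inherits(mapper, "circscan_index"))
  best <- list(identity = 0, coverage = 0, chrom = NA_character_,
               start = NA_integer_, end = NA_integer_, n_blocks = 0L,
               colinear = NA)
  for (orient in c("+", "-")) {
    P <- if (orient == "+") probe$sequence else revcomp(probe$sequence)
    h <- score_orientation(P, probe, mapper, config)
    if (!is.null(h) && h$identity > best$identity) best <- h
  }
  data.frame(circ_id = probe$circ_id,
             is_linear = best$identity >= config$min_identity &&
               best$coverage >= config$min_coverage,
             chrom = best$chrom, hit_start = best$start, hit_end = best$end,
             identity = best$identity, coverage = best$coverage,
             n_blocks = best$n_blocks, colinear = best$colinear)
}

score_orientation <- function(P, probe, mapper, config) {
  n <- nchar(P)
  sk <- mapper$k
  if (n < sk) return(NULL)
  spos <- seq_len(n - sk + 1L)
  seeds <- substring(P, spos, spos + sk - 1L)
  hits <- index_query(mapper, seeds)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits$diag <- hits$pos - spos[hits$query] + 1L  # genome start of probe pos 1
  dg <- aggregate(query ~ chrom + diag, data = hits, FUN = length)
  names(dg)[3] <- "n_seeds"
  dg <- dg[order(-dg$n_seeds), , drop = FALSE]
  if (nrow(dg) > 50L) dg <- dg[1:50, , drop = FALSE]
  # mask diagonals dominated by the probe's own source spans
  src <- rbind(probe$donor_span, probe$acceptor_span)
  self_hit <- dg$chrom == probe$chrom &
    apply(dg, 1, function(r) {
      d <- as.integer(r[["diag"]])
      ov <- pmin(src[, 2], d + n - 1L) - pmax(src[, 1], d) + 1L
      any(ov > n / 4)
    })
  dg <- dg[!self_hit, , drop = FALSE]
  if (!nrow(dg)) return(NULL)

  Praw <- charToRaw(P)
  match_vec <- function(chrom, d) {
    g <- mapper$genome$raw[[chrom]]
    i <- seq_len(n)
    gi <- d + i - 1L
    ok <- gi >= 1L & gi <= length(g)
    m <- rep(FALSE, n)
    m[ok] <- g[gi[ok]] == Praw[ok]
    list(m = m, aligned = sum(ok))
  }
  mv <- vector("list", nrow(dg))
  best <- NULL
  upd <- function(best, cand) {
    if (is.null(best) || cand$identity > best$identity) cand else best
  }
  for (i in seq_len(nrow(dg))) {
    mv[[i]] <- match_vec(dg$chrom[i], dg$diag[i])
    best <- upd(best, list(identity = sum(mv[[i]]$m) / n,
                           coverage = mv[[i]]$aligned / n,
                           chrom = dg$chrom[i], start = dg$diag[i],
                           end = dg$diag[i] + n - 1L, n_blocks = 1L,
                           colinear = TRUE))
  }
  # two colinear blocks separated by >= 20 nt (spliced-but-colinear mapping)
  strong <- which(dg$n_seeds >= 2L)
  for (i in strong) for (j in strong) {
    if (dg$chrom[i] != dg$chrom[j]) next
    gap <- dg$diag[j] - dg$diag[i]
    if (gap < 20L) next
    c1 <- cumsum(mv[[i]]$m); c2 <- cumsum(mv[[j]]$m)
    tot2 <- c2[n]
    sc <- c1 + tot2 - c2   # split after position s
    s <- which.max(sc)
    best <- upd(best, list(identity = sc[s] / n,
                           coverage = min(mv[[i]]$aligned, mv[[j]]$aligned) / n,
                           chrom = dg$chrom[i], start = dg$diag[i],
                           end = dg$diag[j] + n - 1L, n_blocks = 2L,
                           colinear = TRUE))
  }
  best
}

#' Partition candidate circRNAs by linear-mapping verdicts
#'
#' @param circs data.frame of candidate circRNAs with circ_id.
#' @param verdicts data.frame of [linear_map_check()] verdicts (one per circ).
#' @return List: `kept`, `removed` (data.frames) and `removed_fraction`.
#' @export
filter_candidates <- function(circs, verdicts) {
  if (!all(circs$circ_id %in% verdicts$circ_id)) {
    stop("missing verdict for: ",
         paste(setdiff(circs$circ_id, verdicts$circ_id), collapse = ", "))
  }
  v <- verdicts$is_linear[match(circs$circ_id, verdicts$circ_id)]
  list(kept = circs[!v, , drop = FALSE], removed = circs[v, , drop = FALSE],
       removed_fraction = if (nrow(circs)) sum(v) / nrow(circs) else 0)
}

#' Run the mis-annotation filter on a candidate set
#'
#' Builds a junction probe for every candidate, checks each for linear
#' mappability and partitions the set.
#'
#' @param circs data.frame of candidates (circ_id, chrom, start, end, strand).
#' @param genome Genome (any form acceptable to [build_index()]).
#' @param gene_models Optional exon table for exonic probe construction.
#' @param config A [pipeline_config()].
#' @param mapper Optional precomputed [linear_mapper()].
#' @return List: `kept`, `removed`, `removed_fraction`, `verdicts`.
#' @export
run_misannotation_filter <- function(circs, genome, gene_models = NULL,
                                     config = pipeline_config(),
                                     mapper = NULL) {
  genome <- as_genome(genome)
  if (is.null(mapper)) mapper <- linear_mapper(genome)
  verdicts <- do.call(rbind, lapply(seq_len(nrow(circs)), function(i) {
    pr <- build_junction_probe(circs[i, ], genome, gene_models,
                               J = config$probe_half)
    linear_map_check(pr, mapper, config)
  }))
  if (is.null(verdicts)) {
    verdicts <- data.frame(circ_id = character(0), is_linear = logical(0))
  }
  c(filter_candidates(circs, verdicts), list(verdicts = verdicts))
}
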