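#' Remove reads explained by a contiguous linear genome match
#'
#' A read with a full-length contiguous exact or near-exact (at most
#' `max_mismatch` substitutions) match to the genome on either strand is
#' linear and cannot support a back-splice junction; it is removed before
#' anchor analysis. Terminal anchors seed the check, so a read whose both
#' terminal k-mers are absent from the genome (e.g. all Ns) is retained here
#' and discarded downstream for lack of anchor hits.
#'
#' @param reads Named character vector of read sequences.
#' @param index A `circscan_index`.
#' @param max_mismatch Substitutions tolerated in a full-length match.
#' @return List with `unexplained` (named character vector) and
#'   `removed` (ids of linearly explained reads).
#' @export
filter_linear_reads <- function(reads, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "circscan_index"))
  if (!length(reads)) {
    return(list(unexplained = reads, removed = character(0)))
  }
  k <- index$k
  L <- nchar(reads)
  stopifnot(all(L >= k))
  first <- substring(reads, 1L, k)
  last <- substring(reads, L - k + 1L, L)
  hits <- index_query(index, c(first, last))
  n <- length(reads)
  hits$read <- ((hits$query - 1L) %% n) + 1L
  hits$which_anchor <- ifelse(hits$query > n, "last", "first")
  sp <- split(hits, hits$read)

  removed <- logical(n)
  for (nm in names(sp)) {
    i <- as.integer(nm)
    h <- sp[[nm]]
    r <- reads[[i]]; Li <- L[i]
    rr <- charToRaw(r)
    rcr <- NULL
    plus <- h$strand == "+"
    at_first <- h$which_anchor == "first"
    start <- ifelse(plus == at_first, h$pos, h$pos - (Li - k))
    rc <- !plus
    dup <- duplicated(paste(h$chrom, start, rc))
    for (j in which(!dup)) {
      s <- start[j]
      g <- index$genome$raw[[h$chrom[j]]]
      if (s < 1L || s + Li - 1L > length(g)) next
      probe <- if (rc[j]) {
        if (is.null(rcr)) rcr <- charToRaw(revcomp(r))
        rcr
      } else rr
      if (sum(g[s:(s + Li - 1L)] != probe) <= max_mismatch) {
        removed[i] <- TRUE
        break
      }
    }
  }
  list(unexplained = reads[!removed], removed = names(reads)[removed])
}

#' Detect a back-splice junction in one read
#'
#' Implements the strict dual-exact-anchor split mapping: the first and last
#' `anchor_len` nt of the read must each have exactly one exact genomic hit
#' (the "mapping score 40" contract), on the same chromosome and strand,
#' with the 3'-anchor locus genomically upstream of the 5'-anchor locus
#' (reversed order, the back-splice signature) within `max_span`. The
#' anchors are then extended toward the read interior to locate a breakpoint
#' that explains every read base with at most `max_mismatch` substitutions
#' (outside the anchors) and places GT..AG (strand-appropriate) at the
#' inferred donor/acceptor intron edges. Exactly one such breakpoint yields
#' a candidate; zero or several reject the read.
#'
#' @param read A single read sequence (length >= 2 * anchor_len).
#' @param index A `circscan_index` built with `k = config$anchor_len`.
#' @param config A [pipeline_config()].
#' @param read_id Identifier recorded in the candidate.
#' @return List with `candidate` (one-row data.frame with chrom, start, end,
#'   strand, read_id, breakpoint_unique, anchors_unique_exact; or NULL) and
#'   `reason` (NA for success, otherwise the rejection reason).
#' @export
detect_backsplice <- function(read, index, config = pipeline_config(),
                              read_id = "read") {
  stopifnot(inherits(index, "circscan_index"), index$k == config$anchor_len)
  k <- config$anchor_len
  if (nchar(read) < 2L * k) {
    return(list(candidate = NULL, reason = "read too short"))
  }
  h <- index_query(index, c(substring(read, 1L, k),
                            substring(read, nchar(read) - k + 1L, nchar(read))))
  .detect_one(read, h[h$query == 1L, , drop = FALSE],
              h[h$query == 2L, , drop = FALSE], index, config, read_id)
}

.detect_one <- function(read, h1, h2, index, config, read_id) {
  reject <- function(why) list(candidate = NULL, reason = why)
  if (nrow(h1) != 1L || nrow(h2) != 1L) {
    return(reject("ambiguous/unmapped anchor"))
  }
  if (h1$chrom != h2$chrom) return(reject("anchors on different chromosomes"))
  if (h1$strand != h2$strand) return(reject("anchor strand mismatch"))
  k <- config$anchor_len
  L <- nchar(read)
  if (h1$strand == "-") {
    # work in forward-genome space on the reverse complement of the read;
    # the anchor loci swap roles
    s <- revcomp(read)
    q1 <- h2$pos; q2 <- h1$pos
  } else {
    s <- read
    q1 <- h1$pos; q2 <- h2$pos
  }
  if (q1 <= q2) return(reject("colinear anchors (linear splice)"))
  chrom <- h1$chrom
  gl <- index$lens[[chrom]]
  span <- q1 - q2 + L - k          # end - start + 1 for any breakpoint
  if (span > config$max_span) return(reject("span exceeds max_span"))
  if (q2 + 2L * k - L - 2L < 1L || q1 + L - k + 1L > gl) {
    return(reject("anchor extension out of chromosome bounds"))
  }

  g <- index$genome$raw[[chrom]]
  sr <- charToRaw(s)
  mid <- (k + 1L):(L - k)                    # extension region positions
  pre_mm <- cumsum(sr[mid] != g[q1 + mid - 1L])
  m2 <- sr[mid] != g[q2 + mid + k - L - 1L]
  suf_mm <- rev(cumsum(rev(m2)))             # suf_mm[i] = mismatches at >= mid[i]
  bks <- k:(L - k)                           # donor-side nt in the read
  tot <- vapply(bks, function(b) {
    pre <- if (b == k) 0L else pre_mm[b - k]
    suf <- if (b == L - k) 0L else suf_mm[b - k + 1L]
    pre + suf
  }, numeric(1))
  # The circ strand comes from the splice-signal orientation, not from which
  # genome strand the read matched: a plus-strand junction shows GT (donor)
  # to the right and AG (acceptor) to the left in forward coordinates; a
  # minus-strand junction shows CT / AC (the reverse complements).
  don_mot <- vapply(bks, function(b) {
    e <- q1 + b - 1L
    rawToChar(g[(e + 1L):(e + 2L)])
  }, character(1))
  acc_mot <- vapply(bks, function(b) {
    a <- q2 + b + k - L
    rawToChar(g[(a - 2L):(a - 1L)])
  }, character(1))
  ok <- tot <= config$max_mismatch
  valid_plus <- which(ok & don_mot == "GT" & acc_mot == "AG")
  valid_minus <- which(ok & don_mot == "CT" & acc_mot == "AC")
  if (length(valid_plus) + length(valid_minus) == 0L) {
    return(reject("no canonical breakpoint"))
  }
  # prefer the best-scoring breakpoint; reject only genuine score ties
  best_mm <- min(tot[c(valid_plus, valid_minus)])
  valid_plus <- valid_plus[tot[valid_plus] == best_mm]
  valid_minus <- valid_minus[tot[valid_minus] == best_mm]
  if (length(valid_plus) + length(valid_minus) > 1L) {
    return(reject("ambiguous breakpoint"))
  }
  strand <- if (length(valid_plus)) "+" else "-"
  b <- bks[c(valid_plus, valid_minus)]
  start <- q2 + b + k - L
  end <- q1 + b - 1L
  list(candidate = data.frame(chrom = chrom, start = start, end = end,
                              strand = strand, read_id = read_id,
                              breakpoint_unique = TRUE,
                              anchors_unique_exact = TRUE),
       reason = NA_character_)
}

#' Detect back-splice candidates in a set of reads
#'
#' Batch version of [detect_backsplice()]: one anchor-index query for all
#' reads, then per-read breakpoint resolution.
#'
#' @param reads Named character vector (already linearly filtered).
#' @param index A `circscan_index`.
#' @param config A [pipeline_config()].
#' @return List with `candidates` (data.frame) and `rejections` (data.frame
#'   read_id, reason).
#' @export
detect_backsplice_all <- function(reads, index, config = pipeline_config()) {
  if (!length(reads)) {
    return(list(candidates = empty_candidates(), rejections =
                  data.frame(read_id = character(0), reason = character(0))))
  }
  k <- config$anchor_len
  L <- nchar(reads)
  n <- length(reads)
  first <- substring(reads, 1L, k)
  last <- substring(reads, L - k + 1L, L)
  hits <- index_query(index, c(first, last))
  hits$read <- ((hits$query - 1L) %% n) + 1L
  hits$anchor <- ifelse(hits$query > n, 2L, 1L)
  sp <- split(hits[c("chrom", "pos", "strand", "anchor")], hits$read)
  cands <- list(); rej_id <- character(0); rej_why <- character(0)
  empty_h <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0))
  for (i in seq_len(n)) {
    h <- sp[[as.character(i)]]
    h1 <- if (is.null(h)) empty_h else h[h$anchor == 1L, , drop = FALSE]
    h2 <- if (is.null(h)) empty_h else h[h$anchor == 2L, , drop = FALSE]
    res <- .detect_one(reads[[i]], h1, h2, index, config, names(reads)[i])
    if (is.null(res$candidate)) {
      rej_id <- c(rej_id, names(reads)[i]); rej_why <- c(rej_why, res$reason)
    } else {
      cands[[length(cands) + 1L]] <- res$candidate
    }
  }
  list(candidates = if (length(cands)) do.call(rbind, cands)
                    else empty_candidates(),
       rejections = data.frame(read_id = rej_id, reason = rej_why))
}

empty_candidates <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), read_id = character(0),
             breakpoint_unique = logical(0), anchors_unique_exact = logical(0))
}

#' Call circRNAs from back-splice candidates
#'
#' Groups candidates by junction (chrom, start, end, strand) and keeps
#' junctions with at least `config$support_min` supporting reads within at
#' least one single sample. Per-sample support is recorded for every kept
#' junction.
#'
#' @param candidates data.frame of candidates with a `sample` column (as
#'   produced by [detect_circRNAs()]; single-sample candidate tables may omit
#'   it and pass `sample`).
#' @param config A [pipeline_config()].
#' @param sample Sample name used when `candidates` lacks a sample column.
#' @return data.frame: circ_id, chrom, start, end, strand, sample, support
#'   (long format, one row per kept circRNA x sample with nonzero support).
#' @export
call_circRNAs <- function(candidates, config = pipeline_config(),
                          sample = "sample1") {
  if (!nrow(candidates)) {
    return(data.frame(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), sample = character(0),
                      support = integer(0)))
  }
  stopifnot(all(candidates$breakpoint_unique),
            all(candidates$anchors_unique_exact))
  if (is.null(candidates$sample)) candidates$sample <- sample
  candidates$circ_id <- sprintf("%s:%d-%d:%s", candidates$chrom,
                                candidates$start, candidates$end,
                                candidates$strand)
  agg <- aggregate(read_id ~ circ_id + chrom + start + end + strand + sample,
                   data = candidates, FUN = length)
  names(agg)[names(agg) == "read_id"] <- "support"
  keep_ids <- unique(agg$circ_id[agg$support >= config$support_min])
  out <- agg[agg$circ_id %in% keep_ids, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Run the detection stage on one sample
#'
#' Linear filtering, anchor-based back-splice detection and the >= 2-read
#' support rule, in order. Reads removed as linear never contribute
#' candidates (stage exclusivity).
#'
#' @param reads A `circscan_reads` object or named character vector.
#' @param index A `circscan_index` with `k = config$anchor_len`.
#' @param config A [pipeline_config()].
#' @param sample Sample name (taken from the reads object when available).
#' @return List of class `circscan_detection`: `circs` (called junctions,
#'   long format with per-sample support), `candidates`, `rejections`,
#'   `n_linear_removed`, `sample`, `total_raw_reads` (NA for plain vectors).
#' @export
detect_circRNAs <- function(reads, index, config = pipeline_config(),
                            sample = NULL) {
  total_raw <- NA_real_
  if (inherits(reads, "circscan_reads")) {
    if (is.null(sample)) sample <- reads$sample
    total_raw <- reads$total_raw_reads
    reads <- reads$reads
  }
  if (is.null(sample)) sample <- "sample1"
  flt <- filter_linear_reads(reads, index, config$max_mismatch)
  det <- detect_backsplice_all(flt$unexplained, index, config)
  if (nrow(det$candidates)) det$candidates$sample <- sample
  circs <- call_circRNAs(det$candidates, config, sample = sample)
  out <- list(circs = circs, candidates = det$candidates,
              rejections = det$rejections,
              n_linear_removed = length(flt$removed), sample = sample,
              total_raw_reads = total_raw)
  class(out) <- "circscan_detection"
  out
}

#' @export
print.circscan_detection <- function(x, ...) {
  cat(sprintf("circscan detection [%s]: %d circRNA(s) from %d candidate read(s); %d linear read(s) removed, %d rejected\n",
              x$sample, length(unique(x$circs$circ_id)), nrow(x$candidates),
              x$n_linear_removed, nrow(x$rejections)))
  invisible(x)
}
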