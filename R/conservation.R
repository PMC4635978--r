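#' Read a UCSC chain file
#'
#' Validates the chain dialect (11-field headers, numeric block lines) and
#' imports it with rtracklayer. Malformed files raise a parse error naming
#' the offending line.
#'
#' @param path Chain file path.
#' @return An rtracklayer `Chain` object mapping the chain's t-side
#'   coordinates to its q-side.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  in_chain <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { in_chain <- FALSE; next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "chain") {
      if (length(f) != 13L) {
        stop(sprintf("chain parse error at line %d: expected 13 header fields, got %d",
                     i, length(f)))
      }
      in_chain <- TRUE
    } else {
      if (!in_chain) stop(sprintf("chain parse error at line %d: block outside chain", i))
      if (!length(f) %in% c(1L, 3L) || anyNA(suppressWarnings(as.numeric(f)))) {
        stop(sprintf("chain parse error at line %d: malformed block line", i))
      }
      if (length(f) == 1L) in_chain <- FALSE
    }
  }
  rtracklayer::import.chain(path)
}

#' Lift circRNA ends through a chain and recombine
#'
#' The paper-style end-anchored lift: intronic sequence between species is
#' poorly conserved, so whole multi-exon circRNAs rarely lift. Instead the
#' terminal `end_len` bp of each circRNA are lifted independently and the
#' outermost lifted coordinates recombined into a target-assembly circRNA.
#' Both ends must map fully within single chain blocks, to the same target
#' chromosome and strand, with their relative order preserved; otherwise the
#' circ is reported unlifted with a reason (end unmapped, end split,
#' cross-chromosome, strand mismatch, inverted order).
#'
#' @param circs data.frame with circ_id, chrom, start, end, strand.
#' @param chain A `Chain` from [read_chain()].
#' @param end_len End length in bp (default 20).
#' @return data.frame (LiftedCirc): circ_id, status ("lifted"/"unlifted"),
#'   reason, target_chrom, lifted_start, lifted_end, target_strand.
#' @importFrom rtracklayer liftOver
#' @export
lift_circ_ends <- function(circs, chain, end_len = 20L) {
  end_len <- as.integer(end_len)
  out <- data.frame(circ_id = circs$circ_id, status = "unlifted",
                    reason = NA_character_, target_chrom = NA_character_,
                    lifted_start = NA_integer_, lifted_end = NA_integer_,
                    target_strand = NA_character_)
  if (!nrow(circs)) return(out)
  left <- GenomicRanges::GRanges(circs$chrom,
                                 IRanges::IRanges(circs$start,
                                                  circs$start + end_len - 1L),
                                 strand = circs$strand)
  right <- GenomicRanges::GRanges(circs$chrom,
                                  IRanges::IRanges(circs$end - end_len + 1L,
                                                   circs$end),
                                  strand = circs$strand)
  lv <- rtracklayer::liftOver(left, chain)
  rv <- rtracklayer::liftOver(right, chain)
  for (i in seq_len(nrow(circs))) {
    l <- lv[[i]]; r <- rv[[i]]
    if (length(l) == 0L || length(r) == 0L) { out$reason[i] <- "end unmapped"; next }
    if (length(l) > 1L || length(r) > 1L ||
        GenomicRanges::width(l) != end_len || GenomicRanges::width(r) != end_len) {
      out$reason[i] <- "end split"; next
    }
    if (as.character(GenomicRanges::seqnames(l)) !=
        as.character(GenomicRanges::seqnames(r))) {
      out$reason[i] <- "cross-chromosome"; next
    }
    sl <- as.character(GenomicRanges::strand(l))
    if (sl != as.character(GenomicRanges::strand(r))) {
      out$reason[i] <- "strand mismatch"; next
    }
    # end order on the target must match the source order (possibly swapped
    # as a whole by a strand flip)
    flipped <- sl != circs$strand[i]
    ls <- GenomicRanges::start(l); rs <- GenomicRanges::start(r)
    ordered <- if (flipped) rs < ls else ls < rs
    if (!ordered) { out$reason[i] <- "inverted order"; next }
    out$status[i] <- "lifted"
    out$target_chrom[i] <- as.character(GenomicRanges::seqnames(l))
    out$lifted_start[i] <- min(GenomicRanges::start(l), GenomicRanges::start(r))
    out$lifted_end[i] <- max(GenomicRanges::end(l), GenomicRanges::end(r))
    out$target_strand[i] <- sl
  }
  out
}

#' Count circRNAs with identical coordinates in another set
#'
#' Identity means same target chromosome, start and end exactly (and strand,
#' unless `check_strand = FALSE`). The fraction uses successfully lifted
#' circRNAs as the denominator.
#'
#' @param lifted [lift_circ_ends()] output.
#' @param target_circs data.frame with chrom, start, end, strand on the
#'   target assembly.
#' @param check_strand Require strand equality (default TRUE).
#' @return List: `n_lifted`, `n_identical`, `fraction` and `identical`
#'   (logical per lifted circ, NA for unlifted).
#' @export
count_identical <- function(lifted, target_circs, check_strand = TRUE) {
  ok <- lifted$status == "lifted"
  key <- function(chrom, start, end, strand) {
    if (check_strand) paste(chrom, start, end, strand)
    else paste(chrom, start, end)
  }
  tk <- key(target_circs$chrom, target_circs$start, target_circs$end,
            target_circs$strand)
  ident <- rep(NA, nrow(lifted))
  ident[ok] <- key(lifted$target_chrom[ok], lifted$lifted_start[ok],
                   lifted$lifted_end[ok], lifted$target_strand[ok]) %in% tk
  list(n_lifted = sum(ok), n_identical = sum(ident[ok]),
       fraction = if (sum(ok)) sum(ident[ok]) / sum(ok) else NA_real_,
       identical = ident)
}

#' Enumerate candidate in-silico circRNAs
#'
#' Every contiguous exon run (exons i..j, i <= j) of every transcript of the
#' supplied genes, deduplicated by outer genomic coordinates. A transcript
#' with n exons yields n(n+1)/2 runs.
#'
#' @param exons Exon table.
#' @param gene_ids Genes to enumerate.
#' @return data.frame circ_id, chrom, start, end, strand, gene_id.
#' @export
enumerate_circle_candidates <- function(exons, gene_ids) {
  ex <- exons[exons$gene_id %in% gene_ids, , drop = FALSE]
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    et <- ex[ex$transcript_id == tx, , drop = FALSE]
    et <- et[order(et$exon_number), ]
    n <- nrow(et)
    for (i in seq_len(n)) for (j in i:n) {
      s <- min(et$start[i:j]); e <- max(et$end[i:j])
      out[[length(out) + 1L]] <- data.frame(
        circ_id = sprintf("%s:%d-%d:%s", et$chrom[1], s, e, et$strand[1]),
        chrom = et$chrom[1], start = s, end = e, strand = et$strand[1],
        gene_id = et$gene_id[1])
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(circ_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               gene_id = character(0))
  out[!duplicated(out$circ_id), , drop = FALSE]
}

#' Generate in-silico control circRNAs
#'
#' The conservation null model: all possible single- and multi-exonic
#' circRNAs are formed from genes expressed above `fpkm_insilico`, the
#' actually detected circRNAs are removed, and candidates are drawn at random
#' (without replacement) until `n_target` of them lift successfully through
#' the chain — matching the observed number of successfully lifted circRNAs.
#'
#' @param exons Exon table.
#' @param gene_fpkm Named vector (or data.frame gene_id, fpkm) of host-gene
#'   expression.
#' @param real_circs data.frame of detected circRNAs (removed from the pool).
#' @param n_target Number of lifted controls required.
#' @param chain Chain used for lifting.
#' @param seed Integer seed for the sampling order.
#' @param config A [pipeline_config()].
#' @param end_len End length for lifting.
#' @return List: `controls` (sampled candidates), `lifted` (their lift
#'   results; exactly `n_target` rows have status "lifted"), `pool_size`.
#' @export
generate_insilico_controls <- function(exons, gene_fpkm, real_circs, n_target,
                                       chain, seed = 1L,
                                       config = pipeline_config(),
                                       end_len = NULL) {
  if (is.data.frame(gene_fpkm)) {
    gene_fpkm <- setNames(gene_fpkm$fpkm, gene_fpkm$gene_id)
  }
  if (is.null(end_len)) end_len <- config$lift_end_len
  genes <- names(gene_fpkm)[gene_fpkm > config$fpkm_insilico]
  pool <- enumerate_circle_candidates(exons, genes)
  real_key <- paste(real_circs$chrom, real_circs$start, real_circs$end)
  pool <- pool[!(paste(pool$chrom, pool$start, pool$end) %in% real_key), ,
               drop = FALSE]
  if (nrow(pool) < n_target) {
    stop(sprintf("in-silico candidate pool (%d) smaller than n_target (%d)",
                 nrow(pool), n_target))
  }
  ord <- with_seed(seed, sample.int(nrow(pool)))
  pool <- pool[ord, , drop = FALSE]
  taken <- 0L; lifted_n <- 0L
  lifts <- list()
  batch <- max(n_target, 64L)
  while (lifted_n < n_target && taken < nrow(pool)) {
    idx <- (taken + 1L):min(taken + batch, nrow(pool))
    lv <- lift_circ_ends(pool[idx, , drop = FALSE], chain, end_len)
    need <- n_target - lifted_n
    ok <- which(lv$status == "lifted")
    if (length(ok) > need) {
      cut <- ok[need]
      lv <- lv[seq_len(cut), , drop = FALSE]
      idx <- idx[seq_len(cut)]
      ok <- ok[seq_len(need)]
    }
    lifts[[length(lifts) + 1L]] <- lv
    lifted_n <- lifted_n + length(ok)
    taken <- idx[length(idx)]
  }
  if (lifted_n < n_target) {
    stop(sprintf("only %d of %d required control circRNAs lifted (pool %d)",
                 lifted_n, n_target, nrow(pool)))
  }
  controls <- pool[seq_len(taken), , drop = FALSE]
  stopifnot(!any(paste(controls$chrom, controls$start, controls$end) %in% real_key))
  list(controls = controls, lifted = do.call(rbind, lifts),
       pool_size = nrow(pool))
}

#' Chi-squared test of conservation against the in-silico null
#'
#' Pearson chi-squared (no continuity correction) on the 2x2 table of
#' identical vs non-identical counts for observed and control circRNAs.
#'
#' @param n_identical_obs,n_obs Identical and total lifted observed circRNAs.
#' @param n_identical_ctrl,n_ctrl Same for the in-silico controls.
#' @return List: `statistic`, `p.value`, `table`.
#' @export
conservation_test <- function(n_identical_obs, n_obs, n_identical_ctrl,
                              n_ctrl) {
  stopifnot(n_identical_obs >= 0, n_identical_ctrl >= 0,
            n_obs >= n_identical_obs, n_ctrl >= n_identical_ctrl)
  tab <- rbind(observed = c(identical = n_identical_obs,
                            other = n_obs - n_identical_obs),
               control = c(identical = n_identical_ctrl,
                           other = n_ctrl - n_identical_ctrl))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is zero")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value, table = tab)
}
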