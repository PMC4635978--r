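#' Extract the introns flanking circularized exons
#'
#' For each circRNA (or control exon treated as a single-exon pseudo-circ)
#' whose outer splice sites coincide with annotated exon boundaries of a host
#' transcript, returns the intron immediately upstream of the acceptor and
#' immediately downstream of the donor (transcript orientation). CircRNAs
#' starting at a transcript's first exon or ending at its last are excluded
#' (no flanking intron on that side).
#'
#' @param circs data.frame with circ_id, chrom, start, end, strand.
#' @param exons Exon table (see [read_gene_models()]).
#' @return List: `pairs` (data.frame with the two flanking intron intervals;
#'   `left_*` is the genomically left intron abutting the circ start,
#'   `right_*` the genomically right one, plus `up_len`/`down_len` in
#'   transcript orientation) and `excluded` (circ_id, reason).
#' @export
extract_flanking_introns <- function(circs, exons) {
  pairs <- list(); exc_id <- character(0); exc_why <- character(0)
  for (i in seq_len(nrow(circs))) {
    cc <- circs[i, ]
    res <- flank_one(cc, exons)
    if (is.character(res)) {
      exc_id <- c(exc_id, cc$circ_id); exc_why <- c(exc_why, res)
    } else {
      pairs[[length(pairs) + 1L]] <- res
    }
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(circ_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0), strand = character(0),
                    left_start = integer(0), left_end = integer(0),
                    right_start = integer(0), right_end = integer(0),
                    up_len = integer(0), down_len = integer(0)),
       excluded = data.frame(circ_id = exc_id, reason = exc_why))
}

flank_one <- function(cc, exons) {
  ex <- exons[exons$chrom == cc$chrom & exons$strand == cc$strand, , drop = FALSE]
  for (tx in unique(ex$transcript_id)) {
    et <- ex[ex$transcript_id == tx, , drop = FALSE]
    et <- et[order(et$exon_number), ]
    inside <- et[et$start >= cc$start & et$end <= cc$end, , drop = FALSE]
    if (!nrow(inside)) next
    if (min(inside$start) != cc$start || max(inside$end) != cc$end) next
    a <- min(inside$exon_number); b <- max(inside$exon_number)
    n <- max(et$exon_number)
    if (a == 1L || b == n) return("no flanking intron")
    # introns in transcript orientation: upstream = between exon a-1 and a,
    # downstream = between exon b and b+1
    up <- intron_interval(et, a - 1L, a)
    down <- intron_interval(et, b, b + 1L)
    left <- if (up[1] < down[1]) up else down
    right <- if (up[1] < down[1]) down else up
    return(data.frame(circ_id = cc$circ_id, chrom = cc$chrom,
                      start = cc$start, end = cc$end, strand = cc$strand,
                      left_start = left[1], left_end = left[2],
                      right_start = right[1], right_end = right[2],
                      up_len = up[2] - up[1] + 1L,
                      down_len = down[2] - down[1] + 1L))
  }
  "no matching transcript"
}

# Genomic interval of the intron between transcript exons i and j = i+1.
intron_interval <- function(et, i, j) {
  e1 <- et[et$exon_number == i, ]; e2 <- et[et$exon_number == j, ]
  if (e1$start < e2$start) c(e1$end + 1L, e2$start - 1L)
  else c(e2$end + 1L, e1$start - 1L)
}

#' Control exons for flanking-feature comparisons
#'
#' Internal, never-circularized exons of circRNA-hosting genes, with the same
#' first/last-exon exclusion as the circRNA set. Each is returned as a
#' single-exon pseudo-circ usable with [extract_flanking_introns()].
#'
#' @param circs Genuine circRNA table (circ_id, chrom, start, end, strand).
#' @param exons Exon table.
#' @return data.frame of pseudo-circs (circ_id "ctrl:<...>").
#' @export
control_exons <- function(circs, exons) {
  hosts <- match_hosts(circs, aggregate_genes(exons))
  host_genes <- unique(na.omit(hosts$assignment$host_gene))
  ex <- exons[exons$gene_id %in% host_genes, , drop = FALSE]
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    et <- ex[ex$transcript_id == tx, , drop = FALSE]
    n <- max(et$exon_number)
    et <- et[et$exon_number > 1L & et$exon_number < n, , drop = FALSE]
    if (!nrow(et)) next
    # drop exons inside any circ span
    for (i in seq_len(nrow(et))) {
      circd <- any(circs$chrom == et$chrom[i] & circs$strand == et$strand[i] &
                     circs$start <= et$start[i] & circs$end >= et$end[i])
      if (!circd) {
        out[[length(out) + 1L]] <- data.frame(
          circ_id = sprintf("ctrl:%s:%d-%d:%s", et$chrom[i], et$start[i],
                            et$end[i], et$strand[i]),
          chrom = et$chrom[i], start = et$start[i], end = et$end[i],
          strand = et$strand[i])
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(circ_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0))
}

# Gene intervals from an exon table.
aggregate_genes <- function(exons) {
  sp <- split(exons, exons$gene_id)
  do.call(rbind, lapply(sp, function(ex) data.frame(
    gene_id = ex$gene_id[1], chrom = ex$chrom[1], start = min(ex$start),
    end = max(ex$end), strand = ex$strand[1])))
}

#' Expression tier of a circRNA
#'
#' Tiers by RPM: low (rpm_min to t2], medium (t2 to t3], high (> t3) with
#' `rpm_tiers = (rpm_min, t2, t3)`.
#'
#' @param rpm Numeric RPM values (typically each circ's maximum over samples).
#' @param config A [pipeline_config()].
#' @return Character vector: "below", "low", "medium" or "high".
#' @export
expression_tier <- function(rpm, config = pipeline_config()) {
  t <- config$rpm_tiers
  out <- rep("below", length(rpm))
  out[rpm >= t[1] & rpm <= t[2]] <- "low"
  out[rpm > t[2] & rpm <= t[3]] <- "medium"
  out[rpm > t[3]] <- "high"
  out
}

#' Flanking-intron length statistics
#'
#' Cumulative length distributions, medians and two-sided Kolmogorov-Smirnov
#' tests of each expression tier against the control group. Both introns of
#' each flank pair contribute a length.
#'
#' @param pairs Flank-pair table (from [extract_flanking_introns()]) with a
#'   `tier` column; control pairs carry tier "control".
#' @return List: `stats` (data.frame tier, n, median, ks_D, p vs control)
#'   and `lengths` (named list of length vectors per tier).
#' @importFrom stats ks.test median
#' @export
intron_length_test <- function(pairs) {
  stopifnot("tier" %in% names(pairs))
  lens <- split(c(pairs$up_len, pairs$down_len), rep(pairs$tier, 2L))
  if (is.null(lens$control) || length(lens$control) < 2L) {
    stop("control group empty or too small")
  }
  tiers <- names(lens)
  stats <- do.call(rbind, lapply(tiers, function(tn) {
    x <- lens[[tn]]
    if (length(x) < 2L) stop("tier '", tn, "' has fewer than 2 lengths")
    kp <- if (tn == "control") c(NA_real_, NA_real_) else {
      kt <- suppressWarnings(ks.test(x, lens$control))
      c(unname(kt$statistic), kt$p.value)
    }
    data.frame(tier = tn, n = length(x), median = median(x), ks_D = kp[1],
               p = kp[2])
  }))
  list(stats = stats, lengths = lens)
}

#' SINE-pair complementarity statistics for flanking introns
#'
#' For each flank pair, SINE elements falling in the two different flanking
#' introns are paired across the circularized span. A pair is complementary
#' when both elements belong to the same repeat family and lie on opposite
#' genomic strands (the configuration able to base-pair across the exons).
#' Three analyses:
#' \itemize{
#' \item Bar analysis: pairs whose elements lie within `sine_window_bar` bp
#'   of the circ-facing intron ends, counted complementary vs
#'   non-complementary per tier, with a Pearson chi-squared test against the
#'   control tier (flagged when expected counts are small).
#' \item Cumulative analysis: per circ, the minimum-distance complementary
#'   pair's distance, where distance = (gap between the elements' circ-facing
#'   edges) - (donor-to-acceptor span); KS test per tier vs control.
#' \item Fraction of circs with a complementary pair within
#'   `sine_window_half` bp.
#' }
#'
#' @param pairs Flank-pair table with `tier` column (control rows allowed).
#' @param sines Repeat table: chrom, start, end, strand, family.
#' @param config A [pipeline_config()].
#' @return List: `bar`, `distances`, `ks`, `fraction_within` (see details).
#' @importFrom stats chisq.test
#' @export
sine_pair_stats <- function(pairs, sines, config = pipeline_config()) {
  per_pair <- lapply(seq_len(nrow(pairs)), function(i) {
    fp <- pairs[i, ]
    lef <- sines[sines$chrom == fp$chrom & sines$start >= fp$left_start &
                   sines$end <= fp$left_end, , drop = FALSE]
    rig <- sines[sines$chrom == fp$chrom & sines$start >= fp$right_start &
                   sines$end <= fp$right_end, , drop = FALSE]
    if (!nrow(lef) || !nrow(rig)) return(NULL)
    g <- expand.grid(l = seq_len(nrow(lef)), r = seq_len(nrow(rig)))
    span <- fp$end - fp$start + 1L
    data.frame(circ_id = fp$circ_id, tier = fp$tier,
               complementary = lef$family[g$l] == rig$family[g$r] &
                 lef$strand[g$l] != rig$strand[g$r],
               dist = (rig$start[g$r] - lef$end[g$l] - 1L) - span,
               in_window = (fp$start - lef$end[g$l]) <= config$sine_window_bar &
                 (rig$start[g$r] - fp$end) <= config$sine_window_bar)
  })
  per_pair <- do.call(rbind, per_pair)
  if (is.null(per_pair)) per_pair <- data.frame(
    circ_id = character(0), tier = character(0), complementary = logical(0),
    dist = numeric(0), in_window = logical(0))

  tiers <- unique(pairs$tier)
  # bar analysis: raw pair counts within the window
  bar <- do.call(rbind, lapply(tiers, function(tn) {
    sub <- per_pair[per_pair$tier == tn & per_pair$in_window, , drop = FALSE]
    data.frame(tier = tn, complementary = sum(sub$complementary),
               non_complementary = sum(!sub$complementary))
  }))
  bar$ratio <- ifelse(bar$non_complementary > 0,
                      bar$complementary / bar$non_complementary, NA_real_)
  ctrl <- bar[bar$tier == "control", , drop = FALSE]
  bar$chisq_p <- NA_real_; bar$small_sample <- NA
  if (nrow(ctrl) == 1L) for (i in which(bar$tier != "control")) {
    tab <- rbind(c(bar$complementary[i], bar$non_complementary[i]),
                 c(ctrl$complementary, ctrl$non_complementary))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      bar$chisq_p[i] <- ct$p.value
      bar$small_sample[i] <- any(ct$expected < 5)
    }
  }

  # cumulative analysis: per-circ minimum-distance complementary pair
  comp <- per_pair[per_pair$complementary, , drop = FALSE]
  distances <- if (nrow(comp)) {
    comp <- comp[order(comp$circ_id, comp$dist), ]
    comp[!duplicated(comp$circ_id), c("circ_id", "tier", "dist")]
  } else data.frame(circ_id = character(0), tier = character(0),
                    dist = numeric(0))
  ctrl_d <- distances$dist[distances$tier == "control"]
  ks <- do.call(rbind, lapply(setdiff(tiers, "control"), function(tn) {
    x <- distances$dist[distances$tier == tn]
    p <- if (length(x) >= 2L && length(ctrl_d) >= 2L) {
      suppressWarnings(ks.test(x, ctrl_d))$p.value
    } else NA_real_
    data.frame(tier = tn, n = length(x), median_dist =
                 if (length(x)) median(x) else NA_real_, p = p)
  }))
  frac <- vapply(tiers, function(tn) {
    ids <- unique(pairs$circ_id[pairs$tier == tn])
    if (!length(ids)) return(NA_real_)
    within <- distances$circ_id[distances$tier == tn &
                                  distances$dist <= config$sine_window_half]
    length(unique(within)) / length(ids)
  }, numeric(1))
  list(bar = bar, distances = distances, ks = ks,
       fraction_within = setNames(frac, tiers), pairs_scored = per_pair)
}

#' Sample intron lengths from the generator's length model
#'
#' Exposes the log-uniform intron-length sampler used by
#' [generate_genome()], for calibration studies.
#'
#' @param n Number of lengths.
#' @param class "short" or "long".
#' @param spec A [synthetic_genome_spec()] supplying the ranges.
#' @param round Round to whole base pairs (the genome generator always
#'   does). `FALSE` returns the underlying continuous log-uniform draws —
#'   appropriate for KS-test calibration, since the two-sample KS test
#'   assumes continuous distributions and bp rounding introduces ties that
#'   make it conservative.
#' @return Numeric vector of lengths (bp; integer-valued when rounded).
#' @export
sample_intron_lengths <- function(n, class = c("short", "long"),
                                  spec = synthetic_genome_spec(),
                                  round = TRUE) {
  class <- match.arg(class)
  r <- if (class == "long") spec$intron_length_long else spec$intron_length_short
  x <- rloguniform(n, r[1], r[2])
  if (round) as.integer(round(x)) else x
}
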