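#' Pipeline configuration
#'
#' All thresholds and constants of the circRNA pipeline in one validated
#' record. Defaults follow the analysis of embryonic brain circRNA expression
#' that this package reimplements: 20-nt terminal anchors on 100-nt reads give
#' a 160-nt effective detectable junction length (2 x (100 - 20)), the
#' expression floor is 0.05 RPM (back-splice reads per million raw reads,
#' requiring more than one read at 21M raw reads), host genes count as
#' expressed at 1 FPKM, and hot-spot genes produce three or more circRNA
#' isoforms.
#'
#' @param anchor_len Terminal anchor length in nt used for split mapping.
#' @param read_len Sequencing read length in nt.
#' @param rpm_min Minimum circRNA expression (RPM) to call a circRNA expressed.
#' @param fpkm_min Minimum host-gene expression (FPKM) to call a gene expressed.
#' @param support_min Minimum back-splice junction reads within a single sample.
#' @param fpkm_insilico FPKM floor for genes entering the in-silico control
#'   circRNA pool used as the conservation null.
#' @param fpkm_high FPKM threshold defining "highly expressed" mRNAs.
#' @param rpm_pathway RPM floor at the first time point for pathway candidate
#'   selection.
#' @param fold_pathway Minimum fold decrease between time points for pathway
#'   candidate selection.
#' @param sine_window_bar Window (bp) at the circ-facing ends of flanking
#'   introns scanned for SINE pairs in the bar-graph analysis.
#' @param sine_window_half Distance (bp) within which a complementary SINE
#'   pair counts as "proximal" for the half-of-circRNAs summary.
#' @param rpm_tiers Tier boundaries partitioning circRNA expression into
#'   low (rpm_min to t1], medium (t1 to t2] and high (> t2) groups.
#' @param heatmap_top_n Number of top-expressed circRNAs in profile matrices.
#' @param lift_end_len Length (bp) of each circRNA end lifted through the
#'   chain during conservation analysis.
#' @param hotspot_min Minimum number of circRNA isoforms for a hot-spot gene.
#' @param max_span Maximum genomic span (bp) allowed for a back-splice
#'   junction candidate.
#' @param probe_half Junction-probe context J: nt taken from each side of the
#'   back-splice junction for the linear mis-annotation check (the maximal
#'   context a 100-nt read can assert: reads map up to 80 bp away in each
#'   direction).
#' @param min_identity,min_coverage Identity/coverage fractions above which a
#'   junction probe mapping linearly to the genome flags the circRNA as
#'   mis-annotated.
#' @param max_mismatch Mismatches tolerated in the anchor-extension region of
#'   a read (never in the anchors themselves) and in full-length linear
#'   matching.
#'
#' @return An object of class `circscan_config` (a validated named list) with
#'   the additional derived constant `effective_len = 2 * (read_len -
#'   anchor_len)`, the divisor converting RPM to pseudo-RPKM.
#' @examples
#' cfg <- pipeline_config()
#' cfg$effective_len  # 160
#' @export
pipeline_config <- function(anchor_len = 20L, read_len = 100L,
                            rpm_min = 0.05, fpkm_min = 1.0,
                            support_min = 2L, fpkm_insilico = 10,
                            fpkm_high = 50, rpm_pathway = 0.15,
                            fold_pathway = 2.0, sine_window_bar = 500L,
                            sine_window_half = 1500L,
                            rpm_tiers = c(0.05, 0.5, 2.5),
                            heatmap_top_n = 200L, lift_end_len = 20L,
                            hotspot_min = 3L, max_span = 100000L,
                            probe_half = 80L, min_identity = 0.9,
                            min_coverage = 0.9, max_mismatch = 2L) {
  cfg <- list(
    anchor_len = as.integer(anchor_len), read_len = as.integer(read_len),
    effective_len = 2L * (as.integer(read_len) - as.integer(anchor_len)),
    rpm_min = rpm_min, fpkm_min = fpkm_min,
    support_min = as.integer(support_min),
    fpkm_insilico = fpkm_insilico, fpkm_high = fpkm_high,
    rpm_pathway = rpm_pathway, fold_pathway = fold_pathway,
    sine_window_bar = as.integer(sine_window_bar),
    sine_window_half = as.integer(sine_window_half),
    rpm_tiers = rpm_tiers, heatmap_top_n = as.integer(heatmap_top_n),
    lift_end_len = as.integer(lift_end_len),
    hotspot_min = as.integer(hotspot_min), max_span = as.integer(max_span),
    probe_half = as.integer(probe_half), min_identity = min_identity,
    min_coverage = min_coverage, max_mismatch = as.integer(max_mismatch))
  validate_config(cfg)
  class(cfg) <- "circscan_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$anchor_len >= 8L, cfg$read_len > 2L * cfg$anchor_len,
    cfg$effective_len == 2L * (cfg$read_len - cfg$anchor_len),
    length(cfg$rpm_tiers) == 3L, all(diff(cfg$rpm_tiers) > 0),
    cfg$rpm_min > 0, cfg$fpkm_min > 0, cfg$support_min > 0,
    cfg$rpm_pathway > 0, cfg$fold_pathway > 0,
    cfg$sine_window_bar > 0, cfg$sine_window_half > 0,
    cfg$heatmap_top_n > 0, cfg$lift_end_len > 0, cfg$hotspot_min > 0,
    cfg$max_span > 0, cfg$probe_half >= cfg$anchor_len,
    cfg$min_identity > 0, cfg$min_identity <= 1,
    cfg$min_coverage > 0, cfg$min_coverage <= 1, cfg$max_mismatch >= 0)
  invisible(cfg)
}

#' @export
print.circscan_config <- function(x, ...) {
  cat("circscan pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
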