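#' Build a heatmap-ready expression profile matrix
#'
#' Selects the top N circRNAs by maximum RPM across samples, log2-transforms,
#' substitutes absent (zero) values with the lowest observed log2 value in
#' the selected matrix ("lowest score" policy), then centers each row on its
#' mean.
#'
#' @param rpm Numeric matrix (rows = circ ids, columns = samples) of RPM
#'   values, or a long data.frame with circ_id, sample, rpm.
#' @param N Number of rows to keep (fewer when fewer circs are available).
#' @param config A [pipeline_config()] (`heatmap_top_n` default for N).
#' @return A `circscan_profile` list: `matrix` (centered log2), `log2_floor`
#'   (the substituted value), `selected` (row ids in rank order).
#' @export
build_profile_matrix <- function(rpm, N = NULL, config = pipeline_config()) {
  if (is.data.frame(rpm)) {
    m <- tapply(rpm$rpm, list(rpm$circ_id, rpm$sample), sum, default = 0)
    rpm <- as.matrix(m)
  }
  if (is.null(N)) N <- config$heatmap_top_n
  if (!nrow(rpm) || all(rpm == 0)) stop("all-zero expression matrix")
  mx <- apply(rpm, 1, max)
  keep <- order(-mx)[seq_len(min(N, sum(mx > 0)))]
  m <- rpm[keep, , drop = FALSE]
  lg <- log2(m)
  floor_val <- min(lg[is.finite(lg)])
  lg[!is.finite(lg)] <- floor_val
  centered <- lg - rowMeans(lg)
  out <- list(matrix = centered, log2_floor = floor_val,
              selected = rownames(rpm)[keep])
  class(out) <- "circscan_profile"
  out
}

#' Hierarchical clustering of expression profiles
#'
#' Pearson-correlation average-linkage clustering: distance = 1 - r. Rows are
#' pre-sorted lexicographically by id so the merge sequence is invariant
#' under input row permutation. Zero-variance rows have undefined
#' correlations; they are assigned the maximum distance (2) and flagged.
#'
#' @param mat Numeric matrix (rows clustered) or a `circscan_profile`.
#' @param cluster_cols Also cluster columns (needs >= 3 rows).
#' @return List: `row_hclust`, `col_hclust` (or NULL), `row_order`,
#'   `flagged` (zero-variance row ids).
#' @importFrom stats hclust as.dist cor sd cutree
#' @export
cluster_profiles <- function(mat, cluster_cols = FALSE) {
  if (inherits(mat, "circscan_profile")) mat <- mat$matrix
  stopifnot(nrow(mat) >= 2L)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- cor_distance(t(mat))
  flagged <- rownames(mat)[apply(mat, 1, sd) == 0]
  hr <- hclust(as.dist(d), method = "average")
  hc <- NULL
  if (cluster_cols && nrow(mat) >= 3L && ncol(mat) >= 2L) {
    hc <- hclust(as.dist(cor_distance(mat)), method = "average")
  }
  list(row_hclust = hr, col_hclust = hc, row_order = rownames(mat)[hr$order],
       flagged = flagged)
}

# 1 - Pearson correlation of the columns of x; undefined correlations get
# the maximum distance 2.
cor_distance <- function(x) {
  r <- suppressWarnings(cor(x))
  d <- 1 - r
  d[is.na(d)] <- 2
  diag(d) <- 0
  d
}

#' Pearson correlation between circRNA and host profiles
#'
#' Computed on the same transformed (log2, row-centered) values used for the
#' heatmaps, pooling all paired circ/host profile values into one
#' coefficient.
#'
#' @param circ_mat,host_mat Matrices with matching dimensions; row i of
#'   `host_mat` is the host profile paired with circ row i (same samples).
#' @return Pearson r.
#' @export
circ_host_correlation <- function(circ_mat, host_mat) {
  if (inherits(circ_mat, "circscan_profile")) circ_mat <- circ_mat$matrix
  if (inherits(host_mat, "circscan_profile")) host_mat <- host_mat$matrix
  stopifnot(all(dim(circ_mat) == dim(host_mat)))
  if (ncol(circ_mat) < 3L) stop("need at least 3 common samples")
  cor(as.vector(circ_mat), as.vector(host_mat))
}

#' Hot-spot gene report
#'
#' Groups circRNAs by host gene and reports genes producing `hotspot_min` or
#' more distinct circRNA isoforms, classifying whether all isoforms share
#' the splice donor, the splice acceptor, or neither. Also emits the
#' splice-site table (site coordinate, side, number of isoforms using it)
#' that feeds the hot-spot vs single-isoform flanking-intron comparison.
#'
#' @param circs data.frame with circ_id, chrom, start, end, strand and
#'   host_gene (from [match_hosts()]).
#' @param expr Optional expression table; per-sample RPM is attached to the
#'   isoform list when given.
#' @param config A [pipeline_config()].
#' @return List: `reports` (gene_id, n_isoforms, shared_site), `isoforms`
#'   (per-gene isoform rows for reported genes), `splice_sites` (all hosted
#'   genes' donor/acceptor usage counts).
#' @export
hotspot_report <- function(circs, expr = NULL, config = pipeline_config()) {
  circs <- circs[!is.na(circs$host_gene) & !duplicated(circs$circ_id), ,
                 drop = FALSE]
  sp <- split(circs, circs$host_gene)
  reports <- list(); isoforms <- list(); sites <- list()
  for (g in names(sp)) {
    cs <- sp[[g]]
    # transcript-orientation roles: on "+" the acceptor is the start
    # coordinate and the donor the end; reversed on "-"
    donor <- if (cs$strand[1] == "+") cs$end else cs$start
    acceptor <- if (cs$strand[1] == "+") cs$start else cs$end
    for (side in c("donor", "acceptor")) {
      co <- if (side == "donor") donor else acceptor
      tb <- table(co)
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = g, side = side, coord = as.integer(names(tb)),
        n_isoforms = as.integer(tb))
    }
    if (nrow(cs) < config$hotspot_min) next
    shared <- if (length(unique(donor)) == 1L) "donor"
      else if (length(unique(acceptor)) == 1L) "acceptor" else "none"
    reports[[length(reports) + 1L]] <- data.frame(
      gene_id = g, n_isoforms = nrow(cs), shared_site = shared)
    iso <- cs
    if (!is.null(expr)) {
      rpm <- tapply(expr$rpm, list(expr$circ_id, expr$sample), sum)
      iso <- cbind(iso, rpm[iso$circ_id, , drop = FALSE])
    }
    isoforms[[length(isoforms) + 1L]] <- iso
  }
  list(reports = if (length(reports)) do.call(rbind, reports) else
         data.frame(gene_id = character(0), n_isoforms = integer(0),
                    shared_site = character(0)),
       isoforms = if (length(isoforms)) do.call(rbind, isoforms) else NULL,
       splice_sites = if (length(sites)) do.call(rbind, sites) else
         data.frame(gene_id = character(0), side = character(0),
                    coord = integer(0), n_isoforms = integer(0)))
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two clusterings agree (co-clustered in
#' both or separated in both).
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
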