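#' RPM normalization
#'
#' Back-splice junction spanning reads per million raw reads.
#'
#' @param support Junction read count(s).
#' @param raw_reads Total raw reads of the sample (> 0).
#' @return `support * 1e6 / raw_reads`.
#' @examples
#' rpm_normalize(2, 21e6)   # 0.0952..., passes the 0.05 RPM cutoff
#' rpm_normalize(1, 21e6)   # 0.0476..., fails it
#' @export
rpm_normalize <- function(support, raw_reads) {
  if (any(raw_reads <= 0)) stop("raw_reads must be positive")
  support * 1e6 / raw_reads
}

#' Pseudo-RPKM from RPM
#'
#' Rescales circRNA RPM by the effective detectable junction length so it is
#' comparable to host-gene FPKM: with 100-nt reads and 20-nt anchors a
#' back-splice can be detected by reads mapping up to 80 bp away in each
#' direction, so RPM is divided by 160 and multiplied by 1000 (per kilobase),
#' i.e. multiplied by 6.25.
#'
#' @param rpm RPM value(s).
#' @param config A [pipeline_config()] (supplies `effective_len`).
#' @return `rpm * 1000 / effective_len`.
#' @export
pseudo_rpkm <- function(rpm, config = pipeline_config()) {
  stopifnot(all(rpm >= 0))
  rpm * (1000 / config$effective_len)
}

#' Exon-union length per gene
#'
#' @param exons Exon table (see [read_gene_models()]).
#' @return Named numeric vector of per-gene exon-union lengths (bp).
#' @export
exon_union_length <- function(exons) {
  sp <- split(exons, exons$gene_id)
  vapply(sp, function(ex) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ex$start, ex$end))))
  }, numeric(1))
}

#' Assign reads to genes by anchor mapping
#'
#' Simple exon-union read counter for synthetic data: each read is placed at
#' the unique exact genomic hit of one of its terminal anchors (first anchor,
#' falling back to the last) and assigned to the gene whose exon union
#' overlaps the implied read interval the most. Unmapped or ambiguous reads
#' are unassigned.
#'
#' @param reads Named character vector of read sequences.
#' @param index A `circscan_index`.
#' @param exons Exon table.
#' @return Named integer vector of read counts per gene (all genes present).
#' @importFrom GenomicRanges GRanges reduce findOverlaps pintersect seqnames
#'   start end strand
#' @importFrom S4Vectors queryHits subjectHits
#' @export
count_gene_reads <- function(reads, index, exons) {
  genes <- unique(exons$gene_id)
  counts <- setNames(rep(0L, length(genes)), genes)
  if (!length(reads)) return(counts)
  k <- index$k
  L <- nchar(reads)
  n <- length(reads)
  hits <- index_query(index, c(substring(reads, 1L, k),
                               substring(reads, L - k + 1L, L)))
  hits$read <- ((hits$query - 1L) %% n) + 1L
  hits$anchor <- ifelse(hits$query > n, 2L, 1L)
  # keep reads whose chosen anchor has a unique hit; prefer the first anchor
  tab1 <- hits[hits$anchor == 1L, ]
  u1 <- names(which(table(tab1$read) == 1L))
  tab2 <- hits[hits$anchor == 2L & !(hits$read %in% as.integer(u1)), ]
  u2 <- names(which(table(tab2$read) == 1L))
  picked <- rbind(tab1[tab1$read %in% as.integer(u1), ],
                  tab2[tab2$read %in% as.integer(u2), ])
  if (!nrow(picked)) return(counts)
  # implied read interval on the forward strand
  Lr <- L[picked$read]
  s <- ifelse(picked$anchor == 1L,
              ifelse(picked$strand == "+", picked$pos, picked$pos - (Lr - k)),
              ifelse(picked$strand == "+", picked$pos - (Lr - k), picked$pos))
  gr <- GenomicRanges::GRanges(picked$chrom,
                               IRanges::IRanges(pmax(s, 1L), s + Lr - 1L))
  ug <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end),
    gene_id = exons$gene_id))
  exg <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start, exons$end))
  ov <- GenomicRanges::findOverlaps(gr, exg)
  if (!length(ov)) return(counts)
  w <- IRanges::width(GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                                exg[S4Vectors::subjectHits(ov)]))
  df <- data.frame(read = S4Vectors::queryHits(ov),
                   gene = exons$gene_id[S4Vectors::subjectHits(ov)], w = w)
  df <- df[order(df$read, -df$w), ]
  df <- df[!duplicated(df$read), ]
  tab <- table(df$gene)
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  counts
}

#' FPKM from assigned read counts
#'
#' `FPKM = assigned_reads * 1e9 / (total_reads * exon_union_length)`.
#'
#' @param counts Named vector of assigned reads per gene.
#' @param union_len Named vector of exon-union lengths (bp) per gene.
#' @param total_reads Total (raw) reads of the sample.
#' @return Named numeric vector of FPKM values.
#' @export
compute_fpkm <- function(counts, union_len, total_reads) {
  stopifnot(total_reads > 0)
  ul <- union_len[names(counts)]
  counts * 1e9 / (total_reads * ul)
}

#' Match circRNAs to host genes by genomic location
#'
#' The host is the gene whose interval overlaps the circRNA span with the
#' largest overlap, on the same strand. CircRNAs overlapping no gene get no
#' host (their circ/host ratio stays undefined); antisense overlaps are
#' recorded but never assigned.
#'
#' @param circs data.frame with circ_id, chrom, start, end, strand.
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @return List: `assignment` (data.frame circ_id, host_gene (NA if none),
#'   overlap_bp, n_overlapping) and `overlaps` (all same-strand overlaps).
#' @export
match_hosts <- function(circs, genes) {
  assignment <- data.frame(circ_id = circs$circ_id, host_gene = NA_character_,
                           overlap_bp = 0L, n_overlapping = 0L)
  empty <- data.frame(circ_id = character(0), gene_id = character(0),
                      overlap_bp = integer(0))
  if (!nrow(circs) || !nrow(genes)) {
    return(list(assignment = assignment, overlaps = empty))
  }
  cg <- GenomicRanges::GRanges(circs$chrom,
                               IRanges::IRanges(circs$start, circs$end),
                               strand = circs$strand)
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(cg, gg)  # strand-matched by default
  if (!length(ov)) return(list(assignment = assignment, overlaps = empty))
  w <- IRanges::width(GenomicRanges::pintersect(cg[S4Vectors::queryHits(ov)],
                                                gg[S4Vectors::subjectHits(ov)]))
  overlaps <- data.frame(circ_id = circs$circ_id[S4Vectors::queryHits(ov)],
                         gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
                         overlap_bp = w)
  best <- overlaps[order(match(overlaps$circ_id, circs$circ_id), -overlaps$overlap_bp), ]
  nov <- table(best$circ_id)
  best <- best[!duplicated(best$circ_id), ]
  i <- match(best$circ_id, assignment$circ_id)
  assignment$host_gene[i] <- best$gene_id
  assignment$overlap_bp[i] <- best$overlap_bp
  assignment$n_overlapping[i] <- as.integer(nov[best$circ_id])
  list(assignment = assignment, overlaps = overlaps)
}

#' Build the per-sample circRNA expression table
#'
#' One row per circRNA x sample: support, RPM, pseudo-RPKM, host gene, host
#' FPKM and the circ/host ratio (undefined — NA, never 0 or Inf — when the
#' host is absent or unexpressed).
#'
#' @param circs Long-format called circRNAs ([call_circRNAs()] output:
#'   circ_id, chrom, start, end, strand, sample, support).
#' @param raw_reads Named vector: total raw reads per sample.
#' @param hosts Host assignment ([match_hosts()] `$assignment`).
#' @param gene_fpkm data.frame gene_id, sample, fpkm.
#' @param config A [pipeline_config()].
#' @return data.frame of expression records; absent circ x sample
#'   combinations are filled with support 0.
#' @export
expression_table <- function(circs, raw_reads, hosts = NULL,
                             gene_fpkm = NULL, config = pipeline_config()) {
  samples <- names(raw_reads)
  ids <- unique(circs$circ_id)
  grid <- expand.grid(circ_id = ids, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(paste(grid$circ_id, grid$sample),
             paste(circs$circ_id, circs$sample))
  grid$support <- ifelse(is.na(i), 0L, circs$support[i])
  grid$raw_reads <- raw_reads[grid$sample]
  grid$rpm <- rpm_normalize(grid$support, grid$raw_reads)
  grid$pseudo_rpkm <- pseudo_rpkm(grid$rpm, config)
  grid$host_gene <- if (!is.null(hosts)) {
    hosts$host_gene[match(grid$circ_id, hosts$circ_id)]
  } else rep(NA_character_, nrow(grid))
  grid$host_fpkm <- if (!is.null(gene_fpkm)) {
    gene_fpkm$fpkm[match(paste(grid$host_gene, grid$sample),
                         paste(gene_fpkm$gene_id, gene_fpkm$sample))]
  } else rep(NA_real_, nrow(grid))
  grid$ratio <- ifelse(!is.na(grid$host_gene) & !is.na(grid$host_fpkm) &
                         grid$host_fpkm > 0,
                       grid$pseudo_rpkm / grid$host_fpkm, NA_real_)
  grid
}

#' Summary table of circRNA expression
#'
#' Per-sample (plus an "All" column using at-least-one-sample logic):
#' circRNAs expressed at or above the RPM floor; genes expressed at or above
#' the FPKM floor; number and percentage of expressed genes producing a
#' circRNA; circRNAs expressed above their host (pseudo-RPKM strictly greater
#' than host FPKM); number and percentage of genes producing `hotspot_min`
#' or more circRNAs.
#'
#' @param expr Expression table from [expression_table()].
#' @param gene_fpkm data.frame gene_id, sample, fpkm.
#' @param config A [pipeline_config()].
#' @return data.frame with one row per statistic, one column per sample plus
#'   "All".
#' @export
summarize_circ_expression <- function(expr, gene_fpkm,
                                      config = pipeline_config()) {
  samples <- union(unique(expr$sample), unique(gene_fpkm$sample))
  one <- function(sub, genes_expr) {
    on_circ <- sub[sub$rpm >= config$rpm_min, , drop = FALSE]
    hosting <- unique(na.omit(on_circ$host_gene))
    hosting_expr <- intersect(hosting, genes_expr)
    iso <- table(na.omit(on_circ$host_gene[!duplicated(on_circ$circ_id)]))
    hot <- names(iso)[iso >= config$hotspot_min]
    c(n_circ = length(unique(on_circ$circ_id)),
      n_genes_expressed = length(genes_expr),
      n_genes_circ = length(hosting_expr),
      pct_genes_circ = if (length(genes_expr))
        100 * length(hosting_expr) / length(genes_expr) else 0,
      n_above_host = length(unique(on_circ$circ_id[
        !is.na(on_circ$host_fpkm) & on_circ$pseudo_rpkm > on_circ$host_fpkm])),
      n_hotspot = length(hot),
      pct_hotspot = if (length(genes_expr))
        100 * length(hot) / length(genes_expr) else 0)
  }
  cols <- lapply(samples, function(sm) {
    genes_expr <- unique(gene_fpkm$gene_id[gene_fpkm$sample == sm &
                                             gene_fpkm$fpkm >= config$fpkm_min])
    one(expr[expr$sample == sm, , drop = FALSE], genes_expr)
  })
  names(cols) <- samples
  # "All": union over samples of per-sample calls
  genes_all <- unique(gene_fpkm$gene_id[gene_fpkm$fpkm >= config$fpkm_min])
  expr_on <- expr[expr$rpm >= config$rpm_min, , drop = FALSE]
  hosting_all <- intersect(unique(na.omit(expr_on$host_gene)), genes_all)
  iso_all <- table(na.omit(expr_on$host_gene[!duplicated(expr_on$circ_id)]))
  hot_all <- names(iso_all)[iso_all >= config$hotspot_min]
  cols$All <- c(
    n_circ = length(unique(expr_on$circ_id)),
    n_genes_expressed = length(genes_all),
    n_genes_circ = length(hosting_all),
    pct_genes_circ = if (length(genes_all))
      100 * length(hosting_all) / length(genes_all) else 0,
    n_above_host = length(unique(expr_on$circ_id[
      !is.na(expr_on$host_fpkm) & expr_on$pseudo_rpkm > expr_on$host_fpkm])),
    n_hotspot = length(hot_all),
    pct_hotspot = if (length(genes_all))
      100 * length(hot_all) / length(genes_all) else 0)
  out <- as.data.frame(cols, check.names = FALSE)
  out <- cbind(statistic = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Select pathway-analysis candidate hosts
#'
#' CircRNAs expressed above `rpm_pathway` RPM at the first time point that
#' decrease `fold_pathway`-fold or more at the second (a zero at the second
#' time point counts as an infinite fold decrease, flagged). Exports the
#' unique host genes plus a background list of expressed genes for external
#' enrichment tools.
#'
#' @param expr Expression table covering both samples.
#' @param t1,t2 Sample names of the two time points.
#' @param gene_fpkm data.frame gene_id, sample, fpkm (background source).
#' @param config A [pipeline_config()].
#' @return List: `circs` (selected, with rpm_t1/rpm_t2/fold/infinite),
#'   `genes` (unique hosts), `background` (genes at or above `fpkm_min` in
#'   at least one sample).
#' @export
select_pathway_candidates <- function(expr, t1, t2, gene_fpkm = NULL,
                                      config = pipeline_config()) {
  e1 <- expr[expr$sample == t1, , drop = FALSE]
  e2 <- expr[expr$sample == t2, , drop = FALSE]
  stopifnot(nrow(e1) > 0, nrow(e2) > 0)
  m <- match(e1$circ_id, e2$circ_id)
  df <- data.frame(circ_id = e1$circ_id, host_gene = e1$host_gene,
                   rpm_t1 = e1$rpm, rpm_t2 = e2$rpm[m])
  df$infinite <- df$rpm_t2 == 0
  df$fold <- ifelse(df$infinite, Inf, df$rpm_t1 / df$rpm_t2)
  sel <- df[df$rpm_t1 > config$rpm_pathway & df$fold >= config$fold_pathway, ,
            drop = FALSE]
  background <- if (!is.null(gene_fpkm)) {
    unique(gene_fpkm$gene_id[gene_fpkm$fpkm >= config$fpkm_min])
  } else character(0)
  list(circs = sel, genes = unique(na.omit(sel$host_gene)),
       background = background)
}
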