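#' Generate an ortholog genome with a liftOver chain
#'
#' Produces an indel-mutated copy of a synthetic genome together with a valid
#' UCSC chain file mapping source to target coordinates (and the exact
#' inverse chain). Indels are confined to intergenic sequence, so every gene
#' lifts intact; exactly `ceiling(conserved_fraction * n_circs)` planted
#' (non-decoy) circRNA splice-site pairs are recorded as identical junctions
#' in the ortholog circRNA annotation.
#'
#' @param sim A `circscan_sim` from [generate_genome()].
#' @param conserved_fraction Fraction of planted circRNAs conserved in the
#'   ortholog annotation, in [0, 1].
#' @param seed Integer seed.
#' @param n_indels_per_chrom Indel events per chromosome (0 gives an identity
#'   chain with a single block per chromosome).
#' @param max_indel Maximum indel length (bp); lengths are uniform on
#'   [20, max_indel].
#' @param outdir Optional directory; when given, the ortholog FASTA/GTF, the
#'   two chain files and the conservation truth TSV are written there.
#' @return A list of class `circscan_ortholog`: `genome`, `exons`,
#'   `ortholog_circs` (the ortholog circ annotation, target coordinates),
#'   `conserved` (truth: circ_id, conserved flag, lifted coordinates),
#'   `chain` and `inverse_chain` (character vectors of chain-file lines).
#' @export
generate_ortholog_genome <- function(sim, conserved_fraction, seed = 1L,
                                     n_indels_per_chrom = 4L, max_indel = 300L,
                                     outdir = NULL) {
  stopifnot(inherits(sim, "circscan_sim"),
            conserved_fraction >= 0, conserved_fraction <= 1)
  orth <- with_seed(seed, build_ortholog_impl(sim, conserved_fraction,
                                              n_indels_per_chrom, max_indel))
  if (!is.null(outdir)) write_ortholog_files(orth, outdir)
  orth
}

build_ortholog_impl <- function(sim, conserved_fraction, n_indels, max_indel) {
  chroms <- names(sim$genome$seq)
  blocks <- list()   # per chrom: data.frame(src_start, src_end, tgt_start)
  tseqs <- setNames(character(length(chroms)), chroms)

  for (cn in chroms) {
    src <- sim$genome$seq[[cn]]
    slen <- nchar(src)
    gaps <- sim$intergenic[sim$intergenic$chrom == cn, , drop = FALSE]
    gaps <- gaps[gaps$end - gaps$start + 1L >= max_indel + 40L, , drop = FALSE]
    ev <- NULL
    if (n_indels > 0L && nrow(gaps)) {
      pick <- gaps[sample.int(nrow(gaps), min(n_indels, nrow(gaps))), ,
                   drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        len <- sample1(20:max_indel)
        pos <- sample1((pick$start[i] + 10L):(pick$end[i] - len - 10L))
        ev <- rbind(ev, data.frame(pos = pos, len = len,
                                   type = sample(c("del", "ins"), 1L)))
      }
      ev <- ev[order(ev$pos), , drop = FALSE]
    }
    b <- NULL; pieces <- character(0)
    s <- 1L; t <- 0L
    if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
      # aligned block up to the event
      bend <- if (ev$type[i] == "del") ev$pos[i] - 1L else ev$pos[i]
      seg <- substring(src, s, bend)
      pieces <- c(pieces, seg)
      b <- rbind(b, data.frame(src_start = s, src_end = bend, tgt_start = t + 1L))
      t <- t + (bend - s + 1L)
      if (ev$type[i] == "del") {
        s <- bend + ev$len[i] + 1L
      } else {
        pieces <- c(pieces, random_dna(ev$len[i], sim$spec$gc_content))
        t <- t + ev$len[i]
        s <- bend + 1L
      }
    }
    pieces <- c(pieces, substring(src, s, slen))
    b <- rbind(b, data.frame(src_start = s, src_end = slen, tgt_start = t + 1L))
    blocks[[cn]] <- b
    tseqs[cn] <- paste(pieces, collapse = "")
  }

  lift_pos <- function(chrom, pos) {
    b <- blocks[[chrom]]
    i <- which(b$src_start <= pos & pos <= b$src_end)
    if (!length(i)) return(NA_integer_)
    b$tgt_start[i[1]] + (pos - b$src_start[i[1]])
  }

  ex <- sim$exons
  if (nrow(ex)) {
    ex$start <- mapply(lift_pos, ex$chrom, ex$start)
    ex$end <- mapply(lift_pos, ex$chrom, ex$end)
    stopifnot(!anyNA(ex$start), !anyNA(ex$end))
  }

  real <- sim$circs[!sim$circs$is_decoy, , drop = FALSE]
  n_cons <- ceiling(conserved_fraction * nrow(real))
  cons_idx <- if (n_cons > 0L) sample.int(nrow(real), n_cons) else integer(0)
  conserved <- data.frame(circ_id = real$circ_id,
                          conserved = seq_len(nrow(real)) %in% cons_idx)
  if (nrow(real)) {
    conserved$target_chrom <- real$chrom
    conserved$target_start <- mapply(lift_pos, real$chrom, real$start)
    conserved$target_end <- mapply(lift_pos, real$chrom, real$end)
    conserved$strand <- real$strand
  }
  oc <- conserved[conserved$conserved, , drop = FALSE]
  ortholog_circs <- data.frame(
    circ_id = if (nrow(oc)) sprintf("%s:%d-%d:%s", oc$target_chrom,
                                    oc$target_start, oc$target_end, oc$strand)
              else character(0),
    chrom = oc$target_chrom, start = oc$target_start, end = oc$target_end,
    strand = oc$strand, source_circ = oc$circ_id)
  rownames(ortholog_circs) <- NULL

  src_len <- genome_lengths(sim$genome)
  tgt_len <- nchar(tseqs)
  orth <- list(genome = as_genome(tseqs), exons = ex,
               ortholog_circs = ortholog_circs, conserved = conserved,
               blocks = blocks,
               chain = format_chain(blocks, src_len, tgt_len, inverse = FALSE),
               inverse_chain = format_chain(blocks, src_len, tgt_len,
                                            inverse = TRUE))
  class(orth) <- "circscan_ortholog"
  orth
}

# Serialize per-chromosome block lists as UCSC chain lines. The chain maps
# its t-side (source assembly by default; target when inverse) to its q-side.
format_chain <- function(blocks, src_len, tgt_len, inverse = FALSE) {
  lines <- character(0)
  id <- 0L
  for (cn in names(blocks)) {
    b <- blocks[[cn]]
    id <- id + 1L
    sizes <- b$src_end - b$src_start + 1L
    n <- nrow(b)
    dt <- if (n > 1L) b$src_start[-1L] - b$src_end[-n] - 1L else integer(0)
    dq <- if (n > 1L) b$tgt_start[-1L] - (b$tgt_start[-n] + sizes[-n]) else integer(0)
    if (inverse) { tmp <- dt; dt <- dq; dq <- tmp }
    tl <- if (inverse) tgt_len[[cn]] else src_len[[cn]]
    ql <- if (inverse) src_len[[cn]] else tgt_len[[cn]]
    t0 <- if (inverse) b$tgt_start[1L] - 1L else b$src_start[1L] - 1L
    t1 <- if (inverse) b$tgt_start[n] + sizes[n] - 1L else b$src_end[n]
    q0 <- if (inverse) b$src_start[1L] - 1L else b$tgt_start[1L] - 1L
    q1 <- if (inverse) b$src_end[n] else b$tgt_start[n] + sizes[n] - 1L
    header <- sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
                      cn, tl, t0, t1, cn, ql, q0, q1, id)
    body <- if (n > 1L) c(paste(sizes[-n], dt, dq), as.character(sizes[n]))
            else as.character(sizes)
    lines <- c(lines, header, body, "")
  }
  lines
}

#' Write ortholog genome files
#'
#' @param orth A `circscan_ortholog`.
#' @param outdir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
write_ortholog_files <- function(orth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(outdir, "ortholog.fa"),
             gtf = file.path(outdir, "ortholog.gtf"),
             chain = file.path(outdir, "source_to_ortholog.chain"),
             inverse_chain = file.path(outdir, "ortholog_to_source.chain"),
             circs = file.path(outdir, "ortholog_circs.tsv"),
             conserved = file.path(outdir, "conservation_truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(orth$genome$seq),
                              paths["fasta"])
  export_gene_models_gtf(orth$exons, paths["gtf"])
  writeLines(orth$chain, paths["chain"])
  writeLines(orth$inverse_chain, paths["inverse_chain"])
  write.table(orth$ortholog_circs, paths["circs"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(orth$conserved, paths["conserved"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' @export
print.circscan_ortholog <- function(x, ...) {
  cat(sprintf("circscan ortholog genome: %d chromosome(s), %d/%d circRNAs conserved\n",
              length(x$genome$seq), sum(x$conserved$conserved),
              nrow(x$conserved)))
  invisible(x)
}
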