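#' Synthetic genome specification
#'
#' Parameters controlling the synthetic genome/gene-model/repeat generator.
#' The generator lays out multi-exon genes (non-overlapping, both strands)
#' with canonical GT..AG introns, plants exonic circRNAs on internal
#' contiguous exon runs, inserts SINE elements into introns (with
#' complementary pairs planted preferentially in circ-flanking introns), and
#' optionally plants decoy junctions whose back-splice probe sequence also
#' occurs contiguously (linearly) elsewhere in the genome.
#'
#' Defaults encode the study conditions this package emulates: flanking
#' introns of circularized exons drawn from a long-intron class (circRNAs are
#' preferentially flanked by large introns), and a complementary-SINE
#' planting bias of 0.5 (roughly half of circRNAs carry a proximal
#' complementary SINE pair).
#'
#' @param n_chromosomes,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes laid out across chromosomes.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length Integer range (bp) of exon lengths.
#' @param intron_length_short,intron_length_long Ranges (bp) of the two
#'   intron-length classes; lengths are drawn log-uniformly within the range.
#' @param flank_intron_class `"long"` draws the two introns flanking each
#'   planted circRNA from the long class (all other introns short);
#'   `"same"` draws every intron from the short class (homogeneous genome,
#'   used for null calibration).
#' @param sine_consensus Consensus sequence of the synthetic SINE family
#'   (~160 bp by default).
#' @param sine_density Background SINE insertions per 10 kb of intron.
#' @param sine_families Family labels assigned to background elements.
#' @param complementary_flank_bias Probability that a planted circRNA's two
#'   flanking introns receive a complementary SINE pair (same family,
#'   opposite genomic strands) within `sine_window` bp of the circ-facing
#'   intron ends.
#' @param sine_window Window (bp) used when planting complementary pairs.
#' @param gc_content Genome GC fraction.
#' @param n_circs Number of genuine circRNAs planted (at most one per gene,
#'   on internal exon runs so both flanking introns exist).
#' @param n_decoys Number of decoy junctions planted: internal exon runs of
#'   otherwise circ-free genes whose 160-bp junction probe is copied exactly
#'   into intergenic sequence (a linear-mimic locus).
#' @param circ_exon_max Maximum exons per planted circRNA.
#' @param circ_rpm Range of planted abundances (RPM), drawn log-uniformly.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return An object of class `circscan_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 5L, chrom_length = 100000L,
                                  n_genes = 60L, exons_per_gene = c(4L, 7L),
                                  exon_length = c(120L, 250L),
                                  intron_length_short = c(200L, 800L),
                                  intron_length_long = c(1500L, 6000L),
                                  flank_intron_class = c("long", "same"),
                                  sine_consensus = NULL,
                                  sine_density = 5, sine_families = c("SINEA", "SINEB"),
                                  complementary_flank_bias = 0.5,
                                  sine_window = 500L,
                                  gc_content = 0.42, n_circs = 25L,
                                  n_decoys = 0L, circ_exon_max = 3L,
                                  circ_rpm = c(0.5, 20), seed = 1L) {
  flank_intron_class <- match.arg(flank_intron_class)
  if (is.null(sine_consensus)) sine_consensus <- circscan_sine_consensus
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chrom_length = as.integer(chrom_length),
               n_genes = as.integer(n_genes),
               exons_per_gene = as.integer(exons_per_gene),
               exon_length = as.integer(exon_length),
               intron_length_short = as.integer(intron_length_short),
               intron_length_long = as.integer(intron_length_long),
               flank_intron_class = flank_intron_class,
               sine_consensus = sine_consensus,
               sine_density = sine_density,
               sine_families = sine_families,
               complementary_flank_bias = complementary_flank_bias,
               sine_window = as.integer(sine_window),
               gc_content = gc_content, n_circs = as.integer(n_circs),
               n_decoys = as.integer(n_decoys),
               circ_exon_max = as.integer(circ_exon_max),
               circ_rpm = circ_rpm, seed = as.integer(seed))
  stopifnot(spec$n_chromosomes >= 1L, spec$chrom_length >= 1000L,
            spec$n_genes >= 0L, spec$exons_per_gene[1] >= 1L,
            spec$exon_length[1] >= 100L,
            spec$complementary_flank_bias >= 0,
            spec$complementary_flank_bias <= 1,
            spec$gc_content > 0, spec$gc_content < 1,
            spec$n_circs >= 0L, spec$n_decoys >= 0L,
            spec$circ_exon_max >= 1L,
            spec$circ_rpm[1] > 0, spec$circ_rpm[2] >= spec$circ_rpm[1])
  if (spec$n_circs > 0L || spec$n_decoys > 0L) {
    stopifnot(spec$exons_per_gene[1] >= 3L)
  }
  class(spec) <- "circscan_genome_spec"
  spec
}

# Fixed synthetic SINE consensus (160 bp). Arbitrary but constant so that
# identical specs give identical genomes.
circscan_sine_consensus <- paste0(
  "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGA",
  "GGCGGGCGGATCACGAGGTCAGGAGATCGAGACCATCCTGGCTAACACGG",
  "TGAAACCCCGTCTCTACTAAAAATACAAAAAATTAGCCGGGCGTGGTGGC")

# Run expr with a private, restored RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# ---- gene structure -------------------------------------------------------

# Draw the exon/intron skeleton of one gene (lengths in transcript order).
draw_gene_structure <- function(spec, has_circ, circ_exon_max) {
  n_ex <- sample1(spec$exons_per_gene[1]:spec$exons_per_gene[2])
  ex_len <- sample(spec$exon_length[1]:spec$exon_length[2], n_ex, replace = TRUE)
  n_int <- n_ex - 1L
  cls <- rep("short", n_int)
  circ <- NULL
  if (has_circ) {
    # internal contiguous run: start exon a in 2..(n_ex-1)
    max_run <- min(circ_exon_max, n_ex - 2L)
    run <- sample1(seq_len(max_run))
    a <- sample1(2:(n_ex - run))
    b <- a + run - 1L
    circ <- c(a = a, b = b)
    if (spec$flank_intron_class == "long") cls[c(a - 1L, b)] <- "long"
  }
  int_len <- integer(n_int)
  for (i in seq_len(n_int)) {
    r <- if (cls[i] == "long") spec$intron_length_long else spec$intron_length_short
    int_len[i] <- as.integer(round(rloguniform(1, r[1], r[2])))
  }
  list(n_ex = n_ex, ex_len = ex_len, int_len = int_len, int_class = cls,
       circ = circ)
}

# Place non-overlapping SINE intervals inside one intron (transcript
# orientation offsets). Returns data.frame(off, len, orient, family, planted).
place_intron_sines <- function(spec, intron_len, planted = NULL) {
  clen <- nchar(spec$sine_consensus)
  out <- planted
  n_bg <- rpois(1, intron_len * spec$sine_density / 1e4)
  if (n_bg > 0 && intron_len >= clen + 10L) {
    for (i in seq_len(n_bg)) {
      for (try in 1:10) {
        off <- sample1(3:(intron_len - clen - 2L))
        ok <- is.null(out) ||
          all(off + clen - 1L < out$off | off > out$off + out$len - 1L)
        if (ok) {
          out <- rbind(out, data.frame(
            off = off, len = clen,
            orient = sample(c("+", "-"), 1L),
            family = sample(spec$sine_families, 1L),
            planted = FALSE))
          break
        }
      }
    }
  }
  out
}

# ---- main generator -------------------------------------------------------

#' Generate a synthetic genome with planted circRNA truth
#'
#' Builds chromosome sequences, gene models, a strand-annotated SINE repeat
#' track and a truth table of planted circRNAs (and optional decoy junctions
#' with exact linear-mimic copies). Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param outdir Optional directory; when given, FASTA/GTF/BED and truth TSVs
#'   are written there (see [write_genome_files()]).
#' @return A list of class `circscan_sim` with elements `genome`
#'   (`circscan_genome`), `genes`, `exons`, `circs`, `sines` (data.frames),
#'   `intergenic` (gap intervals usable for ortholog indels) and `spec`.
#' @export
generate_genome <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "circscan_genome_spec"))
  sim <- with_seed(spec$seed, build_genome_impl(spec))
  if (!is.null(outdir)) write_genome_files(sim, outdir)
  sim
}

build_genome_impl <- function(spec) {
  clen <- nchar(spec$sine_consensus)
  n_genes <- spec$n_genes

  # decide circ / decoy gene assignment up front
  circ_gene <- integer(0); decoy_gene <- integer(0)
  if (n_genes > 0L && (spec$n_circs + spec$n_decoys) > 0L) {
    if (spec$n_circs + spec$n_decoys > n_genes) {
      stop("n_circs + n_decoys exceeds n_genes: cannot place without overlap")
    }
    picked <- sample.int(n_genes, spec$n_circs + spec$n_decoys)
    circ_gene <- picked[seq_len(spec$n_circs)]
    decoy_gene <- setdiff(picked, circ_gene)
  }

  chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  pieces <- setNames(vector("list", spec$n_chromosomes), chrom_names)
  cursor <- setNames(rep(0L, spec$n_chromosomes), chrom_names)
  intergenic <- list()

  genes <- list(); exons <- list(); sines <- list(); circs <- list()
  gene_seqs <- list()   # transcript-orientation exon sequences per gene

  chrom_i <- 1L
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%03d", g)
    has_circ <- g %in% circ_gene
    is_decoy <- g %in% decoy_gene
    st <- draw_gene_structure(spec, has_circ || is_decoy, spec$circ_exon_max)
    strand <- sample(c("+", "-"), 1L)

    plant_pair <- has_circ && runif(1) < spec$complementary_flank_bias
    # bump flanking introns so a planted element fits inside the window
    if (plant_pair) {
      fl <- c(st$circ["a"] - 1L, st$circ["b"])
      st$int_len[fl] <- pmax(st$int_len[fl], clen + 270L)
    }

    # SINE placement per intron (transcript-orientation offsets)
    fam_pair <- sample(spec$sine_families, 1L)
    intron_sines <- vector("list", st$n_ex - 1L)
    for (i in seq_len(st$n_ex - 1L)) {
      planted <- NULL
      if (plant_pair && i == st$circ["a"] - 1L) {
        d <- sample1(5:min(250L, st$int_len[i] - clen - 5L))
        planted <- data.frame(off = st$int_len[i] - d - clen + 1L, len = clen,
                              orient = "+", family = fam_pair, planted = TRUE)
      }
      if (plant_pair && i == st$circ["b"]) {
        d <- sample1(5:min(250L, st$int_len[i] - clen - 5L))
        planted <- data.frame(off = d + 1L, len = clen, orient = "-",
                              family = fam_pair, planted = TRUE)
      }
      intron_sines[i] <- list(place_intron_sines(spec, st$int_len[i], planted))
    }

    # build sequence in transcript orientation
    ex_seq <- vapply(st$ex_len, random_dna, character(1), gc = spec$gc_content)
    int_seq <- character(st$n_ex - 1L)
    for (i in seq_len(st$n_ex - 1L)) {
      s <- random_dna(st$int_len[i], spec$gc_content)
      substr(s, 1L, 2L) <- "GT"
      substr(s, st$int_len[i] - 1L, st$int_len[i]) <- "AG"
      si <- intron_sines[[i]]
      if (!is.null(si)) for (j in seq_len(nrow(si))) {
        ins <- if (si$orient[j] == "+") spec$sine_consensus else revcomp(spec$sine_consensus)
        substr(s, si$off[j], si$off[j] + si$len[j] - 1L) <- ins
      }
      int_seq[i] <- s
    }
    tr_seq <- character(2L * st$n_ex - 1L)
    tr_seq[seq(1L, by = 2L, length.out = st$n_ex)] <- ex_seq
    if (st$n_ex > 1L) tr_seq[seq(2L, by = 2L, length.out = st$n_ex - 1L)] <- int_seq
    gene_seq <- paste(tr_seq, collapse = "")
    glen <- nchar(gene_seq)

    # place on a chromosome (cycle, bounded retries across chromosomes)
    placed <- FALSE
    for (k in seq_len(spec$n_chromosomes)) {
      cn <- chrom_names[chrom_i]
      gap <- sample1(500:2000)
      if (cursor[cn] + gap + glen <= spec$chrom_length - 1000L) {
        if (gap > 0L) {
          pieces[[cn]] <- c(pieces[[cn]], random_dna(gap, spec$gc_content))
          intergenic[[length(intergenic) + 1L]] <-
            data.frame(chrom = cn, start = cursor[cn] + 1L,
                       end = cursor[cn] + gap)
          cursor[cn] <- cursor[cn] + gap
        }
        gstart <- cursor[cn] + 1L
        gseq <- if (strand == "+") gene_seq else revcomp(gene_seq)
        pieces[[cn]] <- c(pieces[[cn]], gseq)
        cursor[cn] <- cursor[cn] + glen
        placed <- TRUE
        chrom_i <- chrom_i %% spec$n_chromosomes + 1L
        break
      }
      chrom_i <- chrom_i %% spec$n_chromosomes + 1L
    }
    if (!placed) {
      stop(sprintf("gene %s (%d bp) cannot be placed within chromosome bounds",
                   gid, glen))
    }

    # transcript-orientation offsets -> genomic coordinates
    seg_len <- c(rbind(st$ex_len, c(st$int_len, 0L)))[seq_len(2L * st$n_ex - 1L)]
    seg_off <- cumsum(c(0L, seg_len[-length(seg_len)]))
    t2g <- function(a, b) {  # transcript-orientation [a,b] within gene -> genomic
      if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
      else c(gstart + glen - b, gstart + glen - a)
    }
    ex_coords <- t(vapply(seq_len(st$n_ex), function(i) {
      o <- seg_off[2L * i - 1L]
      t2g(o + 1L, o + st$ex_len[i])
    }, numeric(2)))
    genes[[g]] <- data.frame(gene_id = gid, chrom = cn, start = gstart,
                             end = gstart + glen - 1L, strand = strand,
                             n_exons = st$n_ex)
    exons[[g]] <- data.frame(gene_id = gid, transcript_id = paste0("t_", gid),
                             chrom = cn, start = ex_coords[, 1],
                             end = ex_coords[, 2], strand = strand,
                             exon_number = seq_len(st$n_ex))
    for (i in seq_len(st$n_ex - 1L)) {
      si <- intron_sines[[i]]
      if (is.null(si)) next
      o <- seg_off[2L * i]
      for (j in seq_len(nrow(si))) {
        gc <- t2g(o + si$off[j], o + si$off[j] + si$len[j] - 1L)
        gstrand <- if (strand == "+") si$orient[j] else chartr("+-", "-+", si$orient[j])
        sines[[length(sines) + 1L]] <- data.frame(
          chrom = cn, start = gc[1], end = gc[2], strand = gstrand,
          family = si$family[j], gene_id = gid, intron_index = i,
          planted = si$planted[j])
      }
    }
    if (has_circ || is_decoy) {
      a <- st$circ["a"]; b <- st$circ["b"]
      span <- t2g(seg_off[2L * a - 1L] + 1L, seg_off[2L * b - 1L] + st$ex_len[b])
      circs[[length(circs) + 1L]] <- data.frame(
        chrom = cn, start = span[1], end = span[2], strand = strand,
        gene_id = gid, exon_first = as.integer(a), exon_last = as.integer(b),
        target_rpm = rloguniform(1, spec$circ_rpm[1], spec$circ_rpm[2]),
        is_decoy = is_decoy, has_comp_pair = plant_pair,
        mimic_chrom = NA_character_, mimic_start = NA_integer_,
        mimic_end = NA_integer_)
    }
    gene_seqs[[gid]] <- ex_seq
  }

  circs <- if (length(circs)) do.call(rbind, circs) else data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), gene_id = character(0), exon_first = integer(0),
    exon_last = integer(0), target_rpm = numeric(0), is_decoy = logical(0),
    has_comp_pair = logical(0), mimic_chrom = character(0),
    mimic_start = integer(0), mimic_end = integer(0))
  exons <- if (length(exons)) do.call(rbind, exons) else data.frame(
    gene_id = character(0), transcript_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    exon_number = integer(0))
  genes <- if (length(genes)) do.call(rbind, genes) else data.frame(
    gene_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), n_exons = integer(0))
  sines <- if (length(sines)) do.call(rbind, sines) else data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), family = character(0), gene_id = character(0),
    intron_index = integer(0), planted = logical(0))

  # decoy mimic loci: exact copies of the decoy junction probes, appended
  # after the genes on their chromosome
  if (any(circs$is_decoy)) {
    for (ci in which(circs$is_decoy)) {
      gid <- circs$gene_id[ci]
      a <- circs$exon_first[ci]; b <- circs$exon_last[ci]
      ex_seq <- gene_seqs[[gid]]
      probe <- paste0(substring(ex_seq[b], nchar(ex_seq[b]) - 79L),
                      substring(ex_seq[a], 1L, 80L))
      cn <- circs$chrom[ci]
      gap <- 200L
      if (cursor[cn] + gap + nchar(probe) > spec$chrom_length) {
        stop("decoy mimic locus cannot be placed within chromosome bounds")
      }
      pieces[[cn]] <- c(pieces[[cn]], random_dna(gap, spec$gc_content), probe)
      circs$mimic_chrom[ci] <- cn
      circs$mimic_start[ci] <- cursor[cn] + gap + 1L
      circs$mimic_end[ci] <- cursor[cn] + gap + nchar(probe)
      cursor[cn] <- cursor[cn] + gap + nchar(probe)
    }
  }

  # pad chromosomes to full length
  for (cn in chrom_names) {
    pad <- spec$chrom_length - cursor[cn]
    if (pad > 0L) {
      intergenic[[length(intergenic) + 1L]] <-
        data.frame(chrom = cn, start = cursor[cn] + 1L,
                   end = spec$chrom_length)
      pieces[[cn]] <- c(pieces[[cn]], random_dna(pad, spec$gc_content))
    }
  }
  seqs <- vapply(pieces, paste, character(1), collapse = "")
  genome <- as_genome(seqs)

  rownames(circs) <- NULL
  if (nrow(circs)) {
    circs$circ_id <- sprintf("%s:%d-%d:%s", circs$chrom, circs$start,
                             circs$end, circs$strand)
    circs <- circs[, c("circ_id", setdiff(names(circs), "circ_id"))]
    # generation-time invariant: every decoy probe has an exact linear copy
    for (ci in which(circs$is_decoy)) {
      probe <- genome_sub(genome, circs$mimic_chrom[ci], circs$mimic_start[ci],
                          circs$mimic_end[ci])
      stopifnot(grepl(probe, genome$seq[[circs$mimic_chrom[ci]]], fixed = TRUE))
    }
  } else {
    circs$circ_id <- character(0)
  }

  sim <- list(genome = genome, genes = genes, exons = exons, circs = circs,
              sines = sines,
              intergenic = if (length(intergenic)) do.call(rbind, intergenic)
                           else data.frame(chrom = character(0),
                                           start = integer(0), end = integer(0)),
              spec = spec)
  class(sim) <- "circscan_sim"
  sim
}

#' @export
print.circscan_sim <- function(x, ...) {
  cat(sprintf(paste0("circscan synthetic dataset: %d chromosome(s), %d genes, ",
                     "%d planted circRNAs (%d decoys), %d SINE elements\n"),
              length(x$genome$seq), nrow(x$genes),
              nrow(x$circs), sum(x$circs$is_decoy), nrow(x$sines)))
  invisible(x)
}
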