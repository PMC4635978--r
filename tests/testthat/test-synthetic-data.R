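test_that("a gene-free spec yields a genome with empty annotation", {
  spec <- synthetic_genome_spec(n_chromosomes = 1, chrom_length = 5000,
                                n_genes = 0, n_circs = 0, seed = 1)
  sim <- generate_genome(spec)
  expect_equal(nchar(sim$genome$seq[["chr1"]]), 5000)
  expect_equal(nrow(sim$exons), 0)
  expect_equal(nrow(sim$circs), 0)
  d <- withr::local_tempdir()
  paths <- write_genome_files(sim, d)
  expect_true(file.exists(paths["fasta"]))
  expect_equal(length(readLines(paths["gtf"])), 0)
})

test_that("identical seeds give byte-identical output files", {
  spec <- synthetic_genome_spec(n_chromosomes = 2, chrom_length = 40000,
                                n_genes = 8, n_circs = 3, n_decoys = 1,
                                seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_genome_files(generate_genome(spec), d1)
  p2 <- write_genome_files(generate_genome(spec), d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[nm])), unname(tools::md5sum(p2[nm])),
                     info = nm)
  }
  rd1 <- suppressWarnings(simulate_reads(generate_genome(spec),
                                         read_sim_params(n_linear_reads = 500,
                                                         seed = 5)))
  rd2 <- suppressWarnings(simulate_reads(generate_genome(spec),
                                         read_sim_params(n_linear_reads = 500,
                                                         seed = 5)))
  expect_identical(rd1$reads, rd2$reads)
})

test_that("full complementarity bias plants a complementary SINE pair at every circ", {
  spec <- synthetic_genome_spec(n_chromosomes = 3, chrom_length = 120000,
                                n_genes = 30, n_circs = 20,
                                complementary_flank_bias = 1.0, seed = 13)
  sim <- generate_genome(spec)
  real <- sim$circs[!sim$circs$is_decoy, ]
  expect_equal(nrow(real), 20)
  expect_true(all(real$has_comp_pair))
  # verify from the repeat truth table: each circ's flanking introns hold a
  # planted same-family opposite-strand pair within the window
  fl <- extract_flanking_introns(real, sim$exons)
  expect_equal(nrow(fl$pairs), 20)
  for (i in seq_len(nrow(fl$pairs))) {
    fp <- fl$pairs[i, ]
    pl <- sim$sines[sim$sines$planted & sim$sines$chrom == fp$chrom &
                      ((sim$sines$start >= fp$left_start &
                          sim$sines$end <= fp$left_end) |
                         (sim$sines$start >= fp$right_start &
                            sim$sines$end <= fp$right_end)), ]
    expect_equal(nrow(pl), 2)
    expect_equal(length(unique(pl$family)), 1)
    expect_setequal(pl$strand, c("+", "-"))
    # both elements inside the stated window of the circ-facing intron ends
    lefts <- pl[pl$end <= fp$start, ]; rights <- pl[pl$start >= fp$end, ]
    expect_lte(fp$start - lefts$end, spec$sine_window)
    expect_lte(rights$start - fp$end, spec$sine_window)
  }
})

test_that("every decoy junction probe has an exact contiguous genomic copy", {
  sim <- decoy_sim()
  dec <- sim$circs[sim$circs$is_decoy, ]
  expect_equal(nrow(dec), 10)
  for (i in seq_len(nrow(dec))) {
    probe <- build_junction_probe(dec[i, ], sim$genome, sim$exons, J = 80)
    expect_true(grepl(probe$sequence,
                      sim$genome$seq[[dec$mimic_chrom[i]]], fixed = TRUE))
  }
})

test_that("junction read counts follow round(rpm x depth / 1e6)", {
  sim <- small_sim()
  rd <- small_reads()
  real <- sim$circs[!sim$circs$is_decoy, ]
  for (i in seq_len(nrow(real))) {
    got <- sum(rd$meta$source_id == real$circ_id[i])
    expect_equal(got, round(real$target_rpm[i] * rd$total_raw_reads / 1e6),
                 info = real$circ_id[i])
  }
})

test_that("error-free junction reads are exact substrings of the doubled circular sequence", {
  sim <- small_sim()
  rd <- small_reads()
  jr <- rd$meta[rd$meta$origin == "junction", ]
  for (cid in unique(jr$source_id)) {
    ci <- which(sim$circs$circ_id == cid)
    ctx <- circscan:::circ_transcript_seq(sim, ci)
    doubled <- paste0(ctx, ctx)
    for (id in jr$read_id[jr$source_id == cid]) {
      expect_true(grepl(rd$reads[[id]], doubled, fixed = TRUE))
    }
  }
})

test_that("without planted circs only linear-transcript reads are emitted", {
  spec <- synthetic_genome_spec(n_chromosomes = 1, chrom_length = 50000,
                                n_genes = 6, n_circs = 0, seed = 3)
  rd <- simulate_reads(generate_genome(spec),
                       read_sim_params(n_linear_reads = 300, seed = 1))
  expect_setequal(unique(rd$meta$origin), "linear")
  expect_equal(length(rd$reads), 300)
})

test_that("a circ below one expected read is omitted from reads but kept in truth", {
  spec <- synthetic_genome_spec(n_chromosomes = 1, chrom_length = 50000,
                                n_genes = 6, n_circs = 2,
                                circ_rpm = c(0.2, 0.4), seed = 8)
  sim <- generate_genome(spec)
  w <- capture_warnings(rd <- simulate_reads(sim, read_sim_params(
    n_linear_reads = 100, total_raw_reads = 1e6, seed = 1)))
  expect_length(w, 2)   # one per sub-threshold circ
  expect_true(all(grepl("yields no reads", w)))
  expect_equal(sum(rd$meta$origin == "junction"), 0)
  expect_equal(nrow(sim$circs), 2)
})

test_that("substitution errors are applied at the requested rate", {
  sim <- small_sim()
  rd0 <- suppressWarnings(simulate_reads(sim, read_sim_params(
    n_linear_reads = 400, error_rate = 0, seed = 9)))
  rd1 <- suppressWarnings(simulate_reads(sim, read_sim_params(
    n_linear_reads = 400, error_rate = 0.05, seed = 9)))
  diffs <- mapply(function(a, b) {
    sum(charToRaw(a) != charToRaw(b))
  }, rd0$reads, rd1$reads)
  rate <- sum(diffs) / sum(nchar(rd0$reads))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("identity-settings ortholog has one chain block per chromosome and conserves everything", {
  sim <- small_sim()
  orth <- generate_ortholog_genome(sim, conserved_fraction = 1.0, seed = 2,
                                   n_indels_per_chrom = 0)
  expect_identical(orth$genome$seq, sim$genome$seq)
  expect_true(all(vapply(orth$blocks, nrow, integer(1)) == 1L))
  expect_true(all(orth$conserved$conserved))
  d <- withr::local_tempdir()
  write_ortholog_files(orth, d)
  ch <- read_chain(file.path(d, "source_to_ortholog.chain"))
  real <- sim$circs[!sim$circs$is_decoy, ]
  lf <- lift_circ_ends(real, ch)
  expect_true(all(lf$status == "lifted"))
  expect_equal(lf$lifted_start, real$start)
  expect_equal(lf$lifted_end, real$end)
})

test_that("GTF and FASTQ files round-trip through their readers", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  paths <- write_genome_files(sim, d)
  ex <- read_gene_models(paths["gtf"])
  key <- function(df) df[order(df$gene_id, df$exon_number),
                         c("gene_id", "chrom", "start", "end", "strand",
                           "exon_number")]
  expect_equal(unname(as.list(key(ex))), unname(as.list(key(sim$exons))))
  rd <- small_reads()
  fq <- file.path(d, "reads.fq")
  write_reads_fastq(rd$reads, fq)
  back <- read_reads_fastq(fq)
  expect_identical(back, rd$reads)
})

test_that("conserved_fraction controls the ortholog truth exactly", {
  spec <- synthetic_genome_spec(n_chromosomes = 3, chrom_length = 200000,
                                n_genes = 45, n_circs = 40, seed = 21)
  sim <- generate_genome(spec)
  orth <- generate_ortholog_genome(sim, conserved_fraction = 0.5, seed = 4)
  expect_equal(sum(orth$conserved$conserved), 20)
  expect_equal(nrow(orth$ortholog_circs), 20)
  orth0 <- generate_ortholog_genome(sim, conserved_fraction = 0, seed = 4)
  d <- withr::local_tempdir()
  write_ortholog_files(orth0, d)
  lf <- lift_circ_ends(sim$circs[!sim$circs$is_decoy, ],
                       read_chain(file.path(d, "source_to_ortholog.chain")))
  ci <- count_identical(lf, orth0$ortholog_circs)
  expect_equal(ci$n_identical, 0)
})
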