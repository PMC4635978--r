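write_chain_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".chain",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("malformed chain files raise parse errors naming the line", {
  f <- write_chain_fixture(c("chain 100 chrA 100 + 0 100 chrB 100 + 0 100",
                             "100", ""))
  expect_error(read_chain(f), "line 1")
  f2 <- write_chain_fixture(c("chain 100 chrA 100 + 0 100 chrB 100 + 0 100 1",
                              "50 x 0", "50", ""))
  expect_error(read_chain(f2), "line 2")
})

test_that("identity and shift chains lift circ ends exactly", {
  circs <- data.frame(circ_id = "c", chrom = "chrA", start = 101L, end = 400L,
                      strand = "+")
  ident <- read_chain(write_chain_fixture(
    c("chain 1000 chrA 1000 + 0 1000 chrA 1000 + 0 1000 1", "1000", "")))
  lf <- lift_circ_ends(circs, ident)
  expect_equal(lf$status, "lifted")
  expect_equal(lf$lifted_start, 101L)
  expect_equal(lf$lifted_end, 400L)
  shift <- read_chain(write_chain_fixture(
    c("chain 1000 chrA 1000 + 0 1000 chrB 1010 + 10 1010 1", "1000", "")))
  ls <- lift_circ_ends(circs, shift)
  expect_equal(ls$lifted_start, 111L)
  expect_equal(ls$lifted_end, 410L)
  expect_equal(ls$target_chrom, "chrB")
})

test_that("a deletion covering one 20-bp end leaves the circ unlifted", {
  # target chrA: [1,380] aligns, then 40 bp of source [381,420] are deleted
  del <- read_chain(write_chain_fixture(
    c("chain 1000 chrA 1000 + 0 1000 chrB 960 + 0 960 1", "380 40 0", "580",
      "")))
  circs <- data.frame(circ_id = "c", chrom = "chrA", start = 101L, end = 400L,
                      strand = "+")
  lf <- lift_circ_ends(circs, del)
  expect_equal(lf$status, "unlifted")
  expect_equal(lf$reason, "end unmapped")
  # a deletion through the middle of the end splits it
  del2 <- read_chain(write_chain_fixture(
    c("chain 1000 chrA 1000 + 0 1000 chrB 995 + 0 995 1", "390 5 0", "605",
      "")))
  lf2 <- lift_circ_ends(circs, del2)
  expect_equal(lf2$reason, "end split")
})

test_that("ends landing on different chromosomes are rejected", {
  two <- read_chain(write_chain_fixture(
    c("chain 100 chrA 1000 + 0 200 chrB 1000 + 0 200 1", "200", "",
      "chain 100 chrA 1000 + 300 500 chrC 1000 + 300 500 2", "200", "")))
  circs <- data.frame(circ_id = "c", chrom = "chrA", start = 101L, end = 400L,
                      strand = "+")
  lf <- lift_circ_ends(circs, two)
  expect_equal(lf$reason, "cross-chromosome")
})

test_that("lifting through a chain and its inverse restores coordinates", {
  sim <- small_sim()
  orth <- generate_ortholog_genome(sim, conserved_fraction = 0.5, seed = 6)
  d <- withr::local_tempdir()
  write_ortholog_files(orth, d)
  ch <- read_chain(file.path(d, "source_to_ortholog.chain"))
  inv <- read_chain(file.path(d, "ortholog_to_source.chain"))
  real <- sim$circs[!sim$circs$is_decoy, ]
  lf <- lift_circ_ends(real, ch)
  expect_true(all(lf$status == "lifted"))
  back <- lift_circ_ends(
    data.frame(circ_id = lf$circ_id, chrom = lf$target_chrom,
               start = lf$lifted_start, end = lf$lifted_end,
               strand = lf$target_strand), inv)
  expect_equal(back$lifted_start, real$start)
  expect_equal(back$lifted_end, real$end)
})

test_that("identity counting is exact on equal, disjoint and truth-matched sets", {
  sim <- small_sim()
  ident <- read_chain(write_chain_fixture(c(
    sprintf("chain 1000 %s %d + 0 %d %s %d + 0 %d %d",
            names(sim$genome$seq), nchar(sim$genome$seq),
            nchar(sim$genome$seq), names(sim$genome$seq),
            nchar(sim$genome$seq), nchar(sim$genome$seq),
            seq_along(sim$genome$seq))[1],
    as.character(nchar(sim$genome$seq[1])), "",
    sprintf("chain 1000 %s %d + 0 %d %s %d + 0 %d %d",
            names(sim$genome$seq), nchar(sim$genome$seq),
            nchar(sim$genome$seq), names(sim$genome$seq),
            nchar(sim$genome$seq), nchar(sim$genome$seq),
            seq_along(sim$genome$seq))[2],
    as.character(nchar(sim$genome$seq[2])), "")))
  real <- sim$circs[!sim$circs$is_decoy, ]
  lf <- lift_circ_ends(real, ident)
  ci <- count_identical(lf, real)
  expect_equal(ci$fraction, 1.0)
  expect_equal(ci$n_identical, nrow(real))
  far <- real; far$start <- far$start + 1L
  expect_equal(count_identical(lf, far)$n_identical, 0)
})

test_that("in-silico candidate enumeration follows n(n+1)/2 with removals", {
  ex <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                   start = c(100L, 300L, 500L), end = c(199L, 399L, 599L),
                   strand = "+", exon_number = 1:3)
  en <- enumerate_circle_candidates(ex, "g1")
  expect_equal(nrow(en), 6)
  # removing the single-exon-2 circle leaves 5
  real <- data.frame(chrom = "chr1", start = 300L, end = 399L)
  key <- paste(en$chrom, en$start, en$end)
  expect_equal(sum(!(key %in% paste(real$chrom, real$start, real$end))), 5)
  # FPKM threshold excludes a gene at 9.9
  ident <- read_chain(write_chain_fixture(
    c("chain 1000 chr1 1000 + 0 1000 chr1 1000 + 0 1000 1", "1000", "")))
  expect_error(
    generate_insilico_controls(ex, c(g1 = 9.9), real[0, ], n_target = 1,
                               chain = ident),
    "pool \\(0\\) smaller")
})

test_that("control sampling accrues exactly the requested number of lifted controls", {
  sim <- small_sim()
  orth <- generate_ortholog_genome(sim, conserved_fraction = 0.5, seed = 6)
  d <- withr::local_tempdir()
  write_ortholog_files(orth, d)
  ch <- read_chain(file.path(d, "source_to_ortholog.chain"))
  fpkm <- setNames(rep(20, nrow(sim$genes)), sim$genes$gene_id)
  real <- sim$circs[!sim$circs$is_decoy, ]
  ic <- generate_insilico_controls(sim$exons, fpkm, real, n_target = 25,
                                   chain = ch, seed = 3)
  expect_equal(sum(ic$lifted$status == "lifted"), 25)
  # controls never include a real circ
  expect_false(any(paste(ic$controls$chrom, ic$controls$start,
                         ic$controls$end) %in%
                     paste(real$chrom, real$start, real$end)))
})

test_that("the conservation chi-squared test behaves at both extremes", {
  eq <- conservation_test(50, 100, 50, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  strong <- conservation_test(200, 1000, 20, 1000)
  expect_lt(strong$p.value, 1e-5)
  expect_error(conservation_test(0, 0, 5, 10), "degenerate")
})
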