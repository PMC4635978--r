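# A 4-exon plus-strand gene fixture with exact intron intervals.
flank_gene <- function() {
  data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
             start = c(1001L, 2001L, 4001L, 7001L),
             end = c(1200L, 2200L, 4200L, 7200L), strand = "+",
             exon_number = 1:4)
}

test_that("flanking introns are the ones immediately around the circularized run", {
  ex <- flank_gene()
  # circ = exon 2 alone: flanks are intron 1 [1201,2000] and intron 2 [2201,4000]
  c1 <- data.frame(circ_id = "c1", chrom = "chr1", start = 2001L, end = 2200L,
                   strand = "+")
  fp <- extract_flanking_introns(c1, ex)$pairs
  expect_equal(c(fp$left_start, fp$left_end), c(1201L, 2000L))
  expect_equal(c(fp$right_start, fp$right_end), c(2201L, 4000L))
  expect_equal(fp$up_len, 800L)
  expect_equal(fp$down_len, 1800L)
  # circ = exons 2-3: flanks are introns 1 and 3
  c2 <- data.frame(circ_id = "c2", chrom = "chr1", start = 2001L, end = 4200L,
                   strand = "+")
  fp2 <- extract_flanking_introns(c2, ex)$pairs
  expect_equal(c(fp2$left_start, fp2$left_end), c(1201L, 2000L))
  expect_equal(c(fp2$right_start, fp2$right_end), c(4201L, 7000L))
})

test_that("first/last-exon circs are excluded with a reason", {
  ex <- flank_gene()
  c_first <- data.frame(circ_id = "cf", chrom = "chr1", start = 1001L,
                        end = 1200L, strand = "+")
  res <- extract_flanking_introns(c_first, ex)
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$excluded$reason, "no flanking intron")
  c_last <- data.frame(circ_id = "cl", chrom = "chr1", start = 4001L,
                       end = 7200L, strand = "+")
  expect_equal(extract_flanking_introns(c_last, ex)$excluded$reason,
               "no flanking intron")
})

test_that("minus-strand transcript orientation maps up/down introns correctly", {
  ex <- flank_gene()
  ex$strand <- "-"
  ex$exon_number <- 4:1   # transcript order reversed on the minus strand
  cc <- data.frame(circ_id = "m", chrom = "chr1", start = 2001L, end = 2200L,
                   strand = "-")
  fp <- extract_flanking_introns(cc, ex)$pairs
  # upstream (transcript) intron is the genomically right one
  expect_equal(fp$up_len, 1800L)
  expect_equal(fp$down_len, 800L)
})

test_that("expression tiers follow the RPM boundaries", {
  expect_equal(expression_tier(c(0.04, 0.05, 0.5, 0.51, 2.5, 2.51)),
               c("below", "low", "low", "medium", "medium", "high"))
})

test_that("SINE pair distance subtracts the circ span from the genomic gap", {
  # 1-based version of the worked arithmetic: circ [1001,2000], upstream SINE
  # [801,900], downstream SINE [2101,2200] -> gap 1200, span 1000, distance 200
  pairs <- data.frame(circ_id = "c", tier = "high", chrom = "chr1",
                      start = 1001L, end = 2000L, strand = "+",
                      left_start = 701L, left_end = 1000L,
                      right_start = 2001L, right_end = 2400L,
                      up_len = 300L, down_len = 400L)
  sines <- data.frame(chrom = "chr1", start = c(801L, 2101L),
                      end = c(900L, 2200L), strand = c("+", "-"),
                      family = "SINEA")
  ss <- sine_pair_stats(pairs, sines)
  expect_equal(nrow(ss$distances), 1)
  expect_equal(ss$distances$dist, 200)
  expect_true(ss$pairs_scored$complementary)
  # shifting the whole locus leaves the distance unchanged
  shift <- 5000L
  pairs2 <- pairs
  for (cl in c("start", "end", "left_start", "left_end", "right_start",
               "right_end")) pairs2[[cl]] <- pairs2[[cl]] + shift
  sines2 <- sines
  sines2$start <- sines2$start + shift; sines2$end <- sines2$end + shift
  expect_equal(sine_pair_stats(pairs2, sines2)$distances$dist, 200)
})

test_that("same-strand pairs are never complementary; swapping strands is symmetric", {
  pairs <- data.frame(circ_id = "c", tier = "high", chrom = "chr1",
                      start = 1001L, end = 2000L, strand = "+",
                      left_start = 701L, left_end = 1000L,
                      right_start = 2001L, right_end = 2400L,
                      up_len = 300L, down_len = 400L)
  same <- data.frame(chrom = "chr1", start = c(801L, 2101L),
                     end = c(900L, 2200L), strand = c("+", "+"),
                     family = "SINEA")
  expect_false(any(sine_pair_stats(pairs, same)$pairs_scored$complementary))
  # complementarity is symmetric in which intron carries the plus element
  sw1 <- same; sw1$strand <- c("+", "-")
  sw2 <- same; sw2$strand <- c("-", "+")
  expect_equal(sum(sine_pair_stats(pairs, sw1)$pairs_scored$complementary),
               sum(sine_pair_stats(pairs, sw2)$pairs_scored$complementary))
  # cross-family pairs are non-complementary even on opposite strands
  xf <- sw1; xf$family <- c("SINEA", "SINEB")
  expect_false(any(sine_pair_stats(pairs, xf)$pairs_scored$complementary))
})

test_that("the minimum-distance complementary pair is the reported one", {
  pairs <- data.frame(circ_id = "c", tier = "high", chrom = "chr1",
                      start = 1001L, end = 2000L, strand = "+",
                      left_start = 1L, left_end = 1000L,
                      right_start = 2001L, right_end = 3400L,
                      up_len = 1000L, down_len = 1400L)
  sines <- data.frame(chrom = "chr1",
                      start = c(101L, 801L, 2101L, 3001L),
                      end = c(200L, 900L, 2200L, 3100L),
                      strand = c("+", "+", "-", "-"), family = "SINEA")
  ss <- sine_pair_stats(pairs, sines)
  comp <- ss$pairs_scored[ss$pairs_scored$complementary, ]
  expect_equal(nrow(comp), 4)           # 2 left x 2 right, all complementary
  expect_equal(ss$distances$dist, min(comp$dist))
  expect_true(all(ss$distances$dist <= comp$dist))
})

test_that("identical tier and control samples give D = 0 and p = 1", {
  lens <- data.frame(circ_id = sprintf("c%d", 1:10), tier = "high",
                     up_len = 100L + (1:10), down_len = 200L + (1:10))
  ctrl <- lens; ctrl$tier <- "control"; ctrl$circ_id <- paste0("k", 1:10)
  it <- intron_length_test(rbind(lens, ctrl))
  row <- it$stats[it$stats$tier == "high", ]
  expect_equal(row$ks_D, 0)
  expect_equal(row$p, 1)
  expect_error(intron_length_test(lens), "control")
})

test_that("long-intron planting is detected against short-intron controls", {
  spec <- synthetic_genome_spec(n_chromosomes = 3, chrom_length = 200000,
                                n_genes = 66, n_circs = 40, sine_density = 12,
                                complementary_flank_bias = 1.0,
                                circ_rpm = c(0.06, 20), seed = 19)
  sim <- generate_genome(spec)
  real <- sim$circs[!sim$circs$is_decoy, ]
  fp <- extract_flanking_introns(real, sim$exons)$pairs
  fp$tier <- expression_tier(real$target_rpm[match(fp$circ_id, real$circ_id)])
  ctrl <- control_exons(real, sim$exons)
  cf <- extract_flanking_introns(ctrl, sim$exons)$pairs
  cf$tier <- "control"
  allp <- rbind(fp, cf)
  it <- intron_length_test(allp)
  non_ctrl <- it$stats[it$stats$tier != "control", ]
  ctrl_med <- it$stats$median[it$stats$tier == "control"]
  expect_true(all(non_ctrl$median > ctrl_med))
  expect_true(all(non_ctrl$p < 0.01))
  # complementary planting shows up as enrichment (tiers pooled vs control)
  pooled <- allp
  pooled$tier[pooled$tier != "control"] <- "circ"
  ss <- sine_pair_stats(pooled, sim$sines)
  expect_lt(ss$bar$chisq_p[ss$bar$tier == "circ"], 0.01)
  expect_equal(unname(ss$fraction_within["circ"]), 1)
})
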