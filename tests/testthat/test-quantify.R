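test_that("RPM arithmetic matches the cutoff rationale at 21M raw reads", {
  # two reads at the shallowest sample pass the 0.05 RPM floor; one does not
  expect_equal(rpm_normalize(2, 21e6), 2e6 / 21e6 * 1)
  expect_gt(rpm_normalize(2, 21e6), 0.05)
  expect_lt(rpm_normalize(1, 21e6), 0.05)
  expect_equal(rpm_normalize(21, 21e6), 1.0)
  expect_equal(rpm_normalize(0, 1e6), 0)
  expect_error(rpm_normalize(2, 0), "positive")
  # scale invariance
  expect_equal(rpm_normalize(8, 4e6), rpm_normalize(16, 8e6))
})

test_that("pseudo-RPKM is exactly linear in RPM with slope 6.25", {
  expect_equal(pseudo_rpkm(0), 0)
  expect_equal(pseudo_rpkm(0.16), 1.0)
  rpm <- c(0.05, 0.5, 2.5, 19.2)
  expect_equal(pseudo_rpkm(rpm), rpm * 6.25)
  expect_equal(pipeline_config()$effective_len, 160L)
})

test_that("hosts are assigned by largest strand-matched overlap", {
  genes <- data.frame(gene_id = c("gA", "gB", "gAnti"),
                      chrom = "chr1", start = c(1000L, 1801L, 3000L),
                      end = c(1800L, 2600L, 4000L),
                      strand = c("+", "+", "-"))
  circs <- data.frame(circ_id = c("inside", "split", "intergenic", "anti"),
                      chrom = "chr1",
                      start = c(1100L, 1401L, 5000L, 3200L),
                      end = c(1500L, 1900L, 5400L, 3600L),
                      strand = "+")
  mh <- match_hosts(circs, genes)
  a <- mh$assignment
  expect_equal(a$host_gene[a$circ_id == "inside"], "gA")
  # split circ overlaps gA by 400 bp and gB by 100 bp
  expect_equal(a$host_gene[a$circ_id == "split"], "gA")
  expect_equal(a$n_overlapping[a$circ_id == "split"], 2)
  expect_true(all(c("gA", "gB") %in%
                    mh$overlaps$gene_id[mh$overlaps$circ_id == "split"]))
  expect_true(is.na(a$host_gene[a$circ_id == "intergenic"]))
  # antisense overlap is never a host
  expect_true(is.na(a$host_gene[a$circ_id == "anti"]))
})

test_that("circ/host ratios stay undefined without an expressed host", {
  circs <- data.frame(circ_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(1L, 1L, 1L), end = c(100L, 100L, 100L),
                      strand = "+", sample = "s1", support = c(4L, 4L, 4L))
  hosts <- data.frame(circ_id = c("a", "b", "c"),
                      host_gene = c("g1", "g2", NA))
  fpkm <- data.frame(gene_id = c("g1", "g2"), sample = "s1", fpkm = c(5, 0))
  expr <- expression_table(circs, c(s1 = 1e6), hosts, fpkm)
  expect_equal(expr$ratio[expr$circ_id == "a"],
               pseudo_rpkm(4) / 5)
  expect_true(is.na(expr$ratio[expr$circ_id == "b"]))  # host at 0 FPKM
  expect_true(is.na(expr$ratio[expr$circ_id == "c"]))  # no host
  expect_false(any(is.infinite(expr$ratio), na.rm = TRUE))
})

test_that("summary bookkeeping counts hot-spot genes and above-host circs", {
  # genes A (3 isoforms), B (2), C (4): two hot-spot genes at the >= 3 rule
  mk <- function(gene, n, start0) {
    data.frame(circ_id = sprintf("%s_c%d", gene, 1:n), chrom = "chr1",
               start = start0 + (1:n) * 10L, end = start0 + 2000L + (1:n) * 10L,
               strand = "+", sample = "s1", support = 4L)
  }
  circs <- rbind(mk("gA", 3, 1000L), mk("gB", 2, 10000L), mk("gC", 4, 20000L))
  hosts <- data.frame(circ_id = circs$circ_id,
                      host_gene = sub("_c\\d+", "", circs$circ_id))
  fpkm <- data.frame(gene_id = c("gA", "gB", "gC", "gD"), sample = "s1",
                     fpkm = c(10, 10, 10, 0.5))
  expr <- expression_table(circs, c(s1 = 1e6), hosts, fpkm)
  sm <- summarize_circ_expression(expr, fpkm)
  get <- function(stat) sm$s1[sm$statistic == stat]
  expect_equal(get("n_circ"), 9)
  expect_equal(get("n_genes_expressed"), 3)   # gD below 1 FPKM
  expect_equal(get("n_genes_circ"), 3)
  expect_equal(get("n_hotspot"), 2)           # gA and gC
  # all circs have pseudo-RPKM 25 > host FPKM 10
  expect_equal(get("n_above_host"), 9)
  expect_equal(sm$All[sm$statistic == "n_circ"], 9)
})

test_that("a circ at pseudo-RPKM 5 with host FPKM 4 counts as above host", {
  circs <- data.frame(circ_id = "x", chrom = "chr1", start = 1L, end = 100L,
                      strand = "+", sample = "s1", support = 8L)
  hosts <- data.frame(circ_id = "x", host_gene = "g1")
  fpkm <- data.frame(gene_id = "g1", sample = "s1", fpkm = 4)
  expr <- expression_table(circs, c(s1 = 1e7), hosts, fpkm)  # rpm 0.8 -> 5
  expect_equal(expr$pseudo_rpkm, 5)
  sm <- summarize_circ_expression(expr, fpkm)
  expect_equal(sm$s1[sm$statistic == "n_above_host"], 1)
})

test_that("an empty circ set keeps gene counts and zeroes circ statistics", {
  circs <- data.frame(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), sample = character(0),
                      support = integer(0))
  fpkm <- data.frame(gene_id = c("g1", "g2"), sample = "s1", fpkm = c(3, 2))
  expr <- expression_table(circs, c(s1 = 1e6), NULL, fpkm)
  sm <- summarize_circ_expression(expr, fpkm)
  expect_equal(sm$s1[sm$statistic == "n_circ"], 0)
  expect_equal(sm$s1[sm$statistic == "n_genes_expressed"], 2)
})

test_that("summary circ counts are monotone non-increasing in the RPM floor", {
  set.seed(77)
  circs <- data.frame(circ_id = sprintf("c%02d", 1:30), chrom = "chr1",
                      start = 1L, end = 1000L, strand = "+", sample = "s1",
                      support = rpois(30, 3))
  fpkm <- data.frame(gene_id = "g", sample = "s1", fpkm = 2)
  expr <- expression_table(circs, c(s1 = 2e7), NULL, fpkm)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5), function(fl) {
    sm <- summarize_circ_expression(expr, fpkm, pipeline_config(rpm_min = fl))
    sm$s1[sm$statistic == "n_circ"]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pathway candidates need >0.15 RPM at t1 and a >=2-fold drop", {
  mk <- function(id, r1, r2) {
    rbind(data.frame(circ_id = id, sample = "E60", rpm = r1,
                     host_gene = paste0("g_", id)),
          data.frame(circ_id = id, sample = "E80", rpm = r2,
                     host_gene = paste0("g_", id)))
  }
  expr <- rbind(mk("sel", 0.2, 0.05), mk("weakfold", 0.2, 0.15),
                mk("lowstart", 0.14, 0), mk("inf", 0.3, 0))
  sel <- select_pathway_candidates(expr, "E60", "E80")
  expect_setequal(sel$circs$circ_id, c("sel", "inf"))
  expect_true(sel$circs$infinite[sel$circs$circ_id == "inf"])
  expect_setequal(sel$genes, c("g_sel", "g_inf"))
})

test_that("the exon-union FPKM counter recovers simulated gene expression", {
  sim <- small_sim()
  rd <- small_reads()
  idx <- small_index()
  counts <- count_gene_reads(rd$reads[rd$meta$origin == "linear"], idx,
                             sim$exons)
  # anchor-based assignment recovers nearly all linear reads at the right gene
  expect_gt(sum(counts), 0.9 * sum(rd$gene_reads))
  expect_true(all(abs(counts - rd$gene_reads[names(counts)]) <=
                    pmax(3, 0.15 * rd$gene_reads[names(counts)])))
  ul <- exon_union_length(sim$exons)
  fpkm <- compute_fpkm(counts, ul, rd$total_raw_reads)
  expect_equal(unname(fpkm["gene001"]),
               unname(counts["gene001"] * 1e9 / (rd$total_raw_reads * ul["gene001"])))
})
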