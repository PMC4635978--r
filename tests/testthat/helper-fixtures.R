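# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small genome with genuine circs and decoys, plus reads and an anchor index.
small_sim <- function() fixture("small_sim", function() {
  generate_genome(synthetic_genome_spec(
    n_chromosomes = 2, chrom_length = 60000, n_genes = 12, n_circs = 5,
    n_decoys = 2, seed = 7))
})

small_reads <- function() fixture("small_reads", function() {
  suppressWarnings(simulate_reads(
    small_sim(), read_sim_params(n_linear_reads = 2000,
                                 total_raw_reads = 1e6, seed = 3)))
})

small_index <- function() fixture("small_index", function() {
  build_index(small_sim()$genome, 20)
})

small_detection <- function() fixture("small_detection", function() {
  detect_circRNAs(small_reads(), small_index())
})

# Genome with enough decoys to measure filter sensitivity/specificity.
decoy_sim <- function() fixture("decoy_sim", function() {
  generate_genome(synthetic_genome_spec(
    n_chromosomes = 4, chrom_length = 160000, n_genes = 52, n_circs = 40,
    n_decoys = 10, seed = 11))
})

# Hand-built two-exon back-splice fixture on a 700 bp chromosome:
# e1=[31,90], e2=[101,200] (A), e3=[301,400] (B), e4=[411,470], plus-strand
# gene with canonical GT..AG at every intron edge. The planted circ is e2-e3.
two_exon_fixture <- function() fixture("two_exon_fixture", function() {
  set.seed(202)
  s <- strsplit(paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                      collapse = ""), "")[[1]]
  put <- function(pos, what) {
    s[pos:(pos + nchar(what) - 1L)] <<- strsplit(what, "")[[1]]
  }
  put(91, "GT"); put(99, "AG")     # intron 1 = [91,100]
  put(201, "GT"); put(299, "AG")   # intron 2 = [201,300]
  put(401, "GT"); put(409, "AG")   # intron 3 = [401,410]
  genome <- c(chrF = paste(s, collapse = ""))
  exons <- data.frame(gene_id = "gF", transcript_id = "t_gF", chrom = "chrF",
                      start = c(31, 101, 301, 411),
                      end = c(90, 200, 400, 470), strand = "+",
                      exon_number = 1:4)
  seqA <- substring(genome, 101, 200)
  seqB <- substring(genome, 301, 400)
  list(genome = genome, exons = exons, seqA = seqA, seqB = seqB,
       # back-splice read: o nt of donor (B) tail followed by the head of A
       junction_read = function(o = 50L) {
         paste0(substring(seqB, 101 - o, 100), substring(seqA, 1, 100 - o))
       },
       # colinear splice read across the normal A->B junction
       linear_splice_read = function(o = 50L) {
         paste0(substring(seqA, 101 - o, 100), substring(seqB, 1, 100 - o))
       })
})

two_exon_index <- function() fixture("two_exon_index", function() {
  build_index(two_exon_fixture()$genome, 20)
})

# Four well-separated six-sample expression archetypes (decreasing,
# increasing, mid-peak, oscillating) with n noisy copies each.
archetype_profiles <- function(n_per = 10, sd = 0.4, seed = 43) {
  arch <- rbind(c(2, 1, 0, -1, -2, 0),
                c(0, -2, -1, 0, 1, 2),
                c(-1, 1, 2, 1, -1, -2),
                c(1, -2, 1, 1, -2, 1))
  set.seed(seed)
  rows <- arch[rep(1:4, each = n_per), ] +
    matrix(rnorm(4 * n_per * 6, sd = sd), 4 * n_per, 6)
  rownames(rows) <- sprintf("r%02d", seq_len(4 * n_per))
  list(matrix = rows, truth = rep(1:4, each = n_per))
}
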