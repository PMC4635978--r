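# Brute-force back-splice oracle: enumerate every contiguous exon run of
# every transcript, build the junction-spanning sequence (J nt each side),
# and hash every read-length window of it. A read is a back-splice read iff
# it (or its reverse complement) is one of those windows; the expected
# junction coordinates come straight from the annotation. Independent of the
# anchor-based detector.

oracle_build <- function(sim, read_len = 100L, J = 80L) {
  tab <- new.env(parent = emptyenv(), hash = TRUE)
  sp <- split(sim$exons, sim$exons$gene_id)
  for (ex in sp) {
    ex <- ex[order(ex$exon_number), ]
    n <- nrow(ex)
    seqs <- vapply(seq_len(n), function(i)
      circscan:::genome_sub(sim$genome, ex$chrom[i], ex$start[i], ex$end[i],
                 ex$strand[i]), character(1))
    for (i in seq_len(n)) for (j in i:n) {
      donor_tail <- substring(seqs[j], nchar(seqs[j]) - J + 1L)
      acceptor_head <- substring(seqs[i], 1L, J)
      jseq <- paste0(donor_tail, acceptor_head)
      gs <- min(ex$start[i:j]); ge <- max(ex$end[i:j])
      val <- c(ex$chrom[1], gs, ge, ex$strand[1])
      for (o in seq_len(nchar(jseq) - read_len + 1L)) {
        w <- substring(jseq, o, o + read_len - 1L)
        assign(w, val, envir = tab)
      }
    }
  }
  tab
}

oracle_lookup <- function(tab, read) {
  if (exists(read, envir = tab)) return(get(read, envir = tab))
  rc <- circscan:::revcomp(read)
  if (exists(rc, envir = tab)) return(get(rc, envir = tab))
  NULL
}
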