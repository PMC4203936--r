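# shared toy fixtures, built in code

# a random DNA genome with a fixed seed
toy_genome <- function(n = 500L, seed = 101L, chrom = "chr1") {
  withr::with_seed(seed, stats::setNames(
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""), chrom))
}

# single-exon plus-strand gene with a 5'UTR
toy_tx <- function(id = "tx1", gene = "g1", start = 50L, len = 200L,
                   utr = 60L, strand = "+", chrom = "chr1") {
  transcript_model(id, gene, chrom, strand, cbind(start, start + len),
                   cds_start_tx = utr)
}

# independent Mann-Whitney oracle: U from pairwise comparisons, p from
# enumerating all group labelings of the pooled values
brute_mwu <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pool <- c(x, y)
  nx <- length(x); n <- length(pool)
  mu <- nx * length(y) / 2
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2L, function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-9))
}

printed_utrs <- function() reporter_utrs()
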