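test_that("transcript models validate their invariants", {
  expect_error(transcript_model("t", "g", "c", "+", rbind(c(10, 5)), 0),
               "inverted")
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(0, 50), c(40, 80)), 0), "overlapping")
  expect_error(transcript_model("t", "g", "c", "+", rbind(c(0, 50)), 60),
               "outside")
  t <- transcript_model("t", "g", "c", "-", rbind(c(70, 100), c(10, 50)), 20)
  expect_equal(t$length, 70L)
  expect_equal(t$exons[, 1], c(10L, 70L))  # sorted genomically
})

test_that("canonical transcript selection follows the longest-CDS policy", {
  t1 <- transcript_model("a", "g", "c", "+", rbind(c(0, 400)), 100,
                         cds_len = 300L)
  t2 <- transcript_model("b", "g", "c", "+", rbind(c(0, 700)), 100,
                         cds_len = 600L)
  db <- transcript_db(list(t1, t2))
  expect_equal(unname(db$canonical["g"]), "b")
  # tie on CDS -> longest transcript; tie on both -> lexicographic id
  t3 <- transcript_model("c", "g2", "c", "+", rbind(c(0, 500)), 100,
                         cds_len = 300L)
  t4 <- transcript_model("d", "g2", "c", "+", rbind(c(0, 400)), 100,
                         cds_len = 300L)
  expect_equal(unname(transcript_db(list(t3, t4))$canonical["g2"]), "c")
  t5 <- transcript_model("z", "g3", "c", "+", rbind(c(0, 400)), 100)
  t6 <- transcript_model("y", "g3", "c", "+", rbind(c(0, 400)), 100)
  expect_equal(unname(transcript_db(list(t5, t6))$canonical["g3"]), "y")
  # single candidate is canonical
  expect_equal(unname(transcript_db(list(t1))$canonical["g"]), "a")
})

test_that("5'UTR extraction is strand-aware and start-codon exclusive", {
  genome <- toy_genome(400)
  tp <- toy_tx(start = 50, len = 120, utr = 30, strand = "+")
  up <- extract_five_prime_utr(tp, genome)
  expect_equal(nchar(up), 30)
  expect_equal(up, chartr("T", "U", substr(genome[[1]], 51, 80)))
  # minus strand: reverse complement of the plus-strand slice
  tm <- toy_tx(id = "tx2", start = 200, len = 60, utr = 12, strand = "-")
  um <- extract_five_prime_utr(tm, genome)
  slice <- chartr("T", "U", substr(genome[[1]], 249, 260))
  rc <- paste(rev(strsplit(chartr("ACGU", "UGCA", slice), "")[[1]]),
              collapse = "")
  expect_equal(um, rc)
  # no 5'UTR -> empty string, not an error
  expect_equal(extract_five_prime_utr(toy_tx(utr = 0), genome), "")
  # missing chromosome errors
  expect_error(extract_five_prime_utr(toy_tx(chrom = "chrX"), genome),
               "chromosome")
  # length always equals cds_start_tx
  for (u in c(1L, 7L, 55L))
    expect_equal(nchar(extract_five_prime_utr(toy_tx(utr = u), genome)), u)
})

test_that("a transcript built from the printed ARF6wt insert returns it minus the start codon", {
  arf6 <- printed_utrs()[["ARF6wt"]]
  L <- nchar(arf6)
  genome <- stats::setNames(chartr("U", "T", arf6), "ins")
  t <- transcript_model("r1", "ARF6", "ins", "+", rbind(c(0, L)),
                        cds_start_tx = L - 3L)
  expect_equal(extract_five_prime_utr(t, genome), substr(arf6, 1, L - 3))
})

test_that("BED12 round trip preserves structure and UTR sequences", {
  genome <- toy_genome(600)
  txs <- list(
    transcript_model("t1", "gA", "chr1", "+", rbind(c(10, 60), c(90, 150)), 70),
    transcript_model("t2", "gA", "chr1", "+", rbind(c(30, 150)), 40),
    transcript_model("t3", "gB", "chr1", "-", rbind(c(300, 420)), 25))
  db <- transcript_db(txs)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(db, f)
  db2 <- load_annotation(f)
  for (id in names(db$transcripts)) {
    expect_identical(db2$transcripts[[id]]$exons, db$transcripts[[id]]$exons)
    expect_equal(db2$transcripts[[id]]$cds_start_tx,
                 db$transcripts[[id]]$cds_start_tx)
    expect_equal(extract_five_prime_utr(db2$transcripts[[id]], genome),
                 extract_five_prime_utr(db$transcripts[[id]], genome))
  }
  expect_equal(db2$canonical, db$canonical)
})

test_that("GTF loading computes the coding start and rejects stray CDS", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t11\t50\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tx\texon\t71\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tx\tCDS\t36\t50\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tx\tCDS\t71\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";'),
    gtf)
  db <- load_annotation(gtf)
  expect_equal(db$transcripts$tx1$cds_start_tx, 25L)
  expect_equal(db$transcripts$tx1$cds_len, 45L)
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t11\t50\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tx\tCDS\t60\t80\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";'),
    bad)
  expect_error(load_annotation(bad), "CDS outside exons")
})

test_that("variant 5'UTR detection covers alternative TSS and UTR introns", {
  one <- transcript_model("t1", "g", "c", "+", rbind(c(0, 300)), 80)
  expect_false(detect_utr_variants(list(one))$is_variant)
  # two transcripts whose TSS differ by 50 nt
  two <- transcript_model("t2", "g", "c", "+", rbind(c(50, 300)), 30)
  v <- detect_utr_variants(list(one, two))
  expect_true(v$has_alt_tss)
  expect_true(v$is_variant)
  # junction at transcript position 40 with coding start 120
  spl <- transcript_model("t3", "g", "c", "+", rbind(c(0, 40), c(100, 300)), 120)
  v2 <- detect_utr_variants(list(spl))
  expect_true(v2$has_utr_intron)
  expect_false(v2$has_alt_tss)
  # junction downstream of the coding start is not a 5'UTR intron
  spl2 <- transcript_model("t4", "g", "c", "+", rbind(c(0, 40), c(100, 300)), 20)
  expect_false(detect_utr_variants(list(spl2))$has_utr_intron)
  # permutation invariance
  a <- detect_utr_variants(list(one, two, spl))
  b <- detect_utr_variants(list(spl, one, two))
  expect_identical(a[c("has_alt_tss", "has_utr_intron", "is_variant")],
                   b[c("has_alt_tss", "has_utr_intron", "is_variant")])
  # minus-strand TSS is the rightmost base
  m1 <- transcript_model("m1", "gm", "c", "-", rbind(c(0, 300)), 10)
  m2 <- transcript_model("m2", "gm", "c", "-", rbind(c(0, 250)), 10)
  expect_true(detect_utr_variants(list(m1, m2))$has_alt_tss)
})
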