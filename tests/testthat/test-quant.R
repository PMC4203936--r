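mkreads <- function(chrom, start, length, strand, n_alignments = 1L) {
  data.frame(chrom = chrom, start = start, length = length, strand = strand,
             n_alignments = n_alignments, stringsAsFactors = FALSE)
}

test_that("P-site assignment follows the 5'-end offset rule", {
  r <- mkreads("c", c(1000, 1000), c(32, 32), c("+", "-"))
  expect_equal(psite_position(r), c(1012, 1019))
  expect_error(psite_position(mkreads("c", 0, 10, "+")), "offset")
  # per-length override
  off <- psite_offset_table(12, by_length = c(`28` = 11))
  expect_equal(psite_position(mkreads("c", 100, 28, "+"), off), 111)
})

test_that("midpoint assignment floors toward the 5' end", {
  expect_equal(midpoint_position(mkreads("c", 100, 31, "+")), 115)
  expect_equal(midpoint_position(mkreads("c", 100, 32, "+")), 115)
  expect_equal(midpoint_position(mkreads("c", 7, 1, "+")), 7)
  # minus strand mirrors from the 5' end (rightmost base)
  expect_equal(midpoint_position(mkreads("c", 100, 31, "-")), 115)
  expect_equal(midpoint_position(mkreads("c", 100, 32, "-")), 116)
})

test_that("RPKM arithmetic and error contracts", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(50, 2500, 2e7), 1)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "total")
  # invariant under duplicating reads and doubling the library
  expect_equal(rpkm(20, 1500, 2e6), rpkm(10, 1500, 1e6))
})

test_that("read length histogram is exact", {
  r <- mkreads("c", 1:3, c(30, 32, 34), "+")
  h <- read_length_histogram(r)
  expect_equal(h$mean, 32)
  expect_equal(h$histogram, c(`30` = 1L, `32` = 1L, `34` = 1L))
  expect_error(read_length_histogram(r[0, ]), "no reads")
})

test_that("count profiles apply uniqueness, overlap and strand rules", {
  db <- transcript_db(list(toy_tx(start = 100, len = 200, utr = 40)))
  inside <- 100 + 40 + 5  # P-site target inside the transcript
  r <- mkreads("chr1", rep(inside - 12, 5), 30, "+")
  prof <- build_count_profile(r, db, mode = "rf")
  expect_equal(sum(prof$tx1$counts), 5)
  expect_equal(length(prof$tx1$counts), 200)
  # non-unique reads contribute nothing
  r2 <- mkreads("chr1", inside - 12, 30, "+", n_alignments = 3L)
  expect_equal(sum(build_count_profile(r2, db, "rf")$tx1$counts), 0)
  # antisense reads are not assigned
  r3 <- mkreads("chr1", inside - 12, 30, "-")
  p3 <- build_count_profile(r3, db, "rf")
  expect_equal(sum(p3$tx1$counts), 0)
  # unknown chromosome warns and skips
  expect_warning(p4 <- build_count_profile(mkreads("chrZ", 50, 30, "+"), db, "rf"),
                 "unknown")
  expect_equal(attr(p4, "log")[["n_skipped"]], 1L)
})

test_that("positions shared by two canonical transcripts are masked", {
  # two single-transcript genes overlapping 100 nt
  t1 <- transcript_model("t1", "g1", "chr1", "+", rbind(c(0, 300)), 50)
  t2 <- transcript_model("t2", "g2", "chr1", "+", rbind(c(200, 500)), 50)
  db <- transcript_db(list(t1, t2))
  overlap_pos <- 250L
  r <- mkreads("chr1", overlap_pos - 12L, 30, "+")
  prof <- build_count_profile(r, db, mode = "rf")
  expect_equal(sum(prof$t1$counts), 0)
  expect_equal(sum(prof$t2$counts), 0)
  expect_equal(attr(prof, "log")[["n_masked"]], 1L)
  # the mask marks the shared span in both profiles
  expect_true(all(prof$t1$excluded_mask[201:300]))
  expect_true(all(prof$t2$excluded_mask[1:100]))
  expect_false(any(prof$t1$excluded_mask[1:200]))
  # effective length shrinks accordingly
  q <- quantify_genes(prof, prof, db)
  expect_equal(q$effective_length, c(200L, 200L))
  q2 <- quantify_genes(prof, prof, db, length_mode = "full")
  expect_equal(q2$effective_length, c(300L, 300L))
  # with masking disabled the read is counted
  p2 <- build_count_profile(r, db, mode = "rf", mask = FALSE)
  expect_equal(sum(p2$t1$counts) + sum(p2$t2$counts), 1)
})

test_that("reads are conserved across counting outcomes", {
  t1 <- transcript_model("t1", "g1", "chr1", "+", rbind(c(0, 300)), 50)
  t2 <- transcript_model("t2", "g2", "chr1", "+", rbind(c(200, 500)), 50)
  db <- transcript_db(list(t1, t2))
  withr::with_seed(8, {
    r <- mkreads("chr1", sample(0:600, 400, TRUE), 30, "+",
                 n_alignments = sample(c(1L, 1L, 1L, 4L), 400, TRUE))
  })
  prof <- suppressWarnings(build_count_profile(r, db, mode = "rf"))
  lg <- attr(prof, "log")
  expect_equal(lg[["n_input"]],
               lg[["n_nonunique"]] + lg[["n_skipped"]] + lg[["n_masked"]] +
                 lg[["n_counted"]])
  expect_equal(sum(vapply(prof, function(p) sum(p$counts), 0L)),
               lg[["n_counted"]])
})

test_that("counts are invariant under mirroring the locus to the other strand", {
  L <- 1000L
  t1 <- transcript_model("t1", "g1", "chr1", "+", rbind(c(100, 400)), 60)
  db1 <- transcript_db(list(t1))
  withr::with_seed(21, {
    pos <- sample(160:360, 200, TRUE)
  })
  reads_plus <- mkreads("chr1", pos - 12L, 30, "+")
  # mirrored layout: same transcript on the minus strand
  t2 <- transcript_model("t1", "g1", "chr1", "-",
                         rbind(c(L - 400, L - 100)), 60)
  db2 <- transcript_db(list(t2))
  five_prime <- reads_plus$start  # 5' end of a plus-strand read
  mstart <- L - 1L - (five_prime + 30L - 1L)
  reads_minus <- mkreads("chr1", mstart, 30, "-")
  p1 <- build_count_profile(reads_plus, db1, "rf")
  p2 <- build_count_profile(reads_minus, db2, "rf")
  expect_equal(p1$t1$counts, p2$t1$counts)
})

test_that("SAM and BED round trips preserve the read table", {
  r <- mkreads("chr1", c(10, 50, 90), c(32, 28, 30), c("+", "-", "+"),
               n_alignments = c(1L, 2L, 1L))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(r, sam, c(chr1 = 1000L))
  r2 <- read_alignments(sam)
  expect_equal(r2[order(r2$start), names(r)], r[order(r$start), ],
               ignore_attr = TRUE)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tread\t%d\t%s", r$start, r$start + r$length,
                     r$n_alignments, r$strand), bed)
  r3 <- read_alignments(bed)
  expect_equal(r3[, names(r)], r, ignore_attr = TRUE)
})
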