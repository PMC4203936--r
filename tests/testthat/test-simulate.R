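test_that("configuration validates fractions and sizes", {
  expect_error(simulation_config(frac_sensitive = 0.8, frac_resistant = 0.4),
               "fractions")
  expect_error(simulation_config(library_size = 0), "library_size")
  cfg <- simulation_config(n_genes = 10L)
  expect_equal(cfg$library_size, 25000L)
})

test_that("ground truth respects the configured class fractions", {
  cfg <- simulation_config(n_genes = 100, frac_sensitive = 0, seed = 3)
  sim <- simulate_transcriptome(cfg)
  expect_equal(sum(sim$truth$true_class == "decreased"), 0)
  expect_true(all(sim$truth$true_log2_te_shift[
    sim$truth$true_class == "insensitive"] == 0))
  cfg2 <- simulation_config(n_genes = 400, seed = 3)
  sim2 <- simulate_transcriptome(cfg2)
  frac <- mean(sim2$truth$true_class == "decreased")
  expect_lt(abs(frac - 0.075), 3 * sqrt(0.075 * 0.925 / 400))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 60, seed = 9)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$utrs, b$utrs)
  expect_identical(a$truth, b$truth)
  ca <- simulate_counts(a); cb <- simulate_counts(b)
  expect_identical(ca$counts, cb$counts)
  ra <- emit_alignments(a, ca$counts[, 1], assay = "rf")
  rb <- emit_alignments(b, cb$counts[, 1], assay = "rf")
  expect_identical(ra, rb)
  # and the FASTA bytes round-trip identically
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(cfg, dir = d1)
  simulate_experiment(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "utrs.fa")),
                   readLines(file.path(d2, "utrs.fa")))
})

test_that("sensitive genes get longer 5'UTRs than insensitive genes", {
  sim <- simulate_transcriptome(simulation_config(n_genes = 2000, seed = 7))
  lsens <- sim$truth$utr_length[sim$truth$true_class == "decreased"]
  lins <- sim$truth$utr_length[sim$truth$true_class == "insensitive"]
  mw <- mann_whitney_u(lsens, lins, mode = "normal")
  expect_gt(mean(lsens), mean(lins))
  expect_lt(mw$p_two_sided, 1e-6)
})

test_that("count means obey the effect model", {
  # unshifted genes: expected treated/control footprint ratio is 1;
  # mRNA means are identical across conditions
  cfg <- simulation_config(n_genes = 600, frac_sensitive = 0,
                           frac_resistant = 0, nb_dispersion = 0, seed = 13)
  cc <- simulate_counts(simulate_transcriptome(cfg))
  rf_c <- rowSums(cc$counts[, cc$libraries$assay == "rf" &
                              cc$libraries$condition == "control"])
  rf_t <- rowSums(cc$counts[, cc$libraries$assay == "rf" &
                              cc$libraries$condition == "treated"])
  expect_lt(abs(sum(rf_t) / sum(rf_c) - 1), 0.02)
  m_c <- rowSums(cc$counts[, cc$libraries$assay == "mrna" &
                             cc$libraries$condition == "control"])
  m_t <- rowSums(cc$counts[, cc$libraries$assay == "mrna" &
                             cc$libraries$condition == "treated"])
  expect_lt(abs(sum(m_t) / sum(m_c) - 1), 0.02)
  # a -2 log2 shift produces a footprint ratio near 0.25 with mRNA unchanged
  cfg2 <- simulation_config(n_genes = 600, frac_sensitive = 0.5,
                            frac_resistant = 0, effect_mean_sensitive = -2,
                            effect_sd_sensitive = 0, nb_dispersion = 0,
                            seed = 14)
  sim2 <- simulate_transcriptome(cfg2)
  cc2 <- simulate_counts(sim2)
  sens <- sim2$truth$true_class == "decreased"
  rf_c2 <- rowSums(cc2$counts[, cc2$libraries$assay == "rf" &
                                cc2$libraries$condition == "control"])
  rf_t2 <- rowSums(cc2$counts[, cc2$libraries$assay == "rf" &
                                cc2$libraries$condition == "treated"])
  expect_lt(abs(sum(rf_t2[sens]) / sum(rf_c2[sens]) - 0.25), 0.01)
  m_c2 <- rowSums(cc2$counts[, cc2$libraries$assay == "mrna" &
                               cc2$libraries$condition == "control"])
  m_t2 <- rowSums(cc2$counts[, cc2$libraries$assay == "mrna" &
                               cc2$libraries$condition == "treated"])
  expect_lt(abs(sum(m_t2[sens]) / sum(m_c2[sens]) - 1), 0.02)
})

test_that("near-zero dispersion approaches Poisson scatter", {
  cfg <- simulation_config(n_genes = 500, frac_sensitive = 0,
                           frac_resistant = 0, nb_dispersion = 0, seed = 5)
  cc <- simulate_counts(simulate_transcriptome(cfg))
  tot <- colSums(cc$counts)
  # each library total is within Poisson error of the configured size
  expect_true(all(abs(tot - cfg$library_size) <
                    5 * sqrt(cfg$library_size)))
})

test_that("emitted footprint lengths centre on 32 nt", {
  cfg <- simulation_config(n_genes = 40, library_size = 12000, seed = 6)
  sim <- simulate_transcriptome(cfg)
  cc <- simulate_counts(sim)
  reads <- emit_alignments(sim, cc$counts[, 1], assay = "rf")
  expect_gt(nrow(reads), 10000)
  h <- read_length_histogram(reads)
  expect_lt(abs(h$mean - 32), 0.5)
  expect_true(all(reads$length >= 26 & reads$length <= 36))
})

test_that("emitted reads round-trip through counting exactly", {
  cfg <- simulation_config(n_genes = 30, library_size = 6000, seed = 17)
  sim <- simulate_transcriptome(cfg)
  cc <- simulate_counts(sim)
  for (lib in c(1L, 3L)) {  # one footprint, one mRNA library
    assay <- cc$libraries$assay[lib]
    reads <- emit_alignments(sim, cc$counts[, lib], assay = assay)
    prof <- build_count_profile(reads, sim$db, mode = assay, mask = FALSE)
    rec <- vapply(prof, function(p) sum(p$counts), 0L)
    gene_of <- sub("\\.t1$", "", names(rec))
    expect_equal(unname(rec), unname(cc$counts[gene_of, lib]))
    lg <- attr(prof, "log")
    expect_equal(lg[["n_input"]], lg[["n_counted"]])
  }
})

test_that("pipeline TE converges to the generating TE at deep coverage", {
  cfg <- simulation_config(n_genes = 40, frac_sensitive = 0,
                           frac_resistant = 0, nb_dispersion = 0,
                           library_size = 4e6, seed = 19)
  sim <- simulate_transcriptome(cfg)
  cc <- simulate_counts(sim)
  lens <- sim$truth$utr_length + sim$truth$cds_length
  res <- te_analysis(cc$counts, lens, cc$libraries, min_count = 1)
  # pipeline TE is defined up to a library-size scale: compare shapes after
  # normalizing both to geometric mean 1
  obs <- res$te_control / exp(mean(log(res$te_control)))
  ref <- cc$true_te / exp(mean(log(cc$true_te)))
  expect_lt(max(abs(obs / unname(ref) - 1)), 0.05)
})

test_that("the sensitive pool carries the 5'UTR signature end to end", {
  sim <- simulate_transcriptome(simulation_config(n_genes = 1500, seed = 23))
  tr <- sim$truth
  dec <- tr$true_class == "decreased"
  ins <- tr$true_class == "insensitive"
  gc <- vapply(sim$utrs, gc_content, 0)
  expect_lt(mann_whitney_u(tr$utr_length[dec], tr$utr_length[ins],
                           mode = "normal")$p_two_sided, 1e-4)
  expect_lt(mann_whitney_u(gc[dec], gc[ins], mode = "normal")$p_two_sided,
            1e-4)
  expect_lt(mean(gc[dec]), mean(gc[ins]))
  # variant flags concentrate in the sensitive pool
  expect_gt(mean(tr$is_variant[dec]), mean(tr$is_variant[ins]))
  # variant genes have two transcripts with distinct TSS
  vg <- tr$gene_id[tr$is_variant][1]
  expect_true(detect_utr_variants(
    sim$db$transcripts[sim$db$genes[[vg]]])$has_alt_tss)
})
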