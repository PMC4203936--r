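#' Configuration for a synthetic ribosome-profiling experiment
#'
#' Defines the study conditions the generator emulates: two conditions
#' (control and an eIF4A-inhibitor treatment), footprint and fragmented-mRNA
#' libraries with replicates, a minority of genes with reduced TE in
#' treatment and unchanged mRNA abundance, and TE reduction enriched in
#' long, structured, lower-GC 5'UTRs.
#'
#' Defaults: treatment-sensitive genes (`frac_sensitive`) draw their log2 TE
#' shift from Normal(-2.5, 0.5), resistant genes (`frac_resistant`) from
#' Normal(+1.8, 0.4), all others shift 0.  Counts are negative binomial with
#' a single dispersion (`nb_dispersion`, Poisson in the limit 0).  Footprint
#' lengths are Normal(32, 1.5) truncated to \[26, 36\].  5'UTR pools differ
#' by sensitivity class: sensitive genes get long (mean ~490 nt, capped at
#' `utr_max`), stem-enriched, lower-GC UTRs; insensitive genes short (~224
#' nt) higher-GC UTRs; resistant genes the shortest (~172 nt) and most
#' GC-rich.
#'
#' @param n_genes number of genes.
#' @param frac_sensitive,frac_resistant fractions in \[0, 1\], sum <= 1.
#' @param effect_mean_sensitive,effect_sd_sensitive log2-shift distribution
#'   of sensitive genes.
#' @param effect_mean_resistant,effect_sd_resistant likewise for resistant
#'   genes.
#' @param library_size reads per library (default `2500 * n_genes`,
#'   echoing the tens of millions of mapped reads per library over ~17,700
#'   transcripts typical of the emulated experimental design).
#' @param nb_dispersion negative-binomial dispersion (0 -> Poisson).
#' @param n_replicates replicates per condition (default 2).
#' @param footprint_mean,footprint_sd,footprint_min,footprint_max footprint
#'   read-length model.
#' @param mrna_read_length mRNA-seq read length (nt).
#' @param psite_offset P-site offset used when emitting footprint reads.
#' @param utr_max cap on simulated 5'UTR length (nt).
#' @param seed integer seed; the same seed gives byte-identical outputs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              frac_sensitive = 0.075,
                              frac_resistant = 0.025,
                              effect_mean_sensitive = -2.5,
                              effect_sd_sensitive = 0.5,
                              effect_mean_resistant = 1.8,
                              effect_sd_resistant = 0.4,
                              library_size = NULL,
                              nb_dispersion = 0.05,
                              n_replicates = 2L,
                              footprint_mean = 32, footprint_sd = 1.5,
                              footprint_min = 26L, footprint_max = 36L,
                              mrna_read_length = 50L,
                              psite_offset = 12L,
                              utr_max = 600L,
                              seed = 1L) {
  if (frac_sensitive < 0 || frac_resistant < 0 ||
      frac_sensitive + frac_resistant > 1)
    stop("config error: fractions must be in [0,1] and sum <= 1")
  if (is.null(library_size)) library_size <- 2500L * n_genes
  if (library_size <= 0) stop("config error: library_size must be > 0")
  structure(as.list(environment()), class = "simulation_config")
}

# random sequence at a GC target
rand_seq <- function(n, gc) {
  sample(c("A", "C", "G", "U"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# plant GC-rich stems: a donor segment and its reverse complement written a
# short spacer apart, so localized structure coincides with GC clusters
plant_stems <- function(ch, n_stems) {
  L <- length(ch)
  for (k in seq_len(n_stems)) {
    sl <- sample(12:20, 1L)
    sp <- sample(4:8, 1L)
    span <- 2L * sl + sp
    if (L < span + 2L) break
    a <- sample.int(L - span, 1L)
    stem <- rand_seq(sl, gc = 0.85)
    ch[a:(a + sl - 1L)] <- stem
    rc <- rev(chartr("ACGU", "UGCA", stem))
    ch[(a + sl + sp):(a + span - 1L)] <- rc
  }
  ch
}

sim_utr_seq <- function(len, gc, utr_class) {
  ch <- rand_seq(len, gc)
  if (utr_class == "structured")
    ch <- plant_stems(ch, n_stems = max(1L, round(len / 150)))
  if (utr_class == "TOP") {
    run <- sample(5:12, 1L)
    ch[seq_len(min(len, run + 1L))] <-
      c("C", sample(c("C", "U"), run, replace = TRUE))[seq_len(min(len, run + 1L))]
  }
  paste(ch, collapse = "")
}

sim_cds_seq <- function(len) {
  # len is a multiple of 3 and >= 9; internal codons avoid stop codons
  n_inner <- len / 3L - 2L
  codons <- character(n_inner)
  for (i in seq_len(n_inner)) {
    repeat {
      cd <- paste(rand_seq(3L, 0.5), collapse = "")
      if (!cd %in% c("UAA", "UAG", "UGA")) break
    }
    codons[i] <- cd
  }
  paste0("AUG", paste(codons, collapse = ""), "UAA")
}

#' Simulate a transcriptome with class-structured 5'UTRs
#'
#' Builds a synthetic genome and transcript annotation in which each gene's
#' 5'UTR reflects its ground-truth sensitivity class: sensitive genes
#' preferentially receive long, stem-enriched, lower-GC UTRs, mirroring the
#' signature of eIF4A-dependent transcripts; a configurable fraction of
#' genes additionally get a second transcript with a shifted TSS (variant
#' 5'UTR).  Genes alternate between the two strands of one synthetic
#' chromosome and do not overlap.
#'
#' @param config a [simulation_config()].
#' @return list with `db` (a `transcript_db`), `genome` (named DNA string),
#'   `utrs` (named RNA vector, canonical 5'UTR per gene), `truth`
#'   (data.frame `gene_id, true_class, true_log2_te_shift, utr_class,
#'   is_variant`) and `config`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    classes <- sample(c("decreased", "increased", "insensitive"), n,
                      replace = TRUE,
                      prob = c(config$frac_sensitive, config$frac_resistant,
                               1 - config$frac_sensitive - config$frac_resistant))
    shift <- numeric(n)
    shift[classes == "decreased"] <- stats::rnorm(
      sum(classes == "decreased"),
      config$effect_mean_sensitive, config$effect_sd_sensitive)
    shift[classes == "increased"] <- stats::rnorm(
      sum(classes == "increased"),
      config$effect_mean_resistant, config$effect_sd_resistant)

    # 5'UTR class mixing and pool-level length/GC targets per
    # sensitivity class (structured/variant enrichment in the sensitive pool)
    mix <- rbind(decreased   = c(structured = 0.50, variant = 0.30,
                                 TOP = 0.02, plain = 0.18),
                 insensitive = c(structured = 0.08, variant = 0.005,
                                 TOP = 0.04, plain = 0.875),
                 increased   = c(structured = 0.08, variant = 0,
                                 TOP = 0.02, plain = 0.90))
    len_mean <- c(decreased = 490, insensitive = 224, increased = 172)
    gc_mean <- c(decreased = 0.598, insensitive = 0.669, increased = 0.712)

    utr_class <- vapply(classes, function(cl)
      sample(colnames(mix), 1L, prob = mix[cl, ]), "")
    sdlog <- 0.6
    utr_len <- pmin(config$utr_max, pmax(30L, round(stats::rlnorm(
      n, meanlog = log(len_mean[classes]) - sdlog^2 / 2, sdlog = sdlog))))
    utr_gc <- pmin(0.9, pmax(0.3, stats::rnorm(n, gc_mean[classes], 0.04)))
    cds_len <- round(stats::rlnorm(n, log(900), 0.25))
    cds_len <- pmax(300L, cds_len - cds_len %% 3L)

    gene_id <- sprintf("gene%04d", seq_len(n))
    utrs <- character(n)
    txs <- list()
    genome_parts <- character(0)
    cursor <- 0L
    for (g in seq_len(n)) {
      utrs[g] <- sim_utr_seq(utr_len[g], utr_gc[g], utr_class[g])
      tx_seq <- paste0(utrs[g], sim_cds_seq(cds_len[g]))
      L <- nchar(tx_seq)
      strand <- if (g %% 2L == 0L) "-" else "+"
      gseq <- if (strand == "+") tx_seq else revcomp_rna(tx_seq)
      spacer <- paste(rand_seq(100L, 0.5), collapse = "")
      genome_parts <- c(genome_parts, gseq, spacer)
      start <- cursor
      cursor <- cursor + L + 100L
      tid <- paste0(gene_id[g], ".t1")
      txs[[length(txs) + 1L]] <- transcript_model(
        tid, gene_id[g], "sim1", strand,
        cbind(start, start + L), cds_start_tx = utr_len[g],
        cds_len = cds_len[g])
      if (utr_class[g] == "variant") {
        # second transcript from a downstream TSS (shorter 5'UTR)
        d <- min(utr_len[g] - 10L, sample(30:80, 1L))
        ex <- if (strand == "+") cbind(start + d, start + L)
              else cbind(start, start + L - d)
        txs[[length(txs) + 1L]] <- transcript_model(
          paste0(gene_id[g], ".t2"), gene_id[g], "sim1", strand, ex,
          cds_start_tx = utr_len[g] - d, cds_len = cds_len[g])
      }
    }
    genome <- chartr("U", "T", paste(genome_parts, collapse = ""))
    names(genome) <- "sim1"
    truth <- data.frame(gene_id = gene_id, true_class = classes,
                        true_log2_te_shift = shift, utr_class = utr_class,
                        is_variant = utr_class == "variant",
                        utr_length = utr_len, cds_length = cds_len,
                        row.names = NULL)
    list(db = transcript_db(txs), genome = genome,
         utrs = stats::setNames(utrs, gene_id), truth = truth,
         config = config)
  })
}

#' Simulate per-library gene counts
#'
#' Negative-binomial counts for footprint and mRNA libraries of both
#' conditions.  Per gene, mRNA means are proportional to abundance x
#' transcript length and identical across conditions (treatment leaves mRNA
#' levels untouched); footprint means are proportional to abundance x CDS
#' length x baseline TE, multiplied in the treated condition by
#' `2^true_log2_te_shift`.  Expected counts are scaled so a control library
#' totals `library_size`; treated footprint libraries shrink by the summed
#' TE loss (no renormalization, so an unshifted gene has the same expected
#' footprint count in both conditions).
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param config defaults to `sim$config`.
#' @return list with `counts` (matrix genes x libraries) and `libraries`
#'   (data.frame `library, condition, assay, replicate`).
#' @export
simulate_counts <- function(sim, config = sim$config) {
  with_seed(config$seed + 1L, {
    truth <- sim$truth
    n <- nrow(truth)
    abundance <- stats::rlnorm(n, 0, 1)
    te_base <- stats::rlnorm(n, 0, 0.5)
    tx_len <- truth$utr_length + truth$cds_length
    w_mrna <- abundance * tx_len
    w_rf_ctrl <- abundance * truth$cds_length * te_base
    w_rf_trt <- w_rf_ctrl * 2^truth$true_log2_te_shift
    libs <- expand.grid(replicate = seq_len(config$n_replicates),
                        assay = c("rf", "mrna"),
                        condition = c("control", "treated"),
                        stringsAsFactors = FALSE)
    libs$library <- paste(libs$condition, libs$assay, libs$replicate,
                          sep = "_")
    draw <- function(mu) {
      if (config$nb_dispersion > 0)
        stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      else stats::rpois(n, mu)
    }
    counts <- sapply(seq_len(nrow(libs)), function(k) {
      w <- switch(libs$assay[k],
                  mrna = w_mrna,
                  rf = if (libs$condition[k] == "treated") w_rf_trt
                       else w_rf_ctrl)
      # scale factor anchored on the control-condition weights
      w0 <- if (libs$assay[k] == "mrna") w_mrna else w_rf_ctrl
      draw(config$library_size * w / sum(w0))
    })
    rownames(counts) <- truth$gene_id
    colnames(counts) <- libs$library
    list(counts = counts,
         libraries = libs[, c("library", "condition", "assay", "replicate")],
         # generating quantities, for parameter-recovery checks: the TE the
         # RPKM pipeline estimates is proportional to te_base * cds/tx length
         abundance = stats::setNames(abundance, truth$gene_id),
         true_te = stats::setNames(te_base * truth$cds_length / tx_len,
                                   truth$gene_id))
  })
}

#' Emit aligned reads realizing simulated counts
#'
#' Places one read per count on the synthetic genome: footprint reads are
#' positioned so that their P-site (at `config$psite_offset` from the 5'
#' end) falls uniformly inside the CDS; mRNA reads are uniform over the
#' transcript.  All reads are unique and strand-matched to their
#' transcript.  Running the emitted reads back through
#' [build_count_profile()] with masking disabled recovers the input counts
#' exactly.
#'
#' @param sim a [simulate_transcriptome()] result.
#' @param counts one column of [simulate_counts()] counts (named by gene) or
#'   a named vector.
#' @param assay `"rf"` or `"mrna"`.
#' @param config defaults to `sim$config`.
#' @param seed per-library seed (so each library gets distinct reads).
#' @return read data.frame (see [read_alignments()]).
#' @export
emit_alignments <- function(sim, counts, assay = c("rf", "mrna"),
                            config = sim$config, seed = config$seed + 2L) {
  assay <- match.arg(assay)
  with_seed(seed, {
    cm <- canonical_models(sim$db)
    gene_of <- vapply(cm, function(t) t$gene_id, "")
    out <- vector("list", length(cm))
    for (k in seq_along(cm)) {
      t <- cm[[k]]
      nk <- counts[[gene_of[k]]]
      if (is.na(nk) || nk < 1L) next
      if (assay == "rf") {
        len <- pmin(config$footprint_max, pmax(config$footprint_min,
          round(stats::rnorm(nk, config$footprint_mean, config$footprint_sd))))
        off <- config$psite_offset
        # P-site uniform in the CDS, read fully inside the transcript
        lo <- pmax(t$cds_start_tx, off)
        hi <- pmin(t$length - (len - off), t$length) - 1L
        p <- lo + floor(stats::runif(nk) * (hi - lo + 1L))
        five <- p - off
      } else {
        len <- rep(min(config$mrna_read_length, t$length), nk)
        five <- floor(stats::runif(nk) * (t$length - len + 1L))
      }
      g5 <- tx_to_genomic(t, five)
      start <- if (t$strand == "+") g5 else g5 - (len - 1L)
      out[[k]] <- data.frame(chrom = t$chrom, start = start, length = len,
                             strand = t$strand, n_alignments = 1L,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out[!vapply(out, is.null, TRUE)])
  })
}

#' Run a full synthetic experiment
#'
#' Convenience wrapper: transcriptome + counts, optionally writing the
#' annotation (BED12), genome and 5'UTRs (FASTA), reads (SAM) and ground
#' truth (TSV) to a directory in the pipeline's input dialects.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @param write_reads also emit SAM files per library (can be large).
#' @return list with `sim`, `counts`, `libraries`.
#' @export
simulate_experiment <- function(config = simulation_config(), dir = NULL,
                                write_reads = FALSE) {
  sim <- simulate_transcriptome(config)
  cc <- simulate_counts(sim, config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bed12(sim$db, file.path(dir, "annotation.bed"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genome), file.path(dir, "genome.fa"))
    Biostrings::writeXStringSet(
      Biostrings::RNAStringSet(sim$utrs), file.path(dir, "utrs.fa"))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_reads) {
      cl <- stats::setNames(nchar(sim$genome), names(sim$genome))
      for (k in seq_len(nrow(cc$libraries))) {
        reads <- emit_alignments(sim, cc$counts[, k],
                                 assay = cc$libraries$assay[k],
                                 seed = config$seed + 2L + k)
        write_sam(reads, file.path(dir, paste0(cc$libraries$library[k], ".sam")),
                  cl)
      }
    }
  }
  c(list(sim = sim), cc)
}
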