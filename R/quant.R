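#' Aligned reads as a data frame
#'
#' The quantification functions consume aligned reads in a plain data frame
#' with columns `chrom`, `start` (0-based leftmost genomic base), `length`
#' (nt), `strand` (`+`/`-`) and `n_alignments` (reported alignment count; a
#' read is unique iff `n_alignments == 1`).
#'
#' @param path a SAM/BAM file (the `NH` tag supplies `n_alignments`, default
#'   1) or a 6-column BED file (`chrom start end name score strand`, with the
#'   score column read as the alignment count; 0/NA -> 1).
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return data.frame of reads.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam", "bed")) ext else
      stop("cannot guess alignment format from extension: ", path)
  }
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("need 6-column BED: ", path)
    score <- suppressWarnings(as.integer(df[[5L]]))
    score[is.na(score) | score < 1L] <- 1L
    return(data.frame(chrom = as.character(df[[1L]]), start = df[[2L]],
                      length = df[[3L]] - df[[2L]],
                      strand = as.character(df[[6L]]),
                      n_alignments = score, stringsAsFactors = FALSE))
  }
  bam <- if (format == "sam")
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  else path
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(1L, length(x$pos))
  nh[is.na(nh)] <- 1L
  data.frame(chrom = as.character(x$rname), start = x$pos - 1L,
             length = x$qwidth, strand = as.character(x$strand),
             n_alignments = nh, stringsAsFactors = FALSE)
}

#' Write reads to SAM
#'
#' Minimal single-end SAM writer for simulated or filtered reads; emits an
#' `NH` tag with the alignment count and an all-`N` query sequence of the
#' correct length so that read widths survive a round trip.
#'
#' @param reads read data.frame (see [read_alignments()]).
#' @param path output `.sam` file.
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @export
write_sam <- function(reads, path, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in names(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, chrom_lengths[[ch]]), con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    lines <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                     seq_len(nrow(reads)), flag, reads$chrom,
                     reads$start + 1L, reads$length,
                     strrep("N", reads$length), reads$n_alignments)
    writeLines(lines, con)
  }
  invisible(path)
}

#' P-site offset table
#'
#' @param default offset (nt from the read 5' end) used for lengths not
#'   listed explicitly.
#' @param by_length optional named vector of per-length offsets.
#' @return named list used by [psite_position()].
#' @export
psite_offset_table <- function(default = 12L, by_length = NULL) {
  list(default = as.integer(default),
       by_length = if (!is.null(by_length))
         stats::setNames(as.integer(by_length), names(by_length)))
}

#' Genomic position of the ribosomal P-site of footprint reads
#'
#' Footprint counts are assigned to the genomic base occupying the ribosome
#' P-site, a fixed offset from the read's 5'-terminal base: `start + offset`
#' on the plus strand, `(start + length - 1) - offset` on the minus strand.
#'
#' @param reads read data.frame.
#' @param offsets a [psite_offset_table()].
#' @return integer vector of 0-based genomic positions.
#' @export
psite_position <- function(reads, offsets = psite_offset_table()) {
  off <- rep(offsets$default, nrow(reads))
  if (!is.null(offsets$by_length)) {
    hit <- match(as.character(reads$length), names(offsets$by_length))
    off[!is.na(hit)] <- offsets$by_length[hit[!is.na(hit)]]
  }
  if (any(off >= reads$length))
    stop("P-site offset >= read length for ",
         sum(off >= reads$length), " read(s)")
  ifelse(reads$strand == "+", reads$start + off,
         reads$start + reads$length - 1L - off)
}

#' Genomic position of the read midpoint
#'
#' mRNA-seq counts are assigned to the middle of each read:
#' `start + floor((length - 1) / 2)` on the plus strand, mirrored from the 5'
#' end on the minus strand (even lengths round toward the 5' end).
#'
#' @inheritParams psite_position
#' @return integer vector of 0-based genomic positions.
#' @export
midpoint_position <- function(reads) {
  half <- (reads$length - 1L) %/% 2L
  ifelse(reads$strand == "+", reads$start + half,
         reads$start + reads$length - 1L - half)
}

#' Read-length histogram
#'
#' @inheritParams psite_position
#' @return list with `histogram` (named counts by length) and `mean`.
#' @export
read_length_histogram <- function(reads) {
  if (!nrow(reads)) stop("no reads")
  tab <- table(reads$length)
  list(histogram = stats::setNames(as.integer(tab), names(tab)),
       mean = mean(reads$length))
}

# genomic positions covered by more than one canonical transcript, as a
# GRanges (strand-agnostic, matching position-level exclusion)
multi_transcript_positions <- function(db) {
  cm <- canonical_models(db)
  grl <- lapply(cm, function(t)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      t$chrom, IRanges::IRanges(t$exons[, 1] + 1L, t$exons[, 2]))))
  cov <- GenomicRanges::coverage(do.call(c, unname(grl)))
  gr <- GenomicRanges::GRanges(cov > 1L)
  gr[S4Vectors::mcols(gr)[[1L]]]
}

#' Per-transcript positional count profiles
#'
#' Converts aligned reads into per-position counts along each canonical
#' transcript, applying the positional assignment and exclusion rules:
#' non-uniquely aligned reads are discarded; footprint reads are assigned by
#' [psite_position()] and mRNA reads by [midpoint_position()]; genomic
#' positions covered by more than one canonical transcript are masked and
#' reads falling there are not counted.
#'
#' @param reads read data.frame (see [read_alignments()]).
#' @param db a `transcript_db`.
#' @param mode `"rf"` (P-site assignment) or `"mrna"` (midpoint assignment).
#' @param offsets P-site offsets, used in `"rf"` mode.
#' @param mask apply the multi-transcript position exclusion?
#' @return object of class `count_profiles`: named list (by transcript) of
#'   lists with `transcript_id`, `counts` (integer vector over transcript
#'   positions) and `excluded_mask` (logical, same length); the attribute
#'   `log` counts input, non-unique, skipped, masked and counted reads.
#' @export
build_count_profile <- function(reads, db, mode = c("rf", "mrna"),
                                offsets = psite_offset_table(), mask = TRUE) {
  mode <- match.arg(mode)
  cm <- canonical_models(db)
  n_input <- nrow(reads)
  nonuniq <- reads$n_alignments > 1L
  n_nonunique <- sum(nonuniq)
  reads <- reads[!nonuniq, , drop = FALSE]

  known <- unique(vapply(cm, function(t) t$chrom, ""))
  off_chrom <- !(reads$chrom %in% known)
  if (any(off_chrom))
    warning(sum(off_chrom), " read(s) on unknown chromosome(s), skipped")
  reads <- reads[!off_chrom, , drop = FALSE]

  pos <- if (mode == "rf") psite_position(reads, offsets)
         else midpoint_position(reads)

  excl <- if (mask) multi_transcript_positions(db) else GenomicRanges::GRanges()
  profiles <- lapply(cm, function(t) {
    m <- rep(FALSE, t$length)
    if (length(excl) > 0L) {
      sel <- excl[GenomicRanges::seqnames(excl) == t$chrom]
      if (length(sel)) {
        gpos <- unlist(lapply(seq_along(sel), function(k)
          (GenomicRanges::start(sel)[k] - 1L):(GenomicRanges::end(sel)[k] - 1L)))
        tp <- genomic_to_tx(t, gpos)
        m[tp[!is.na(tp)] + 1L] <- TRUE
      }
    }
    list(transcript_id = t$transcript_id,
         counts = integer(t$length), excluded_mask = m)
  })
  names(profiles) <- vapply(cm, function(t) t$transcript_id, "")

  n_counted <- 0L; n_masked <- 0L; n_skipped <- sum(off_chrom)
  if (nrow(reads)) {
    # assign each read position to the canonical transcript containing it
    pts <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(pos + 1L, pos + 1L),
                                  strand = reads$strand)
    exg <- do.call(c, unname(lapply(cm, function(t)
      GenomicRanges::GRanges(t$chrom,
                             IRanges::IRanges(t$exons[, 1] + 1L, t$exons[, 2]),
                             strand = t$strand,
                             transcript_id = t$transcript_id))))
    hits <- GenomicRanges::findOverlaps(pts, exg)
    tid_of <- S4Vectors::mcols(exg)$transcript_id
    qh <- S4Vectors::queryHits(hits)
    th <- tid_of[S4Vectors::subjectHits(hits)]
    # a position masked out lies in >1 transcript; count via the mask below
    first <- !duplicated(qh)
    assigned_tx <- th[first]
    assigned_read <- qh[first]
    unassigned <- setdiff(seq_len(nrow(reads)), assigned_read)
    n_skipped <- n_skipped + length(unassigned)
    for (k in seq_along(assigned_read)) {
      r <- assigned_read[k]
      t <- cm[[match(assigned_tx[k], names(profiles))]]
      tp <- genomic_to_tx(t, pos[r])
      if (profiles[[t$transcript_id]]$excluded_mask[tp + 1L]) {
        n_masked <- n_masked + 1L
      } else {
        profiles[[t$transcript_id]]$counts[tp + 1L] <-
          profiles[[t$transcript_id]]$counts[tp + 1L] + 1L
        n_counted <- n_counted + 1L
      }
    }
  }
  structure(profiles, class = "count_profiles",
            log = c(n_input = n_input, n_nonunique = n_nonunique,
                    n_skipped = n_skipped, n_masked = n_masked,
                    n_counted = n_counted))
}

#' RPKM
#'
#' Reads per kilobase of (effective) gene length per million mapped reads:
#' `count / ((effective_length_nt / 1000) * (total_mapped / 1e6))`.
#'
#' @param count read count (vectorized).
#' @param effective_length_nt length in nt, `> 0`.
#' @param total_mapped library size, `> 0`.
#' @export
rpkm <- function(count, effective_length_nt, total_mapped) {
  if (any(effective_length_nt <= 0))
    stop("undefined RPKM: effective length must be > 0")
  if (any(total_mapped <= 0))
    stop("undefined RPKM: total mapped reads must be > 0")
  count / ((effective_length_nt / 1000) * (total_mapped / 1e6))
}

#' Gene-level expression table from count profiles
#'
#' Sums per-position counts over non-excluded positions of each canonical
#' transcript and computes RPKM for the footprint and mRNA libraries.
#'
#' @param rf_profiles,mrna_profiles [build_count_profile()] results.
#' @param db the `transcript_db` the profiles were built against.
#' @param total_rf,total_mrna library sizes; default the number of counted
#'   reads in each profile set.
#' @param length_mode `"effective"` (non-excluded positions only, the
#'   default) or `"full"` (whole transcript length) for the RPKM denominator.
#' @return data.frame `gene_id, rf_count, mrna_count, effective_length,
#'   rf_rpkm, mrna_rpkm`.
#' @export
quantify_genes <- function(rf_profiles, mrna_profiles, db,
                           total_rf = NULL, total_mrna = NULL,
                           length_mode = c("effective", "full")) {
  length_mode <- match.arg(length_mode)
  if (is.null(total_rf)) total_rf <- attr(rf_profiles, "log")[["n_counted"]]
  if (is.null(total_mrna)) total_mrna <- attr(mrna_profiles, "log")[["n_counted"]]
  cm <- canonical_models(db)
  gene_id <- vapply(cm, function(t) t$gene_id, "")
  tid <- vapply(cm, function(t) t$transcript_id, "")
  eff_len <- vapply(tid, function(id) {
    p <- rf_profiles[[id]]
    if (length_mode == "full") length(p$counts) else sum(!p$excluded_mask)
  }, 0L)
  rf_count <- vapply(tid, function(id)
    sum(rf_profiles[[id]]$counts[!rf_profiles[[id]]$excluded_mask]), 0L)
  mrna_count <- vapply(tid, function(id)
    sum(mrna_profiles[[id]]$counts[!mrna_profiles[[id]]$excluded_mask]), 0L)
  data.frame(gene_id = gene_id,
             rf_count = rf_count, mrna_count = mrna_count,
             effective_length = eff_len,
             rf_rpkm = rpkm(rf_count, eff_len, max(total_rf, 1L)),
             mrna_rpkm = rpkm(mrna_count, eff_len, max(total_mrna, 1L)),
             row.names = NULL)
}
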