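#' Construct a transcript model
#'
#' The package's unit of annotation: one transcript of one gene, with its
#' genomic exon structure and the transcript-coordinate offset of the coding
#' start.  Coordinates are 0-based, half-open genomic intervals; transcript
#' coordinates run 0-based from the transcription start site (TSS) in
#' transcript orientation.  The 5'UTR is transcript positions
#' `[0, cds_start_tx)`.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame (`start`, `end`), 0-based
#'   half-open, in genomic order; must be non-overlapping.
#' @param cds_start_tx offset of the first coding base in transcript
#'   coordinates (`0` = no 5'UTR); must not exceed the transcript length.
#' @param cds_len optional CDS length in nt (used by the canonical-transcript
#'   policy); `NA` if unknown.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start_tx, cds_len = NA_integer_) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript needs >= 1 exon")
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  len <- sum(exons[, 2] - exons[, 1])
  if (cds_start_tx < 0L || cds_start_tx > len)
    stop("cds_start_tx outside transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start_tx = as.integer(cds_start_tx),
                 cds_len = as.integer(cds_len), length = as.integer(len)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s:%s %d exon(s), %d nt, 5'UTR %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$length, x$cds_start_tx))
  invisible(x)
}

# transcript-orientation cumulative exon widths; exon order 5'->3'
tx_exon_order <- function(t) {
  if (t$strand == "+") seq_len(nrow(t$exons)) else rev(seq_len(nrow(t$exons)))
}

# map transcript coordinates (0-based) to genomic coordinates (0-based)
tx_to_genomic <- function(t, pos) {
  ord <- tx_exon_order(t)
  w <- t$exons[ord, 2] - t$exons[ord, 1]
  cum <- cumsum(c(0L, w))
  if (any(pos < 0L | pos >= t$length)) stop("transcript position out of range")
  ei <- findInterval(pos, cum, rightmost.closed = FALSE)
  off <- pos - cum[ei]
  ex <- t$exons[ord[ei], , drop = FALSE]
  if (t$strand == "+") ex[, 1] + off else ex[, 2] - 1L - off
}

# map genomic coordinates to transcript coordinates; NA when outside exons
genomic_to_tx <- function(t, gpos) {
  ord <- tx_exon_order(t)
  w <- t$exons[ord, 2] - t$exons[ord, 1]
  cum <- cumsum(c(0L, w))
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_along(ord)) {
    ex <- t$exons[ord[k], ]
    inside <- gpos >= ex[1] & gpos < ex[2]
    if (!any(inside)) next
    off <- if (t$strand == "+") gpos[inside] - ex[1] else ex[2] - 1L - gpos[inside]
    out[inside] <- cum[k] + off
  }
  out
}

# genomic TSS of a transcript (0-based position of the first transcribed base)
tss_position <- function(t) {
  if (t$strand == "+") t$exons[1L, 1L] else t$exons[nrow(t$exons), 2L] - 1L
}

pick_canonical <- function(txs, policy = "longest_cds") {
  stopifnot(policy == "longest_cds")
  cds <- vapply(txs, function(t) {
    if (!is.na(t$cds_len)) t$cds_len else t$length - t$cds_start_tx
  }, 0L)
  len <- vapply(txs, function(t) t$length, 0L)
  id <- vapply(txs, function(t) t$transcript_id, "")
  id[order(-cds, -len, id)][1L]
}

#' Load transcript annotation from GTF or BED12
#'
#' Parses a transcript annotation and returns every transcript as a
#' [transcript_model()], plus one canonical transcript per gene chosen by
#' `canonical_policy` (default `"longest_cds"`: longest CDS, ties broken by
#' transcript length then lexicographic id).  All transcripts are retained
#' for variant-5'UTR detection.
#'
#' GTF files must carry `gene_id`/`transcript_id` attributes with `exon` and
#' `CDS` features.  BED12 `name` fields of the form `gene|transcript` give
#' both identifiers (a bare name is used for both); the thick range is the
#' CDS.
#'
#' @param path annotation file (`.gtf`/`.gff` or `.bed`).
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @param canonical_policy canonical-transcript selection policy.
#' @return an object of class `transcript_db`: list with `transcripts`
#'   (named list of `transcript_model`), `genes` (gene -> transcript ids) and
#'   `canonical` (gene -> canonical transcript id).
#' @export
load_annotation <- function(path, format = c("auto", "gtf", "bed12"),
                            canonical_policy = "longest_cds") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  txs <- if (format == "gtf") parse_gtf(path) else parse_bed12(path)
  transcript_db(txs, canonical_policy)
}

#' Assemble a transcript database from transcript models
#'
#' @param txs list of [transcript_model()] objects.
#' @inheritParams load_annotation
#' @return a `transcript_db`.
#' @export
transcript_db <- function(txs, canonical_policy = "longest_cds") {
  names(txs) <- vapply(txs, function(t) t$transcript_id, "")
  gene_of <- vapply(txs, function(t) t$gene_id, "")
  genes <- split(names(txs), gene_of)
  canonical <- vapply(genes, function(ids)
    pick_canonical(txs[ids], canonical_policy), "")
  structure(list(transcripts = txs, genes = genes, canonical = canonical),
            class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat(sprintf("transcript_db: %d transcript(s), %d gene(s)\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

canonical_models <- function(db) db$transcripts[unname(db$canonical)]

#' @importFrom rtracklayer import
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id))
    stop("GTF must carry gene_id and transcript_id attributes: ", path)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  txs <- list()
  for (tid in unique(md$transcript_id)) {
    sel <- md$transcript_id == tid
    sub <- gr[sel]
    ex <- sub[S4Vectors::mcols(sub)$type == "exon"]
    cds <- sub[S4Vectors::mcols(sub)$type == "CDS"]
    if (length(ex) == 0L) stop("transcript without exons: ", tid)
    exons <- cbind(start = GenomicRanges::start(ex) - 1L,
                   end = GenomicRanges::end(ex))
    t <- transcript_model(
      tid, S4Vectors::mcols(ex)$gene_id[1L],
      as.character(GenomicRanges::seqnames(ex))[1L],
      as.character(GenomicRanges::strand(ex))[1L],
      exons, cds_start_tx = 0L)
    if (length(cds) > 0L) {
      cstart <- min(GenomicRanges::start(cds)) - 1L
      cend <- max(GenomicRanges::end(cds))
      g5 <- if (t$strand == "+") cstart else cend - 1L
      tx5 <- genomic_to_tx(t, g5)
      if (is.na(tx5))
        stop("validation error: CDS outside exons for transcript ", tid)
      t$cds_start_tx <- tx5
      t$cds_len <- sum(GenomicRanges::width(cds))
    }
    txs[[length(txs) + 1L]] <- t
  }
  txs
}

parse_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$blocks)) stop("expected BED12 with block columns: ", path)
  txs <- list()
  for (k in seq_along(gr)) {
    nm <- md$name[k]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    gid <- parts[1L]
    tid <- if (length(parts) > 1L) parts[2L] else parts[1L]
    chrom_start <- GenomicRanges::start(gr[k]) - 1L
    bl <- md$blocks[[k]]  # ranges relative to chromStart, 1-based
    exons <- cbind(start = chrom_start + S4Vectors::start(bl) - 1L,
                   end = chrom_start + S4Vectors::end(bl))
    strand <- as.character(GenomicRanges::strand(gr[k]))
    t <- transcript_model(tid, gid,
                          as.character(GenomicRanges::seqnames(gr[k])),
                          strand, exons, cds_start_tx = 0L)
    th <- md$thick[k]
    if (!is.null(th) && S4Vectors::width(th) > 0L) {
      g5 <- if (strand == "+") S4Vectors::start(th) - 1L else S4Vectors::end(th) - 1L
      tx5 <- genomic_to_tx(t, g5)
      if (is.na(tx5)) stop("validation error: thick range outside blocks: ", tid)
      t$cds_start_tx <- tx5
      # CDS length inside exons
      cds_pos <- genomic_to_tx(t, (S4Vectors::start(th) - 1L):(S4Vectors::end(th) - 1L))
      t$cds_len <- sum(!is.na(cds_pos))
    }
    txs[[length(txs) + 1L]] <- t
  }
  txs
}

#' Write transcript models to BED12
#'
#' The name field is written as `gene|transcript`; the thick range spans the
#' CDS (from `cds_start_tx` to the transcript end).  Reloading with
#' [load_annotation()] reproduces the transcript models.
#'
#' @param db a `transcript_db` or list of `transcript_model`s.
#' @param path output file.
#' @export
write_bed12 <- function(db, path) {
  txs <- if (inherits(db, "transcript_db")) db$transcripts else db
  lines <- vapply(txs, function(t) {
    ex <- t$exons
    chrom_start <- ex[1L, 1L]
    chrom_end <- ex[nrow(ex), 2L]
    if (t$cds_start_tx < t$length) {
      g <- tx_to_genomic(t, c(t$cds_start_tx, t$length - 1L))
      thick_start <- min(g); thick_end <- max(g) + 1L
    } else {
      thick_start <- thick_end <- chrom_start
    }
    paste(t$chrom, chrom_start, chrom_end,
          paste0(t$gene_id, "|", t$transcript_id), 0L, t$strand,
          thick_start, thick_end, "0", nrow(ex),
          paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
          paste0(paste(ex[, 1] - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
}

# fetch the plus-strand genomic slice [start, end) for a chromosome; the
# genome accessor is a named character vector, DNAStringSet, or FASTA path
genome_slice <- function(genome, chrom, start, end) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome)))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "XStringSet")) genome <- as.character(genome)
  # FASTA headers may carry descriptions after the id
  names(genome) <- sub("\\s.*", "", names(genome))
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  substr(genome[[chrom]], start + 1L, end)
}

#' Transcript sequence in transcript orientation
#'
#' @param t a [transcript_model()].
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @return RNA-alphabet sequence 5'->3'.
#' @export
transcript_sequence <- function(t, genome) {
  parts <- vapply(seq_len(nrow(t$exons)), function(k)
    genome_slice(genome, t$chrom, t$exons[k, 1L], t$exons[k, 2L]), "")
  s <- paste(parts, collapse = "")
  s <- toupper(chartr("Tt", "Uu", s))
  if (t$strand == "-") revcomp_rna(s) else s
}

#' Extract the 5'UTR sequence of a transcript
#'
#' Returns the transcript-orientation sequence of positions
#' `[0, cds_start_tx)` in the RNA alphabet, excluding the start codon;
#' minus-strand transcripts are reverse-complemented.  A transcript with
#' `cds_start_tx == 0` yields the empty string.
#'
#' @inheritParams transcript_sequence
#' @return RNA string (possibly empty).
#' @export
extract_five_prime_utr <- function(t, genome) {
  if (t$cds_start_tx == 0L) return("")
  substr(transcript_sequence(t, genome), 1L, t$cds_start_tx)
}

#' Detect variant 5'UTRs for one gene
#'
#' A gene has a variant 5'UTR when its transcripts start at distinct genomic
#' TSS coordinates (alternative TSS) or when any transcript carries an
#' exon-exon junction upstream of its coding start (5'UTR intron).
#'
#' @param txs list of [transcript_model()]s of one gene (>= 1).
#' @param genome optional genome accessor; when given, the distinct 5'UTR
#'   sequences are reported (exact string deduplication).
#' @return object of class `gene_utr_set`: list with `gene_id`,
#'   `utr_sequences`, `has_alt_tss`, `has_utr_intron`, `is_variant`.
#' @export
detect_utr_variants <- function(txs, genome = NULL) {
  if (!length(txs)) stop("need >= 1 transcript")
  gid <- unique(vapply(txs, function(t) t$gene_id, ""))
  if (length(gid) != 1L) stop("transcripts from more than one gene")
  tss <- vapply(txs, tss_position, 0L)
  has_alt_tss <- length(unique(tss)) > 1L
  has_utr_intron <- any(vapply(txs, function(t) {
    if (nrow(t$exons) < 2L) return(FALSE)
    ord <- tx_exon_order(t)
    w <- t$exons[ord, 2] - t$exons[ord, 1]
    junc <- cumsum(w)[-length(w)]  # transcript coord of first base after junction
    any(junc < t$cds_start_tx)
  }, TRUE))
  utrs <- if (!is.null(genome))
    unique(vapply(txs, extract_five_prime_utr, "", genome = genome))
  else character(0)
  structure(list(gene_id = gid, utr_sequences = utrs,
                 has_alt_tss = has_alt_tss, has_utr_intron = has_utr_intron,
                 is_variant = has_alt_tss || has_utr_intron),
            class = "gene_utr_set")
}

#' Write per-gene 5'UTR sequences to FASTA
#'
#' One record per gene, taken from the canonical transcript; genes with empty
#' 5'UTRs are skipped.
#'
#' @param db a `transcript_db`.
#' @inheritParams transcript_sequence
#' @param path output FASTA.
#' @export
write_utr_fasta <- function(db, genome, path) {
  utrs <- vapply(canonical_models(db), extract_five_prime_utr, "",
                 genome = genome)
  names(utrs) <- vapply(canonical_models(db), function(t) t$gene_id, "")
  utrs <- utrs[nzchar(utrs)]
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(utrs), path)
}
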