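#' Classify a 5'UTR start as TOP, TOP-like or neither
#'
#' A 5' terminal oligopyrimidine (TOP) motif is a cap-adjacent cytidine
#' followed by an uninterrupted pyrimidine tract: here, position 1 must be C
#' and the pyrimidine run starting at position 2 must have length between
#' `min_run` and `max_run`.  A TOP-like start has a pyrimidine run of at
#' least `toplike_min_run` beginning within the first `toplike_window`
#' nucleotides while failing the strict rule.
#'
#' @param seq cap-proximal 5'UTR sequence (RNA or DNA).
#' @param min_run,max_run bounds on the strict-TOP pyrimidine run (default
#'   4..15).
#' @param toplike_min_run,toplike_window TOP-like parameters (default: a run
#'   of at least 5 starting within the first 4 nt).
#' @return `"TOP"`, `"TOP-like"` or `"none"`.
#' @export
classify_top <- function(seq, min_run = 4L, max_run = 15L,
                         toplike_min_run = 5L, toplike_window = 4L) {
  s <- toupper(as_rna_chr(seq))
  if (!nzchar(s)) return("none")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pyr <- ch %in% c("C", "U")
  run_from <- function(i) {
    if (i > length(ch)) return(0L)
    r <- 0L
    while (i + r <= length(ch) && pyr[i + r]) r <- r + 1L
    r
  }
  if (ch[1] == "C") {
    r <- run_from(2L)
    if (r >= min_run && r <= max_run) return("TOP")
  }
  for (i in seq_len(min(toplike_window, length(ch))))
    if (run_from(i) >= toplike_min_run) return("TOP-like")
  "none"
}

#' Detect the (CGG)4 guanine-quartet repeat
#'
#' Reports every occurrence (including overlapping ones) of the
#' 12-nucleotide `CGGCGGCGGCGG` repeat, and separately of the 9-nucleotide
#' `CGGCGGCGG` form.
#'
#' @param seq sequence to scan.
#' @return list with `has_cgg4` and `positions` (0-based starts of 12-nt
#'   matches), plus `has_cgg4_9nt` / `positions_9nt` for the shorter form.
#' @export
detect_cgg4 <- function(seq) {
  s <- toupper(as_rna_chr(seq))
  find <- function(motif) {
    h <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
    if (h[1] == -1) integer(0) else as.integer(h) - 1L
  }
  p12 <- find("CGGCGGCGGCGG")
  p9 <- find("CGGCGGCGG")
  list(has_cgg4 = length(p12) > 0L, positions = p12,
       has_cgg4_9nt = length(p9) > 0L, positions_9nt = p9)
}

#' Assign a 5'UTR to a signature category
#'
#' Categories follow a documented precedence (default structured, then
#' variant, then TOP, then other): `structured` when the folding free energy is below
#' `dg_threshold`, `variant` when the gene has alternative-TSS or
#' 5'UTR-intron transcripts, `TOP` when the start is TOP or TOP-like, else
#' `other` (non-TOP, non-complex).  Raw flags should be kept alongside so
#' that overlapping membership stays recoverable (see
#' [signature_summary()]).
#'
#' @param dg folding free energy (kcal/mol); `NA` -> `NA` category with a
#'   warning.
#' @param is_variant logical.
#' @param top_class `"TOP"`, `"TOP-like"` or `"none"`.
#' @param dg_threshold structured threshold (default -104 kcal/mol).
#' @param precedence category order.
#' @return character vector of categories.
#' @export
assign_category <- function(dg, is_variant, top_class, dg_threshold = -104,
                            precedence = c("structured", "variant", "TOP",
                                           "other")) {
  n <- max(length(dg), length(is_variant), length(top_class))
  dg <- rep_len(dg, n); is_variant <- rep_len(is_variant, n)
  top_class <- rep_len(top_class, n)
  if (anyNA(dg)) warning(sum(is.na(dg)), " gene(s) without dG: category undetermined")
  flags <- cbind(structured = !is.na(dg) & dg < dg_threshold,
                 variant = is_variant,
                 TOP = top_class %in% c("TOP", "TOP-like"),
                 other = TRUE)
  out <- apply(flags[, precedence, drop = FALSE], 1L,
               function(f) precedence[which(f)[1L]])
  out[is.na(dg)] <- NA_character_
  out
}

#' Per-gene 5'UTR feature table
#'
#' Combines folding, composition, TOP classification, variant flags and the
#' (CGG)4 scan into the feature table consumed by [signature_summary()].
#'
#' @param utrs named character vector of 5'UTR sequences (gene ids as
#'   names).
#' @param is_variant named or positional logical vector (default all
#'   `FALSE`).
#' @param model energy model for folding.
#' @param dg optional precomputed free energies (skips folding).
#' @inheritParams assign_category
#' @return data.frame with `gene_id, length, gc_pct, dg, is_variant,
#'   top_class, has_cgg4, category`.
#' @export
utr_features <- function(utrs, is_variant = FALSE,
                         model = default_energy_model(), dg = NULL,
                         dg_threshold = -104,
                         precedence = c("structured", "variant", "TOP",
                                        "other")) {
  gene_id <- names(utrs)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_along(utrs))
  if (is.null(dg))
    dg <- vapply(utrs, function(s) mfe_fold(s, model)$dg, 0, USE.NAMES = FALSE)
  is_variant <- rep_len(is_variant, length(utrs))
  top_class <- vapply(utrs, classify_top, "", USE.NAMES = FALSE)
  has_cgg4 <- vapply(utrs, function(s) detect_cgg4(s)$has_cgg4, TRUE,
                     USE.NAMES = FALSE)
  data.frame(gene_id = gene_id, length = nchar(utrs),
             gc_pct = vapply(utrs, gc_content, 0, USE.NAMES = FALSE),
             dg = dg, is_variant = is_variant, top_class = top_class,
             has_cgg4 = has_cgg4,
             category = assign_category(dg, is_variant, top_class,
                                        dg_threshold, precedence),
             row.names = NULL)
}

#' Category composition of a gene pool
#'
#' Summarizes a pool of 5'UTR feature rows as percentages per category,
#' twice: once under the single-label precedence (percentages sum to 100)
#' and once as overlapping memberships (a structured variant gene counts in
#' both; percentages may exceed 100).
#'
#' @param features data.frame from [utr_features()] (nonempty).
#' @inheritParams assign_category
#' @return list with `single` and `overlap` named percentage vectors and
#'   `n`.
#' @export
signature_summary <- function(features, dg_threshold = -104,
                              precedence = c("structured", "variant", "TOP",
                                             "other")) {
  if (!nrow(features)) stop("empty gene pool")
  n <- nrow(features)
  single <- 100 * table(factor(features$category, levels = precedence)) / n
  overlap <- c(
    structured = 100 * sum(!is.na(features$dg) &
                             features$dg < dg_threshold) / n,
    variant = 100 * sum(features$is_variant) / n,
    TOP = 100 * sum(features$top_class %in% c("TOP", "TOP-like")) / n,
    other = 100 * sum(features$category == "other", na.rm = TRUE) / n)
  list(single = c(single), overlap = overlap, n = n)
}
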