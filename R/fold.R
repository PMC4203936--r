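#' Read a nearest-neighbor energy parameter table
#'
#' The folding engine is parameter-table-driven: all stacking energies, loop
#' initiation penalties and multiloop terms come from a plain-text file, one
#' keyword per line (see the shipped table under
#' `system.file("extdata/params/nn_compact.par", package = "riboTE")` for the
#' format).  Pairs allowed are AU, UA, CG, GC, GU, UG; anything else scores
#' +Inf.  Loop penalties beyond the tabulated sizes are extrapolated with the
#' Jacobson-Stockmayer form `dG(n) = dG(n_max) + coef * RT * log(n / n_max)`.
#'
#' @param path path to a parameter file.
#' @return an object of class `energy_model`: a list with the stack matrix
#'   (kcal/mol), loop penalty tables, multiloop terms, `rt` and bookkeeping
#'   fields.  The model `name` is carried into every fold result for
#'   provenance.
#' @export
read_energy_model <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln[!grepl("^\\s*(#|$)", ln)])
  tok <- strsplit(ln, "\\s+")
  key <- vapply(tok, `[`, "", 1L)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(Inf, 6, 6, dimnames = list(pairs, pairs))
  num <- function(k) {
    i <- which(key == k)
    if (length(i) != 1L) stop("parameter file needs exactly one '", k, "' line")
    as.numeric(tok[[i]][2])
  }
  tab <- function(k) {
    i <- which(key == k)
    if (!length(i)) stop("parameter file has no '", k, "' lines")
    v <- vapply(tok[i], function(t) as.numeric(t[3]), 0)
    names(v) <- vapply(tok[i], `[`, "", 2L)
    v
  }
  for (i in which(key == "stack")) {
    p <- tok[[i]][2]; q <- tok[[i]][3]
    if (!p %in% pairs || !q %in% pairs) stop("bad stack pair: ", p, " ", q)
    stack[p, q] <- as.numeric(tok[[i]][4])
  }
  if (any(!is.finite(stack))) stop("stack table incomplete")
  m <- list(
    name = tok[[which(key == "name")]][2],
    rt = num("rt"),
    min_hairpin = as.integer(num("min_hairpin")),
    max_interior = as.integer(num("max_interior")),
    terminal_au = num("terminal_au"),
    ml_close = num("ml_close"), ml_branch = num("ml_branch"),
    ml_unpaired = num("ml_unpaired"),
    loop_extrapolation = num("loop_extrapolation"),
    interior_asym = num("interior_asym"),
    interior_asym_max = num("interior_asym_max"),
    stack = stack,
    hairpin = tab("hairpin"), bulge = tab("bulge"), interior = tab("interior")
  )
  class(m) <- "energy_model"
  m
}

#' @export
print.energy_model <- function(x, ...) {
  cat("energy_model '", x$name, "': RT=", x$rt,
      " kcal/mol, min hairpin loop ", x$min_hairpin,
      ", interior span cap ", x$max_interior, " nt\n", sep = "")
  invisible(x)
}

.model_cache <- new.env(parent = emptyenv())

#' Default energy model shipped with the package
#'
#' A compact nearest-neighbor table (Watson-Crick and wobble stacks, loop
#' initiation penalties, affine multiloops, terminal AU/GU penalty) in the
#' style of the standard nearest-neighbor rules.
#'
#' @return an `energy_model` (cached after the first call).
#' @export
default_energy_model <- function() {
  if (is.null(.model_cache$default)) {
    .model_cache$default <- read_energy_model(
      system.file("extdata/params/nn_compact.par", package = "riboTE",
                  mustWork = TRUE))
  }
  .model_cache$default
}

# loop penalty vector up to size n (index = size), Jacobson-Stockmayer
# extrapolation beyond the tabulated sizes
loop_penalty_vector <- function(tab, n, model) {
  sizes <- as.integer(names(tab))
  v <- rep(1e9, max(n, max(sizes)) + 1L)
  v[sizes + 1L] <- tab
  nmax <- max(sizes)
  if (n > nmax) {
    extra <- (nmax + 1L):n
    v[extra + 1L] <- tab[as.character(nmax)] +
      model$loop_extrapolation * model$rt * log(extra / nmax)
  }
  # returned 0-based by size: element [size + 1]
  v
}

# assemble the flat parameter list consumed by the C++ kernels
fold_par <- function(model, n) {
  # loop_penalty_vector puts penalty(size) at R index size + 1, which is
  # exactly C++ 0-based v[size] as read by loop_pen()
  hp <- loop_penalty_vector(model$hairpin, max(n, 10L), model)
  bu <- loop_penalty_vector(model$bulge, max(n, 10L), model)
  ii <- loop_penalty_vector(model$interior, max(n, 10L), model)
  list(stack = unname(model$stack),
       hp_by_size = hp, bu_by_size = bu, in_by_size = ii,
       terminal_au = model$terminal_au,
       ml_close = model$ml_close, ml_branch = model$ml_branch,
       ml_unpaired = model$ml_unpaired,
       interior_asym = model$interior_asym,
       interior_asym_max = model$interior_asym_max,
       rt = model$rt, max_interior = model$max_interior,
       min_hairpin = model$min_hairpin)
}

#' Minimum-free-energy fold of an RNA sequence
#'
#' Dynamic program over the nested-structure space (hairpins, stacks, bulges,
#' interior loops, multiloops) under a nearest-neighbor [energy
#' model][read_energy_model].  Lonely pairs are allowed, pseudoknots are not;
#' interior loops are capped at `model$max_interior` unpaired bases.  Ties are
#' broken deterministically in favor of the 5'-most opening pair.
#'
#' @param seq RNA (or DNA; T is read as U) sequence, case-insensitive.  `N`
#'   never pairs.  An empty sequence folds to dG 0 with an empty structure.
#' @param model an `energy_model`; default the shipped compact table.
#' @param id optional sequence identifier carried into the result.
#' @return a `fold_result`: list with `dg` (kcal/mol, <= 0), `structure`
#'   (dot-bracket), `id` and `model` (model name).
#' @examples
#' mfe_fold("GGGGCAAAAGCCCC")$dg
#' @export
mfe_fold <- function(seq, model = default_energy_model(), id = NA_character_) {
  codes <- encode_rna(seq)
  if (length(codes) == 0L) {
    res <- list(id = id, dg = 0, structure = "", model = model$name)
    class(res) <- "fold_result"
    return(res)
  }
  out <- .c_mfe(codes, fold_par(model, length(codes)))
  res <- list(id = id, dg = out$dg, structure = out$structure,
              model = model$name)
  class(res) <- "fold_result"
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(if (!is.na(x$id)) paste0(x$id, ": ") else "",
      sprintf("dG = %.2f kcal/mol [%s]\n", x$dg, x$model), sep = "")
  cat(x$structure, "\n")
  invisible(x)
}

#' McCaskill partition function and base-pair probabilities
#'
#' Inside/outside recursions over the same structure space and energies as
#' [mfe_fold()].  The ensemble free energy is `-RT * ln(Z)`; the base-pair
#' probability matrix is symmetric with entries in `[0, 1]` and row sums
#' `<= 1`.  The probability (outside) pass costs O(n^4) in the worst case and
#' can be skipped for long sequences with `return_bpp = FALSE` (the ensemble
#' free energy only needs the O(n^3) inside pass).
#'
#' @inheritParams mfe_fold
#' @param return_bpp compute the base-pair probability matrix?
#' @return list with `ensemble_dg` (kcal/mol), `lnZ`, and `bpp` (matrix, or
#'   `NULL` when not requested).
#' @export
partition_function <- function(seq, model = default_energy_model(),
                               return_bpp = TRUE) {
  codes <- encode_rna(seq)
  if (length(codes) == 0L)
    return(list(ensemble_dg = 0, lnZ = 0,
                bpp = if (return_bpp) matrix(0, 0, 0)))
  mfe <- .c_mfe(codes, fold_par(model, length(codes)))$dg
  out <- .c_partition(codes, fold_par(model, length(codes)), mfe, return_bpp)
  list(ensemble_dg = -model$rt * out$lnz, lnZ = out$lnz,
       bpp = if (return_bpp) out$bpp)
}

#' GC content of a sequence, in percent
#'
#' @param seq nonempty sequence (RNA or DNA).
#' @return `100 * (#G + #C) / length`.
#' @export
gc_content <- function(seq) {
  s <- toupper(as_rna_chr(seq))
  if (!nzchar(s)) stop("gc_content: empty sequence")
  n <- nchar(s)
  100 * (n - nchar(gsub("[GC]", "", s))) / n
}

#' Sliding-window free-energy and GC profile
#'
#' Breaks a sequence into windows of `w` nucleotides advancing by `step` and
#' reports, per window, the MFE free energy of the fragment and its GC
#' percentage.  With `step = 1` there are `L - w + 1` windows (none when
#' `L < w`).
#'
#' @inheritParams mfe_fold
#' @param w window size in nt (default 20).
#' @param step step in nt (default 1).
#' @return a data.frame of class `window_profile` with columns `start`
#'   (0-based window start), `dg` and `gc`.
#' @export
window_profile <- function(seq, w = 20L, step = 1L,
                           model = default_energy_model()) {
  if (w < 1L || step < 1L) stop("window_profile: w and step must be >= 1")
  s <- toupper(as_rna_chr(seq))
  L <- nchar(s)
  starts <- if (L < w) integer(0) else seq(0L, L - w, by = step)
  dg <- gc <- numeric(length(starts))
  for (k in seq_along(starts)) {
    frag <- substr(s, starts[k] + 1L, starts[k] + w)
    dg[k] <- mfe_fold(frag, model)$dg
    gc[k] <- gc_content(frag)
  }
  out <- data.frame(start = starts, dg = dg, gc = gc)
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Pick structured windows from a window profile
#'
#' Convenience for the mutation designer: returns maximal runs of window
#' starts whose fragment free energy falls below `dg_cutoff`, merged into
#' target regions.
#'
#' @param profile a [window_profile()] result.
#' @param dg_cutoff windows with `dg < dg_cutoff` are called structured.
#' @param w the window size the profile was computed with.
#' @return data.frame with 0-based half-open `start`, `end` columns.
#' @export
structured_windows <- function(profile, dg_cutoff = -8, w = 20L) {
  hit <- profile$start[profile$dg < dg_cutoff]
  if (!length(hit)) return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(0L, which(diff(hit) > 1L), length(hit))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    run <- hit[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start = run[1L], end = run[length(run)] + w)
  }))
  out
}

#' Design structure-disrupting point mutations
#'
#' Greedy search over GC-preserving single-nucleotide substitutions
#' (A<->U, G<->C) inside caller-supplied target windows, emulating the manual
#' procedure of removing base-pairing interactions from structured 5'UTR
#' regions one substitution at a time.  Each accepted substitution must raise
#' the refolded target-window free energy and must not make the full-length
#' free energy more negative.  Length and global GC content are preserved by
#' construction; positions inside protected motifs (by default every
#' occurrence of the (CGG)4 repeat `CGGCGGCGGCGG`) and the 3' start-codon
#' context are never touched.
#'
#' @inheritParams mfe_fold
#' @param target_windows data.frame with 0-based half-open `start`,`end`
#'   columns (e.g. from [structured_windows()]).  Empty -> sequence returned
#'   unchanged.
#' @param window_dg_threshold a window counts as resolved once the refolded
#'   fragment free energy is `>=` this (kcal/mol).
#' @param protect_motifs character vector of motifs whose occurrences are
#'   frozen.
#' @param protect_tail number of 3'-terminal nucleotides kept fixed (start
#'   codon context).
#' @param max_subs cap on accepted substitutions.
#' @return list with `sequence` (mutated positions in lowercase), `report`
#'   (data.frame `position` 0-based, `ref`, `alt`), `dg_before`, `dg_after`,
#'   and `unresolved` (target windows whose threshold could not be reached;
#'   reported, not an error).
#' @export
design_destructuring_mutations <- function(seq, target_windows,
                                           model = default_energy_model(),
                                           window_dg_threshold = -4,
                                           protect_motifs = "CGGCGGCGGCGG",
                                           protect_tail = 6L,
                                           max_subs = 100L) {
  s0 <- as_rna_chr(seq)
  s <- strsplit(toupper(s0), "", fixed = TRUE)[[1]]
  L <- length(s)
  dg_before <- mfe_fold(paste(s, collapse = ""), model)$dg
  if (is.null(target_windows) || nrow(target_windows) == 0L) {
    return(list(sequence = s0, report = data.frame(
      position = integer(0), ref = character(0), alt = character(0)),
      dg_before = dg_before, dg_after = dg_before,
      unresolved = target_windows))
  }
  protected <- rep(FALSE, L)
  if (protect_tail > 0L) protected[seq(max(1L, L - protect_tail + 1L), L)] <- TRUE
  str <- paste(s, collapse = "")
  for (mo in protect_motifs) {
    mo <- toupper(chartr("Tt", "Uu", mo))
    hits <- gregexpr(paste0("(?=", mo, ")"), str, perl = TRUE)[[1]]
    for (h in hits) if (h > 0) protected[h:(h + nchar(mo) - 1L)] <- TRUE
  }
  swap <- c(A = "U", U = "A", G = "C", C = "G")
  dg_cur <- dg_before
  changed <- integer(0)
  report <- list()
  win_dg <- function(wi) {
    a <- target_windows$start[wi] + 1L
    b <- min(L, target_windows$end[wi])
    mfe_fold(paste(s[a:b], collapse = ""), model)$dg
  }
  unresolved <- logical(nrow(target_windows))
  for (wi in order(vapply(seq_len(nrow(target_windows)), win_dg, 0))) {
    stalled <- FALSE
    while (!stalled && win_dg(wi) < window_dg_threshold &&
           length(changed) < max_subs) {
      a <- target_windows$start[wi] + 1L
      b <- min(L, target_windows$end[wi])
      cand <- setdiff(a:b, c(which(protected), changed))
      if (!length(cand)) { stalled <- TRUE; break }
      base_dg <- win_dg(wi)
      gains <- vapply(cand, function(p) {
        old <- s[p]; s[p] <<- swap[[old]]
        g <- win_dg(wi) - base_dg
        s[p] <<- old
        g
      }, 0)
      ord <- cand[order(-gains)]
      gains <- gains[order(-gains)]
      accepted <- FALSE
      for (ti in seq_len(min(8L, length(ord)))) {
        if (gains[ti] <= 1e-9) break
        p <- ord[ti]
        old <- s[p]
        s[p] <- swap[[old]]
        dg_new <- mfe_fold(paste(s, collapse = ""), model)$dg
        if (dg_new >= dg_cur - 1e-9) {
          dg_cur <- dg_new
          changed <- c(changed, p)
          report[[length(report) + 1L]] <-
            data.frame(position = p - 1L, ref = old, alt = s[p])
          accepted <- TRUE
          break
        }
        s[p] <- old
      }
      if (!accepted) stalled <- TRUE
    }
    unresolved[wi] <- win_dg(wi) < window_dg_threshold
  }
  out <- s
  out[changed] <- tolower(out[changed])
  list(sequence = paste(out, collapse = ""),
       report = if (length(report)) do.call(rbind, report) else
         data.frame(position = integer(0), ref = character(0),
                    alt = character(0)),
       dg_before = dg_before, dg_after = dg_cur,
       unresolved = target_windows[unresolved, , drop = FALSE])
}

#' Fold a set of sequences into a feature table
#'
#' Applies [mfe_fold()] and [gc_content()] to every sequence and returns the
#' per-sequence table used by the 5'UTR signature analysis.
#'
#' @param seqs named character vector, `DNAStringSet`/`RNAStringSet`, or path
#'   to a FASTA file.
#' @inheritParams mfe_fold
#' @return data.frame with `seq_id`, `length`, `gc_pct`, `dg`, `model`.
#' @export
fold_sequences <- function(seqs, model = default_energy_model()) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      !grepl("^[ACGTUNacgtun]+$", seqs))
    seqs <- Biostrings::readBStringSet(seqs)
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  data.frame(
    seq_id = ids,
    length = nchar(seqs),
    gc_pct = vapply(seqs, gc_content, 0, USE.NAMES = FALSE),
    dg = vapply(seqs, function(s) mfe_fold(s, model)$dg, 0, USE.NAMES = FALSE),
    model = model$name,
    row.names = NULL
  )
}

#' The five reporter 5'UTR sequences shipped with the package
#'
#' 5'UTR inserts of the luciferase reporter constructs (ARF6 wild-type and
#' its structure-disrupted mutant, CyclinD1, ROCK1, PFN2), stored verbatim
#' including their cloning context; lowercase letters in `ARF6mut` mark the
#' mutated residues.
#'
#' @return named character vector of RNA sequences.
#' @export
reporter_utrs <- function() {
  x <- Biostrings::readBStringSet(
    system.file("extdata/reporter_5utrs.fa", package = "riboTE",
                mustWork = TRUE))
  as.character(x)
}
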