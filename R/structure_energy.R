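#' Free energy of a given secondary structure
#'
#' Evaluates a dot-bracket structure under an [energy
#' model][read_energy_model] by loop decomposition: hairpins, stacks, bulges,
#' interior loops (asymmetry-penalized, span-capped), affine multiloops, and
#' terminal AU/GU penalties at every helix end adjacent to a loop or to the
#' exterior.  This scorer is independent of the dynamic-programming engine
#' and defines the energy that [mfe_fold()] minimizes and
#' [partition_function()] sums over.
#'
#' @inheritParams mfe_fold
#' @param structure dot-bracket string of the same length as `seq`.
#' @return energy in kcal/mol; `Inf` if the structure is invalid under the
#'   model (disallowed pair, hairpin loop below the minimum size, interior
#'   loop above the span cap).
#' @export
structure_energy <- function(seq, structure, model = default_energy_model()) {
  codes <- encode_rna(seq)
  n <- length(codes)
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (length(ch) != n) stop("structure length != sequence length")
  pt <- integer(n)
  stk <- integer(0)
  for (k in seq_len(n)) {
    if (ch[k] == "(") stk <- c(stk, k)
    else if (ch[k] == ")") {
      if (!length(stk)) stop("unbalanced dot-bracket")
      i <- stk[length(stk)]; stk <- stk[-length(stk)]
      pt[i] <- k; pt[k] <- i
    } else if (ch[k] != ".") stop("bad structure character: ", ch[k])
  }
  if (length(stk)) stop("unbalanced dot-bracket")

  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  letters4 <- c("A", "C", "G", "U", "N")
  ptype_chr <- function(i, j) {
    p <- paste0(letters4[codes[i] + 1L], letters4[codes[j] + 1L])
    if (p %in% pairs) p else NA_character_
  }
  au <- function(p) if (p %in% c("AU", "UA", "GU", "UG")) model$terminal_au else 0
  pen <- function(tab, size) {
    sizes <- as.integer(names(tab))
    if (size < min(sizes)) return(Inf)
    if (size <= max(sizes)) return(unname(tab[as.character(size)]))
    nmax <- max(sizes)
    unname(tab[as.character(nmax)]) +
      model$loop_extrapolation * model$rt * log(size / nmax)
  }
  # direct children pairs inside (i, j); i, j may be 0/n+1 for the exterior
  children <- function(i, j) {
    out <- list()
    k <- i + 1L
    while (k <= j - 1L) {
      if (pt[k] > k) { out[[length(out) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
      else if (pt[k] != 0L && pt[k] < k) stop("crossing pairs")
      else k <- k + 1L
    }
    out
  }
  loop_e <- function(i, j) {
    p <- ptype_chr(i, j)
    if (is.na(p)) return(Inf)
    kids <- children(i, j)
    e <- if (length(kids) == 0L) {
      size <- j - i - 1L
      if (size < model$min_hairpin) return(Inf)
      pen(model$hairpin, size) + au(p)
    } else if (length(kids) == 1L) {
      k <- kids[[1L]][1L]; l <- kids[[1L]][2L]
      q <- ptype_chr(k, l)
      if (is.na(q)) return(Inf)
      d1 <- k - i - 1L; d2 <- j - l - 1L
      if (d1 == 0L && d2 == 0L) model$stack[p, q]
      else if (d1 + d2 > model$max_interior) return(Inf)
      else if (d1 == 0L || d2 == 0L) pen(model$bulge, d1 + d2) + au(p) + au(q)
      else pen(model$interior, d1 + d2) +
        min(model$interior_asym_max, model$interior_asym * abs(d1 - d2)) +
        au(p) + au(q)
    } else {
      unpaired <- (j - i - 1L) - sum(vapply(kids, function(x) x[2] - x[1] + 1L, 0L))
      model$ml_close + model$ml_branch * (1L + length(kids)) +
        model$ml_unpaired * unpaired + au(p) +
        sum(vapply(kids, function(x) au(ptype_chr(x[1], x[2])), 0))
    }
    for (kd in kids) e <- e + loop_e(kd[1L], kd[2L])
    e
  }
  top <- children(0L, n + 1L)
  e <- sum(vapply(top, function(x) au(ptype_chr(x[1], x[2])), 0))
  for (kd in top) e <- e + loop_e(kd[1L], kd[2L])
  e
}
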