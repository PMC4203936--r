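# Brute-force folding oracle: enumerate every nested secondary structure
# (allowed pairs, minimum hairpin loop) and score each with
# structure_energy().  Feasible up to ~16 nt; independent of the C++ engine.

enumerate_structures <- function(seq, model = default_energy_model()) {
  codes <- encode_rna(seq)
  n <- length(codes)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  letters4 <- c("A", "C", "G", "U", "N")
  can_pair <- function(i, j) {
    paste0(letters4[codes[i] + 1L], letters4[codes[j] + 1L]) %in% pairs
  }
  mh <- model$min_hairpin
  rec <- function(i, j) {
    if (i > j) return(list(integer(0)))
    # i unpaired
    out <- lapply(rec(i + 1L, j), function(s) c(0L, s))
    # i paired with l
    ls <- if (j >= i + mh + 1L) (i + mh + 1L):j else integer(0)
    for (l in ls) {
      if (!can_pair(i, l)) next
      inner <- rec(i + 1L, l - 1L)
      rest <- rec(l + 1L, j)
      for (a in inner) for (b in rest)
        out[[length(out) + 1L]] <- c(l - i + 1L, a, 0L, b)[seq_len(j - i + 1L)]
    }
    out
  }
  # rec returns relative pair offsets; convert to dot-bracket
  rels <- rec(1L, n)
  vapply(rels, function(r) {
    db <- rep(".", n)
    for (i in seq_len(n)) if (r[i] > 0L) {
      j <- i + r[i] - 1L
      db[i] <- "("; db[j] <- ")"
    }
    paste(db, collapse = "")
  }, "")
}

oracle_fold <- function(seq, model = default_energy_model()) {
  structs <- enumerate_structures(seq, model)
  e <- vapply(structs, structure_energy, 0, seq = seq, model = model,
              USE.NAMES = FALSE)
  keep <- is.finite(e)
  structs <- structs[keep]; e <- e[keep]
  w <- exp(-e / model$rt)
  n <- nchar(seq)
  bpp <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    ch <- strsplit(structs[s], "", fixed = TRUE)[[1]]
    stk <- integer(0)
    for (k in seq_len(n)) {
      if (ch[k] == "(") stk <- c(stk, k)
      else if (ch[k] == ")") {
        i <- stk[length(stk)]; stk <- stk[-length(stk)]
        bpp[i, k] <- bpp[i, k] + w[s]
        bpp[k, i] <- bpp[i, k]
      }
    }
  }
  list(dg = min(e), structure = structs[which.min(e)], z = sum(w),
       bpp = bpp / sum(w), n_structures = length(structs))
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
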