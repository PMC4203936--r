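# internal sequence helpers: the package works on RNA strings internally
# (T -> U, case-insensitive); inputs may be character vectors, DNAString(Set)
# or RNAString(Set)

#' @importFrom methods is
as_rna_chr <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) x <- as.character(x)
  if (!is.character(x)) stop("sequence must be a character vector or Biostrings object")
  x <- chartr("Tt", "Uu", x)
  bad <- grepl("[^ACGUNacgun]", x)
  if (any(bad)) stop("invalid sequence character(s) in: ",
                     paste(utils::head(which(bad), 3), collapse = ", "))
  x
}

# integer codes A=0 C=1 G=2 U=3 N=4 for one sequence
encode_rna <- function(seq) {
  s <- strsplit(toupper(as_rna_chr(seq)), "", fixed = TRUE)[[1]]
  unname(c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)[s])
}

revcomp_rna <- function(seq) {
  s <- toupper(as_rna_chr(seq))
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
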