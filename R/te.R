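#' Translation efficiency
#'
#' TE = footprint RPKM / mRNA RPKM for the same gene, normalizing ribosome
#' occupancy to steady-state transcript abundance.  Genes with zero mRNA
#' RPKM are unquantifiable and get `NA`.
#'
#' @param rf_rpkm,mrna_rpkm numeric vectors.
#' @export
translation_efficiency <- function(rf_rpkm, mrna_rpkm) {
  ifelse(mrna_rpkm > 0, rf_rpkm / mrna_rpkm, NA_real_)
}

#' TE fold change between conditions
#'
#' The per-gene TE fold change is the treated TE over the control TE; both
#' the ratio and its log2 are returned.  Non-positive inputs mark the gene
#' unquantified (`NA`).
#'
#' @param te_treated,te_control numeric vectors.
#' @return list with `ratio` and `log2`.
#' @export
delta_te <- function(te_treated, te_control) {
  ok <- !is.na(te_treated) & !is.na(te_control) &
    te_treated > 0 & te_control > 0
  ratio <- ifelse(ok, te_treated / te_control, NA_real_)
  list(ratio = ratio, log2 = log2(ratio))
}

#' z-score classification of TE changes
#'
#' Standardizes the log2 TE fold changes over all quantified genes (mean 0,
#' population standard deviation 1) and classifies genes as `decreased`
#' (z below `low`), `increased` (z above `high`) or `insensitive`.
#' Unquantified genes (`NA` input) carry no z-score.
#'
#' @param x numeric vector of log2 TE fold changes (may contain `NA`).
#' @param low,high classification thresholds (default -1.5 / +1.5).
#' @return data.frame with `zscore` and `klass`
#'   (`decreased`/`increased`/`insensitive`/`unquantified`); attributes
#'   `mean` and `sd` hold the standardization constants.
#' @export
zscore_classify <- function(x, low = -1.5, high = 1.5) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("need >= 2 finite values to standardize")
  mu <- mean(x[ok])
  sdev <- sqrt(mean((x[ok] - mu)^2))  # population sd
  z <- rep(NA_real_, length(x))
  klass <- rep("unquantified", length(x))
  if (sdev == 0) {
    warning("zero variance: all quantified genes classified insensitive")
    z[ok] <- 0
    klass[ok] <- "insensitive"
  } else {
    z[ok] <- (x[ok] - mu) / sdev
    klass[ok] <- ifelse(z[ok] < low, "decreased",
                        ifelse(z[ok] > high, "increased", "insensitive"))
  }
  structure(data.frame(zscore = z, klass = klass),
            mean = mu, sd = sdev)
}

#' Robust-measurement gene filter
#'
#' A gene is kept only when its count is at least `min_count` in every
#' library (footprint and mRNA, every condition and replicate), the
#' "sufficiently represented to provide reliable measurements" rule.
#'
#' @param counts matrix of counts, genes in rows, libraries in columns.
#' @param min_count threshold (default 32).
#' @return logical vector per gene.
#' @export
robust_filter <- function(counts, min_count = 32L) {
  apply(counts >= min_count, 1L, all)
}

#' Mann-Whitney U test (exact by enumeration, or normal approximation)
#'
#' Two-sided rank-sum comparison of two pools.  In exact mode the null
#' distribution of U is obtained by enumerating all group labelings of the
#' pooled sample (midranks for ties), feasible for `n_x + n_y <= 16`; the
#' normal mode uses the tie-corrected variance with continuity correction.
#'
#' @param x,y numeric samples (nonempty).
#' @param mode `"auto"` (exact when `n_x + n_y <= 16`), `"exact"` or
#'   `"normal"`.
#' @param metric optional label carried into the result.
#' @return object of class `pool_comparison`: list with `U` (U statistic of
#'   `x`), `p_two_sided`, `n_x`, `n_y`, `mode`, `metric`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           metric = NA_character_) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (mode == "auto") mode <- if (n <= 16L) "exact" else "normal"
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (mode == "exact") {
    if (n > 20L) stop("exact enumeration infeasible for n > 20")
    combos <- utils::combn(n, nx)
    us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      if (z < 0) z <- 0
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  structure(list(U = U, p_two_sided = p, n_x = nx, n_y = ny,
                 mode = mode, metric = metric),
            class = "pool_comparison")
}

#' @export
print.pool_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U%s: U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              if (!is.na(x$metric)) paste0(" on ", x$metric) else "",
              x$U, x$n_x, x$n_y, x$p_two_sided, x$mode))
  invisible(x)
}

#' Replicate correlation
#'
#' Pearson correlation between paired expression measurements of biological
#' replicates, by default on `log2(RPKM + eps)`.
#'
#' @param rpkm_a,rpkm_b paired vectors.
#' @param log_transform correlate on the log2 scale?
#' @param eps pseudo-count added before the log.
#' @export
replicate_correlation <- function(rpkm_a, rpkm_b, log_transform = TRUE,
                                  eps = 0.5) {
  ok <- is.finite(rpkm_a) & is.finite(rpkm_b)
  if (sum(ok) < 3L) stop("need >= 3 finite pairs")
  a <- rpkm_a[ok]; b <- rpkm_b[ok]
  if (log_transform) { a <- log2(a + eps); b <- log2(b + eps) }
  stats::cor(a, b)
}

#' Condition-level TE analysis
#'
#' The central statistic of the pipeline: starting from a count matrix over
#' footprint/mRNA libraries of a control and a treated condition, computes
#' per-gene RPKM, TE, the TE fold change, and the z-score classification of
#' treatment-sensitive (decreased TE) and treatment-resistant (increased TE)
#' genes.
#'
#' Replicates (and multiple treatment time points) are by default pooled by
#' summing counts before the RPKM calculation (`replicate_mode = "pool"`);
#' `"mean-te"` instead computes TE per replicate and averages.  z-scores are
#' computed on log2 fold changes by default (`z_space = "log2"`), where the
#' distribution is approximately symmetric; `"ratio"` standardizes the raw
#' ratio instead.
#'
#' @param counts integer matrix, genes x libraries (rownames = gene ids).
#' @param lengths effective gene lengths in nt (recycled by gene).
#' @param libraries data.frame with one row per column of `counts`:
#'   `condition` (`"control"`/`"treated"`), `assay` (`"rf"`/`"mrna"`) and
#'   optionally `replicate`.
#' @param min_count robust-measurement threshold applied to every library.
#' @param z_low,z_high classification thresholds.
#' @param z_space `"log2"` or `"ratio"`.
#' @param replicate_mode `"pool"` or `"mean-te"`.
#' @return data.frame of class `te_result` with per-gene
#'   `te_control, te_treated, delta_te, log2_delta_te, zscore, klass`;
#'   attribute `summary` holds class counts and the standardization mean/sd.
#' @export
te_analysis <- function(counts, lengths, libraries, min_count = 32L,
                        z_low = -1.5, z_high = 1.5,
                        z_space = c("log2", "ratio"),
                        replicate_mode = c("pool", "mean-te")) {
  z_space <- match.arg(z_space)
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(ncol(counts) == nrow(libraries),
            all(libraries$condition %in% c("control", "treated")),
            all(libraries$assay %in% c("rf", "mrna")))
  genes <- rownames(counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))
  keep <- robust_filter(counts, min_count)

  grp <- paste(libraries$condition, libraries$assay, sep = ".")
  te_of <- function(cond) {
    sel_rf <- grp == paste0(cond, ".rf")
    sel_m <- grp == paste0(cond, ".mrna")
    if (replicate_mode == "pool") {
      rf <- rowSums(counts[, sel_rf, drop = FALSE])
      mr <- rowSums(counts[, sel_m, drop = FALSE])
      translation_efficiency(rpkm(rf, lengths, sum(rf)),
                             rpkm(mr, lengths, sum(mr)))
    } else {
      rfs <- which(sel_rf); mrs <- which(sel_m)
      k <- min(length(rfs), length(mrs))
      tes <- vapply(seq_len(k), function(i)
        translation_efficiency(
          rpkm(counts[, rfs[i]], lengths, sum(counts[, rfs[i]])),
          rpkm(counts[, mrs[i]], lengths, sum(counts[, mrs[i]]))),
        numeric(nrow(counts)))
      rowMeans(tes)
    }
  }
  te_c <- te_of("control")
  te_t <- te_of("treated")
  dte <- delta_te(te_t, te_c)
  xin <- if (z_space == "log2") dte$log2 else dte$ratio
  xin[!keep] <- NA_real_
  zc <- zscore_classify(xin, z_low, z_high)
  out <- data.frame(gene_id = genes, te_control = te_c, te_treated = te_t,
                    delta_te = dte$ratio, log2_delta_te = dte$log2,
                    zscore = zc$zscore, klass = zc$klass, row.names = NULL)
  out$klass[!keep] <- "unquantified"
  out$zscore[!keep] <- NA_real_
  attr(out, "summary") <- list(
    n = c(table(factor(out$klass, levels = c("decreased", "increased",
                                             "insensitive", "unquantified")))),
    mean = attr(zc, "mean"), sd = attr(zc, "sd"))
  class(out) <- c("te_result", "data.frame")
  out
}
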