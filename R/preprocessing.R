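#' Transcripts per million from read counts
#'
#' Standard TPM: per sample, the length-normalized rate
#' `count / (length/1000)` is rescaled so the column sums to 1e6.
#'
#' @param counts Nonnegative gene-by-sample matrix.
#' @param lengths Per-gene effective length in bases (> 0), recycled along
#'   rows; names, if present, must match the rownames of `counts`.
#' @return Gene-by-sample TPM matrix; every column sums to 1e6.
#' @examples
#' tpmFromCounts(matrix(c(10, 20), ncol = 1,
#'                      dimnames = list(c("a", "b"), "s1")),
#'               lengths = c(1000, 2000))
#' @export
tpmFromCounts <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .validationError("counts must be nonnegative")
  if (any(!is.finite(counts))) .validationError("counts must be finite")
  if (length(lengths) == 1L) lengths <- rep(lengths, nrow(counts))
  if (length(lengths) != nrow(counts))
    .usageError("need one length per gene (%d lengths for %d genes)",
                length(lengths), nrow(counts))
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    .validationError("gene lengths must be finite and > 0")
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- as.character(which(tot == 0))
    .validationError("sample '%s' has all-zero counts", bad[1L])
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Fit a parametric negative-binomial dispersion trend
#'
#' Method-of-moments estimate of the per-gene dispersion,
#' `alpha_g = max(0, (s2_g - mean_g) / mean_g^2)`, followed by an
#' unweighted least-squares fit of the trend `alpha(mu) = a0 + a1/mu` over
#' genes with a positive moment estimate and mean > 1. Accepts any
#' nonnegative count-like matrix (raw counts or TPM).
#'
#' @param values Gene-by-sample matrix, >= 10 genes and >= 2 samples.
#' @param minMu Minimum gene mean for a gene to enter the fit (default 1).
#' @return A [DispersionTrend-class]. `a0` is floored at 1e-8 and `a1` at
#'   0, since the closed-form transform requires `a0 > 0`.
#' @examples
#' set.seed(1)
#' mu <- runif(200, 5, 500)
#' y <- matrix(rnbinom(200 * 20, mu = mu, size = 1 / 0.1), nrow = 200)
#' fitDispersionTrend(y)
#' @export
fitDispersionTrend <- function(values, minMu = 1) {
  values <- as.matrix(values)
  if (nrow(values) < 10L)
    .fitError("need >= 10 genes to fit a dispersion trend (got %d)", nrow(values))
  if (ncol(values) < 2L)
    .fitError("need >= 2 samples to fit a dispersion trend (got %d)", ncol(values))
  if (any(!is.finite(values)) || any(values < 0))
    .validationError("values must be finite and nonnegative")
  mu <- rowMeans(values)
  s2 <- apply(values, 1L, stats::var)
  alphaHat <- (s2 - mu) / mu^2
  use <- is.finite(alphaHat) & alphaHat > 0 & mu > minMu
  if (sum(use) < 10L)
    .fitError("only %d usable genes (positive moment dispersion, mean > %g); need >= 10",
              sum(use), minMu)
  fit <- stats::lm.fit(cbind(1, 1 / mu[use]), alphaHat[use])
  a0 <- max(unname(fit$coefficients[1L]), 1e-8)
  a1 <- max(unname(fit$coefficients[2L]), 0)
  DispersionTrend(a0, a1, nGenesUsed = sum(use))
}

#' Variance-stabilizing transformation for NB count-like data
#'
#' Closed-form stabilizer for the negative-binomial family with mean-
#' dispersion trend `alpha(mu) = a0 + a1/mu` (variance
#' `(1 + a1) mu + a0 mu^2`):
#' \deqn{f(q) = \log_2\frac{1 + a_1 + 2 a_0 q +
#'   2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0}}
#' `f` is strictly increasing, applied elementwise, and behaves like
#' `log2(q)` for large `q`.
#'
#' @param values Nonnegative numeric vector or matrix.
#' @param trend A [DispersionTrend-class], fitted or constructed.
#' @return Transformed values, same shape as the input.
#' @examples
#' vstTransform(c(0, 10, 100, 1000), DispersionTrend(0.05, 2))
#' @export
vstTransform <- function(values, trend) {
  stopifnot(is(trend, "DispersionTrend"))
  if (any(!is.finite(values))) .validationError("values must be finite")
  if (any(values < 0)) .validationError("values must be nonnegative")
  a0 <- trend@a0; a1 <- trend@a1
  q <- values
  out <- log2((1 + a1 + 2 * a0 * q +
                 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
  out
}

#' Variance-stabilize an ExpressionTable
#'
#' Convenience wrapper producing the `vst`-scale table the metrics
#' consume. With `trend = NULL` a [DispersionTrend-class] is fitted per
#' species on that species' gene-by-sample matrix; a supplied trend (e.g.
#' the known truth of a simulation) is applied to all species. With
#' `fallbackLog2 = TRUE` a `log2(x + 1)` transform is used instead — an
#' explicit opt-in for tables with too few genes to fit a trend, never the
#' default.
#'
#' @param x An [ExpressionTable-class] at scale `counts` or `tpm`.
#' @param trend Optional [DispersionTrend-class].
#' @param fallbackLog2 Use `log2(x + 1)` instead of the NB stabilizer.
#' @return An [ExpressionTable-class] at scale `vst`; the choice made is
#'   recorded in its provenance.
#' @examples
#' tab <- makeExampleExpression(seed = 1)
#' vst <- applyVst(tab, trend = DispersionTrend(0.05, 2))
#' @export
applyVst <- function(x, trend = NULL, fallbackLog2 = FALSE) {
  stopifnot(is(x, "ExpressionTable"))
  if (x@scale == "vst") .usageError("table is already on the vst scale")
  rec <- x@records
  if (fallbackLog2) {
    rec$value <- log2(rec$value + 1)
    prov <- "log2(x+1) fallback transform"
  } else if (!is.null(trend)) {
    rec$value <- vstTransform(rec$value, trend)
    prov <- sprintf("vst with supplied trend a0=%.6g a1=%.6g", trend@a0, trend@a1)
  } else {
    prov <- character()
    for (sp in unique(rec$species)) {
      idx <- rec$species == sp
      m <- .castGeneBySample(rec[idx, , drop = FALSE])
      tr <- fitDispersionTrend(m)
      rec$value[idx] <- vstTransform(rec$value[idx], tr)
      prov <- c(prov, sprintf("vst per species %s: a0=%.6g a1=%.6g (%d genes)",
                              sp, tr@a0, tr@a1, tr@nGenesUsed))
    }
  }
  new("ExpressionTable", records = rec, scale = "vst",
      provenance = c(x@provenance, prov))
}

# Long records of ONE species -> gene x (tissue:sample) matrix.
.castGeneBySample <- function(rec) {
  genes <- sort(unique(rec$gene_id))
  cols <- sort(unique(paste(rec$tissue, rec$sample_id, sep = ":")))
  m <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, cols))
  m[cbind(match(rec$gene_id, genes),
          match(paste(rec$tissue, rec$sample_id, sep = ":"), cols))] <- rec$value
  m[is.na(m)] <- 0
  m
}

#' Per-group median expression matrix
#'
#' Computes the median over samples within each (gene, group) cell, where
#' groups are tissues within one species (`axis = "tissue"`) or species
#' within one tissue (`axis = "species"`). Odd sample counts give the
#' middle value, even counts the midpoint of the two middle values; cells
#' with no samples are NA, never zero.
#'
#' @param x An [ExpressionTable-class] (any scale; metrics expect `vst`).
#' @param axis `"tissue"` or `"species"` — what the columns are.
#' @param species For `axis = "tissue"`: which species to slice (required
#'   if the table holds several).
#' @param tissue For `axis = "species"`: which tissue to slice (if NULL,
#'   medians pool all tissues of each species).
#' @return A [MedianMatrix-class].
#' @examples
#' vst <- applyVst(makeExampleExpression(seed = 1),
#'                 trend = DispersionTrend(0.05, 2))
#' medianByGroup(vst, axis = "tissue", species = "human")
#' @export
medianByGroup <- function(x, axis = c("tissue", "species"),
                          species = NULL, tissue = NULL) {
  stopifnot(is(x, "ExpressionTable"))
  axis <- match.arg(axis)
  rec <- x@records
  if (nrow(rec) == 0L) .usageError("empty expression table")
  if (axis == "tissue") {
    sps <- unique(rec$species)
    if (is.null(species)) {
      if (length(sps) > 1L)
        .usageError("table holds %d species; pass `species` to slice one",
                    length(sps))
      species <- sps
    } else species <- normalizeSpecies(species)
    rec <- rec[rec$species == species, , drop = FALSE]
    if (nrow(rec) == 0L) .selectionError("no records for species '%s'", species)
    groupCol <- "tissue"; context <- species
  } else {
    if (!is.null(tissue)) {
      rec <- rec[rec$tissue == tissue, , drop = FALSE]
      if (nrow(rec) == 0L) .selectionError("no records for tissue '%s'", tissue)
      context <- tissue
    } else context <- "(all)"
    groupCol <- "species"
  }
  genes <- sort(unique(rec$gene_id))
  groups <- sort(unique(rec[[groupCol]]))
  m <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  med <- tapply(rec$value, list(factor(rec$gene_id, genes),
                                factor(rec[[groupCol]], groups)),
                stats::median)
  m[] <- med
  new("MedianMatrix", values = m, axis = axis, context = context)
}

#' Min-max scaling to [0, 1]
#'
#' `(x - min) / (max - min)`: preserves the shape of the distribution and
#' the ranks while mapping the range onto [0, 1]. Missing entries
#' propagate; a constant vector maps to all zeros with the `"degenerate"`
#' attribute set to TRUE (there is no meaningful range to stretch).
#'
#' @param x Numeric vector with at least one finite value.
#' @return Scaled vector in [0, 1], with attribute `degenerate`.
#' @examples
#' minMaxScale(c(3, 5, 9))
#' @export
minMaxScale <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) .validationError("min-max scaling of an all-missing vector")
  rng <- range(x[ok])
  if (diff(rng) == 0) {
    out <- ifelse(ok, 0, NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1L]) / diff(rng)
  attr(out, "degenerate") <- FALSE
  out
}

# Row-wise min-max scaling of a matrix; degenerate rows recorded by name.
.minMaxScaleRows <- function(m) {
  degenerate <- character()
  out <- m
  for (i in seq_len(nrow(m))) {
    if (!any(is.finite(m[i, ]))) { degenerate <- c(degenerate, rownames(m)[i]); next }
    s <- minMaxScale(m[i, ])
    if (isTRUE(attr(s, "degenerate")))
      degenerate <- c(degenerate, rownames(m)[i])
    out[i, ] <- s
  }
  attr(out, "degenerate_rows") <- degenerate
  out
}
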