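#' Shannon entropy of a probability profile
#'
#' `H = -sum over p_i > 0 of p_i * log2(p_i)`, in bits, with the usual
#' convention `0 * log 0 = 0`. The profile must be nonnegative and sum to
#' 1 (within numerical tolerance); anything else is an error, not a silent
#' renormalization.
#'
#' @param p Numeric probability vector.
#' @return Entropy in bits (nonnegative scalar).
#' @examples
#' shannonEntropy(rep(1/5, 5))   # log2(5)
#' shannonEntropy(c(1, 0, 0))    # 0
#' @export
shannonEntropy <- function(p) {
  if (length(p) == 0L || any(!is.finite(p)) || any(p < 0))
    .validationError("profile must be a nonnegative finite vector")
  if (abs(sum(p) - 1) > 1e-8)
    .validationError("profile is not normalized (sums to %.12g)", sum(p))
  pos <- p[p > 0]
  -sum(pos * log2(pos))
}

#' Diversity and specificity of a gene's expression profile
#'
#' For a gene's probability profile over `T >= 2` categories (tissues or
#' species), diversity is the normalized entropy `D = H(p) / log2(T)`
#' (1 = evenly expressed everywhere) and specificity the normalized
#' divergence from the uniform profile,
#' `S = KL(p || uniform) / log2(T) = 1 - D` (1 = expression confined to a
#' single category). Both lie in [0, 1] and are exactly complementary.
#'
#' @param p Numeric probability profile, length >= 2.
#' @return Named numeric `c(diversity, specificity)`.
#' @examples
#' geneDiversitySpecificity(rep(1/4, 4))      # (1, 0)
#' geneDiversitySpecificity(c(1, 0, 0, 0))    # (0, 1)
#' @export
geneDiversitySpecificity <- function(p) {
  if (length(p) < 2L)
    .usageError("need >= 2 categories for diversity/specificity (got %d)",
                length(p))
  d <- shannonEntropy(p) / log2(length(p))
  c(diversity = d, specificity = 1 - d)
}

#' Diversity and specialization of a tissue
#'
#' From a genes-by-tissues matrix of (row-scaled) expression weights:
#' tissue diversity is the normalized entropy of the tissue's profile over
#' genes, `H(q) / log2(G)` with `q_g = w[g, t] / sum_g w[g, t]`; tissue
#' specificity (specialization) is the expression-weighted mean of the
#' genes' unnormalized specificities,
#' `sum_g q_g * (log2(T) - H(p_g)) / log2(T)`, where `p_g` is gene g's
#' profile over tissues. A tissue expressing mostly tissue-restricted
#' genes scores high; unlike the gene-level metrics, tissue diversity and
#' specificity are not complements.
#'
#' @param scaled Numeric genes-by-tissues matrix of nonnegative weights
#'   (typically row min-max-scaled medians), >= 2 rows and columns.
#' @param tissue Column name or index.
#' @return Named numeric `c(diversity, specificity)`; both NA with a
#'   `"reason"` attribute if the column has zero total weight.
#' @examples
#' w <- rbind(g1 = c(8, 1, 1), g2 = c(1, 8, 1), g3 = c(1, 1, 8))
#' colnames(w) <- paste0("t", 1:3)
#' tissueDiversitySpecificity(w, "t1")
#' @export
tissueDiversitySpecificity <- function(scaled, tissue) {
  scaled <- as.matrix(scaled)
  if (nrow(scaled) < 2L || ncol(scaled) < 2L)
    .usageError("need >= 2 genes and >= 2 tissues")
  if (any(!is.na(scaled) & scaled < 0))
    .validationError("weights must be nonnegative")
  col <- scaled[, tissue]
  usable <- rowSums(is.na(scaled)) == 0L
  col <- col[usable]
  w <- scaled[usable, , drop = FALSE]
  if (sum(usable) < 2L || sum(col) == 0) {
    out <- c(diversity = NA_real_, specificity = NA_real_)
    attr(out, "reason") <- if (sum(usable) < 2L) "insufficient_genes" else "all_zero_column"
    return(out)
  }
  G <- nrow(w); Tn <- ncol(w)
  q <- col / sum(col)
  diversity <- shannonEntropy(q) / log2(G)
  rowTot <- rowSums(w)
  sg <- vapply(seq_len(G), function(i) {
    if (rowTot[i] == 0) return(0)  # zero-weight gene: no contribution
    log2(Tn) - shannonEntropy(w[i, ] / rowTot[i])
  }, numeric(1L))
  specificity <- sum(q * sg) / log2(Tn)
  c(diversity = diversity, specificity = specificity)
}

#' Coefficient of variation: standard deviation over the median
#'
#' The variability metric used throughout: sample standard deviation
#' (n - 1 denominator) divided by the median of the values. Invariant
#' under positive rescaling and zero iff the vector is constant.
#'
#' @param values Numeric vector (expected: VST values or their per-group
#'   medians).
#' @return Nonnegative scalar, or NA with a `"reason"` attribute
#'   (`insufficient_values` for < 2 finite values, `zero_median` when
#'   |median| < 1e-12).
#' @examples
#' computeCV(c(2, 4, 6))   # sd 2 / median 4 = 0.5
#' @export
computeCV <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) {
    out <- NA_real_; attr(out, "reason") <- "insufficient_values"; return(out)
  }
  med <- stats::median(v)
  if (abs(med) < 1e-12) {
    out <- NA_real_; attr(out, "reason") <- "zero_median"; return(out)
  }
  stats::sd(v) / med
}

.cvModes <- c("cv_tissue", "cv_species")

#' Coefficient-of-variation analysis across tissues or species
#'
#' Two modes, both on VST values. `cv_tissue` computes, per (gene,
#' species), the CV across that species' tissues; `cv_species` computes,
#' per (gene, tissue), the CV across species — meaningful once ortholog
#' ids have been harmonized upstream so that one gene id spans species
#' (see [mapOrthologs()]). By default the CV runs over per-group medians
#' of the VST values (`on = "medians"`); `on = "samples"` instead pools
#' all sample-level values of the group set.
#'
#' @param x An [ExpressionTable-class] at scale `vst`.
#' @param spec A [SelectionSpec-class].
#' @param mode `"cv_tissue"` or `"cv_species"`.
#' @param on `"medians"` (default) or `"samples"`.
#' @param refSpecies For `cv_species`: the reference species id carried on
#'   each gene row (default: first selected species alphabetically).
#' @return A CVResult data.frame: `gene_id, species, mode, group_label,
#'   cv, n_values, reason`.
#' @examples
#' vst <- applyVst(makeExampleExpression(seed = 1),
#'                 trend = DispersionTrend(0.05, 2))
#' cvAnalysis(vst, mode = "cv_tissue")
#' @export
cvAnalysis <- function(x, spec = SelectionSpec(), mode = .cvModes,
                       on = c("medians", "samples"), refSpecies = NULL) {
  stopifnot(is(x, "ExpressionTable"))
  mode <- match.arg(mode)
  on <- match.arg(on)
  if (x@scale != "vst")
    .usageError("cvAnalysis expects a vst-scale table (got %s); see applyVst()",
                x@scale)
  x <- suppressMessages(filterExpression(x, spec))
  rec <- x@records
  rows <- list()
  emit <- function(gene, sp, label, vals) {
    cv <- computeCV(vals)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene, species = sp, mode = mode, group_label = label,
      cv = as.numeric(cv), n_values = sum(is.finite(vals)),
      reason = if (is.na(cv)) attr(cv, "reason") else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (mode == "cv_tissue") {
    for (sp in sort(unique(rec$species))) {
      sub <- rec[rec$species == sp, , drop = FALSE]
      tissues <- sort(unique(sub$tissue))
      if (length(tissues) < 2L)
        .usageError("cv_tissue needs >= 2 tissues in species %s", sp)
      label <- paste(tissues, collapse = "|")
      for (gene in sort(unique(rec$gene_id))) {
        gsub <- sub[sub$gene_id == gene, , drop = FALSE]
        vals <- if (on == "medians")
          tapply(gsub$value, factor(gsub$tissue, tissues), stats::median)
        else gsub$value
        emit(gene, sp, label, as.numeric(vals))
      }
    }
  } else {
    species <- sort(unique(rec$species))
    if (length(species) < 2L)
      .usageError("cv_species needs >= 2 species")
    if (is.null(refSpecies)) refSpecies <- species[1L]
    else refSpecies <- normalizeSpecies(refSpecies)
    for (tis in sort(unique(rec$tissue))) {
      sub <- rec[rec$tissue == tis, , drop = FALSE]
      for (gene in sort(unique(rec$gene_id))) {
        gsub <- sub[sub$gene_id == gene, , drop = FALSE]
        vals <- if (on == "medians")
          tapply(gsub$value, factor(gsub$species, species), stats::median)
        else gsub$value
        emit(gene, refSpecies, tis, as.numeric(vals))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$species, out$group_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.dsModes <- c("ds_gene", "ds_gene_all", "ds_tissue", "ds_tissue_all")

.dsRow <- function(unit, unitId, sp, mode, d, s, n, flags) {
  data.frame(unit = unit, unit_id = unitId, species = sp, mode = mode,
             diversity = d, specificity = s, n_categories = n,
             flags = flags, stringsAsFactors = FALSE)
}

#' Diversity and specificity analysis
#'
#' The four modes slice a genes-by-tissues median matrix per species and
#' compute Shannon-entropy diversity/specificity: `ds_gene` scores the
#' selected genes over the selected tissues, `ds_gene_all` over all
#' tissues; `ds_tissue` scores the selected tissues over the selected
#' genes, `ds_tissue_all` over all genes. The pipeline per species is:
#' per-(gene, tissue) medians of VST values, per-gene min-max rescaling,
#' probability profiles (per gene over tissues, or per tissue over genes),
#' then [geneDiversitySpecificity()] / [tissueDiversitySpecificity()].
#'
#' Degenerate rows: a gene expressed at the same nonzero level in every
#' tissue has no range to rescale — it is treated as uniformly expressed
#' (diversity 1) and flagged `degenerate_uniform`; an all-zero gene row is
#' emitted with missing metrics and flag `all_zero`.
#'
#' @param x An [ExpressionTable-class] at scale `vst`, or a
#'   [MedianMatrix-class] with tissue columns for a single species.
#' @param spec A [SelectionSpec-class].
#' @param mode One of `"ds_gene"`, `"ds_gene_all"`, `"ds_tissue"`,
#'   `"ds_tissue_all"`.
#' @param ... Passed between methods.
#' @return A DSResult data.frame: `unit, unit_id, species, mode,
#'   diversity, specificity, n_categories, flags`.
#' @examples
#' vst <- applyVst(makeExampleExpression(seed = 1),
#'                 trend = DispersionTrend(0.05, 2))
#' dsAnalysis(vst, mode = "ds_gene_all")
#' @name dsAnalysis
NULL

#' @rdname dsAnalysis
setMethod("dsAnalysis", "ExpressionTable",
  function(x, spec = SelectionSpec(), mode, ...) {
    mode <- match.arg(mode, .dsModes)
    if (x@scale != "vst")
      .usageError("dsAnalysis expects a vst-scale table (got %s)", x@scale)
    # Gene modes score each selected gene's own tissue profile, so the
    # matrix keeps all genes (row scaling is per gene) and spec@genes only
    # picks the scored units; the tissue slice matters for ds_gene.
    # Tissue modes build profiles over genes, so spec@genes restricts the
    # matrix itself for ds_tissue; tissue columns are kept so each gene's
    # full profile feeds the specialization term.
    sel <- SelectionSpec(
      genes = if (mode == "ds_tissue") spec@genes else character(),
      tissues = if (mode == "ds_gene") spec@tissues else character(),
      species = spec@species)
    x <- suppressMessages(filterExpression(x, sel))
    out <- list()
    for (sp in sort(unique(x@records$species))) {
      mm <- medianByGroup(x, axis = "tissue", species = sp)
      res <- dsAnalysis(mm, spec = spec, mode = mode, species = sp)
      out[[sp]] <- res
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })

#' @rdname dsAnalysis
#' @param species Label for the species the matrix belongs to (the
#'   MedianMatrix method uses its `context` by default).
setMethod("dsAnalysis", "MedianMatrix",
  function(x, spec = SelectionSpec(), mode, species = medianContext(x), ...) {
    mode <- match.arg(mode, .dsModes)
    if (x@axis != "tissue")
      .usageError("dsAnalysis needs a gene-by-tissue MedianMatrix")
    m <- x@values
    if (nrow(m) < 2L || ncol(m) < 2L)
      .usageError("need >= 2 genes and >= 2 tissues (got %d x %d)",
                  nrow(m), ncol(m))
    scaled <- .minMaxScaleRows(m)
    degenerate <- attr(scaled, "degenerate_rows")
    rows <- list()
    if (mode %in% c("ds_gene", "ds_gene_all")) {
      units <- if (length(spec@genes)) intersect(rownames(m), spec@genes)
               else rownames(m)
      for (gene in sort(units)) {
        orig <- m[gene, ]
        ok <- !is.na(orig)
        if (sum(ok) < 2L) {
          rows[[length(rows) + 1L]] <- .dsRow("gene", gene, species, mode,
                                              NA_real_, NA_real_, sum(ok),
                                              "insufficient_tissues")
          next
        }
        if (gene %in% degenerate) {
          if (all(orig[ok] == 0)) {
            rows[[length(rows) + 1L]] <- .dsRow("gene", gene, species, mode,
                                                NA_real_, NA_real_, sum(ok),
                                                "all_zero")
          } else {
            # constant nonzero profile: uniform by convention
            rows[[length(rows) + 1L]] <- .dsRow("gene", gene, species, mode,
                                                1, 0, sum(ok),
                                                "degenerate_uniform")
          }
          next
        }
        w <- scaled[gene, ok]
        ds <- geneDiversitySpecificity(w / sum(w))
        rows[[length(rows) + 1L]] <- .dsRow("gene", gene, species, mode,
                                            ds[["diversity"]],
                                            ds[["specificity"]], sum(ok), "")
      }
    } else {
      units <- if (length(spec@tissues)) intersect(colnames(m), spec@tissues)
               else colnames(m)
      use <- !(rownames(scaled) %in% degenerate)
      wmat <- scaled[use, , drop = FALSE]
      for (tis in sort(units)) {
        if (nrow(wmat) < 2L) {
          rows[[length(rows) + 1L]] <- .dsRow("tissue", tis, species, mode,
                                              NA_real_, NA_real_, nrow(wmat),
                                              "insufficient_genes")
          next
        }
        ds <- tissueDiversitySpecificity(wmat, tis)
        flag <- attr(ds, "reason")
        rows[[length(rows) + 1L]] <- .dsRow("tissue", tis, species, mode,
                                            ds[["diversity"]],
                                            ds[["specificity"]],
                                            sum(!is.na(wmat[, tis])),
                                            if (is.null(flag)) "" else flag)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
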