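#' @import methods
NULL

.exprColumns <- c("gene_id", "species", "tissue", "sample_id", "value")
.exprScales  <- c("counts", "tpm", "vst")

#' ExpressionTable: long-format expression records
#'
#' Canonical in-memory container for expression values across genes,
#' species, tissues and samples. The long format is canonical; wide
#' matrices (e.g. gene-by-tissue median matrices) are views derived on
#' demand. Values carry a declared scale: raw `counts`, length-normalized
#' `tpm`, or variance-stabilized `vst`.
#'
#' Validity requires: the five canonical columns; every
#' (gene_id, species, tissue, sample_id) tuple unique; finite values,
#' nonnegative when the scale is `counts` or `tpm`; species drawn from
#' [supportedSpecies()].
#'
#' @slot records data.frame with columns `gene_id`, `species`, `tissue`,
#'   `sample_id`, `value`.
#' @slot scale One of `"counts"`, `"tpm"`, `"vst"`.
#' @slot provenance Free-text metadata describing how the table was made.
#' @aliases ExpressionTable
#' @exportClass ExpressionTable
setClass("ExpressionTable",
  representation(records = "data.frame", scale = "character",
                 provenance = "character"))

setValidity("ExpressionTable", function(object) {
  rec <- object@records
  missing <- setdiff(.exprColumns, names(rec))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (length(object@scale) != 1L || !object@scale %in% .exprScales)
    return(sprintf("scale must be one of %s", paste(.exprScales, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (!is.numeric(rec$value)) return("value column must be numeric")
  if (any(!is.finite(rec$value)))
    return(sprintf("non-finite value at row %d", which(!is.finite(rec$value))[1L]))
  if (object@scale %in% c("counts", "tpm") && any(rec$value < 0))
    return(sprintf("negative %s value at row %d", object@scale,
                   which(rec$value < 0)[1L]))
  bad <- setdiff(unique(rec$species), .speciesRegistry$species)
  if (length(bad))
    return(sprintf("unsupported species: %s", paste(bad, collapse = ", ")))
  key <- paste(rec$gene_id, rec$species, rec$tissue, rec$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rec[duplicated(key), , drop = FALSE][1L, ]
    return(sprintf("duplicate record for (%s, %s, %s, %s)",
                   d$gene_id, d$species, d$tissue, d$sample_id))
  }
  TRUE
})

#' Construct an ExpressionTable
#'
#' @param records data.frame with columns `gene_id`, `species`, `tissue`,
#'   `sample_id`, `value` (column order not significant). Species may be
#'   given as short names or taxon ids; they are normalized.
#' @param scale Declared value scale: `"counts"`, `"tpm"` or `"vst"`.
#' @param provenance Optional free-text provenance string.
#' @return A validated [ExpressionTable-class] object.
#' @examples
#' rec <- data.frame(gene_id = "g1", species = "human", tissue = "liver",
#'                   sample_id = "s1", value = 10)
#' ExpressionTable(rec, scale = "counts")
#' @export
ExpressionTable <- function(records, scale = c("counts", "tpm", "vst"),
                            provenance = character()) {
  scale <- match.arg(scale)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(.exprColumns, names(records))
  if (length(missing))
    .formatError("missing column(s): %s", paste(missing, collapse = ", "))
  records <- records[, .exprColumns, drop = FALSE]
  for (col in c("gene_id", "species", "tissue", "sample_id"))
    records[[col]] <- as.character(records[[col]])
  if (nrow(records)) records$species <- normalizeSpecies(records$species)
  records$value <- as.numeric(records$value)
  rownames(records) <- NULL
  new("ExpressionTable", records = records, scale = scale,
      provenance = as.character(provenance))
}

setMethod("show", "ExpressionTable", function(object) {
  rec <- object@records
  cat(sprintf("ExpressionTable: %d records (scale=%s)\n", nrow(rec), object@scale))
  if (nrow(rec)) {
    cat(sprintf("  genes: %d | species: %s | tissues: %d | samples: %d\n",
                length(unique(rec$gene_id)),
                paste(sort(unique(rec$species)), collapse = ","),
                length(unique(rec$tissue)),
                length(unique(rec$sample_id))))
  }
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = "; "), "\n")
  invisible(object)
})

#' SelectionSpec: a selection of genes, tissues and species
#'
#' An empty field means "all". Non-empty fields must resolve against the
#' table they are applied to; unresolved names are reported by
#' [filterExpression()], never silently dropped.
#'
#' @slot genes,tissues,species Character vectors (possibly empty).
#' @aliases SelectionSpec
#' @exportClass SelectionSpec
setClass("SelectionSpec",
  representation(genes = "character", tissues = "character",
                 species = "character"))

#' @param genes,tissues,species Character vectors; empty selects all.
#' @return A `SelectionSpec`.
#' @examples
#' SelectionSpec(genes = c("g1", "g2"), species = "mouse")
#' @rdname SelectionSpec-class
#' @export
SelectionSpec <- function(genes = character(), tissues = character(),
                          species = character()) {
  if (length(species)) species <- normalizeSpecies(species)
  new("SelectionSpec", genes = as.character(genes),
      tissues = as.character(tissues), species = species)
}

setMethod("show", "SelectionSpec", function(object) {
  fmt <- function(x) if (length(x)) paste(x, collapse = ",") else "<all>"
  cat(sprintf("SelectionSpec: genes=%s tissues=%s species=%s\n",
              fmt(object@genes), fmt(object@tissues), fmt(object@species)))
  invisible(object)
})

#' OrthologTable: HomoloGene-style ortholog groups
#'
#' Parsed from the `homologene.data` dialect (six tab-separated columns,
#' no header). Only records for the six supported taxa are retained; the
#' number of dropped records is kept for reporting.
#'
#' @slot groups data.frame with columns `group_id`, `taxon_id`,
#'   `entrez_id`, `symbol`, `protein_gi`, `protein_accession`.
#' @slot droppedTaxa Integer count of records for unsupported taxa that
#'   were dropped at load time.
#' @aliases OrthologTable
#' @exportClass OrthologTable
setClass("OrthologTable",
  representation(groups = "data.frame", droppedTaxa = "integer"))

setValidity("OrthologTable", function(object) {
  g <- object@groups
  need <- c("group_id", "taxon_id", "entrez_id", "symbol",
            "protein_gi", "protein_accession")
  missing <- setdiff(need, names(g))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(g)) {
    bad <- setdiff(unique(g$taxon_id), .speciesRegistry$taxon_id)
    if (length(bad))
      return(sprintf("unsupported taxon id(s): %s", paste(bad, collapse = ", ")))
    key <- paste(g$group_id, g$taxon_id, g$entrez_id, sep = "\r")
    if (anyDuplicated(key))
      return("duplicate (group_id, taxon_id, entrez_id) record")
  }
  TRUE
})

setMethod("show", "OrthologTable", function(object) {
  g <- object@groups
  cat(sprintf("OrthologTable: %d records in %d groups (%d unsupported-taxon records dropped)\n",
              nrow(g), length(unique(g$group_id)), object@droppedTaxa))
  if (nrow(g)) {
    tab <- table(.taxonToSpecies(g$taxon_id))
    cat("  genes per species:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  }
  invisible(object)
})

#' IdMap: per-species gene identifier cross-reference
#'
#' Records of Ensembl id, Entrez id and gene symbol per species. Any field
#' may be absent (NA) for a given gene. Within one species, Ensembl and
#' Entrez ids are each unique when present; symbols need not be.
#'
#' @slot xref data.frame with columns `species`, `ensembl_id`,
#'   `entrez_id`, `symbol` (NA marks an absent identifier).
#' @aliases IdMap
#' @exportClass IdMap
setClass("IdMap", representation(xref = "data.frame"))

setValidity("IdMap", function(object) {
  x <- object@xref
  need <- c("species", "ensembl_id", "entrez_id", "symbol")
  missing <- setdiff(need, names(x))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(x)) {
    bad <- setdiff(unique(x$species), .speciesRegistry$species)
    if (length(bad))
      return(sprintf("unsupported species: %s", paste(bad, collapse = ", ")))
    for (col in c("ensembl_id", "entrez_id")) {
      present <- !is.na(x[[col]])
      key <- paste(x$species[present], x[[col]][present], sep = "\r")
      if (anyDuplicated(key))
        return(sprintf("duplicate %s within one species", col))
    }
  }
  TRUE
})

setMethod("show", "IdMap", function(object) {
  cat(sprintf("IdMap: %d records across %d species\n",
              nrow(object@xref), length(unique(object@xref$species))))
  invisible(object)
})

#' DispersionTrend: fitted negative-binomial mean-dispersion trend
#'
#' Parametrization alpha(mu) = a0 + a1/mu: `a0` is the asymptotic
#' dispersion at large mean and `a1` the extra-Poisson term dominating at
#' small mean. Both are dimensionless.
#'
#' @slot a0 Asymptotic dispersion, > 0.
#' @slot a1 Extra-Poisson term, >= 0.
#' @slot nGenesUsed Number of genes the trend was fitted on (NA when the
#'   trend was supplied rather than fitted).
#' @aliases DispersionTrend
#' @exportClass DispersionTrend
setClass("DispersionTrend",
  representation(a0 = "numeric", a1 = "numeric", nGenesUsed = "integer"))

setValidity("DispersionTrend", function(object) {
  if (length(object@a0) != 1L || !is.finite(object@a0) || object@a0 <= 0)
    return("a0 must be a single finite value > 0")
  if (length(object@a1) != 1L || !is.finite(object@a1) || object@a1 < 0)
    return("a1 must be a single finite value >= 0")
  TRUE
})

#' @param a0 Asymptotic dispersion (> 0).
#' @param a1 Extra-Poisson term (>= 0).
#' @param nGenesUsed Optional gene count the fit used.
#' @return A `DispersionTrend`.
#' @examples
#' DispersionTrend(a0 = 0.05, a1 = 2)
#' @rdname DispersionTrend-class
#' @export
DispersionTrend <- function(a0, a1, nGenesUsed = NA_integer_) {
  new("DispersionTrend", a0 = as.numeric(a0), a1 = as.numeric(a1),
      nGenesUsed = as.integer(nGenesUsed))
}

setMethod("show", "DispersionTrend", function(object) {
  cat(sprintf("DispersionTrend: alpha(mu) = %.6g + %.6g/mu (fitted on %s genes)\n",
              object@a0, object@a1,
              ifelse(is.na(object@nGenesUsed), "?", object@nGenesUsed)))
  invisible(object)
})

#' MedianMatrix: per-group median expression matrix
#'
#' Genes-by-groups matrix of per-group median VST values for one slicing:
#' columns are tissues (one species) or species (one tissue). Cells with
#' no samples are NA, never zero-filled.
#'
#' @slot values Numeric matrix, rows = genes, columns = groups.
#' @slot axis `"tissue"` or `"species"` — what the columns are.
#' @slot context The fixed stratum: the species (axis `"tissue"`) or the
#'   tissue (axis `"species"`); `"(all)"` when not stratified.
#' @aliases MedianMatrix
#' @exportClass MedianMatrix
setClass("MedianMatrix",
  representation(values = "matrix", axis = "character", context = "character"))

setValidity("MedianMatrix", function(object) {
  if (!object@axis %in% c("tissue", "species"))
    return("axis must be 'tissue' or 'species'")
  v <- object@values
  if (length(v) && any(!is.na(v) & !is.finite(v)))
    return("entries must be finite or NA")
  TRUE
})

setMethod("show", "MedianMatrix", function(object) {
  cat(sprintf("MedianMatrix: %d genes x %d %ss (context: %s), %d missing cells\n",
              nrow(object@values), ncol(object@values), object@axis,
              object@context, sum(is.na(object@values))))
  invisible(object)
})

#' SimSpec: specification of a synthetic expression dataset
#'
#' Describes a negative-binomial count simulation: dimensions, baseline
#' mean, the mean-dispersion trend, and a catalog of per-gene effects
#' (see [effectFlat()], [effectTissueSpecific()], [effectHighVar()],
#' [effectSpeciesVariable()]). The seed is mandatory: the same spec always
#' reproduces the same table.
#'
#' @slot nGenes,nSpecies,nTissues,nSamplesPerCell Integer dimensions.
#' @slot baselineMean Baseline negative-binomial mean (> 0).
#' @slot dispersion Numeric length-2 `(a0, a1)` of the trend
#'   alpha(mu) = a0 + a1/mu.
#' @slot effects List of effect descriptors from the effect constructors.
#' @slot seed Integer RNG seed.
#' @aliases SimSpec
#' @exportClass SimSpec
setClass("SimSpec",
  representation(nGenes = "integer", nSpecies = "integer",
                 nTissues = "integer", nSamplesPerCell = "integer",
                 baselineMean = "numeric", dispersion = "numeric",
                 effects = "list", seed = "integer"))

setValidity("SimSpec", function(object) {
  if (object@nGenes < 1L || object@nTissues < 1L || object@nSpecies < 1L ||
      object@nSamplesPerCell < 1L)
    return("all dimensions must be >= 1")
  if (object@nSpecies > nrow(.speciesRegistry))
    return(sprintf("at most %d species are supported", nrow(.speciesRegistry)))
  if (!is.finite(object@baselineMean) || object@baselineMean <= 0)
    return("baselineMean must be > 0")
  if (length(object@dispersion) != 2L || object@dispersion[1L] <= 0 ||
      object@dispersion[2L] < 0)
    return("dispersion must be (a0 > 0, a1 >= 0)")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a seed is mandatory")
  genes   <- paste0("gene", seq_len(object@nGenes))
  tissues <- paste0("tissue", seq_len(object@nTissues))
  species <- .speciesRegistry$species[seq_len(object@nSpecies)]
  for (eff in object@effects) {
    if (!is.list(eff) || is.null(eff$type))
      return("each effect must come from an effect constructor")
    if (!eff$gene %in% genes)
      return(sprintf("effect references unknown gene '%s'", eff$gene))
    if (!is.null(eff$species) && !all(eff$species %in% species))
      return(sprintf("effect references species outside the simulated set"))
    if (identical(eff$type, "tissue_specific")) {
      if (!eff$tissue %in% tissues)
        return(sprintf("effect references unknown tissue '%s'", eff$tissue))
      if (!is.finite(eff$fold) || eff$fold <= 0) return("fold must be > 0")
    }
    if (identical(eff$type, "high_var") &&
        (!is.finite(eff$spread) || eff$spread <= 1))
      return("high_var spread must be > 1")
    if (identical(eff$type, "species_variable")) {
      if (length(eff$foldProfile) != object@nTissues)
        return("species_variable foldProfile must have one fold per tissue")
      if (any(!is.finite(eff$foldProfile)) || any(eff$foldProfile <= 0))
        return("foldProfile folds must be > 0")
    }
  }
  TRUE
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: %d genes x %d species x %d tissues x %d samples/cell (seed %d)\n",
    object@nGenes, object@nSpecies, object@nTissues, object@nSamplesPerCell,
    object@seed))
  cat(sprintf("  baseline mean %.3g, alpha(mu) = %.3g + %.3g/mu, %d effect(s)\n",
              object@baselineMean, object@dispersion[1L], object@dispersion[2L],
              length(object@effects)))
  invisible(object)
})
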