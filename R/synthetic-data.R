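#' Effect descriptors for the count simulator
#'
#' Build entries for the effect catalog of a [SimSpec-class]. Each effect
#' applies to one gene, optionally restricted to one or more species
#' (default: all simulated species):
#' \itemize{
#'   \item `effectFlat()` — baseline expression everywhere (the default
#'     for genes with no catalog entry; an explicit entry documents
#'     intent).
#'   \item `effectTissueSpecific()` — the gene's mean is multiplied by
#'     `fold` in one tissue.
#'   \item `effectHighVar()` — the gene's mean follows a deterministic
#'     symmetric log-spaced profile across tissues, from `1/spread` up to
#'     `spread` times baseline, giving high cross-tissue variability that
#'     does not depend on the seed.
#'   \item `effectSpeciesVariable()` — an arbitrary per-tissue fold
#'     profile applied in the named species only.
#' }
#'
#' @param gene Gene id (`"gene1"`, ... for a spec with `nGenes` genes).
#' @param species Species short name(s) the effect applies to, or NULL
#'   for all.
#' @param tissue Tissue id for `effectTissueSpecific()`.
#' @param fold Fold change (> 0).
#' @param spread Fold at the extreme tissues for `effectHighVar()` (> 1).
#' @param foldProfile Numeric vector of per-tissue folds.
#' @return A list usable in the `effects` slot of a [SimSpec-class].
#' @name simEffects
#' @examples
#' effectTissueSpecific("gene2", tissue = "tissue1", fold = 8,
#'                      species = "human")
NULL

#' @rdname simEffects
#' @export
effectFlat <- function(gene, species = NULL)
  list(type = "flat", gene = gene, species = species)

#' @rdname simEffects
#' @export
effectTissueSpecific <- function(gene, tissue, fold, species = NULL)
  list(type = "tissue_specific", gene = gene, tissue = tissue,
       fold = fold, species = species)

#' @rdname simEffects
#' @export
effectHighVar <- function(gene, spread, species = NULL)
  list(type = "high_var", gene = gene, spread = spread, species = species)

#' @rdname simEffects
#' @export
effectSpeciesVariable <- function(gene, species, foldProfile)
  list(type = "species_variable", gene = gene, species = species,
       foldProfile = foldProfile)

#' Construct a SimSpec
#'
#' @param nGenes,nSpecies,nTissues,nSamplesPerCell Dimensions of the
#'   simulated dataset. Species are the first `nSpecies` of
#'   [supportedSpecies()]; genes and tissues are named `gene1..`,
#'   `tissue1..`.
#' @param baselineMean Baseline NB mean count (> 0).
#' @param dispersion `(a0, a1)` of the mean-dispersion trend
#'   alpha(mu) = a0 + a1/mu.
#' @param effects List of effect descriptors (see [simEffects]).
#' @param seed Mandatory integer seed.
#' @return A validated [SimSpec-class].
#' @examples
#' SimSpec(nGenes = 10, nSpecies = 2, nTissues = 5, seed = 1)
#' @export
SimSpec <- function(nGenes, nSpecies, nTissues, nSamplesPerCell = 4L,
                    baselineMean = 100, dispersion = c(0.05, 2),
                    effects = list(), seed) {
  if (missing(seed)) .usageError("a seed is mandatory for SimSpec")
  new("SimSpec", nGenes = as.integer(nGenes), nSpecies = as.integer(nSpecies),
      nTissues = as.integer(nTissues),
      nSamplesPerCell = as.integer(nSamplesPerCell),
      baselineMean = as.numeric(baselineMean),
      dispersion = as.numeric(dispersion), effects = effects,
      seed = as.integer(seed))
}

#' Read a SimSpec from YAML
#'
#' Keys mirror the [SimSpec()] arguments; `effects` is a list of mappings
#' with a `type` key and the matching effect fields.
#'
#' @param path Path to a YAML file.
#' @return A [SimSpec-class].
#' @export
simSpecFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  effects <- lapply(y$effects, function(e) {
    switch(e$type,
      flat = effectFlat(e$gene, e$species),
      tissue_specific = effectTissueSpecific(e$gene, e$tissue, e$fold,
                                             e$species),
      high_var = effectHighVar(e$gene, e$spread, e$species),
      species_variable = effectSpeciesVariable(e$gene, e$species,
                                               as.numeric(e$foldProfile)),
      .usageError("unknown effect type '%s'", e$type))
  })
  SimSpec(nGenes = y$nGenes, nSpecies = y$nSpecies, nTissues = y$nTissues,
          nSamplesPerCell = if (is.null(y$nSamplesPerCell)) 4L else y$nSamplesPerCell,
          baselineMean = if (is.null(y$baselineMean)) 100 else y$baselineMean,
          dispersion = if (is.null(y$dispersion)) c(0.05, 2) else as.numeric(y$dispersion),
          effects = effects, seed = y$seed)
}

# mu[g, s, t] from baseline and the effect catalog
.simMeans <- function(spec) {
  genes   <- paste0("gene", seq_len(spec@nGenes))
  species <- .speciesRegistry$species[seq_len(spec@nSpecies)]
  tissues <- paste0("tissue", seq_len(spec@nTissues))
  mu <- array(spec@baselineMean, dim = c(spec@nGenes, spec@nSpecies, spec@nTissues),
              dimnames = list(genes, species, tissues))
  for (eff in spec@effects) {
    sps <- if (is.null(eff$species)) species else eff$species
    folds <- switch(eff$type,
      flat = rep(1, spec@nTissues),
      tissue_specific = {
        f <- rep(1, spec@nTissues)
        f[match(eff$tissue, tissues)] <- eff$fold
        f
      },
      high_var = {
        z <- if (spec@nTissues == 1L) 0
             else seq(-1, 1, length.out = spec@nTissues)
        eff$spread^z
      },
      species_variable = eff$foldProfile)
    for (sp in sps) mu[eff$gene, sp, ] <- mu[eff$gene, sp, ] * folds
  }
  mu
}

#' Simulate negative-binomial expression counts
#'
#' Draws counts with mean `mu[g, s, t]` (baseline times the fold factors
#' of the effect catalog) and variance `mu + alpha(mu) * mu^2`, with
#' `alpha(mu) = a0 + a1/mu` from the spec's dispersion. The same spec
#' (which carries its seed) always yields the same table; the caller's
#' RNG state is left untouched.
#'
#' @param spec A [SimSpec-class].
#' @return An [ExpressionTable-class] at scale `counts` with attribute
#'   `"truth"`: a data.frame of the true means per (gene, species,
#'   tissue).
#' @examples
#' tab <- simulateCounts(SimSpec(nGenes = 3, nSpecies = 2, nTissues = 4,
#'                               seed = 7))
#' @export
simulateCounts <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  validObject(spec)
  mu <- .simMeans(spec)
  a0 <- spec@dispersion[1L]; a1 <- spec@dispersion[2L]
  dn <- dimnames(mu)
  grid <- expand.grid(gene_id = dn[[1L]], species = dn[[2L]],
                      tissue = dn[[3L]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  truth <- grid
  truth$mu <- mu[as.matrix(grid[, c("gene_id", "species", "tissue")])]
  n <- spec@nSamplesPerCell
  rec <- truth[rep(seq_len(nrow(truth)), each = n), , drop = FALSE]
  rec$sample_id <- paste0("s", rep(seq_len(n), times = nrow(truth)))
  rec$value <- .withSeed(spec@seed, {
    alpha <- a0 + a1 / rec$mu
    stats::rnbinom(nrow(rec), mu = rec$mu, size = 1 / alpha)
  })
  rec$mu <- NULL
  out <- ExpressionTable(rec, scale = "counts",
                         provenance = sprintf("simulated NB counts (seed %d)",
                                              spec@seed))
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  out
}

#' The five-gene, two-species demonstration dataset
#'
#' A seeded synthetic dataset with the structure used to demonstrate the
#' metrics: 5 genes x 2 species (human, mouse) x 5 tissues x 4 samples.
#' Genes 1, 3 and 4 are flat (low variability everywhere); gene5 has a
#' deterministic high-variability profile across tissues in both species;
#' gene2 is tissue1-specific (8-fold) in the first species but flat in the
#' second — so gene2 shows species-specific variability, and high
#' specificity in species 1 versus high diversity in species 2. Gene ids
#' are shared across the two species, standing for an already-resolved 1:1
#' ortholog pairing.
#'
#' @param seed Integer seed.
#' @return An [ExpressionTable-class] at scale `counts`, 200 records, with
#'   the simulation truth attached as for [simulateCounts()].
#' @examples
#' tab <- makeExampleExpression(seed = 1)
#' nrow(exprData(tab))  # 200
#' @export
makeExampleExpression <- function(seed) {
  spec <- SimSpec(
    nGenes = 5L, nSpecies = 2L, nTissues = 5L, nSamplesPerCell = 4L,
    baselineMean = 100, dispersion = c(0.05, 2),
    effects = list(
      effectFlat("gene1"),
      effectTissueSpecific("gene2", tissue = "tissue1", fold = 8,
                           species = "human"),
      effectFlat("gene2", species = "mouse"),
      effectFlat("gene3"),
      effectFlat("gene4"),
      effectHighVar("gene5", spread = 8)),
    seed = seed)
  simulateCounts(spec)
}
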