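# Internal helpers shared across modules.

# Classed errors so callers and tests can distinguish failure modes.
.cgxStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "crossGEx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.formatError     <- function(fmt, ...) .cgxStop("crossGEx_format_error", fmt, ...)
.validationError <- function(fmt, ...) .cgxStop("crossGEx_validation_error", fmt, ...)
.selectionError  <- function(fmt, ...) .cgxStop("crossGEx_selection_error", fmt, ...)
.fitError        <- function(fmt, ...) .cgxStop("crossGEx_fit_error", fmt, ...)
.usageError      <- function(fmt, ...) .cgxStop("crossGEx_usage_error", fmt, ...)
.ioError         <- function(fmt, ...) .cgxStop("crossGEx_io_error", fmt, ...)

# Evaluate `code` with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.speciesRegistry <- data.frame(
  species    = c("human", "mouse", "rat", "zebrafish", "fly", "worm"),
  taxon_id   = c(9606L, 10090L, 10116L, 7955L, 7227L, 6239L),
  scientific = c("Homo sapiens", "Mus musculus", "Rattus norvegicus",
                 "Danio rerio", "Drosophila melanogaster",
                 "Caenorhabditis elegans"),
  stringsAsFactors = FALSE
)

#' Supported species
#'
#' The six species supported throughout the package, keyed by lowercase
#' short name with NCBI taxon-id aliases accepted wherever a species is
#' named on input.
#'
#' @return A data.frame with columns `species`, `taxon_id` and `scientific`.
#' @examples
#' supportedSpecies()
#' @export
supportedSpecies <- function() .speciesRegistry

#' Normalize species names
#'
#' Maps lowercase short names, scientific names or NCBI taxon ids to the
#' canonical short names used internally. Unknown entries raise an error.
#'
#' @param x Character or numeric vector of species identifiers.
#' @return Character vector of canonical short names.
#' @examples
#' normalizeSpecies(c("human", "10090", "Danio rerio"))
#' @export
normalizeSpecies <- function(x) {
  if (length(x) == 0L) return(character())
  xs <- trimws(as.character(x))
  reg <- .speciesRegistry
  out <- character(length(xs))
  for (i in seq_along(xs)) {
    v <- xs[i]
    hit <- match(tolower(v), reg$species)
    if (is.na(hit)) hit <- match(v, as.character(reg$taxon_id))
    if (is.na(hit)) hit <- match(tolower(v), tolower(reg$scientific))
    if (is.na(hit))
      .validationError("unsupported species: '%s' (supported: %s)",
                       v, paste(reg$species, collapse = ", "))
    out[i] <- reg$species[hit]
  }
  out
}

.taxonToSpecies <- function(taxa) {
  reg <- .speciesRegistry
  reg$species[match(taxa, reg$taxon_id)]
}

.speciesToTaxon <- function(sp) {
  reg <- .speciesRegistry
  reg$taxon_id[match(sp, reg$species)]
}

# 6-significant-digit rendering used by all TSV writers.
.fmtNum <- function(x) {
  out <- ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
  out
}
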