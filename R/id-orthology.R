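#' Load a HomoloGene-style ortholog group table
#'
#' Parses the `homologene.data` dialect: six tab-separated columns
#' `group_id, taxon_id, entrez_gene_id, symbol, protein_gi,
#' protein_accession`, no header. Records for taxa outside the supported
#' six are dropped and counted (real dumps contain ~21 taxa); a line with
#' the wrong number of fields is a parse error naming the line.
#'
#' @param path Path to the file.
#' @return An [OrthologTable-class]; the number of groups and per-species
#'   gene counts are reported via `message()`.
#' @examples
#' f <- tempfile()
#' writeLines(c("3\t9606\t34\tACADM\t4557231\tNP_000007.1",
#'              "3\t10090\t11364\tAcadm\t6680618\tNP_031408.1"), f)
#' loadHomologene(f)
#' @export
loadHomologene <- function(path) {
  if (!file.exists(path)) .ioError("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    .formatError("line %d of %s has %d fields, expected 6",
                 which(nf != 6L)[1L], path, nf[nf != 6L][1L])
  m <- do.call(rbind, fields)
  g <- data.frame(group_id = as.integer(m[, 1L]),
                  taxon_id = as.integer(m[, 2L]),
                  entrez_id = m[, 3L], symbol = m[, 4L],
                  protein_gi = m[, 5L], protein_accession = m[, 6L],
                  stringsAsFactors = FALSE)
  if (anyNA(g$group_id) || anyNA(g$taxon_id))
    .formatError("non-integer group or taxon id in %s", path)
  keep <- g$taxon_id %in% .speciesRegistry$taxon_id
  dropped <- sum(!keep)
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  out <- new("OrthologTable", groups = g, droppedTaxa = as.integer(dropped))
  tab <- table(.taxonToSpecies(g$taxon_id))
  message(sprintf("loadHomologene: %d groups; %s; %d unsupported-taxon records dropped",
                  length(unique(g$group_id)),
                  paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = " "),
                  dropped))
  out
}

#' Read a gene identifier cross-reference table
#'
#' TSV with header `species, ensembl_id, entrez_id, symbol`; an empty
#' string marks an absent identifier.
#'
#' @param path Path to the file.
#' @return An [IdMap-class].
#' @export
readIdMap <- function(path) {
  if (!file.exists(path)) .ioError("file not found: %s", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "", colClasses = "character")
  need <- c("species", "ensembl_id", "entrez_id", "symbol")
  missing <- setdiff(need, names(x))
  if (length(missing))
    .formatError("id map %s is missing column(s): %s", path,
                 paste(missing, collapse = ", "))
  x <- x[, need, drop = FALSE]
  for (col in need) x[[col]][!nzchar(trimws(x[[col]]))] <- NA_character_
  if (anyNA(x$species)) .formatError("id map %s has a record with no species", path)
  x$species <- normalizeSpecies(x$species)
  rownames(x) <- NULL
  new("IdMap", xref = x)
}

.idTypes <- c("ensembl", "entrez", "symbol")
.idCol <- c(ensembl = "ensembl_id", entrez = "entrez_id", symbol = "symbol")

#' Convert gene identifiers within one species
#'
#' Converts among Ensembl ids, Entrez ids and gene symbols using a local
#' [IdMap-class]. Every input id yields at least one output row: unmapped
#' ids get `target_id = NA` and `mapped = FALSE`; one-to-many resolutions
#' (typically symbols) return all matches flagged `ambiguous = TRUE`,
#' never a silent first match.
#'
#' @param ids Character vector of input identifiers (non-empty).
#' @param from,to Identifier types, one of `"ensembl"`, `"entrez"`,
#'   `"symbol"`; must differ.
#' @param species A supported species (short name or taxon id).
#' @param map An [IdMap-class].
#' @return data.frame with columns `input_id, from_type, to_type, species,
#'   target_id, mapped, ambiguous`.
#' @examples
#' map <- readIdMap(system.file("extdata", "toy_idmap.tsv",
#'                              package = "crossGEx"))
#' convertIds("ENSG0001", from = "ensembl", to = "symbol",
#'            species = "human", map = map)
#' @export
convertIds <- function(ids, from, to, species, map) {
  stopifnot(is(map, "IdMap"))
  from <- match.arg(from, .idTypes)
  to <- match.arg(to, .idTypes)
  if (identical(from, to)) .usageError("'from' and 'to' types must differ")
  if (length(ids) == 0L) .usageError("no input ids supplied")
  species <- normalizeSpecies(species)
  x <- map@xref[map@xref$species == species, , drop = FALSE]
  fromCol <- .idCol[[from]]; toCol <- .idCol[[to]]
  rows <- lapply(as.character(ids), function(id) {
    hits <- x[!is.na(x[[fromCol]]) & x[[fromCol]] == id, toCol]
    hits <- unique(hits[!is.na(hits)])
    if (length(hits) == 0L)
      data.frame(input_id = id, from_type = from, to_type = to,
                 species = species, target_id = NA_character_,
                 mapped = FALSE, ambiguous = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(input_id = id, from_type = from, to_type = to,
                 species = species, target_id = sort(hits),
                 mapped = TRUE, ambiguous = length(hits) > 1L,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map orthologs across species via HomoloGene groups
#'
#' For each input gene (Entrez id or symbol) of `fromSpecies`, returns all
#' genes sharing its HomoloGene group in each target species. Genes with
#' no group get a missing row with reason `no_group`; groups lacking a
#' member in a target species give reason `group_lacks_species`. Groups
#' with several members in a target species (paralog expansions) are
#' returned exhaustively with `one_to_many = TRUE`.
#'
#' @param genes Character vector of Entrez ids or symbols (per `idType`).
#' @param fromSpecies Source species; must not be among `toSpecies`.
#' @param toSpecies Character vector of target species.
#' @param orth An [OrthologTable-class].
#' @param idType `"entrez"` or `"symbol"`.
#' @return data.frame with columns `input_id, from_species, to_species,
#'   target_id, target_symbol, group_id, one_to_many, reason` (`reason` is
#'   NA on success; `target_id` is the Entrez id).
#' @export
mapOrthologs <- function(genes, fromSpecies, toSpecies, orth,
                         idType = c("entrez", "symbol")) {
  stopifnot(is(orth, "OrthologTable"))
  idType <- match.arg(idType)
  if (length(genes) == 0L) .usageError("no input genes supplied")
  fromSpecies <- normalizeSpecies(fromSpecies)
  toSpecies <- normalizeSpecies(toSpecies)
  if (fromSpecies %in% toSpecies)
    .usageError("fromSpecies must not be among toSpecies")
  g <- orth@groups
  fromTax <- .speciesToTaxon(fromSpecies)
  idcol <- if (idType == "entrez") "entrez_id" else "symbol"
  rows <- list()
  for (gene in as.character(genes)) {
    groups <- unique(g$group_id[g$taxon_id == fromTax & g[[idcol]] == gene])
    if (length(groups) == 0L) {
      for (sp in toSpecies)
        rows[[length(rows) + 1L]] <- data.frame(
          input_id = gene, from_species = fromSpecies, to_species = sp,
          target_id = NA_character_, target_symbol = NA_character_,
          group_id = NA_integer_, one_to_many = FALSE, reason = "no_group",
          stringsAsFactors = FALSE)
      next
    }
    for (sp in toSpecies) {
      tax <- .speciesToTaxon(sp)
      hits <- g[g$group_id %in% groups & g$taxon_id == tax, , drop = FALSE]
      if (nrow(hits) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          input_id = gene, from_species = fromSpecies, to_species = sp,
          target_id = NA_character_, target_symbol = NA_character_,
          group_id = groups[1L], one_to_many = FALSE,
          reason = "group_lacks_species", stringsAsFactors = FALSE)
      } else {
        hits <- hits[order(hits$group_id, hits$entrez_id), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          input_id = gene, from_species = fromSpecies, to_species = sp,
          target_id = hits$entrez_id, target_symbol = hits$symbol,
          group_id = hits$group_id,
          one_to_many = nrow(hits) > 1L || length(groups) > 1L,
          reason = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
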