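#' Read a long-format expression table from TSV/CSV
#'
#' The file must have a header with the five canonical columns
#' `gene_id, species, tissue, sample_id, value` in any order. Delimiter is
#' chosen from the file extension (`.csv` = comma, otherwise tab).
#'
#' @param path Path to the file.
#' @param scale Declared value scale: `"counts"`, `"tpm"` or `"vst"`.
#' @return A validated [ExpressionTable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(data.frame(gene_id = "g1", species = "human", tissue = "liver",
#'   sample_id = "s1", value = 3), f, sep = "\t", row.names = FALSE,
#'   quote = FALSE)
#' readExpression(f, scale = "counts")
#' @export
readExpression <- function(path, scale = c("counts", "tpm", "vst")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) .ioError("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = TRUE)
  missing <- setdiff(.exprColumns, names(raw))
  if (length(missing))
    .formatError("expression file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", "))
  vals <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(is.na(vals) | !is.finite(vals))[1L]
    .validationError("non-numeric or non-finite value at data row %d of %s",
                     bad, path)
  }
  if (scale %in% c("counts", "tpm") && any(vals < 0)) {
    bad <- which(vals < 0)[1L]
    .validationError("negative %s value %s at data row %d of %s",
                     scale, format(vals[bad]), bad, path)
  }
  key <- paste(raw$gene_id, raw$species, raw$tissue, raw$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- raw[duplicated(key), , drop = FALSE][1L, ]
    .validationError("duplicate record for (%s, %s, %s, %s) in %s",
                     d$gene_id, d$species, d$tissue, d$sample_id, path)
  }
  raw$value <- vals
  ExpressionTable(raw, scale = scale,
                  provenance = sprintf("read from %s (scale=%s)", path, scale))
}

.resolveSelection <- function(requested, available, what) {
  if (length(requested) == 0L) return(available)
  unresolved <- setdiff(requested, available)
  if (length(unresolved))
    .selectionError("unresolved %s name(s): %s", what,
                    paste(unresolved, collapse = ", "))
  requested
}

#' Filter an ExpressionTable by genes, tissues and species
#'
#' Applies a [SelectionSpec-class]: empty fields select everything.
#' Requested names that do not resolve against the table raise a selection
#' error listing them (they are never silently dropped), as does a spec
#' that resolves to zero records. The counts of retained and removed
#' records are reported via `message()` and attached as the
#' `"filter_report"` attribute of the result.
#'
#' @param x An [ExpressionTable-class].
#' @param spec A [SelectionSpec-class].
#' @return The filtered [ExpressionTable-class], same scale.
#' @examples
#' tab <- makeExampleExpression(seed = 1)
#' sub <- filterExpression(tab, SelectionSpec(genes = c("gene1", "gene2")))
#' @export
filterExpression <- function(x, spec = SelectionSpec()) {
  stopifnot(is(x, "ExpressionTable"), is(spec, "SelectionSpec"))
  rec <- x@records
  genes   <- .resolveSelection(spec@genes,   unique(rec$gene_id), "gene")
  tissues <- .resolveSelection(spec@tissues, unique(rec$tissue),  "tissue")
  species <- .resolveSelection(spec@species, unique(rec$species), "species")
  keep <- rec$gene_id %in% genes & rec$tissue %in% tissues &
    rec$species %in% species
  if (!any(keep))
    .selectionError("selection resolves to zero records (genes=%s, tissues=%s, species=%s)",
                    paste(spec@genes, collapse = ","),
                    paste(spec@tissues, collapse = ","),
                    paste(spec@species, collapse = ","))
  out <- new("ExpressionTable",
             records = rec[keep, , drop = FALSE],
             scale = x@scale,
             provenance = c(x@provenance,
                            sprintf("filtered: %d retained, %d removed",
                                    sum(keep), sum(!keep))))
  out@records <- `rownames<-`(out@records, NULL)
  message(sprintf("filterExpression: retained %d records, removed %d",
                  sum(keep), sum(!keep)))
  attr(out, "filter_report") <- c(retained = sum(keep), removed = sum(!keep))
  out
}

# Natural sort keys per result type; first match wins.
.naturalKey <- function(df) {
  candidates <- list(
    c("gene_id", "species", "tissue", "sample_id"),       # ExpressionTable
    c("unit", "unit_id", "species", "mode"),              # DSResult
    c("gene_id", "species", "mode", "group_label"),       # CVResult
    c("input_id", "from_species", "to_species", "target_id"),
    c("input_id", "from_type", "to_type", "target_id")
  )
  for (k in candidates) if (all(k %in% names(df))) return(k)
  names(df)[vapply(df, function(c) is.character(c) || is.factor(c), TRUE)]
}

#' Write a tabular result as deterministic TSV
#'
#' Writes any of the package's tabular results (an
#' [ExpressionTable-class], or a CV / diversity-specificity / mapping
#' result data.frame) as a UTF-8 TSV with header. Rows are sorted by the
#' type's natural key so the same result always produces a byte-identical
#' file; floating-point columns are rendered with 6 significant digits.
#'
#' @param x The result to write.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeResultTable(makeExampleExpression(seed = 1), f)
#' @export
writeResultTable <- function(x, path) {
  if (is(x, "ExpressionTable")) x <- x@records
  if (!is.data.frame(x)) .usageError("not a writable tabular result")
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- .naturalKey(df)
    if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
  }
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (col in names(df)[num]) out[[col]] <- .fmtNum(df[[col]])
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) .ioError("cannot write %s: %s", path,
                                               conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
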