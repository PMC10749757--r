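# Fixtures built in code; the two file-dialect fixtures live in
# inst/extdata and are reached through system.file().

toyRecords <- function() {
  expand.grid(gene_id = c("gA", "gB"), species = c("human", "mouse"),
              tissue = c("liver", "brain"), sample_id = c("s1", "s2"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(value = seq_len(16))
}

toyTable <- function(scale = "counts") ExpressionTable(toyRecords(), scale)

writeToyExpression <- function(records = toyRecords(),
                               path = tempfile(fileext = ".tsv")) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyIdMapPath <- function() system.file("extdata", "toy_idmap.tsv",
                                       package = "crossGEx")
toyHomologenePath <- function() system.file("extdata", "toy_homologene.data",
                                            package = "crossGEx")

toyIdMap <- function() readIdMap(toyIdMapPath())
toyHomologene <- function() suppressMessages(loadHomologene(toyHomologenePath()))

# Random probability profile of length k.
fuzzProfile <- function(k) { p <- runif(k); p / sum(p) }

exampleVst <- function(seed) {
  applyVst(makeExampleExpression(seed = seed),
           trend = DispersionTrend(0.05, 2))
}
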