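## shared fixtures: the worked-example tables, built from the shipped
## JSON files (counts also asserted in test-tables.R)

fixturePath <- function(name) {
  system.file("extdata", name, package = "veribayes", mustWork = TRUE)
}

lungTable <- function() loadTable(fixturePath("table2.json"))

lungExtremeTable <- function() loadTable(fixturePath("table4.json"))

readerTable <- function() loadTable(fixturePath("table6.json"))

riskAucHyper <- function() {
  jsonlite::fromJSON(fixturePath("riskscore_auc_hyper.json"))
}

## independent tie-corrected Mann-Whitney AUC by explicit double loop,
## used as the oracle for the bilinear kernel
aucByEnumeration <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  a <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(q)) {
      if (i > j) a <- a + p[i] * q[j]
      if (i == j) a <- a + p[i] * q[j] / 2
    }
  }
  a
}
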