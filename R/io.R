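#' Write / read a log2 expression matrix as TSV
#'
#' Genes as rows, samples as columns, header row of sample identifiers; the
#' gene symbol sits in the first column (`gene`).
#'
#' @param x SummarizedExperiment or matrix.
#' @param path output path.
#' @export
writeExpressionTsv <- function(x, path) {
  mat <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
         else as.matrix(x)
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeExpressionTsv
#' @return `readExpressionTsv`: numeric matrix with gene rownames.
#' @export
readExpressionTsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d[[1]]
  mat
}

#' Write / read a two-column sample group file
#'
#' @param groups named factor/character (names = sample ids).
#' @param path file path.
#' @export
writeGroupsTsv <- function(groups, path) {
  write.table(data.frame(sample = names(groups),
                         group = as.character(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeGroupsTsv
#' @export
readGroupsTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(factor(d$group), d$sample)
}

#' Write / read a weighted PPI edge list
#'
#' Three tab-separated columns: `protein_a`, `protein_b`, `confidence`
#' (emulating a scored interactome export).
#'
#' @param graph igraph with `confidence` edge attribute.
#' @param path file path.
#' @export
writeEdgeListTsv <- function(graph, path) {
  el <- as_edgelist(graph)
  write.table(data.frame(protein_a = el[, 1], protein_b = el[, 2],
                         confidence = edge_attr(graph, "confidence")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeEdgeListTsv
#' @return `readPpiGraphTsv`: an igraph with `confidence` edge attribute.
#' @export
readPpiGraphTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  g <- graph_from_data_frame(d[, c("protein_a", "protein_b")],
                             directed = FALSE)
  set_edge_attr(g, "confidence", value = d$confidence)
}

#' Write / read per-patient flow events
#'
#' One CSV per patient: one row per event, one column per marker, values on
#' the log10 fluorescence scale.
#'
#' @param events named list of per-patient data.frames.
#' @param dir output directory.
#' @export
writeFlowEventsCsv <- function(events, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in names(events))
    write.csv(events[[p]], file.path(dir, paste0(p, ".csv")),
              row.names = FALSE)
  invisible(file.path(dir, paste0(names(events), ".csv")))
}

#' @rdname writeFlowEventsCsv
#' @export
readFlowEventsCsv <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  ev <- lapply(files, read.csv)
  names(ev) <- sub("\\.csv$", "", basename(files))
  ev
}

#' Write a LAIP profile table
#'
#' Patient-by-marker rows with the -/+/++/+++ symbol, modality, dominant
#' subpopulation fraction, MFI and the binary collapse.
#'
#' @param profiles list of [LAIPProfile-class] objects.
#' @param path output TSV.
#' @export
writeLaipTsv <- function(profiles, path) {
  write.table(laipTable(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Write network significance results
#'
#' A TSV of per-network scores plus a JSON of member lists.
#'
#' @param scoreSet a [NetworkScoreSet-class].
#' @param dir output directory.
#' @export
writeNetworkResults <- function(scoreSet, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(networkScores(scoreSet), file.path(dir, "networks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(networkMembers(scoreSet),
                       file.path(dir, "network_members.json"))
  invisible(dir)
}

#' Write / read the patient outcome table
#'
#' @param patients data.frame with `id`, covariates and `mrd` (character;
#'   below-LOD values carry the `"<LOD"` sentinel).
#' @param path file path.
#' @export
writePatientsTsv <- function(patients, path) {
  write.table(patients, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writePatientsTsv
#' @export
readPatientsTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(mrd = "character"))
}

#' Write ground truth as JSON
#'
#' @param truth a truth record (list).
#' @param path output path.
#' @export
writeTruthJson <- function(truth, path) {
  # named atomic vectors become JSON objects, not bare arrays
  truth <- rapply(truth, function(x)
    if (!is.null(names(x))) as.list(x) else x, how = "replace")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
}
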