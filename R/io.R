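.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# strict TSV reader: header required, fixed schema, ragged rows reported
.readTsv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != length(columns))
  if (length(bad))
    stop(sprintf("%s: line %d has %d field(s); expected %d (%s)",
                 path, bad[1L], nf[bad[1L]], length(columns),
                 paste(columns, collapse = ", ")))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character",
                          comment.char = "", check.names = FALSE)
  if (!identical(names(df), columns))
    stop(sprintf("%s: header is (%s); expected (%s)",
                 path, paste(names(df), collapse = ", "),
                 paste(columns, collapse = ", ")))
  df
}

#' Read the drug table
#'
#' @param path TSV file with header columns \code{drug_id}, \code{smiles}.
#' @return data.frame(drug_id, smiles).
#' @export
readDrugTable <- function(path) {
  df <- .readTsv(path, c("drug_id", "smiles"))
  if (anyDuplicated(df$drug_id))
    stop(path, ": duplicated drug_id values")
  df
}

#' Read a DDI edge list
#'
#' @param path TSV file with header columns \code{drug_id_a},
#'   \code{drug_id_b} (an optional third \code{weight} column is accepted).
#' @return data.frame(drug_id_a, drug_id_b[, weight]).
#' @export
readEdgeList <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  cols <- if (length(nf) && nf[1L] == 3L)
    c("drug_id_a", "drug_id_b", "weight") else c("drug_id_a", "drug_id_b")
  df <- .readTsv(path, cols)
  if ("weight" %in% names(df)) df$weight <- as.numeric(df$weight)
  df
}

#' Read the drug-receptor association table
#'
#' @param path TSV file with header columns \code{drug_id},
#'   \code{receptor_id}, \code{function_type}.
#' @return data.frame(drug_id, receptor_id, function_type).
#' @export
readAssociations <- function(path) {
  .readTsv(path, c("drug_id", "receptor_id", "function_type"))
}

#' Write token embeddings as TSV
#'
#' One row per token: the token followed by its embedding coordinates.
#'
#' @param table a [TokenEmbeddingTable-class].
#' @param path output path.
#' @export
writeEmbeddingsTsv <- function(table, path) {
  m <- table@inputWeights
  df <- data.frame(token = table@vocab, m, check.names = FALSE)
  names(df) <- c("token", paste0("e", seq_len(ncol(m))))
  .writeTsv(df, path)
}

#' Write node embeddings as TSV
#'
#' @param emb a [NodeEmbedding-class].
#' @param path output path.
#' @export
writeNodeEmbeddingsTsv <- function(emb, path) {
  m <- emb@vertexVectors
  df <- data.frame(drug_id = rownames(m), m, check.names = FALSE)
  names(df) <- c("drug_id", paste0("e", seq_len(ncol(m))))
  .writeTsv(df, path)
}

#' Write the fused similarity matrix as TSV
#'
#' N x N matrix with a drug-id header row and first column.
#'
#' @param fused a [FusedSimilarity-class].
#' @param path output path.
#' @export
writeFusedSimilarityTsv <- function(fused, path) {
  m <- fused@matrix
  df <- data.frame(drug_id = rownames(m), m, check.names = FALSE)
  .writeTsv(df, path)
}

#' Write a metrics report as JSON
#'
#' @param report a [MetricsReport-class] or a named numeric vector of
#'   metrics for a single evaluation.
#' @param path output path.
#' @export
writeMetricsJson <- function(report, path) {
  out <- if (is(report, "MetricsReport"))
    list(perFold = report@perFold, summary = report@summary)
  else as.list(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write ranked candidate partners as TSV
#'
#' @param ranking data.frame from [rankCandidates()].
#' @param path output path.
#' @export
writeRankingTsv <- function(ranking, path) {
  .writeTsv(ranking, path)
}
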