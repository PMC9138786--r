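#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default, so a run can be
#' fully described (and re-run) from one object. Defaults:
#' \itemize{
#'   \item tokenizer: \code{"atomwise"} SMILES granularity;
#'   \item CBOW: dim 64, window 5, minCount 1, 15 epochs;
#'   \item drug matrix: 64 rows (pad/truncate);
#'   \item graph embedding: dim 64, coarsening threshold
#'     \code{max(100, ceiling(|V|/32))} (NULL = that rule), 100 edge-sampling
#'     epochs, 5 negative samples, lr 0.025;
#'   \item SNF: K 20 neighbours, 20 iterations, mu 0.5;
#'   \item fusion model: 3x3 conv kernels (64 of them) with ReLU and global
#'     average pooling, dense reducers 64 (net) and 300-64 (bio), attention
#'     d_k 64, head 256/128/64 with dropout 0.3, Adam lr 1e-3, batch 256,
#'     up to 50 epochs with early stopping (patience 5) on the validation
#'     split;
#'   \item protocol: \code{"split_70_20_10"} or \code{"cv5"}; classification
#'     threshold 0.5;
#'   \item ablation toggles: \code{useChem}, \code{useNet}, \code{useBio},
#'     \code{useAttention}, all TRUE.
#' }
#'
#' @param ... overrides of any default, by name. Unknown names are an error.
#' @return named list of settings.
#' @export
ddiConfig <- function(...) {
  cfg <- list(
    tokenizer = "atomwise",
    cbowDim = 64L, cbowWindow = 5L, cbowMinCount = 1L, cbowEpochs = 15L,
    cbowLr = 0.1, cbowBatch = 512L,
    lMax = 64L,
    embedDim = 64L, coarsenThreshold = NULL,
    lineEpochs = 100L, lineNegK = 5L, lineLr = 0.025,
    snfK = 20L, snfT = 20L, snfMu = 0.5,
    convKernels = 64L, convSize = 3L,
    hiddenSizes = c(256L, 128L, 64L), dropout = 0.3,
    adamLr = 1e-3, batchSize = 256L, epochs = 50L, patience = 5L,
    valFraction = 0.1,
    useChem = TRUE, useNet = TRUE, useBio = TRUE, useAttention = TRUE,
    protocol = "split_70_20_10", k = 5L, threshold = 0.5
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Write a resolved configuration next to run outputs
#'
#' @param config list from [ddiConfig()], plus any run metadata.
#' @param path output JSON path.
#' @export
writeConfigJson <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
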