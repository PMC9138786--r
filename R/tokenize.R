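#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the symbol sequence used as the "sentence" for
#' CBOW embedding. Two granularities are supported:
#' \describe{
#'   \item{atomwise}{chemically truthful tokens: bracket atoms
#'     (\code{"[nH]"}, \code{"[O-]"}, ...) and the two-letter organic-subset
#'     elements \code{Cl} and \code{Br} stay single tokens; every other
#'     character is its own token.}
#'   \item{char}{plain character split.}
#' }
#' Concatenating the returned tokens always reconstructs the input.
#'
#' @param smiles non-empty SMILES string.
#' @param mode \code{"atomwise"} (default) or \code{"char"}.
#' @return character vector of tokens.
#' @examples
#' tokenizeSmiles("C(Cl)Br")            # "C" "(" "Cl" ")" "Br"
#' tokenizeSmiles("C(Cl)Br", "char")    # "C" "(" "C" "l" ")" "B" "r"
#' @export
tokenizeSmiles <- function(smiles, mode = c("atomwise", "char")) {
  mode <- match.arg(mode)
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L)
    stop("empty sequence")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  if (mode == "char") return(chars)

  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop(sprintf("unbalanced bracket opened at position %d", i))
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("unbalanced bracket closed at position %d", i))
    } else if (i < n &&
               ((ch == "C" && chars[i + 1L] == "l") ||
                (ch == "B" && chars[i + 1L] == "r"))) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Tokenize a set of SMILES strings into a corpus
#'
#' @param smiles named character vector (names are drug ids) or a
#'   data.frame with columns \code{drug_id} and \code{smiles}.
#' @param mode tokenizer granularity, see [tokenizeSmiles()].
#' @return named list of token vectors, one per drug.
#' @export
tokenizeCorpus <- function(smiles, mode = c("atomwise", "char")) {
  mode <- match.arg(mode)
  if (is.data.frame(smiles)) {
    ids <- smiles$drug_id
    smiles <- smiles$smiles
    names(smiles) <- ids
  }
  lapply(stats::setNames(as.character(smiles), names(smiles)),
         tokenizeSmiles, mode = mode)
}
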