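#' Tokenize clinical note text
#'
#' The single tokenizer shared by every stage of the pipeline (word-count
#' exclusions, document assembly, embedding training, term extraction), so
#' that a "word" means the same thing everywhere: text is lowercased,
#' punctuation is replaced by whitespace, numerals are kept, and the result is
#' split on whitespace.
#'
#' @param text Character vector of raw note texts.
#' @return A list of character vectors (one token vector per input element).
#' @examples
#' tokenize("Patient was very agitated; BP 120/80.")
#' @export
tokenize <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  out <- strsplit(x, " +")
  out[x == ""] <- list(character(0))
  out
}

#' Count words in note text
#'
#' @param text Character vector of raw note texts.
#' @return Integer vector of token counts under [tokenize()].
#' @export
count_words <- function(text) {
  lengths(tokenize(text))
}
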