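# package-local cache for the scoring matrix
.fm_env <- new.env(parent = emptyenv())

# 20 standard amino acids + X (unknown)
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","X")

AA20 <- AA_ALPHABET[1:20]

GAP <- "-"

#' BLOSUM62 substitution matrix restricted to the package alphabet
#'
#' @return a 21 x 21 numeric matrix (20 standard residues plus X).
#' @keywords internal
blosum62 <- function() {
  if (is.null(.fm_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fm_env$b62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .fm_env$b62
}

# BLOSUM62 / 4, the sequence-term scale used throughout the aligners
blosum62_scaled <- function() {
  if (is.null(.fm_env$b62s)) .fm_env$b62s <- blosum62() / 4
  .fm_env$b62s
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

degap <- function(x) gsub("-", "", x, fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
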