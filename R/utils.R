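#' @importFrom stats anova aov lm TukeyHSD sd cor.test pt t.test setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

#' Watson-Crick complement of single bases
#' @param x character vector of single bases.
#' @return complementary bases (A<->T, C<->G).
#' @export
wc_complement <- function(x) chartr("ACGT", "TGCA", x)

## classed errors so the CLI can map failures to exit codes:
## input problems -> exit 2, invariant violations -> exit 3
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pretrna_input_error", "error")))
}

stop_invariant <- function(...) {
  stop(errorCondition(paste0(...), class = c("pretrna_invariant_error", "error")))
}

join_flags <- function(flag_list) {
  vapply(flag_list, function(f) paste(f, collapse = ","), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
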