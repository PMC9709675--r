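#' Canonical treatment-combination strings
#'
#' A treatment combination is the exact set of drug codes a patient is exposed
#' to on a given day. Combinations are represented throughout the package as
#' canonical strings: the distinct codes sorted lexicographically and joined
#' with `"+"`. The empty set -- no active treatment -- renders as `"NONE"`.
#' Equality of combinations is exact set equality, so `"A+B"`, `"A"` and
#' `"A+B+C"` are three distinct therapies.
#'
#' @param drugs character vector of drug codes (ATC-style strings); empty
#'   elements and duplicates are dropped. A zero-length vector is the empty
#'   combination.
#' @return length-1 character string in canonical form.
#' @examples
#' combination(c("C07AB", "B01AC", "B01AC"))  # "B01AC+C07AB"
#' combination(character())                   # "NONE"
#' @export
combination <- function(drugs) {
  drugs <- unique(as.character(drugs))
  drugs <- drugs[!is.na(drugs) & nzchar(drugs) & drugs != NONE_LABEL]
  if (length(drugs) == 0L) return(NONE_LABEL)
  paste(sort(drugs), collapse = "+")
}

#' @rdname combination
#' @param x a canonical combination string.
#' @return for `combination_drugs()`, the character vector of member codes
#'   (zero-length for `"NONE"`).
#' @export
combination_drugs <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x == NONE_LABEL || !nzchar(x)) return(character())
  strsplit(x, "+", fixed = TRUE)[[1L]]
}

NONE_LABEL <- "NONE"
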