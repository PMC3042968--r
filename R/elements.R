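# Supported element table and valence model.

# Standard valences; S and P are multivalent and resolve to the smallest
# allowed valence >= the current bond-order sum.
.mcdl_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

.mcdl_elements <- names(.mcdl_valences)

#' Supported elements
#'
#' MCDL fragments in this package are restricted to a table of common
#' organic-chemistry elements. Multivalent sulfur (2, 4, 6) and phosphorus
#' (3, 5) resolve to the smallest standard valence that accommodates the
#' current bond-order sum.
#'
#' @return Character vector of supported element symbols.
#' @export
mcdl_elements <- function() .mcdl_elements

check_elements <- function(elements) {
  bad <- setdiff(unique(elements), .mcdl_elements)
  if (length(bad) > 0L) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Smallest standard valence >= bond-order sum, or NA if the sum overflows
# every allowed valence.
resolve_valence <- function(element, order_sum) {
  allowed <- .mcdl_valences[[element]]
  ok <- allowed[allowed >= order_sum]
  if (length(ok) == 0L) NA_integer_ else ok[1L]
}

allowed_valences <- function(element) .mcdl_valences[[element]]

# Locale-independent ASCII (byte) ordering.
ascii_order <- function(x) order(x, method = "radix")

ascii_sort <- function(x) x[ascii_order(x)]

# Tokenize a fragment label into element symbols: uppercase letter plus
# optional lowercase letter, longest match. Errors if the label does not
# tokenize exactly.
tokenize_label <- function(label) {
  m <- gregexpr("[A-Z][a-z]?", label)[[1L]]
  if (m[1L] == -1L) stop("cannot tokenize label: ", label, call. = FALSE)
  syms <- regmatches(label, gregexpr("[A-Z][a-z]?", label))[[1L]]
  if (paste(syms, collapse = "") != label) {
    stop("cannot tokenize label: ", label, call. = FALSE)
  }
  check_elements(syms)
  syms
}
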