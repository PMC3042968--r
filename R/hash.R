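# Branch hashing: numbering-independent identification of substituent
# branches by iterative neighborhood refinement.

# Two independent 31-bit modular hash channels, combined into a 64-bit-style
# hex string. Multipliers are < 2^22 so every product stays below 2^53 and
# the arithmetic is exact in doubles on every platform.
.hash_mod <- c(2147483647, 2147483629)
.hash_mul <- c(4194301, 3145721)

hash_mix <- function(h, x) (h * .hash_mul + (x %% .hash_mod)) %% .hash_mod

hash_fold_sorted <- function(values_list) {
  # values_list: list of length-2 numeric channel pairs; fold in sorted order
  if (length(values_list) == 0L) return(c(7, 7))
  m <- do.call(rbind, values_list)
  o <- order(m[, 1L], m[, 2L])
  h <- c(11, 13)
  for (k in o) h <- hash_mix(h, m[k, ])
  h
}

element_code <- function(el) {
  vapply(el, function(s) sum(utf8ToInt(s) * c(256, 1)[seq_along(utf8ToInt(s))]),
         numeric(1L))
}

#' Hash a substituent branch
#'
#' Identifies the branch reached from `root` via `entry`, excluding the bond
#' back to `root`: the subgraph containing `entry` after deleting `root` is
#' refined iteratively (element, degree, then neighbor hashes with bond
#' orders) to stabilization, and folded into a fixed-width hash. Equal
#' branches always receive equal hashes; the value is deterministic across
#' runs and platforms. Unlike a first-shell fragment comparison, full-depth
#' refinement distinguishes branches that differ only away from the
#' stereocenter (ethyl vs propyl).
#'
#' @param g An `mcdl_graph`.
#' @param root Atom index of the stereogenic (or reference) atom.
#' @param entry Atom index of a neighbor of `root`.
#' @return A 16-character hex string.
#' @export
branch_hash <- function(g, root, entry) {
  adj <- adjacency(g)
  if (!entry %in% adj[[root]]) stop("entry must be adjacent to root", call. = FALSE)
  el <- g$atoms$element
  deg <- atom_degree(g)
  # branch atoms: component of entry with root deleted
  sub_adj <- lapply(adj, function(v) v[v != root])
  members <- component_of(sub_adj, entry)
  idx <- match(seq_len(nrow(g$atoms)), members)  # atom -> position or NA

  h <- lapply(members, function(v) hash_mix(c(3, 5), element_code(el[v]) * 64 + deg[v]))
  rounds <- length(members)
  for (r in seq_len(rounds)) {
    h_new <- h
    for (p in seq_along(members)) {
      v <- members[p]
      nb <- sub_adj[[v]]
      nb <- nb[!is.na(idx[nb])]
      contrib <- lapply(nb, function(u) {
        hash_mix(h[[idx[u]]], bond_order_between(g, v, u))
      })
      h_new[[p]] <- hash_mix(h[[p]], hash_fold_sorted(contrib))
    }
    h <- h_new
  }
  final <- hash_mix(hash_mix(c(17, 19), h[[idx[entry]]]), hash_fold_sorted(h))
  sprintf("%08x%08x", as.integer(final[1L]), as.integer(final[2L]))
}

# All branch hashes around one atom, named by neighbor index.
branch_hashes_around <- function(g, center) {
  adj <- adjacency(g)
  nb <- adj[[center]]
  vapply(nb, function(u) branch_hash(g, center, u), character(1L))
}
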