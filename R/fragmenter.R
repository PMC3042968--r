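# Fragment decomposition, composition module, canonical numbering search.

#' Decompose a molecule into MCDL structural fragments
#'
#' A structural fragment is one non-terminal "core" atom together with its
#' degree-1 terminal neighbors. The fragment label is the core element
#' symbol followed by the terminal symbols in ascending ASCII order (e.g.
#' `"CBrHH"` for CH2Br). In a two-atom molecule the atom with the ASCII-
#' smaller element symbol becomes the core; a single atom is a fragment with
#' no terminals.
#'
#' @param g A connected `mcdl_graph` with explicit hydrogens.
#' @return A tibble with columns `core` (atom index), `label`, and
#'   `terminals` (list column of terminal atom indices, sorted by symbol).
#' @export
decompose_fragments <- function(g) {
  n <- nrow(g$atoms)
  deg <- atom_degree(g)
  adj <- adjacency(g)
  el <- g$atoms$element
  if (n == 1L) {
    return(tibble::tibble(core = 1L, label = el[1L], terminals = list(integer())))
  }
  if (n == 2L && all(deg == 1L)) {
    ord <- ascii_order(el)
    core <- ord[1L]; term <- ord[2L]
    if (el[1L] == el[2L]) { core <- 1L; term <- 2L }
    return(tibble::tibble(core = core,
                          label = paste0(el[core], el[term]),
                          terminals = list(term)))
  }
  terminal <- deg == 1L
  cores <- which(!terminal)
  frag <- tibble::tibble(core = cores, label = NA_character_,
                         terminals = vector("list", length(cores)))
  for (fi in seq_along(cores)) {
    c_atom <- cores[fi]
    terms <- adj[[c_atom]][terminal[adj[[c_atom]]]]
    terms <- terms[ascii_order(el[terms])]
    frag$terminals[[fi]] <- terms
    frag$label[fi] <- paste0(el[c_atom], paste(el[terms], collapse = ""))
  }
  frag
}

#' Build the composition module
#'
#' Fragment labels sorted in ascending ASCII order, runs of equal labels
#' collapsed with an integer multiplicity prefix when the count exceeds one,
#' joined with semicolons (e.g. `"C;CHH;2CHHH;CO;2OH"`).
#'
#' @param fragments Output of [decompose_fragments()].
#' @return The composition module string.
#' @export
composition_module <- function(fragments) {
  labs <- ascii_sort(fragments$label)
  r <- rle(labs)
  paste(ifelse(r$lengths > 1L, paste0(r$lengths, r$values), r$values),
        collapse = ";")
}

# Fragment-level adjacency: edges between cores, as a 2-column matrix of
# fragment ids (rows of `fragments`), plus the bond order of each edge.
fragment_edges <- function(g, fragments) {
  core_frag <- integer(nrow(g$atoms))
  core_frag[fragments$core] <- seq_len(nrow(fragments))
  b <- g$bonds
  is_core <- logical(nrow(g$atoms))
  is_core[fragments$core] <- TRUE
  keep <- is_core[b$begin] & is_core[b$end]
  if (!any(keep)) {
    return(list(edges = matrix(integer(), 0L, 2L), order = integer()))
  }
  eb <- b[keep, , drop = FALSE]
  fi <- core_frag[eb$begin]; fj <- core_frag[eb$end]
  list(edges = cbind(pmin(fi, fj), pmax(fi, fj)), order = eb$order)
}

# --- connectivity module --------------------------------------------------

new_connectivity <- function(lists) {
  structure(list(lists = lists), class = "mcdl_connectivity")
}

#' Serialize a connectivity module
#'
#' Per-fragment ascending lists of higher-numbered bonded fragments, joined
#' with semicolons inside square brackets; trailing empty lists are dropped
#' (e.g. `"[2,3,5,6;4;;;7]"`).
#'
#' @param conn A connectivity module from [enumerate_canonical_numberings()].
#' @return The bracketed connectivity string, or `""` for a single fragment.
#' @export
serialize_connectivity <- function(conn) {
  lists <- conn$lists
  if (length(lists) <= 1L) return("")
  last <- max(c(0L, which(vapply(lists, length, 1L) > 0L)))
  if (last == 0L) return("")
  body <- vapply(lists[seq_len(last)],
                 function(v) paste(v, collapse = ","), character(1L))
  paste0("[", paste(body, collapse = ";"), "]")
}

# Flat comparison key: for each fragment, its sorted >i neighbor ranks then a
# -1 terminator. Total length #edges + #fragments, so keys from the same
# constitution align position by position; the terminator sorts before any
# rank, realizing the "exhausted list first" rule.
connectivity_key <- function(lists) {
  unlist(lapply(lists, function(v) c(v, -1L)), use.names = FALSE)
}

lists_from_assignment <- function(edges, rank_of, n) {
  lists <- vector("list", n)
  for (m in seq_len(n)) lists[[m]] <- integer()
  if (nrow(edges) > 0L) {
    a <- pmin(rank_of[edges[, 1L]], rank_of[edges[, 2L]])
    b <- pmax(rank_of[edges[, 1L]], rank_of[edges[, 2L]])
    o <- order(a, b)
    for (k in o) lists[[a[k]]] <- c(lists[[a[k]]], b[k])
  }
  lists
}

#' Compare two connectivity modules
#'
#' Lexicographic comparison of the per-fragment list sequences: lists are
#' compared element-wise with integers compared numerically, and an
#' exhausted (shorter) list sorts before a longer one at the point of
#' difference. The canonical connectivity module is the minimum under this
#' order.
#'
#' @param a,b Connectivity modules with the same fragment count.
#' @return -1, 0 or 1.
#' @export
compare_connectivity <- function(a, b) {
  ka <- connectivity_key(a$lists)
  kb <- connectivity_key(b$lists)
  if (length(ka) != length(kb)) {
    stop("connectivity modules have different sizes", call. = FALSE)
  }
  d <- which(ka != kb)
  if (length(d) == 0L) return(0L)
  if (ka[d[1L]] < kb[d[1L]]) -1L else 1L
}

#' Enumerate canonical numbering schemes
#'
#' Searches all fragment numberings that respect composition (label) order
#' for the minimal connectivity serialization, and returns every scheme
#' achieving that minimum — the constitutionally equivalent set over which
#' stereo canonicalization later selects. The search is a backtracking
#' assignment within equal-label classes with sound prefix pruning against
#' the best solution found so far; an explicit capacity error is raised if
#' the search exceeds one million visited states.
#'
#' @param g A connected `mcdl_graph` with explicit hydrogens.
#' @param fragments Output of [decompose_fragments()].
#' @param cap Maximum number of visited search states.
#' @return List with `connectivity` (the canonical module), `schemes` (list
#'   of integer vectors: `rank_of[fragment id]`), and `composition`.
#' @export
enumerate_canonical_numberings <- function(g, fragments, cap = 1e6) {
  n <- nrow(fragments)
  fe <- fragment_edges(g, fragments)
  edges <- fe$edges
  # classes in ascending ASCII label order
  labs <- fragments$label
  ulabs <- ascii_sort(unique(labs))
  classes <- lapply(ulabs, function(l) which(labs == l))
  class_end <- cumsum(vapply(classes, length, 1L))  # last rank of each class

  # fragment-level neighbor lists
  fadj <- vector("list", n)
  for (i in seq_len(n)) fadj[[i]] <- integer()
  for (k in seq_len(nrow(edges))) {
    fadj[[edges[k, 1L]]] <- c(fadj[[edges[k, 1L]]], edges[k, 2L])
    fadj[[edges[k, 2L]]] <- c(fadj[[edges[k, 2L]]], edges[k, 1L])
  }

  env <- new.env(parent = emptyenv())
  env$rank_of <- integer(n)        # 0 = unassigned
  env$frag_at <- integer(n)
  env$best_key <- NULL
  env$best_lists <- NULL
  env$best_schemes <- list()
  env$visited <- 0

  bump <- function() {
    env$visited <- env$visited + 1
    if (env$visited > cap) {
      stop("canonical numbering search exceeded capacity (", format(cap),
           " states); molecule too symmetric for this search", call. = FALSE)
    }
  }

  # Compare the determined part of the partial assignment (ranks 1..upto all
  # assigned) with the best key. Returns "prune", "win" or "tie".
  prefix_status <- function(upto) {
    if (is.null(env$best_key)) return("tie")
    bk <- env$best_key
    pos <- 0L
    for (m in seq_len(upto)) {
      fid <- env$frag_at[m]
      nb <- fadj[[fid]]
      rk <- env$rank_of[nb]
      known <- sort(rk[rk > m])          # assigned neighbors with rank > m
      complete <- all(env$rank_of[nb] > 0L)
      for (v in known) {
        pos <- pos + 1L
        if (v < bk[pos]) return("win")
        if (v > bk[pos]) return("prune")
      }
      if (!complete) {
        # next element will be some rank > upto
        pos <- pos + 1L
        if (bk[pos] != -1L && bk[pos] <= upto) return("prune")
        return("tie")
      }
      pos <- pos + 1L                    # terminator
      if (bk[pos] != -1L) return("win")  # best has more elements here
    }
    "tie"
  }

  recurse_class <- function(ci) {
    if (ci > length(classes)) {
      bump()
      lists <- lists_from_assignment(edges, env$rank_of, n)
      key <- connectivity_key(lists)
      if (is.null(env$best_key)) cmp <- -1L
      else {
        d <- which(key != env$best_key)
        cmp <- if (length(d) == 0L) 0L
               else if (key[d[1L]] < env$best_key[d[1L]]) -1L else 1L
      }
      if (cmp < 0L) {
        env$best_key <- key
        env$best_lists <- lists
        env$best_schemes <- list(env$rank_of)
      } else if (cmp == 0L) {
        env$best_schemes[[length(env$best_schemes) + 1L]] <- env$rank_of
      }
      return(invisible())
    }
    members <- classes[[ci]]
    start_rank <- if (ci == 1L) 1L else class_end[ci - 1L] + 1L
    assign_pos <- function(p, used) {
      if (p > length(members)) {
        bump()
        st <- prefix_status(class_end[ci])
        if (st != "prune") recurse_class(ci + 1L)
        return(invisible())
      }
      for (m in members[!used]) {
        env$rank_of[m] <- start_rank + p - 1L
        env$frag_at[start_rank + p - 1L] <- m
        used2 <- used
        used2[match(m, members)] <- TRUE
        assign_pos(p + 1L, used2)
        env$rank_of[m] <- 0L
      }
      invisible()
    }
    assign_pos(1L, logical(length(members)))
  }

  recurse_class(1L)
  list(connectivity = new_connectivity(env$best_lists),
       schemes = env$best_schemes,
       composition = composition_module(fragments))
}
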