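# MCDL string parsing, bond-order reconstruction and round-trip
# canonicalization.

#' Parse an MCDL descriptor string
#'
#' Grammar: composition module, optional bracketed connectivity module,
#' optional `{SA:}` module, optional `{SB:}` module. Fragment labels are
#' tokenized into element symbols (uppercase letter plus optional lowercase
#' letter, longest match); empty token positions are dummies; `d` in
#' `x1dx2` marks the double bond. Unrecognized trailing module blocks are
#' kept verbatim (with a warning) but not interpreted.
#'
#' @param text One MCDL descriptor string.
#' @return An object of class `mcdl_descriptor`: composition (tibble of
#'   multiplicity/label), connectivity lists, SA and SB entries.
#' @export
parse_mcdl <- function(text) {
  text <- trimws(text)
  m <- regexec("^([^\\[{]+)(\\[[^]]*\\])?(\\{SA:[^}]*\\})?(\\{SB:[^}]*\\})?(.*)$",
               text)
  parts <- regmatches(text, m)[[1L]]
  if (length(parts) == 0L || parts[2L] == "") {
    stop("unparseable MCDL string: ", text, call. = FALSE)
  }
  comp_str <- parts[2L]; conn_str <- parts[3L]
  sa_str <- parts[4L]; sb_str <- parts[5L]; rest <- parts[6L]
  extra <- character()
  if (nzchar(rest)) {
    if (grepl("^(\\{[A-Za-z0-9]+:[^}]*\\})+$", rest)) {
      warning("unrecognized supplementary MCDL module(s) skipped: ", rest,
              call. = FALSE)
      extra <- rest
    } else {
      stop("unparseable trailing content in MCDL string: ", rest, call. = FALSE)
    }
  }

  # composition
  entries <- strsplit(comp_str, ";", fixed = TRUE)[[1L]]
  if (length(entries) == 0L || any(entries == "")) {
    stop("malformed composition module: ", comp_str, call. = FALSE)
  }
  mult <- integer(length(entries)); label <- character(length(entries))
  for (i in seq_along(entries)) {
    mm <- regexec("^([0-9]+)?([A-Za-z]+)$", entries[i])
    p <- regmatches(entries[i], mm)[[1L]]
    if (length(p) == 0L) {
      stop("malformed composition entry: ", entries[i], call. = FALSE)
    }
    mult[i] <- if (p[2L] == "") 1L else as.integer(p[2L])
    label[i] <- p[3L]
    tokenize_label(label[i])   # validates elements
  }
  composition <- tibble::tibble(mult = mult, label = label)
  nfrag <- sum(mult)
  # rank -> label
  frag_labels <- rep(label, mult)

  # connectivity
  lists <- rep(list(integer()), nfrag)
  if (!is.na(conn_str) && nzchar(conn_str)) {
    body <- substr(conn_str, 2L, nchar(conn_str) - 1L)
    if (nzchar(body)) {
      raw <- strsplit(body, ";", fixed = TRUE)[[1L]]
      # strsplit drops a trailing empty field; recover it
      nsep <- lengths(regmatches(body, gregexpr(";", body, fixed = TRUE)))
      if (length(raw) < nsep + 1L) raw <- c(raw, rep("", nsep + 1L - length(raw)))
      if (length(raw) > nfrag) {
        stop("connectivity module has more lists than fragments", call. = FALSE)
      }
      for (i in seq_along(raw)) {
        if (raw[i] == "") next
        v <- suppressWarnings(as.integer(strsplit(raw[i], ",", fixed = TRUE)[[1L]]))
        if (any(is.na(v))) stop("malformed connectivity list: ", raw[i], call. = FALSE)
        if (any(v <= i)) {
          stop(sprintf("connectivity list %d contains a rank <= %d", i, i),
               call. = FALSE)
        }
        if (any(v > nfrag)) {
          stop(sprintf("fragment rank %d out of range (%d fragments)",
                       max(v), nfrag), call. = FALSE)
        }
        lists[[i]] <- sort(v)
      }
    }
  }

  parse_token <- function(s) {
    if (s == "") return(token_dummy())
    if (grepl("^[0-9]+$", s)) {
      k <- as.integer(s)
      if (k < 1L || k > nfrag) {
        stop(sprintf("fragment rank %d out of range (%d fragments)", k, nfrag),
             call. = FALSE)
      }
      return(token_fragment(k))
    }
    if (grepl("^[A-Z][a-z]?$", s)) {
      check_elements(s)
      return(token_terminal(s))
    }
    stop("malformed stereo token: '", s, "'", call. = FALSE)
  }

  frag_terminals <- function(rank) tokenize_label(frag_labels[rank])[-1L]

  check_terminal_member <- function(tok, rank, what) {
    if (tok$kind == "terminal" && !tok$symbol %in% frag_terminals(rank)) {
      stop(sprintf("%s token %s is not a terminal of fragment %d (%s)",
                   what, tok$symbol, rank, frag_labels[rank]), call. = FALSE)
    }
  }

  sa <- list()
  if (!is.na(sa_str) && nzchar(sa_str)) {
    body <- substr(sa_str, 5L, nchar(sa_str) - 1L)
    for (es in strsplit(body, ";", fixed = TRUE)[[1L]]) {
      f <- strsplit(paste0(es, "\x01"), ",", fixed = TRUE)[[1L]]
      f[length(f)] <- sub("\x01$", "", f[length(f)])
      if (length(f) != 5L) stop("malformed SA entry: ", es, call. = FALSE)
      center <- suppressWarnings(as.integer(f[1L]))
      if (is.na(center) || center < 1L || center > nfrag) {
        stop("SA center rank out of range: ", f[1L], call. = FALSE)
      }
      toks <- lapply(f[2:5], parse_token)
      keys <- vapply(toks, token_key, character(1L))
      if (anyDuplicated(keys)) stop("duplicate tokens in SA entry: ", es, call. = FALSE)
      ord <- order(keys, method = "radix")
      if (ord[1L] != 1L || ord[2L] != 2L) {
        stop("SA entry violates top/bottom priority order: ", es, call. = FALSE)
      }
      for (t in toks) check_terminal_member(t, center, "SA")
      sa[[length(sa) + 1L]] <- list(center = center, top = toks[[1L]],
                                    bottom = toks[[2L]], left = toks[[3L]],
                                    right = toks[[4L]])
    }
  }

  sb <- list()
  if (!is.na(sb_str) && nzchar(sb_str)) {
    body <- substr(sb_str, 5L, nchar(sb_str) - 1L)
    for (es in strsplit(body, ";", fixed = TRUE)[[1L]]) {
      f <- strsplit(paste0(es, "\x01"), ",", fixed = TRUE)[[1L]]
      f[length(f)] <- sub("\x01$", "", f[length(f)])
      if (length(f) != 5L) stop("malformed SB entry: ", es, call. = FALSE)
      xm <- regexec("^([0-9]+)d([0-9]+)$", f[1L])
      xp <- regmatches(f[1L], xm)[[1L]]
      if (length(xp) == 0L) stop("malformed SB bond field: ", f[1L], call. = FALSE)
      x1 <- as.integer(xp[2L]); x2 <- as.integer(xp[3L])
      if (x1 >= x2) stop(sprintf("SB requires x1 < x2, got %dd%d", x1, x2),
                         call. = FALSE)
      if (x2 > nfrag) stop("SB fragment rank out of range: ", f[1L], call. = FALSE)
      toks <- lapply(f[2:5], parse_token)
      k1 <- token_key(toks[[1L]]); k4 <- token_key(toks[[4L]])
      if (identical(sort(c(k1, k4), method = "radix")[1L], k4) && k1 != k4) {
        stop("SB entry violates the n1/n4 priority order: ", es, call. = FALSE)
      }
      check_terminal_member(toks[[1L]], x1, "SB n1")
      check_terminal_member(toks[[4L]], x1, "SB n4")
      check_terminal_member(toks[[2L]], x2, "SB n2")
      check_terminal_member(toks[[3L]], x2, "SB n3")
      sb[[length(sb) + 1L]] <- list(x1 = x1, x2 = x2, n1 = toks[[1L]],
                                    n2 = toks[[2L]], n3 = toks[[3L]],
                                    n4 = toks[[4L]])
    }
  }

  structure(list(composition = composition, connectivity = new_connectivity(lists),
                 sa = sa, sb = sb, extra = extra,
                 frag_labels = frag_labels),
            class = "mcdl_descriptor")
}

#' @export
print.mcdl_descriptor <- function(x, ...) {
  cat("<mcdl_descriptor: ", length(x$frag_labels), " fragments, ",
      length(x$sa), " SA, ", length(x$sb), " SB>\n", sep = "")
  invisible(x)
}

#' Reconstruct a molecular graph from a parsed descriptor
#'
#' Builds one core atom per fragment plus its terminal atoms, connects
#' fragments per the connectivity module, and assigns bond orders by
#' backtracking so that every atom's bond-order sum equals a standard
#' valence. Bonds named in `{SB:}` entries are fixed at order 2. Among
#' multiple valid assignments the deterministic minimum over bonds sorted by
#' (min rank, max rank, terminal symbol) is returned, with a warning —
#' structures capable of valence tautomerism genuinely need extra bond-order
#' information that base MCDL does not store.
#'
#' @param d An `mcdl_descriptor`.
#' @return An `mcdl_graph` with zero coordinates. Attribute
#'   `"core_of_rank"` maps fragment rank to core atom index.
#' @export
reconstruct_bond_orders <- function(d) {
  labels <- d$frag_labels
  n <- length(labels)
  el <- character(0)
  core_of <- integer(n)
  term_atoms <- vector("list", n)   # named by symbol position
  for (k in seq_len(n)) {
    syms <- tokenize_label(labels[k])
    core_of[k] <- length(el) + 1L
    el <- c(el, syms[1L])
    terms <- integer(0)
    if (length(syms) > 1L) {
      tsyms <- ascii_sort(syms[-1L])
      terms <- length(el) + seq_along(tsyms)
      el <- c(el, tsyms)
    }
    term_atoms[[k]] <- terms
  }
  # bonds with sort keys
  bonds <- list()
  add_bond <- function(i, j, key) {
    bonds[[length(bonds) + 1L]] <<- list(begin = i, end = j, key = key,
                                         fixed = NA_integer_)
  }
  for (i in seq_len(n)) {
    for (j in d$connectivity$lists[[i]]) {
      add_bond(core_of[i], core_of[j], list(i, j, ""))
    }
    for (t in term_atoms[[i]]) {
      add_bond(core_of[i], t, list(i, i, el[t]))
    }
  }
  for (e in d$sb) {
    hit <- FALSE
    for (b in seq_along(bonds)) {
      if (bonds[[b]]$begin == core_of[e$x1] && bonds[[b]]$end == core_of[e$x2]) {
        bonds[[b]]$fixed <- 2L; hit <- TRUE
      }
    }
    if (!hit) {
      stop(sprintf("SB entry %dd%d does not correspond to a connectivity bond",
                   e$x1, e$x2), call. = FALSE)
    }
  }
  if (length(bonds) > 0L) {
    keys1 <- vapply(bonds, function(b) b$key[[1L]], 1L)
    keys2 <- vapply(bonds, function(b) b$key[[2L]], 1L)
    keys3 <- vapply(bonds, function(b) b$key[[3L]], "")
    bonds <- bonds[order(keys1, keys2, keys3, method = "radix")]
  }

  natoms <- length(el)
  incident <- vector("list", natoms)
  for (bi in seq_along(bonds)) {
    b <- bonds[[bi]]
    incident[[b$begin]] <- c(incident[[b$begin]], bi)
    incident[[b$end]] <- c(incident[[b$end]], bi)
  }
  maxval <- vapply(el, function(e) max(allowed_valences(e)), 1L)

  orders <- integer(length(bonds))
  solutions <- list()
  search <- function(bi) {
    if (length(solutions) >= 2L) return(invisible())
    if (bi > length(bonds)) {
      sums <- numeric(natoms)
      for (b in seq_along(bonds)) {
        sums[bonds[[b]]$begin] <- sums[bonds[[b]]$begin] + orders[b]
        sums[bonds[[b]]$end] <- sums[bonds[[b]]$end] + orders[b]
      }
      ok <- all(vapply(seq_len(natoms),
                       function(a) sums[a] %in% allowed_valences(el[a]), TRUE))
      if (ok) solutions[[length(solutions) + 1L]] <<- orders
      return(invisible())
    }
    b <- bonds[[bi]]
    choices <- if (!is.na(b$fixed)) b$fixed else 1:3
    for (o in choices) {
      orders[bi] <<- o
      # prune: partial sums must stay feasible
      feasible <- TRUE
      for (a in c(b$begin, b$end)) {
        inc <- incident[[a]]
        assigned <- inc[inc <= bi]
        s <- sum(orders[assigned])
        remaining <- length(inc) - length(assigned)
        if (s + remaining > maxval[a]) { feasible <- FALSE; break }
        if (remaining == 0L && !s %in% allowed_valences(el[a])) {
          feasible <- FALSE; break
        }
      }
      if (feasible) search(bi + 1L)
    }
    orders[bi] <<- 0L
    invisible()
  }
  search(1L)
  if (length(solutions) == 0L) {
    stop("no valence-consistent bond-order assignment exists for this descriptor",
         call. = FALSE)
  }
  if (length(solutions) > 1L) {
    warning("multiple valence-consistent bond-order assignments; ",
            "returning the deterministic minimal one", call. = FALSE)
  }
  orders <- solutions[[1L]]
  btab <- tibble::tibble(
    begin = vapply(bonds, function(b) b$begin, 1L),
    end = vapply(bonds, function(b) b$end, 1L),
    order = as.integer(orders), wedge = "none")
  g <- mcdl_graph(tibble::tibble(element = el, x = 0, y = 0, z = 0,
                                 explicit_h = FALSE),
                  btab, dimensionality = "2D")
  attr(g, "core_of_rank") <- core_of
  attr(g, "term_atoms") <- term_atoms
  g
}

# Abstract stereo configurations from SA/SB entries of a parsed descriptor,
# in the package's internal representation on the reconstructed graph.
abstract_configs <- function(d, g) {
  core_of <- attr(g, "core_of_rank")
  term_atoms <- attr(g, "term_atoms")
  el <- g$atoms$element
  token_atom <- function(tok, rank) {
    switch(tok$kind,
           dummy = 0L,
           fragment = core_of[tok$number],
           terminal = {
             cand <- term_atoms[[rank]][el[term_atoms[[rank]]] == tok$symbol]
             if (length(cand) != 1L) {
               stop(sprintf("terminal token %s is not unique on fragment %d",
                            tok$symbol, rank), call. = FALSE)
             }
             cand
           })
  }
  atom_configs <- lapply(d$sa, function(e) {
    tblr <- vapply(list(e$top, e$bottom, e$left, e$right), token_atom,
                   integer(1L), rank = e$center)
    reals <- sort(tblr[tblr != 0L])
    stored <- if (length(reals) == 3L) c(reals, 0L) else reals
    perm <- match(stored, tblr)
    list(center = core_of[e$center], subs = stored,
         parity = .fischer_parity * perm_sign(perm))
  })
  bond_configs <- lapply(d$sb, function(e) {
    a <- core_of[e$x1]; b <- core_of[e$x2]
    n1 <- token_atom(e$n1, e$x1); n4 <- token_atom(e$n4, e$x1)
    n2 <- token_atom(e$n2, e$x2); n3 <- token_atom(e$n3, e$x2)
    a_subs <- sort(c(n1, n4)); a_subs <- c(a_subs[a_subs != 0L], a_subs[a_subs == 0L])
    b_subs <- sort(c(n2, n3)); b_subs <- c(b_subs[b_subs != 0L], b_subs[b_subs == 0L])
    a_ref <- a_subs[a_subs != 0L][1L]
    b_ref <- b_subs[b_subs != 0L][1L]
    # n1 and n2 are on the same side; translate to the chosen reference pair
    same <- TRUE
    if (a_ref != n1) same <- !same
    if (b_ref != n2) same <- !same
    list(a = a, b = b, a_subs = a_subs, b_subs = b_subs,
         a_ref = a_ref, b_ref = b_ref, same_side = same)
  })
  list(atoms = atom_configs, bonds = bond_configs)
}

#' Decode an MCDL string into a molecular graph
#'
#' Parses, reconstructs bond orders and attaches the abstract stereo
#' configurations as attribute `"stereo"`.
#'
#' @param text One MCDL descriptor string.
#' @return An `mcdl_graph`.
#' @export
mcdl_decode <- function(text) {
  d <- parse_mcdl(text)
  g <- reconstruct_bond_orders(d)
  attr(g, "stereo") <- abstract_configs(d, g)
  g
}

#' Re-canonicalize an MCDL string
#'
#' Parses the descriptor, rebuilds the molecular graph and its abstract
#' stereo configurations, and re-encodes through the full canonical
#' pipeline. Canonical descriptors map to themselves; valid but
#' non-canonical descriptors map to the canonical representative. The
#' renumbering of an SA entry is purely combinatorial: the new token
#' priorities restore the top/bottom positions through even permutations
#' only, flipping left/right exactly when the required permutation is odd —
#' no 3D embedding is involved.
#'
#' @param text One MCDL descriptor string.
#' @return The canonical MCDL string.
#' @export
roundtrip_canonicalize <- function(text) {
  d <- parse_mcdl(text)
  g <- reconstruct_bond_orders(d)
  cfg <- abstract_configs(d, g)
  encode_with_configs(g, provider = "abstract",
                      atom_configs = cfg$atoms, bond_configs = cfg$bonds)
}
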