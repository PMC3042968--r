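# Stereo tokens, {SA:}/{SB:} entry construction, canonical selection and
# descriptor serialization.

# --- tokens ---------------------------------------------------------------

token_dummy <- function() list(kind = "dummy")
token_fragment <- function(k) list(kind = "fragment", number = as.integer(k))
token_terminal <- function(symbol) list(kind = "terminal", symbol = symbol)

# Total priority order: dummy (electron pair, priority 0) before fragments
# by ascending rank before terminal atoms by ascending ASCII symbol. Smaller
# key = higher priority.
token_key <- function(tok) {
  switch(tok$kind,
         dummy = "0",
         fragment = sprintf("1%09d", tok$number),
         terminal = paste0("2", tok$symbol))
}

token_serialize <- function(tok) {
  switch(tok$kind,
         dummy = "",
         fragment = as.character(tok$number),
         terminal = tok$symbol)
}

# Map a substituent atom reference (0 = dummy) to its stereo token under a
# numbering scheme.
ref_token <- function(sub, scheme, frag_of_core, g) {
  if (sub == 0L) return(token_dummy())
  fid <- frag_of_core[sub]
  if (!is.na(fid) && fid > 0L) return(token_fragment(scheme[fid]))
  token_terminal(g$atoms$element[sub])
}

frag_of_core_map <- function(g, fragments) {
  m <- rep(NA_integer_, nrow(g$atoms))
  m[fragments$core] <- seq_len(nrow(fragments))
  m
}

perm_sign <- function(p) {
  n <- length(p)
  sign <- 1
  seen <- logical(n)
  for (i in seq_len(n)) {
    if (!seen[i]) {
      j <- i; len <- 0L
      while (!seen[j]) { seen[j] <- TRUE; j <- p[j]; len <- len + 1L }
      if (len %% 2L == 0L) sign <- -sign
    }
  }
  sign
}

# Parity of the ideal Fischer frame (top/bottom pointing away from the
# viewer, left/right toward): a valid {SA:} arrangement read as
# (top, bottom, left, right) must have this parity. Pinned by the D-lactic
# acid reference descriptor {SA:1,2,3,4,H}.
.fischer_parity <- 1

#' Build one {SA:} entry under a numbering scheme
#'
#' Substituent references are mapped to stereo tokens (fragment rank,
#' terminal symbol, or the empty dummy), the two highest-priority tokens are
#' placed top and bottom, and the remaining two are ordered left/right so
#' the Fischer-projection parity of the (top, bottom, left, right)
#' arrangement realizes the perceived configuration — only even numbers of
#' position switches away from the perceived arrangement are allowed.
#'
#' @param config Atom configuration (`center`, `subs`, `parity`) from
#'   perception or from a parsed descriptor.
#' @param scheme Integer vector mapping fragment id to rank.
#' @param g The `mcdl_graph`.
#' @param fragments Output of [decompose_fragments()].
#' @return An SA entry: list with `center` (rank) and tokens `top`,
#'   `bottom`, `left`, `right`.
#' @export
build_sa_entry <- function(config, scheme, g, fragments) {
  frag_of <- frag_of_core_map(g, fragments)
  tokens <- lapply(config$subs, ref_token, scheme = scheme,
                   frag_of_core = frag_of, g = g)
  keys <- vapply(tokens, token_key, character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate stereo tokens at one center: detection should have excluded this",
         call. = FALSE)
  }
  ord <- order(keys, method = "radix")
  arrangement <- c(ord[1L], ord[2L], ord[3L], ord[4L])
  parity_tblr <- config$parity * perm_sign(arrangement)
  if (parity_tblr != .fischer_parity) {
    arrangement <- c(ord[1L], ord[2L], ord[4L], ord[3L])
  }
  cf <- frag_of[config$center]
  list(center = scheme[cf],
       top = tokens[[arrangement[1L]]], bottom = tokens[[arrangement[2L]]],
       left = tokens[[arrangement[3L]]], right = tokens[[arrangement[4L]]])
}

#' Build one {SB:} entry under a numbering scheme
#'
#' The two double-bond fragment ranks are ordered x1 < x2; n1 is the
#' higher-priority connection to x1 (excluding x2), n4 the other, n2 the
#' connection to x2 lying on the same side of the double bond as n1, and n3
#' the remaining one. Dummies serialize as empty fields.
#'
#' @param config Bond configuration from perception or a parsed descriptor:
#'   `a`, `b`, `a_subs`, `b_subs`, `a_ref`, `b_ref`, `same_side`.
#' @param scheme Integer vector mapping fragment id to rank.
#' @param g The `mcdl_graph`.
#' @param fragments Output of [decompose_fragments()].
#' @return An SB entry: list with `x1`, `x2` and tokens `n1`..`n4`.
#' @export
build_sb_entry <- function(config, scheme, g, fragments) {
  frag_of <- frag_of_core_map(g, fragments)
  r_a <- scheme[frag_of[config$a]]
  r_b <- scheme[frag_of[config$b]]
  if (r_a < r_b) {
    x1 <- r_a; x2 <- r_b
    s1 <- config$a_subs; s2 <- config$b_subs
    ref1 <- config$a_ref; ref2 <- config$b_ref
  } else {
    x1 <- r_b; x2 <- r_a
    s1 <- config$b_subs; s2 <- config$a_subs
    ref1 <- config$b_ref; ref2 <- config$a_ref
  }
  s1 <- pad_dummy(s1); s2 <- pad_dummy(s2)
  t1 <- lapply(s1, ref_token, scheme = scheme, frag_of_core = frag_of, g = g)
  k1 <- vapply(t1, token_key, character(1L))
  o1 <- order(k1, method = "radix")
  n1_sub <- s1[o1[1L]]; n4_sub <- s1[o1[2L]]
  # same-side relation between an x1 substituent and an x2 substituent:
  # the two substituents on one end are on opposite sides, and the dummy is
  # opposite the real substituent by construction.
  same <- function(u, v) {
    xor(xor(config$same_side, u != ref1), v != ref2)
  }
  if (same(n1_sub, s2[1L])) {
    n2_sub <- s2[1L]; n3_sub <- s2[2L]
  } else {
    n2_sub <- s2[2L]; n3_sub <- s2[1L]
  }
  tok <- function(s) ref_token(s, scheme, frag_of, g)
  list(x1 = x1, x2 = x2,
       n1 = tok(n1_sub), n2 = tok(n2_sub), n3 = tok(n3_sub), n4 = tok(n4_sub))
}

pad_dummy <- function(s) {
  if (length(s) == 1L) c(s, 0L) else s
}

sa_stream <- function(entries) {
  unlist(lapply(entries, function(e) {
    c(token_key(token_fragment(e$center)),
      token_key(e$top), token_key(e$bottom), token_key(e$left),
      token_key(e$right))
  }), use.names = FALSE)
}

sb_stream <- function(entries) {
  unlist(lapply(entries, function(e) {
    c(token_key(token_fragment(e$x1)), token_key(token_fragment(e$x2)),
      token_key(e$n1), token_key(e$n2), token_key(e$n3), token_key(e$n4))
  }), use.names = FALSE)
}

#' Select the canonical stereo descriptor across numbering schemes
#'
#' For each constitutionally equivalent numbering scheme the SA entries
#' (sorted by ascending center rank) and SB entries (sorted by ascending x1,
#' x2) are built and flattened into one token stream — SA entries before SB
#' entries, since atomic stereogenic units outrank double bonds. Streams are
#' compared position by position under the token priority order, and the
#' candidate winning at the first difference (highest priority, i.e. the
#' lowest ASCII code sequence) is returned.
#'
#' @param atom_configs List of atom configurations.
#' @param bond_configs List of bond configurations.
#' @param schemes List of numbering schemes (from
#'   [enumerate_canonical_numberings()]).
#' @param g The `mcdl_graph`.
#' @param fragments Output of [decompose_fragments()].
#' @return List with `sa`, `sb` (winning entry lists) and `scheme`.
#' @export
canonical_stereo_select <- function(atom_configs, bond_configs, schemes, g,
                                    fragments) {
  if (length(schemes) == 0L) stop("no numbering schemes supplied", call. = FALSE)
  frag_of <- frag_of_core_map(g, fragments)
  best <- NULL
  for (scheme in schemes) {
    sa <- lapply(atom_configs, build_sa_entry, scheme = scheme, g = g,
                 fragments = fragments)
    if (length(sa) > 0L) {
      sa <- sa[order(vapply(sa, function(e) e$center, 1L))]
    }
    sb <- lapply(bond_configs, build_sb_entry, scheme = scheme, g = g,
                 fragments = fragments)
    if (length(sb) > 0L) {
      sb <- sb[order(vapply(sb, function(e) e$x1, 1L),
                     vapply(sb, function(e) e$x2, 1L))]
    }
    stream <- c(sa_stream(sa), sb_stream(sb))
    if (is.null(best) || stream_less(stream, best$stream)) {
      best <- list(sa = sa, sb = sb, scheme = scheme, stream = stream)
    }
  }
  best[c("sa", "sb", "scheme")]
}

# TRUE when stream a strictly outranks (sorts before) stream b.
# Byte-order (locale-independent) comparison.
stream_less <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- which(a != b)
  if (length(d) == 0L) return(FALSE)
  x <- a[d[1L]]; y <- b[d[1L]]
  identical(sort(c(x, y), method = "radix")[1L], x)
}

serialize_sa <- function(entries) {
  body <- vapply(entries, function(e) {
    paste(c(e$center, token_serialize(e$top), token_serialize(e$bottom),
            token_serialize(e$left), token_serialize(e$right)), collapse = ",")
  }, character(1L))
  paste0("{SA:", paste(body, collapse = ";"), "}")
}

serialize_sb <- function(entries) {
  body <- vapply(entries, function(e) {
    paste(c(paste0(e$x1, "d", e$x2), token_serialize(e$n1),
            token_serialize(e$n2), token_serialize(e$n3),
            token_serialize(e$n4)), collapse = ",")
  }, character(1L))
  paste0("{SB:", paste(body, collapse = ";"), "}")
}

#' Serialize a full MCDL descriptor
#'
#' Composition module, bracketed connectivity module (omitted for a single
#' fragment), then the optional `{SA:}` and `{SB:}` modules. A parsed
#' [mcdl_descriptor][parse_mcdl()] may be passed as the first argument, so
#' `serialize_descriptor(parse_mcdl(x))` is the identity on canonical
#' strings.
#'
#' @param composition Composition module string, or an `mcdl_descriptor`.
#' @param connectivity Connectivity string from [serialize_connectivity()].
#' @param sa,sb Entry lists from [canonical_stereo_select()].
#' @return The MCDL descriptor string.
#' @export
serialize_descriptor <- function(composition, connectivity = "", sa = list(),
                                 sb = list()) {
  if (inherits(composition, "mcdl_descriptor")) {
    d <- composition
    comp <- paste(ifelse(d$composition$mult > 1L,
                         paste0(d$composition$mult, d$composition$label),
                         d$composition$label), collapse = ";")
    return(serialize_descriptor(comp, serialize_connectivity(d$connectivity),
                                d$sa, d$sb))
  }
  out <- paste0(composition, connectivity)
  if (length(sa) > 0L) out <- paste0(out, serialize_sa(sa))
  if (length(sb) > 0L) out <- paste0(out, serialize_sb(sb))
  out
}
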