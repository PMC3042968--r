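# Top-level encoder: molecular graph -> canonical MCDL string.

#' Encode a molecular graph as a canonical MCDL descriptor
#'
#' Runs the full pipeline: hydrogen normalization, 2D wedge lifting when
#' needed, fragment decomposition, canonical numbering search, stereo
#' perception, canonical stereo selection and serialization.
#'
#' Atomic configurations are read from 3D coordinates, or from 2D
#' coordinates with wedge bonds (narrow end at the stereocenter). In a 2D
#' drawing, a topologically stereogenic atom that carries no wedge has an
#' undefined configuration and is silently omitted from the `{SA:}` module;
#' wedges drawn at non-stereogenic atoms are ignored, so such structures
#' encode as achiral. Ambiguous geometry (coplanar substituents in 3D,
#' near-linear sp2 drawings) raises an error.
#'
#' @param g A connected `mcdl_graph`.
#' @param stereo Emit `{SA:}`/`{SB:}` modules? `FALSE` reproduces the
#'   constitution-only descriptor.
#' @return The canonical MCDL string.
#' @export
mcdl_encode <- function(g, stereo = TRUE) {
  validate_graph(g)
  g <- normalize_hydrogens(g)
  if (!is_connected(g)) {
    stop("graph is not connected; use split_components() first", call. = FALSE)
  }
  gp <- g
  if (g$dimensionality == "2D") {
    if (any(g$bonds$wedge != "none")) {
      gp <- wedge_lift(g)
    } else {
      attr(gp, "lifted") <- TRUE   # planar drawing: atom configs undefined
    }
  }
  encode_with_configs(gp, provider = "geometry", stereo = stereo)
}

# Shared canonicalization: configurations come either from geometry or from
# an abstract lookup table (parser path).
encode_with_configs <- function(g, provider, stereo = TRUE,
                                atom_configs = NULL, bond_configs = NULL) {
  fragments <- decompose_fragments(g)
  enum <- enumerate_canonical_numberings(g, fragments)
  conn_str <- serialize_connectivity(enum$connectivity)
  if (!stereo) {
    return(serialize_descriptor(enum$composition, conn_str))
  }
  centers <- detect_stereocenters(g)
  bonds <- detect_stereobonds(g)
  if (identical(provider, "geometry")) {
    acfg <- list()
    for (cand in centers) {
      cfg <- perceive_atom_config(g, cand$center, cand$subs)
      if (!is.null(cfg)) acfg[[length(acfg) + 1L]] <- cfg
    }
    bcfg <- lapply(bonds, perceive_bond_config, g = g)
  } else {
    # abstract: match supplied configurations to detected units
    acfg <- list()
    for (cand in centers) {
      hit <- Filter(function(c) c$center == cand$center, atom_configs)
      if (length(hit) == 1L) {
        cfg <- hit[[1L]]
        stopifnot(identical(sort(cfg$subs), sort(cand$subs)))
        acfg[[length(acfg) + 1L]] <- cfg
      }
    }
    bcfg <- list()
    for (cand in bonds) {
      hit <- Filter(function(c) c$a == cand$a && c$b == cand$b, bond_configs)
      if (length(hit) == 1L) bcfg[[length(bcfg) + 1L]] <- hit[[1L]]
    }
    n_unmatched <- length(atom_configs) - length(acfg) +
      length(bond_configs) - length(bcfg)
    if (n_unmatched > 0L) {
      warning(n_unmatched,
              " stereo configuration(s) at non-stereogenic units dropped",
              call. = FALSE)
    }
  }
  if (length(acfg) == 0L && length(bcfg) == 0L) {
    return(serialize_descriptor(enum$composition, conn_str))
  }
  sel <- canonical_stereo_select(acfg, bcfg, enum$schemes, g, fragments)
  serialize_descriptor(enum$composition, conn_str, sel$sa, sel$sb)
}
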