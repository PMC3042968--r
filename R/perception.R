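# Stereo perception: detection of stereogenic units and extraction of
# numbering-independent configurations from geometry.

# Tunable geometric tolerances (see the methods vignette).
mcdl_opt <- function(name, default) {
  v <- getOption(paste0("mcdl.", name))
  if (is.null(v)) default else v
}

#' Detect atomic stereocenters
#'
#' An atom is stereogenic when its four substituent branches are pairwise
#' distinct under [branch_hash()]. Three-coordinate sulfur atoms (lone-pair
#' centers such as sulfoxides) with three distinct branches are also
#' stereogenic; they receive a "dummy" fourth substituent representing the
#' electron pair, encoded as atom index 0.
#'
#' @param g An `mcdl_graph` with explicit hydrogens.
#' @return List of candidate centers: each a list with `center` (atom index)
#'   and `subs` (four atom indices sorted ascending, 0 = dummy last).
#' @export
detect_stereocenters <- function(g) {
  deg <- atom_degree(g)
  adj <- adjacency(g)
  out <- list()
  for (i in seq_len(nrow(g$atoms))) {
    if (deg[i] == 4L) {
      hs <- branch_hashes_around(g, i)
      if (anyDuplicated(hs) == 0L) {
        out[[length(out) + 1L]] <- list(center = i, subs = sort(adj[[i]]))
      }
    } else if (deg[i] == 3L && g$atoms$element[i] == "S") {
      hs <- branch_hashes_around(g, i)
      if (anyDuplicated(hs) == 0L) {
        out[[length(out) + 1L]] <- list(center = i, subs = c(sort(adj[[i]]), 0L))
      }
    }
  }
  out
}

# Is the bond between a and b part of a ring? (i.e. not a bridge)
bond_in_ring <- function(g, a, b) {
  adj <- adjacency(g)
  adj[[a]] <- adj[[a]][adj[[a]] != b]
  adj[[b]] <- adj[[b]][adj[[b]] != a]
  b %in% component_of(adj, a)
}

#' Detect stereogenic double bonds
#'
#' Acyclic double bonds whose two ends each carry substituents with distinct
#' branch hashes; a missing substituent (two-coordinate end) becomes a dummy.
#' Double bonds within rings are excluded, as are ends that are terminal
#' atoms or carry two identical branches.
#'
#' @param g An `mcdl_graph` with explicit hydrogens.
#' @return List of candidates: each a list with `a`, `b` (atom indices,
#'   a < b) and `a_subs`, `b_subs` (substituent atom indices, 0 = dummy,
#'   each of length 1 or 2, sorted ascending with dummy last).
#' @export
detect_stereobonds <- function(g) {
  deg <- atom_degree(g)
  adj <- adjacency(g)
  b <- g$bonds
  out <- list()
  for (k in which(b$order == 2L)) {
    i <- min(b$begin[k], b$end[k]); j <- max(b$begin[k], b$end[k])
    if (deg[i] < 2L || deg[j] < 2L) next       # terminal end: inside a fragment
    if (deg[i] > 3L || deg[j] > 3L) next       # not sp2-like
    if (bond_in_ring(g, i, j)) next
    end_subs <- function(v, partner) {
      subs <- sort(adj[[v]][adj[[v]] != partner])
      if (length(subs) == 2L) {
        hs <- c(branch_hash(g, v, subs[1L]), branch_hash(g, v, subs[2L]))
        if (hs[1L] == hs[2L]) return(NULL)
        subs
      } else {
        c(subs, 0L)
      }
    }
    si <- end_subs(i, j); if (is.null(si)) next
    sj <- end_subs(j, i); if (is.null(sj)) next
    out[[length(out) + 1L]] <- list(a = i, b = j, a_subs = si, b_subs = sj)
  }
  out
}

#' Unit vectors from a stereocenter to its substituents
#'
#' Returns the four unit direction vectors used by [atom_parity()]. The
#' dummy substituent of a three-coordinate center points to the position of
#' maximum distance from the three real substituents on the unit sphere,
#' realized as the antipode of their normalized vector sum. Coplanar
#' geometry (|det| below the `mcdl.coplanar_tol` option, default 1e-3)
#' raises an ambiguous-geometry error naming the center.
#'
#' @param g An `mcdl_graph` with meaningful coordinates (3D, or 2D lifted by
#'   [wedge_lift()]).
#' @param center Atom index of the center.
#' @param subs Four substituent atom indices (0 = dummy).
#' @return A 4 x 3 matrix of unit vectors.
#' @export
substituent_vectors <- function(g, center, subs) {
  xyz <- coords(g)
  p0 <- xyz[center, ]
  vecs <- matrix(NA_real_, 4L, 3L)
  real <- subs != 0L
  for (k in which(real)) vecs[k, ] <- unitize(xyz[subs[k], ] - p0)
  if (any(!real)) {
    s <- colSums(vecs[real, , drop = FALSE])
    if (sqrt(sum(s^2)) < 1e-8) {
      stop(sprintf("ambiguous geometry at atom %d: degenerate dummy direction",
                   center), call. = FALSE)
    }
    vecs[!real, ] <- rep(-unitize(s), each = sum(!real))
  }
  d <- det(rbind(vecs[2L, ] - vecs[1L, ], vecs[3L, ] - vecs[1L, ],
                 vecs[4L, ] - vecs[1L, ]))
  if (abs(d) < mcdl_opt("coplanar_tol", 1e-3)) {
    stop(sprintf("ambiguous geometry at atom %d: substituents are coplanar",
                 center), call. = FALSE)
  }
  vecs
}

#' Fischer-projection parity of four substituent vectors
#'
#' Implements the rotation procedure for reading a configuration as a
#' Fischer projection: the molecule is rotated so the first vector lies on
#' the +y axis and the second lies in the yz plane with negative z; the
#' parity is +1 when the third vector then reads as Fischer-left (negative
#' x) and -1 otherwise. Swapping any two inputs flips the sign; rigid
#' rotations leave it unchanged.
#'
#' The four vectors are first re-centered on their centroid (and
#' re-normalized), which maps any non-coplanar arrangement — including the
#' flat-plus-wedge geometry of a lifted 2D drawing — onto the tetrahedral
#' regime without changing the handedness of the configuration, so the
#' rotation read is always well conditioned. The result equals the sign of
#' the determinant det(v2-v1, v3-v1, v4-v1) up to one fixed global sign.
#'
#' @param vecs A 4 x 3 matrix of unit vectors.
#' @return +1 or -1.
#' @export
atom_parity <- function(vecs) {
  stopifnot(is.matrix(vecs), nrow(vecs) == 4L, ncol(vecs) == 3L)
  d <- det(rbind(vecs[2L, ] - vecs[1L, ], vecs[3L, ] - vecs[1L, ],
                 vecs[4L, ] - vecs[1L, ]))
  if (abs(d) < mcdl_opt("coplanar_tol", 1e-3)) {
    stop("coplanar substituent vectors: parity undefined", call. = FALSE)
  }
  ctr <- colMeans(vecs)
  vecs <- t(apply(vecs, 1L, function(v) unitize(v - ctr)))
  v1 <- unitize(vecs[1L, ])
  # rotate v1 onto +y
  y <- c(0, 1, 0)
  ax <- cross3(v1, y)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    R1 <- if (v1[2L] > 0) diag(3) else diag(c(-1, -1, 1))
  } else {
    ax <- ax / s
    ang <- acos(max(-1, min(1, sum(v1 * y))))
    R1 <- rotation_matrix(ax, ang)
  }
  v2 <- as.numeric(R1 %*% vecs[2L, ])
  r <- sqrt(v2[1L]^2 + v2[3L]^2)
  if (r < 1e-9) {
    stop("second substituent collinear with the first: parity undefined",
         call. = FALSE)
  }
  # rotate about y so v2 lands in the yz plane with z < 0
  psi <- atan2(v2[1L], v2[3L])
  phi <- pi - psi
  Ry <- rbind(c(cos(phi), 0, sin(phi)), c(0, 1, 0), c(-sin(phi), 0, cos(phi)))
  v3 <- as.numeric(Ry %*% (R1 %*% vecs[3L, ]))
  v4 <- as.numeric(Ry %*% (R1 %*% vecs[4L, ]))
  # the two horizontal Fischer positions carry opposite x signs; read the
  # better-conditioned one (v3 can land in the yz plane when three
  # substituents of a lifted 2D drawing are coplanar with the first two)
  if (abs(v3[1L]) >= abs(v4[1L])) {
    if (v3[1L] < 0) 1 else -1
  } else {
    if (v4[1L] > 0) 1 else -1
  }
}

rotation_matrix <- function(axis, angle) {
  x <- axis[1L]; y <- axis[2L]; z <- axis[3L]
  c0 <- cos(angle); s0 <- sin(angle); C <- 1 - c0
  rbind(c(c0 + x * x * C, x * y * C - z * s0, x * z * C + y * s0),
        c(y * x * C + z * s0, c0 + y * y * C, y * z * C - x * s0),
        c(z * x * C - y * s0, z * y * C + x * s0, c0 + z * z * C))
}

#' Same-side test for double-bond substituents
#'
#' TRUE when the components of the two substituent direction vectors
#' perpendicular to the a-to-b axis point to the same side (positive dot
#' product). A perpendicular component smaller than `mcdl.perp_tol` (default
#' 0.1) times the bond length — the near-linear sp2 drawing — raises an
#' ambiguous-geometry error.
#'
#' @param g An `mcdl_graph`.
#' @param a,b Atom indices of the double bond.
#' @param a_sub Substituent atom index attached to `a` (must not be 0).
#' @param b_sub Substituent atom index attached to `b` (must not be 0).
#' @return Logical.
#' @export
bond_same_side <- function(g, a, b, a_sub, b_sub) {
  xyz <- coords(g)
  axis <- xyz[b, ] - xyz[a, ]
  blen <- sqrt(sum(axis^2))
  u <- axis / blen
  perp <- function(p, origin) {
    w <- p - origin
    w - sum(w * u) * u
  }
  wa <- perp(xyz[a_sub, ], xyz[a, ])
  wb <- perp(xyz[b_sub, ], xyz[b, ])
  tol <- mcdl_opt("perp_tol", 0.1) * blen
  if (sqrt(sum(wa^2)) < tol || sqrt(sum(wb^2)) < tol) {
    stop(sprintf("ambiguous geometry at double bond %d=%d: near-linear substituent",
                 a, b), call. = FALSE)
  }
  sum(wa * wb) > 0
}

#' Lift a 2D wedge drawing into pseudo-3D
#'
#' Interprets up/down wedges (narrow end at the bond's `begin` atom) by
#' setting the far atom's z coordinate to +0.8 or -0.8 times the bond
#' length; all other atoms keep z = 0. The result is returned as a 3D graph
#' (wedge flags consumed) with attribute `"lifted"` set, so the encoder can
#' skip stereocenters that received no wedge information. Conflicting wedges
#' that imply both signs for one atom raise an inconsistent-wedge error.
#'
#' @param g A 2D `mcdl_graph`.
#' @return A 3D `mcdl_graph` with attribute `"lifted" = TRUE`.
#' @export
wedge_lift <- function(g) {
  if (g$dimensionality != "2D") {
    stop("wedge_lift requires a 2D graph", call. = FALSE)
  }
  zoff <- mcdl_opt("wedge_z", 0.8)
  b <- g$bonds
  xyz <- coords(g)
  zsign <- rep(NA_real_, nrow(g$atoms))
  for (k in which(b$wedge != "none")) {
    far <- b$end[k]
    sgn <- if (b$wedge[k] == "up") 1 else -1
    if (!is.na(zsign[far]) && zsign[far] != sgn) {
      stop(sprintf("inconsistent wedges at atom %d", far), call. = FALSE)
    }
    zsign[far] <- sgn
    blen <- sqrt(sum((xyz[far, ] - xyz[b$begin[k], ])^2))
    g$atoms$z[far] <- sgn * zoff * blen
  }
  g$bonds$wedge <- "none"
  g$dimensionality <- "3D"
  attr(g, "lifted") <- TRUE
  g
}

# --- configuration extraction --------------------------------------------

# Geometric atom configuration: parity relative to the stored subs order
# (ascending atom index, dummy last). Returns NULL when the graph is a
# lifted 2D drawing and the center received no wedge (configuration
# undefined -> skipped).
perceive_atom_config <- function(g, center, subs) {
  lifted <- isTRUE(attr(g, "lifted"))
  if (lifted) {
    zs <- g$atoms$z[subs[subs != 0L]]
    if (all(abs(zs) < 1e-8)) return(NULL)  # no wedge from this center: undefined
  }
  vecs <- substituent_vectors(g, center, subs)
  list(center = center, subs = subs, parity = atom_parity(vecs))
}

# Geometric bond configuration: same_side between the first real substituent
# of each end.
perceive_bond_config <- function(g, cand) {
  a_ref <- cand$a_subs[cand$a_subs != 0L][1L]
  b_ref <- cand$b_subs[cand$b_subs != 0L][1L]
  list(a = cand$a, b = cand$b, a_subs = cand$a_subs, b_subs = cand$b_subs,
       a_ref = a_ref, b_ref = b_ref,
       same_side = bond_same_side(g, cand$a, cand$b, a_ref, b_ref))
}
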