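# Coordinate embedding for fixtures: ideal local geometry (tetrahedral
# 109.47 degrees, trigonal 120 degrees, bond length 1.5) on acyclic graphs,
# with per-unit configuration control. Local geometry is exact; global
# clashes are permitted and irrelevant to stereo perception.

.bond_len <- 1.5

# Core placement routine. swap[v] swaps the first two child direction slots
# at atom v (flips the parity of a stereocenter); flip[k] (bond row k) swaps
# the child slots at the far end of double bond k (flips cis/trans).
embed_with_flags <- function(g, swap = NULL, flip = NULL, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  n <- nrow(g$atoms)
  if (is.null(swap)) swap <- logical(n)
  if (is.null(flip)) flip <- logical(nrow(g$bonds))
  adj <- adjacency(g)
  deg <- atom_degree(g)
  if (sum(deg) / 2 != n - 1L) {
    stop("embedding requires a connected acyclic graph", call. = FALSE)
  }
  bond_row <- function(i, j) {
    b <- g$bonds
    which((b$begin == i & b$end == j) | (b$begin == j & b$end == i))[1L]
  }
  xyz <- matrix(0, n, 3L)
  placed <- logical(n)

  hyb <- function(v) {
    ords <- vapply(adj[[v]], function(u) bond_order_between(g, v, u), 0L)
    if (any(ords == 3L) || sum(ords == 2L) >= 2L) "sp"
    else if (any(ords == 2L) && !g$atoms$element[v] %in% c("S", "P")) "sp2"
    else "sp3"   # hypervalent S/P (sulfoxides) stay pyramidal
  }

  # Direction slots for children of v (full slot set; the caller applies the
  # swap flag and then truncates to the number of children, so a flip at a
  # single-child double-bond end still moves the child to the other slot).
  child_dirs <- function(v, e_in, nslots, normal) {
    h <- hyb(v)
    if (mode == "2d") {
      rot2 <- function(d, ang) c(cos(ang) * d[1] - sin(ang) * d[2],
                                 sin(ang) * d[1] + cos(ang) * d[2], 0)
      offs <- switch(h,
                     sp3 = c(120, -120, 180),
                     sp2 = c(120, -120),
                     sp = 180)
      lapply(offs * pi / 180, function(a) rot2(-e_in, a))
    } else {
      switch(h,
        sp3 = {
          u1 <- perpendicular_unit(e_in); u2 <- cross3(e_in, u1)
          phis <- 2 * pi * (0:2) / 3
          lapply(phis, function(phi) {
            (1 / 3) * e_in + sqrt(8) / 3 * (cos(phi) * u1 + sin(phi) * u2)
          })
        },
        sp2 = {
          rot <- function(ang) rotation_matrix(normal, ang)
          lapply(c(2 * pi / 3, -2 * pi / 3),
                 function(a) as.numeric(rot(a) %*% (-e_in)))
        },
        sp = list(e_in))
    }
  }

  place <- function(v, parent, e_in, normal) {
    children <- sort(adj[[v]][adj[[v]] != if (is.null(parent)) -1L else parent])
    k <- length(children)
    if (k == 0L) return(invisible())
    h <- hyb(v)
    is_root <- is.null(parent)
    if (is_root) e_in <- c(0, -1, 0)
    if (h == "sp2" && is.null(normal)) {
      normal <- if (mode == "2d") c(0, 0, 1) else perpendicular_unit(e_in)
    }
    dirs <- child_dirs(v, e_in, k, normal)
    # the root has no parent, so the slot that would point at the parent is
    # available for a child; together with the regular slots this realizes
    # the full coordination (e.g. all four tetrahedral directions)
    if (is_root) dirs <- c(list(-e_in), dirs)
    eff_swap <- isTRUE(swap[v])
    if (!is.null(parent)) {
      br <- bond_row(parent, v)
      if (!is.na(br) && g$bonds$order[br] == 2L && isTRUE(flip[br])) {
        eff_swap <- xor(eff_swap, TRUE)
      }
    }
    if (eff_swap && length(dirs) >= 2L) dirs[c(1L, 2L)] <- dirs[c(2L, 1L)]
    if (length(dirs) < k) stop("not enough direction slots at atom ", v, call. = FALSE)
    for (ci in seq_len(k)) {
      u <- children[ci]
      d <- dirs[[ci]]
      xyz[u, ] <<- xyz[v, ] + .bond_len * d
      placed[u] <<- TRUE
      child_normal <- NULL
      if (mode == "3d") {
        br <- bond_row(v, u)
        if (g$bonds$order[br] == 2L) {
          child_normal <- if (h == "sp2" && !is.null(normal)) normal
                          else perpendicular_unit(d)
        } else if (hyb(u) == "sp2") {
          child_normal <- perpendicular_unit(d)
        }
      }
      place(u, v, d, child_normal)
    }
    invisible()
  }

  root <- which(deg == max(deg))[1L]
  placed[root] <- TRUE
  place(root, NULL, NULL, NULL)
  g$atoms$x <- xyz[, 1L]; g$atoms$y <- xyz[, 2L]; g$atoms$z <- xyz[, 3L]
  if (mode == "2d") {
    g$dimensionality <- "2D"
  } else {
    g$dimensionality <- "3D"
  }
  g
}

#' Embed an acyclic graph in 3D with requested stereo configurations
#'
#' Recursively places atoms with ideal local geometry and then adjusts the
#' branch arrangement at each requested stereogenic unit — swapping two
#' substituent branches at an atom, or rotating one end of a double bond —
#' until every requested configuration is realized.
#'
#' @param g A connected acyclic `mcdl_graph` with explicit hydrogens.
#' @param atom_targets Named list or numeric vector: names are center atom
#'   indices, values +1/-1 target parities (package convention: parity of
#'   the substituents in ascending-atom-index order, dummy last).
#' @param bond_targets List of targets, each
#'   `list(a =, b =, a_sub =, b_sub =, same_side =)`.
#' @return The graph with coordinates set (`dimensionality = "3D"`).
#' @export
embed3d <- function(g, atom_targets = NULL, bond_targets = NULL) {
  n <- nrow(g$atoms)
  swap <- logical(n)
  flip <- logical(nrow(g$bonds))
  bond_row_of <- function(a, b) {
    bb <- g$bonds
    which((bb$begin == a & bb$end == b) | (bb$begin == b & bb$end == a))[1L]
  }
  for (iter in 1:6) {
    ge <- embed_with_flags(g, swap, flip, mode = "3d")
    ok <- TRUE
    for (nm in names(atom_targets)) {
      center <- as.integer(nm)
      adjc <- adjacency(ge)[[center]]
      subs <- sort(adjc)
      if (length(subs) == 3L) subs <- c(subs, 0L)
      if (length(subs) != 4L) {
        stop("atom target at atom ", center, " is not a 3- or 4-coordinate center",
             call. = FALSE)
      }
      p <- atom_parity(substituent_vectors(ge, center, subs))
      if (p != atom_targets[[nm]]) {
        swap[center] <- !swap[center]
        ok <- FALSE
      }
    }
    for (tg in bond_targets) {
      ss <- bond_same_side(ge, tg$a, tg$b, tg$a_sub, tg$b_sub)
      if (ss != tg$same_side) {
        flip[bond_row_of(tg$a, tg$b)] <- !flip[bond_row_of(tg$a, tg$b)]
        ok <- FALSE
      }
    }
    if (ok) return(ge)
  }
  stop("embed3d failed to realize the requested configurations", call. = FALSE)
}

# 2D + wedge variant of a (3D, explicit-H) fixture: planar re-embedding,
# double-bond geometry fixed to match the 3D perception, and one wedge per
# stereocenter chosen so the perceived parity matches the 3D original (the
# try-up-then-flip rule).
as_wedge_2d <- function(g3) {
  stopifnot(g3$dimensionality == "3D")
  centers <- detect_stereocenters(g3)
  sbonds <- detect_stereobonds(g3)
  target_atoms <- lapply(centers, function(cand) {
    list(center = cand$center, subs = cand$subs,
         parity = atom_parity(substituent_vectors(g3, cand$center, cand$subs)))
  })
  target_bonds <- lapply(sbonds, perceive_bond_config, g = g3)

  flip <- logical(nrow(g3$bonds))
  bond_row_of <- function(a, b) {
    bb <- g3$bonds
    which((bb$begin == a & bb$end == b) | (bb$begin == b & bb$end == a))[1L]
  }
  g2 <- NULL
  for (iter in 1:4) {
    g2 <- embed_with_flags(g3, flip = flip, mode = "2d")
    ok <- TRUE
    for (tb in target_bonds) {
      ss <- bond_same_side(g2, tb$a, tb$b, tb$a_ref, tb$b_ref)
      if (ss != tb$same_side) {
        flip[bond_row_of(tb$a, tb$b)] <- !flip[bond_row_of(tb$a, tb$b)]
        ok <- FALSE
      }
    }
    if (ok) break
  }
  # wedge placement: prefer a terminal substituent bond; try up, re-perceive,
  # flip to down if the parity disagrees
  deg <- atom_degree(g2)
  for (ta in target_atoms) {
    subs_real <- ta$subs[ta$subs != 0L]
    cand <- subs_real[order(deg[subs_real] != 1L, subs_real)][1L]
    br <- bond_row_of(ta$center, cand)
    # narrow end at the center
    if (g2$bonds$begin[br] != ta$center) {
      g2$bonds$begin[br] <- ta$center
      g2$bonds$end[br] <- cand
    }
    for (w in c("up", "down")) {
      g2$bonds$wedge[br] <- w
      gl <- wedge_lift(g2)
      p <- atom_parity(substituent_vectors(gl, ta$center, ta$subs))
      if (p == ta$parity) break
    }
  }
  g2
}
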