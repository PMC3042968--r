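# Molecular graph model: atoms, bonds, dimensionality.

#' Construct a molecular graph
#'
#' The in-memory chemical object shared by all MCDL operations: a table of
#' atoms (element symbol and Cartesian coordinates) and a table of bonds
#' (order 1--3 plus an optional wedge flag for 2D depictions). Wedge flags
#' are interpreted with the narrow end at the `begin` atom.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `explicit_h` (logical; marks hydrogens added by
#'   [normalize_hydrogens()]).
#' @param bonds Data frame with columns `begin`, `end`, `order` and
#'   optionally `wedge` (one of `"none"`, `"up"`, `"down"`).
#' @param dimensionality `"2D"` or `"3D"`. 2D graphs must have all z = 0;
#'   wedge flags are only meaningful on 2D graphs.
#' @return An object of class `mcdl_graph`.
#' @export
mcdl_graph <- function(atoms, bonds = NULL, dimensionality = c("3D", "2D")) {
  dimensionality <- match.arg(dimensionality)
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"explicit_h" %in% names(atoms)) atoms$explicit_h <- FALSE
  atoms <- atoms[, c("element", "x", "y", "z", "explicit_h")]
  check_elements(atoms$element)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- tibble::tibble(begin = integer(), end = integer(),
                            order = integer(), wedge = character())
  } else {
    bonds <- tibble::as_tibble(bonds)
    stopifnot(all(c("begin", "end", "order") %in% names(bonds)))
    if (!"wedge" %in% names(bonds)) bonds$wedge <- "none"
    bonds <- bonds[, c("begin", "end", "order", "wedge")]
    bonds$begin <- as.integer(bonds$begin)
    bonds$end <- as.integer(bonds$end)
    bonds$order <- as.integer(bonds$order)
  }
  g <- structure(list(atoms = atoms, bonds = bonds,
                      dimensionality = dimensionality),
                 class = "mcdl_graph")
  validate_graph(g)
  g
}

validate_graph <- function(g) {
  a <- g$atoms; b <- g$bonds
  check_elements(a$element)
  n <- nrow(a)
  if (nrow(b) > 0L) {
    if (any(b$begin == b$end)) stop("bond with identical endpoints", call. = FALSE)
    if (any(b$begin < 1L | b$begin > n | b$end < 1L | b$end > n)) {
      stop("bond endpoint out of range", call. = FALSE)
    }
    if (!all(b$order %in% 1:3)) stop("bond orders must be 1, 2 or 3", call. = FALSE)
    if (!all(b$wedge %in% c("none", "up", "down"))) {
      stop("wedge must be 'none', 'up' or 'down'", call. = FALSE)
    }
    key <- paste(pmin(b$begin, b$end), pmax(b$begin, b$end))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
    if (g$dimensionality == "3D" && any(b$wedge != "none")) {
      stop("wedge flags are only valid on 2D graphs", call. = FALSE)
    }
  }
  if (g$dimensionality == "2D" && n > 0L &&
      any(abs(a$z) > 1e-8 & !a$explicit_h)) {
    stop("2D graph must have z = 0 for all original atoms", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.mcdl_graph <- function(x, ...) {
  cat(sprintf("<mcdl_graph: %d atoms, %d bonds, %s>\n",
              nrow(x$atoms), nrow(x$bonds), x$dimensionality))
  invisible(x)
}

#' Build a molecular graph from a compact specification
#'
#' Convenience constructor used throughout the fixture builders and tests:
#' elements plus an edge list, with all coordinates zero (call [embed3d()]
#' or supply coordinates afterwards).
#'
#' @param elements Character vector of element symbols.
#' @param bonds Matrix or data frame with columns begin, end, order.
#' @param dimensionality Passed to [mcdl_graph()].
#' @return An `mcdl_graph`.
#' @export
graph_from_spec <- function(elements, bonds = NULL, dimensionality = "3D") {
  atoms <- tibble::tibble(element = elements, x = 0, y = 0, z = 0,
                          explicit_h = FALSE)
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("begin", "end", "order")
  }
  mcdl_graph(atoms, bonds, dimensionality)
}

# Neighbor lists (list of integer vectors, sorted ascending).
adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$begin[k]]] <- c(adj[[b$begin[k]]], b$end[k])
    adj[[b$end[k]]] <- c(adj[[b$end[k]]], b$begin[k])
  }
  lapply(adj, sort)
}

atom_degree <- function(g) {
  n <- nrow(g$atoms)
  tabulate(c(g$bonds$begin, g$bonds$end), nbins = n)
}

bond_order_sum <- function(g) {
  n <- nrow(g$atoms)
  s <- numeric(n)
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    s[b$begin[k]] <- s[b$begin[k]] + b$order[k]
    s[b$end[k]] <- s[b$end[k]] + b$order[k]
  }
  as.integer(s)
}

# Order of the bond between atoms i and j (0 if absent).
bond_order_between <- function(g, i, j) {
  b <- g$bonds
  k <- which((b$begin == i & b$end == j) | (b$begin == j & b$end == i))
  if (length(k) == 0L) 0L else b$order[k[1L]]
}

coords <- function(g) as.matrix(g$atoms[, c("x", "y", "z")])

is_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1L) return(TRUE)
  length(component_of(adjacency(g), 1L)) == n
}

component_of <- function(adj, start) {
  seen <- logical(length(adj))
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  which(seen)
}

#' Add implicit hydrogens as explicit atoms
#'
#' MCDL fragment labels count every terminal hydrogen, so encoding requires
#' hydrogens to be explicit. Each atom receives `valence - bond-order sum`
#' hydrogen atoms (for S and P the smallest standard valence that
#' accommodates the current bond-order sum is used). Added hydrogens are
#' placed along the direction opposite the sum of the existing neighbor
#' directions, which puts them at the geometrically sensible open position
#' when coordinates are meaningful and at a harmless placeholder otherwise.
#' Idempotent.
#'
#' @param g An `mcdl_graph`.
#' @return A graph in which every atom's bond-order sum equals a standard
#'   valence.
#' @export
normalize_hydrogens <- function(g) {
  validate_graph(g)
  sums <- bond_order_sum(g)
  adj <- adjacency(g)
  xyz <- coords(g)
  n0 <- nrow(g$atoms)
  atoms <- g$atoms
  bonds <- g$bonds
  for (i in seq_len(n0)) {
    el <- g$atoms$element[i]
    val <- resolve_valence(el, sums[i])
    if (is.na(val)) {
      stop(sprintf("valence overflow at atom %d (%s): bond-order sum %d",
                   i, el, sums[i]), call. = FALSE)
    }
    nh <- val - sums[i]
    if (nh == 0L) next
    dirs <- h_directions(xyz, adj, i, nh, g$dimensionality)
    for (k in seq_len(nh)) {
      atoms <- tibble::add_row(atoms, element = "H",
                               x = unname(xyz[i, 1] + dirs[k, 1]),
                               y = unname(xyz[i, 2] + dirs[k, 2]),
                               z = unname(xyz[i, 3] + dirs[k, 3]),
                               explicit_h = TRUE)
      bonds <- tibble::add_row(bonds, begin = i, end = nrow(atoms),
                               order = 1L, wedge = "none")
    }
  }
  g2 <- g
  g2$atoms <- atoms
  g2$bonds <- bonds
  g2
}

# Placement directions for nh added hydrogens on atom i: antipode of the
# neighbor-direction sum, fanned out when several hydrogens are added.
h_directions <- function(xyz, adj, i, nh, dimensionality) {
  nb <- adj[[i]]
  u <- c(0, 0, 0)
  for (j in nb) {
    d <- xyz[j, ] - xyz[i, ]
    len <- sqrt(sum(d^2))
    if (len > 1e-8) u <- u - d / len
  }
  if (sqrt(sum(u^2)) < 1e-8) u <- c(1, 0, 0)
  u <- u / sqrt(sum(u^2))
  if (nh == 1L) return(matrix(u, nrow = 1L))
  out <- matrix(0, nh, 3L)
  if (dimensionality == "2D") {
    # stay in-plane: fan within +/- 60 degrees of u
    angs <- seq(-60, 60, length.out = nh) * pi / 180
    for (k in seq_len(nh)) {
      a <- angs[k]
      out[k, ] <- c(cos(a) * u[1] - sin(a) * u[2],
                    sin(a) * u[1] + cos(a) * u[2], 0)
    }
  } else {
    q1 <- perpendicular_unit(u)
    q2 <- cross3(u, q1)
    angs <- 2 * pi * (seq_len(nh) - 1L) / nh
    for (k in seq_len(nh)) {
      v <- u + 0.9 * (cos(angs[k]) * q1 + sin(angs[k]) * q2)
      out[k, ] <- v / sqrt(sum(v^2))
    }
  }
  out
}

#' Mirror a 3D molecular graph
#'
#' Returns a copy with every x coordinate negated; topology, bond orders and
#' atom order are unchanged. Applying it twice restores the original
#' coordinates. The mirror image of a chiral molecule encodes to the
#' enantiomeric descriptor; achiral molecules encode identically.
#'
#' @param g A 3D `mcdl_graph`.
#' @return The reflected graph.
#' @export
mirror_graph <- function(g) {
  if (g$dimensionality != "3D") stop("mirror_graph requires a 3D graph", call. = FALSE)
  g$atoms$x <- -g$atoms$x
  g
}

#' Split a graph into connected components
#'
#' Disjoint structures (salts, mixtures) are split into one graph per
#' connected component, with atom indices compacted and components ordered
#' by their smallest original atom index.
#'
#' @param g An `mcdl_graph`.
#' @return List of connected `mcdl_graph` objects.
#' @export
split_components <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) return(list())
  adj <- adjacency(g)
  comp <- integer(n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      ncomp <- ncomp + 1L
      comp[component_of(adj, i)] <- ncomp
    }
  }
  out <- vector("list", ncomp)
  for (c in seq_len(ncomp)) {
    members <- which(comp == c)   # ascending, so first-atom order is kept
    remap <- integer(n)
    remap[members] <- seq_along(members)
    b <- g$bonds
    keep <- b$begin %in% members & b$end %in% members
    bsub <- b[keep, , drop = FALSE]
    bsub$begin <- remap[bsub$begin]
    bsub$end <- remap[bsub$end]
    out[[c]] <- mcdl_graph(g$atoms[members, , drop = FALSE], bsub,
                           g$dimensionality)
  }
  out
}

# Apply a permutation to atom indices: atom i of the result is atom
# perm[i] of the input. Used by invariance tests.
permute_atoms <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- g$bonds
  b$begin <- inv[b$begin]
  b$end <- inv[b$end]
  mcdl_graph(g$atoms[perm, , drop = FALSE], b, g$dimensionality)
}

# --- small vector helpers -------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitize <- function(v) {
  len <- sqrt(sum(v^2))
  if (len < 1e-12) stop("cannot normalize zero vector", call. = FALSE)
  v / len
}

perpendicular_unit <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unitize(cross3(u, ref))
}
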