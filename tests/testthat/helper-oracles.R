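# Independent oracles and small builders shared across the test files.
# These deliberately avoid the package's own search/serialization internals.

# --- determinant chirality oracle ----------------------------------------

det_parity_oracle <- function(vecs) {
  d <- det(rbind(vecs[2, ] - vecs[1, ], vecs[3, ] - vecs[1, ],
                 vecs[4, ] - vecs[1, ]))
  sign(d)
}

# Random comfortably non-coplanar unit-vector quadruple (a random
# tetrahedron of substituent directions).
random_center_quadruple <- function() {
  repeat {
    v <- matrix(stats::rnorm(12), 4, 3)
    v <- v / sqrt(rowSums(v^2))
    ctr <- colMeans(v)
    if (abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) > 0.05 &&
        all(sqrt(rowSums((v - rep(ctr, each = 4))^2)) > 0.05)) {
      return(v)
    }
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

apply_rigid_motion <- function(g, R = random_rotation(), t = stats::rnorm(3)) {
  xyz <- as.matrix(g$atoms[, c("x", "y", "z")]) %*% t(R)
  g$atoms$x <- xyz[, 1] + t[1]
  g$atoms$y <- xyz[, 2] + t[2]
  g$atoms$z <- xyz[, 3] + t[3]
  g
}

random_permutation_copy <- function(g) {
  p <- sample(nrow(g$atoms))
  mcdl:::permute_atoms(g, p)
}

# --- brute-force canonical connectivity oracle ---------------------------

# Enumerates every numbering respecting label order (no pruning, own
# comparison logic) and returns the minimal per-fragment lists plus the
# number of schemes achieving the minimum.
brute_force_connectivity <- function(g, fragments, max_perms = 50000) {
  labs <- fragments$label
  ulabs <- sort(unique(labs), method = "radix")
  classes <- lapply(ulabs, function(l) which(labs == l))
  sizes <- vapply(classes, length, 1L)
  if (prod(factorial(sizes)) > max_perms) {
    stop("brute-force oracle: search space too large")
  }
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  class_perms <- lapply(classes, perms_of)
  fe <- mcdl:::fragment_edges(g, fragments)
  n <- nrow(fragments)

  lists_of <- function(rank_of) {
    lists <- rep(list(integer()), n)
    for (k in seq_len(nrow(fe$edges))) {
      i <- rank_of[fe$edges[k, 1]]; j <- rank_of[fe$edges[k, 2]]
      a <- min(i, j); b <- max(i, j)
      lists[[a]] <- sort(c(lists[[a]], b))
    }
    lists
  }
  # own comparison: element-wise, exhausted list sorts first
  less_than <- function(x, y) {
    for (m in seq_len(n)) {
      a <- x[[m]]; b <- y[[m]]
      for (k in seq_len(max(length(a), length(b)))) {
        if (k > length(a)) return(TRUE)
        if (k > length(b)) return(FALSE)
        if (a[k] != b[k]) return(a[k] < b[k])
      }
    }
    NA   # equal
  }
  best <- NULL
  nbest <- 0L
  grids <- expand.grid(lapply(class_perms, seq_along))
  for (r in seq_len(nrow(grids))) {
    rank_of <- integer(n)
    pos <- 1L
    for (ci in seq_along(classes)) {
      ord <- class_perms[[ci]][[grids[r, ci]]]
      rank_of[ord] <- pos + seq_along(ord) - 1L
      pos <- pos + length(ord)
    }
    lists <- lists_of(rank_of)
    if (is.null(best)) { best <- lists; nbest <- 1L; next }
    lt <- less_than(lists, best)
    if (is.na(lt)) nbest <- nbest + 1L
    else if (lt) { best <- lists; nbest <- 1L }
  }
  list(lists = best, n_schemes = nbest)
}

# --- brute-force bond-order oracle ---------------------------------------

# All valence-consistent order assignments for a reconstructed graph
# skeleton, by full enumeration over 1..3 per bond.
brute_force_orders <- function(elements, bonds_begin, bonds_end,
                               fixed = rep(NA_integer_, length(bonds_begin))) {
  nb <- length(bonds_begin)
  natoms <- length(elements)
  allowed <- mcdl:::.mcdl_valences
  sols <- list()
  rec <- function(bi, orders) {
    if (bi > nb) {
      sums <- numeric(natoms)
      for (k in seq_len(nb)) {
        sums[bonds_begin[k]] <- sums[bonds_begin[k]] + orders[k]
        sums[bonds_end[k]] <- sums[bonds_end[k]] + orders[k]
      }
      if (all(vapply(seq_len(natoms),
                     function(a) sums[a] %in% allowed[[elements[a]]], TRUE))) {
        sols[[length(sols) + 1L]] <<- orders
      }
      return(invisible())
    }
    for (o in if (is.na(fixed[bi])) 1:3 else fixed[bi]) rec(bi + 1L, c(orders, o))
  }
  rec(1L, integer())
  sols
}

# --- small molecule builders ---------------------------------------------

# planar cyclohexene (2D): ring double bond between atoms 1 and 2
build_cyclohexene <- function() {
  ang <- (0:5) * pi / 3
  g <- graph_from_spec(rep("C", 6),
                       rbind(c(1, 2, 2), c(2, 3, 1), c(3, 4, 1),
                             c(4, 5, 1), c(5, 6, 1), c(6, 1, 1)),
                       dimensionality = "2D")
  g$atoms$x <- cos(ang); g$atoms$y <- sin(ang)
  normalize_hydrogens(g)
}

build_ethanol <- function() {
  g <- graph_from_spec(c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1)))
  embed3d(normalize_hydrogens(g))
}

# isobutylene (CH3)2C=CH2
build_isobutylene <- function() {
  g <- graph_from_spec(c("C", "C", "C", "C"),
                       rbind(c(1, 2, 2), c(1, 3, 1), c(1, 4, 1)))
  embed3d(normalize_hydrogens(g))
}

# cis- or trans-2-butene with ideal planar coordinates
build_butene <- function(cis = TRUE) {
  g <- graph_from_spec(c("C", "C", "C", "C"),
                       rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, bond_targets = list(
    list(a = 2, b = 3, a_sub = 1, b_sub = 4, same_side = cis)))
}

fixture_graphs <- function() {
  out <- list()
  for (nm in reference_fixture_names()) {
    fx <- reference_fixture(nm)
    for (i in seq_along(fx$graphs)) {
      out[[paste0(nm, if (length(fx$graphs) > 1) paste0("#", i) else "")]] <-
        fx$graphs[[i]]
    }
  }
  out
}
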