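# Reference molecules with known descriptors, built programmatically, plus
# a seeded random stereo-molecule generator.

.tetra <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                 4L, 3L, byrow = TRUE) / sqrt(3) * 1.5

set_xyz <- function(g, idx, xyz) {
  g$atoms$x[idx] <- xyz[, 1L]
  g$atoms$y[idx] <- xyz[, 2L]
  g$atoms$z[idx] <- xyz[, 3L]
  g
}

# --- individual builders --------------------------------------------------

# D-(R)-lactic acid with hand-pinned tetrahedral coordinates at the chiral
# carbon: methyl, carboxyl C, hydroxyl O and H on the four tetrahedral
# directions. This conformer is the package's absolute-configuration
# reference (R), fixing the Fischer sign convention.
build_lactic_r <- function() {
  g <- graph_from_spec(
    c("C", "C", "C", "O", "H", "O", "O"),
    rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1),
          c(3, 6, 2), c(3, 7, 1)))
  g <- set_xyz(g, 1:5, rbind(c(0, 0, 0), .tetra[1, ], .tetra[2, ],
                             .tetra[3, ], .tetra[4, ]))
  g <- set_xyz(g, 6:7, rbind(.tetra[2, ] + c(1.2, 0, 0),
                             .tetra[2, ] + c(0, 1.2, 0)))
  normalize_hydrogens(g)
}

# S-CHBrClF: F, Br, Cl, H on tetrahedral directions 1..4 (S configuration).
build_chbrclf_s <- function() {
  g <- graph_from_spec(
    c("C", "Br", "Cl", "F", "H"),
    rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1)))
  set_xyz(g, 1:5, rbind(c(0, 0, 0), .tetra[2, ], .tetra[3, ],
                        .tetra[1, ], .tetra[4, ]))
}

# 2-hydroxy-2-methylbutanoic acid, one enantiomer (the pair is completed by
# mirroring).
build_hmba <- function() {
  g <- graph_from_spec(
    c("C", "C", "C", "C", "C", "O", "O", "O"),
    rbind(c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(1, 5, 1), c(1, 8, 1),
          c(5, 6, 2), c(5, 7, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, atom_targets = list(`1` = 1))
}

# meso-tartaric acid: two constitutionally identical centers with opposite
# configurations.
build_meso_tartaric <- function() {
  g <- graph_from_spec(
    c("C", "C", "C", "C", "O", "O", "O", "O", "O", "O"),
    rbind(c(1, 2, 1), c(1, 3, 1), c(1, 5, 1), c(2, 4, 1), c(2, 6, 1),
          c(3, 7, 2), c(3, 8, 1), c(4, 9, 2), c(4, 10, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, atom_targets = list(`1` = 1, `2` = -1))
}

# ethyl(fluoromethyl)sulfoxide, one enantiomer at the sulfur lone-pair
# center.
build_sulfoxide <- function() {
  g <- graph_from_spec(
    c("C", "F", "S", "O", "C", "C"),
    rbind(c(1, 2, 1), c(1, 3, 1), c(3, 4, 2), c(3, 5, 1), c(5, 6, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, atom_targets = list(`3` = 1))
}

# 3,4-dimethyl-3-heptene in the reference configuration: the propyl-side
# CH2 lies on the same side of the double bond as the methyl of the
# ethyl-bearing carbon.
build_heptene <- function() {
  g <- graph_from_spec(
    c("C", "C", "C", "C", "C", "C", "C", "C", "C"),
    rbind(c(1, 2, 2), c(1, 3, 1), c(1, 4, 1), c(2, 5, 1), c(2, 6, 1),
          c(3, 7, 1), c(6, 8, 1), c(8, 9, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, bond_targets = list(
    list(a = 1, b = 2, a_sub = 4, b_sub = 6, same_side = TRUE)))
}

# (Z)-1,2-dibromopropene: H (on the CHBr end) cis to the methyl.
build_dibromopropene <- function() {
  g <- graph_from_spec(
    c("C", "C", "C", "Br", "Br"),
    rbind(c(1, 2, 2), c(1, 3, 1), c(1, 4, 1), c(2, 5, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, bond_targets = list(
    list(a = 1, b = 2, a_sub = 3, b_sub = 5, same_side = FALSE)))
}

build_hexadiene <- function(cis23) {
  g <- graph_from_spec(
    c("C", "C", "C", "C", "C", "C"),
    rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 2), c(5, 6, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, bond_targets = list(
    list(a = 2, b = 3, a_sub = 1, b_sub = 4, same_side = cis23),
    list(a = 4, b = 5, a_sub = 3, b_sub = 6, same_side = FALSE)))
}

build_diaza <- function(cis) {
  g <- graph_from_spec(
    c("C", "N", "N", "C"),
    rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1)))
  g <- normalize_hydrogens(g)
  embed3d(g, bond_targets = list(
    list(a = 2, b = 3, a_sub = 1, b_sub = 4, same_side = cis)))
}

# --- registry -------------------------------------------------------------

.fixture_registry <- list(
  "lactic-acid-D" = function() list(
    graphs = list(build_lactic_r()),
    expected = "CH;CHHH;CO;2OH[2,3,4;;5]{SA:1,2,3,4,H}"),
  "2-hydroxy-2-methylbutanoic-acid" = function() {
    gA <- build_hmba()
    list(graphs = list(gA, mirror_graph(gA)),
         expected = c("C;CHH;2CHHH;CO;2OH[2,3,5,6;4;;;7]{SA:1,2,3,5,6}",
                      "C;CHH;2CHHH;CO;2OH[2,3,5,6;4;;;7]{SA:1,2,3,6,5}"),
         paired = TRUE)
  },
  "meso-tartaric-acid" = function() list(
    graphs = list(build_meso_tartaric()),
    expected = "2CH;2CO;4OH[2,3,5;4,6;7;8]{SA:1,2,3,5,H;2,1,4,H,6}"),
  "ethyl-fluoromethyl-sulfoxide" = function() {
    gA <- build_sulfoxide()
    list(graphs = list(gA, mirror_graph(gA)),
         expected = c("CFHH;CHH;CHHH;SO[4;3,4]{SA:4,,1,2,O}",
                      "CFHH;CHH;CHHH;SO[4;3,4]{SA:4,,1,O,2}"),
         paired = TRUE)
  },
  "3,4-dimethyl-3-heptene" = function() list(
    graphs = list(build_heptene()),
    expected = "2C;3CHH;4CHHH[2,3,6;4,7;5;8;9]{SB:1d2,3,7,4,6}"),
  "1,2-dibromopropene" = function() list(
    graphs = list(build_dibromopropene()),
    expected = "CBr;CBrH;CHHH[2,3]{SB:1d2,3,H,Br,Br}"),
  "trans,trans-hexa-2,4-diene" = function() list(
    graphs = list(build_hexadiene(FALSE)),
    expected = "4CH;2CHHH[2,3;4;5;6]{SB:1d3,2,H,5,H;2d4,1,H,6,H}"),
  "cis,trans-hexa-2,4-diene" = function() list(
    graphs = list(build_hexadiene(TRUE)),
    expected = "4CH;2CHHH[2,3;4;5;6]{SB:1d3,2,5,H,H;2d4,1,H,6,H}"),
  "cis-diaza-2-butene" = function() list(
    graphs = list(build_diaza(TRUE)),
    expected = "2CHHH;2N[3;4;4]{SB:3d4,,,2,1}"),
  "trans-diaza-2-butene" = function() list(
    graphs = list(build_diaza(FALSE)),
    expected = "2CHHH;2N[3;4;4]{SB:3d4,,2,,1}"),
  "CHBrClF-S" = function() list(
    graphs = list(build_chbrclf_s()),
    expected = "CBrClFH{SA:1,Br,Cl,F,H}")
)

#' Names of the registered reference molecules
#' @return Character vector of fixture names.
#' @export
reference_fixture_names <- function() names(.fixture_registry)

#' Build a registered reference molecule
#'
#' Each entry programmatically constructs a molecule with known canonical
#' MCDL descriptor(s), in explicit-hydrogen 3D form adequate for stereo
#' perception. Entries whose absolute configuration is pinned return one
#' graph and one expected string; enantiomer pairs whose left/right identity
#' is depiction-dependent return both mirror-image graphs and the pair of
#' expected strings as a set (`paired = TRUE`).
#'
#' @param name One of [reference_fixture_names()].
#' @return List with `graphs` (list of `mcdl_graph`), `expected` (character
#'   vector of canonical descriptors) and optionally `paired`.
#' @export
reference_fixture <- function(name) {
  f <- .fixture_registry[[name]]
  if (is.null(f)) stop("unknown fixture: ", name, call. = FALSE)
  f()
}

#' Generate a random acyclic stereo molecule
#'
#' Seeded generator of connected acyclic molecules with 4--12 heavy atoms
#' drawn from C, N, O, S, F, Cl and Br, up to two double bonds, explicit
#' hydrogens and ideal-geometry 3D coordinates with randomized
#' configurations at every stereogenic unit. Deterministic per seed; the
#' caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @return An `mcdl_graph`.
#' @export
random_stereo_molecule <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nheavy <- sample(4:12, 1L)
  els <- c("C", "N", "O", "S", "F", "Cl", "Br")
  prob <- c(0.55, 0.10, 0.15, 0.04, 0.06, 0.06, 0.04)
  gen_val <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L)
  element <- "C"
  bonds <- NULL
  free <- 4L
  for (i in 2:nheavy) {
    attachable <- which(free >= 1L)
    if (length(attachable) == 0L) break   # fully saturated early
    at <- if (length(attachable) == 1L) attachable else sample(attachable, 1L)
    el <- sample(els, 1L, prob = prob)
    element <- c(element, el)
    bonds <- rbind(bonds, c(at, i, 1L))
    free[at] <- free[at] - 1L
    free <- c(free, gen_val[[el]] - 1L)
  }
  # upgrade up to two single bonds to double bonds where valence allows and
  # neither end already carries a double bond
  has_double <- logical(nheavy)
  for (k in sample(seq_len(nrow(bonds)))) {
    if (sum(bonds[, 3L] == 2L) >= 2L) break
    a <- bonds[k, 1L]; b <- bonds[k, 2L]
    if (free[a] >= 1L && free[b] >= 1L && !has_double[a] && !has_double[b] &&
        stats::runif(1) < 0.5) {
      bonds[k, 3L] <- 2L
      free[a] <- free[a] - 1L; free[b] <- free[b] - 1L
      has_double[a] <- TRUE; has_double[b] <- TRUE
    }
  }
  g <- graph_from_spec(element, bonds)
  g <- normalize_hydrogens(g)
  swap <- stats::runif(nrow(g$atoms)) < 0.5
  flip <- stats::runif(nrow(g$bonds)) < 0.5
  embed_with_flags(g, swap = swap, flip = flip, mode = "3d")
}

#' Write all reference fixtures as SDF plus an expected-descriptor table
#'
#' Emits `fixtures.sdf` (one record per fixture graph, enantiomer pair
#' members suffixed `#1`/`#2`) and `expected.tsv` (record name and canonical
#' MCDL). For pair entries each graph is matched to its member of the
#' expected pair by encoding; the set of encodings is verified against the
#' registry.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the tibble written to `expected.tsv`.
#' @export
mcdl_write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  rows <- list()
  for (nm in reference_fixture_names()) {
    fx <- reference_fixture(nm)
    if (length(fx$graphs) == 1L) {
      records[[length(records) + 1L]] <- list(graph = fx$graphs[[1L]], name = nm)
      rows[[length(rows) + 1L]] <- tibble::tibble(name = nm, mcdl = fx$expected)
    } else {
      enc <- vapply(fx$graphs, mcdl_encode, character(1L))
      if (!setequal(enc, fx$expected)) {
        stop("fixture pair ", nm, " does not reproduce its expected descriptors",
             call. = FALSE)
      }
      for (i in seq_along(fx$graphs)) {
        nm_i <- paste0(nm, "#", i)
        records[[length(records) + 1L]] <- list(graph = fx$graphs[[i]], name = nm_i)
        rows[[length(rows) + 1L]] <- tibble::tibble(name = nm_i, mcdl = enc[i])
      }
    }
  }
  writeLines(write_sdf(records), file.path(dir, "fixtures.sdf"), sep = "")
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "expected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}
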