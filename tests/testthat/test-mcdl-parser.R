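test_that("parse_mcdl reads composition, connectivity and stereo modules", {
  d <- parse_mcdl("CFHH;CHH;CHHH;SO[4;3,4]{SA:4,,1,2,O}")
  expect_equal(sum(d$composition$mult), 4L)
  expect_equal(d$frag_labels, c("CFHH", "CHH", "CHHH", "SO"))
  expect_equal(d$connectivity$lists[[1]], 4L)
  expect_equal(d$connectivity$lists[[2]], c(3L, 4L))
  expect_length(d$sa, 1L)
  expect_equal(d$sa[[1]]$center, 4L)
  expect_equal(d$sa[[1]]$top$kind, "dummy")
  expect_equal(d$sa[[1]]$right$symbol, "O")

  d2 <- parse_mcdl("2CHHH;2N[3;4;4]{SB:3d4,,2,,1}")
  e <- d2$sb[[1]]
  expect_equal(c(e$x1, e$x2), c(3L, 4L))
  expect_equal(e$n1$kind, "dummy")
  expect_equal(e$n2$number, 2L)
  expect_equal(e$n3$kind, "dummy")
  expect_equal(e$n4$number, 1L)

  # multiplicities expand in order
  d3 <- parse_mcdl("C;CHH;2CHHH;CO;2OH[2,3,5,6;4;;;7]")
  expect_equal(d3$frag_labels,
               c("C", "CHH", "CHHH", "CHHH", "CO", "OH", "OH"))
})

test_that("parse_mcdl validates ranks, priorities and syntax", {
  expect_error(parse_mcdl("C;CHH[3]"), "out of range")
  expect_error(parse_mcdl("2CHHH;2N[3;4;4]{SB:4d3,,2,,1}"), "x1 < x2")
  # top/bottom must be the two highest-priority tokens
  expect_error(parse_mcdl("CH;CHHH;CO;2OH[2,3,4;;5]{SA:1,H,3,2,4}"),
               "top/bottom")
  # n1 must outrank n4
  expect_error(parse_mcdl("CBr;CBrH;CHHH[2,3]{SB:1d2,Br,H,Br,3}"), "n1/n4")
  expect_error(parse_mcdl("CH;;CO"), "composition")
  expect_error(parse_mcdl("CQx;CHH[2]"), "tokenize|unsupported")
  expect_error(parse_mcdl("CH;CHHH;CO;2OH[2,3,4;;5]{SA:1,2,3,4,4}"), "duplicate")
  # a terminal token must exist on the referenced fragment
  expect_error(parse_mcdl("CH;CHHH;CO;2OH[2,3,4;;5]{SA:1,2,3,4,F}"),
               "not a terminal")
  expect_error(parse_mcdl("CH;CHHH;CO;2OH[2,3,4;;5]xyz"), "trailing")
  expect_warning(parse_mcdl("CH;CHHH;CO;2OH[2,3,4;;5]{XY:1,2}"),
                 "unrecognized")
})

test_that("parse then re-serialize is the identity on canonical strings", {
  for (nm in reference_fixture_names()) {
    for (s in reference_fixture(nm)$expected) {
      expect_identical(serialize_descriptor(parse_mcdl(s)), s)
    }
  }
})

test_that("reconstruct_bond_orders assigns valence-consistent orders", {
  # lactic acid: the CO fragment's terminal O must take a double bond
  g <- reconstruct_bond_orders(parse_mcdl("CH;CHHH;CO;2OH[2,3,4;;5]"))
  expect_true(all(mcdl:::bond_order_sum(g) ==
    vapply(g$atoms$element, function(e) min(mcdl:::allowed_valences(e)), 1L) |
    g$atoms$element %in% c("S", "P")))
  co_core <- attr(g, "core_of_rank")[3]
  termO <- attr(g, "term_atoms")[[3]]
  b <- g$bonds
  row <- which((b$begin == co_core & b$end == termO) |
               (b$end == co_core & b$begin == termO))
  expect_equal(b$order[row], 2L)

  # SB-marked bond fixed at order 2, everything else single
  g2 <- reconstruct_bond_orders(parse_mcdl("CBr;CBrH;CHHH[2,3]{SB:1d2,3,H,Br,Br}"))
  cores <- attr(g2, "core_of_rank")
  b2 <- g2$bonds
  row12 <- which((b2$begin == cores[1] & b2$end == cores[2]) |
                 (b2$begin == cores[2] & b2$end == cores[1]))
  expect_equal(b2$order[row12], 2L)
  expect_equal(sum(b2$order == 2L), 1L)

  # saturated molecule: all single
  g3 <- reconstruct_bond_orders(parse_mcdl("2CHHH[2]"))
  expect_true(all(g3$bonds$order == 1L))

  # no consistent assignment
  expect_error(reconstruct_bond_orders(parse_mcdl("2CHHH")),
               "no valence-consistent")
})

test_that("reconstruction matches exhaustive assignment and is minimal", {
  for (s in c("CH;CHHH;CO;2OH[2,3,4;;5]", "CBr;CBrH;CHHH[2,3]{SB:1d2,3,H,Br,Br}",
              "4CH;2CHHH[2,3;4;5;6]", "2CHHH;2N[3;4;4]")) {
    d <- parse_mcdl(s)
    g <- suppressWarnings(reconstruct_bond_orders(d))
    fixed <- rep(NA_integer_, nrow(g$bonds))
    # recompute which bonds the SB entries fix
    cores <- attr(g, "core_of_rank")
    for (e in d$sb) {
      row <- which((g$bonds$begin == cores[e$x1] & g$bonds$end == cores[e$x2]) |
                   (g$bonds$begin == cores[e$x2] & g$bonds$end == cores[e$x1]))
      fixed[row] <- 2L
    }
    sols <- brute_force_orders(g$atoms$element, g$bonds$begin, g$bonds$end,
                               fixed)
    expect_gte(length(sols), 1L)
    keys <- vapply(sols, paste, "", collapse = ",")
    expect_equal(paste(g$bonds$order, collapse = ","),
                 min(keys))   # deterministic minimal assignment
  }
})

test_that("valence-ambiguous descriptors warn and stay deterministic", {
  # cyclooctatetraene-like ring written as MCDL: alternating assignment is
  # not unique
  s <- "4CH[2,4;3;4]"
  expect_warning(g <- reconstruct_bond_orders(parse_mcdl(s)), "multiple")
  expect_warning(g2 <- reconstruct_bond_orders(parse_mcdl(s)), "multiple")
  expect_identical(g$bonds$order, g2$bonds$order)
})

test_that("roundtrip_canonicalize is identity on canonical and fixes others", {
  for (nm in reference_fixture_names()) {
    for (s in reference_fixture(nm)$expected) {
      expect_identical(roundtrip_canonicalize(s), s)
    }
  }
  # the rejected meso candidate canonicalizes to the kept one
  expect_identical(
    roundtrip_canonicalize("2CH;2CO;4OH[2,3,5;4,6;7;8]{SA:1,2,3,H,5;2,1,4,6,H}"),
    "2CH;2CO;4OH[2,3,5;4,6;7;8]{SA:1,2,3,5,H;2,1,4,H,6}")
  # descriptors without stereo modules pass through up to canonical numbering
  expect_identical(roundtrip_canonicalize("CHH;CHHH;OH[2,3]"),
                   "CHH;CHHH;OH[2,3]")
  # idempotence on random molecules
  for (s in 1:25) {
    m <- mcdl_encode(random_stereo_molecule(s + 400))
    r1 <- suppressWarnings(roundtrip_canonicalize(m))
    expect_identical(suppressWarnings(roundtrip_canonicalize(r1)), r1)
  }
})

test_that("reconstructed graphs satisfy the valence invariant exactly", {
  for (nm in reference_fixture_names()) {
    s <- reference_fixture(nm)$expected[1]
    g <- reconstruct_bond_orders(parse_mcdl(s))
    sums <- mcdl:::bond_order_sum(g)
    for (i in seq_len(nrow(g$atoms))) {
      expect_true(sums[i] %in% mcdl:::allowed_valences(g$atoms$element[i]))
    }
  }
})
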