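test_that("equation parsing honours orientation, multiplicity and glyphs", {
  p <- parse_equation("PEP + CO2 <-> OAA + Pi", id = 3)
  expect_equal(p$stoichiometry[c("PEP", "CO2", "OAA", "Pi")],
               c(PEP = -1, CO2 = -1, OAA = 1, Pi = 1))
  expect_true(p$reversible)

  # backward-glyph equations still parse left-to-right; direction is in the
  # flux sign, not the stoichiometry
  p34 <- parse_equation("ATP <- ADP + 2 H + Pi", id = 34)
  expect_equal(p34$stoichiometry[c("ATP", "ADP", "H", "Pi")],
               c(ATP = -1, ADP = 1, H = 2, Pi = 1))
  expect_false(p34$reversible)

  # typeset glyphs normalise to the ASCII grammar
  p_uni <- parse_equation("GPP + 4HB ↔ G-4HB + 2 Pi", id = 48)
  expect_equal(p_uni$stoichiometry[["Pi"]], 2)
  expect_true(p_uni$reversible)

  expect_error(parse_equation("-> B", id = 9), "empty side")
  expect_error(parse_equation("A + ", id = 9), "arrow")
})

test_that("packaged model reproduces the published census", {
  for (variant in c("corrected_r65", "as_printed")) {
    m <- load_packaged_model(variant)
    rxn <- m$network$reactions
    met <- m$network$metabolites
    expect_identical(sum(rxn$kind == "internal"), 82L)
    expect_identical(sum(!met$is_external), 86L)
    expect_identical(dim(m$network$S), c(86L, 104L))
    expect_true(all(colSums(abs(m$network$S)) > 0))
  }
  expect_error(load_packaged_model("nope"))
})

test_that("parse rejects malformed tables", {
  met <- "id\tabbreviation\tname\tcarbon_count\nA\tA\ta\t1\nB\tB\tb\t1\n1000\texternal\text\t0"
  expect_error(parse_network(met, "id\tequation\tkind\n1\tA -> C\tinternal"),
               "unknown species token 'C'")
  expect_error(parse_network(met, "id\tequation\tkind\n1\tA -> B\tinternal\n1\tA -> B\tinternal"),
               "duplicate reaction id")
})

test_that("stoichiometric matrix columns match reaction stoichiometries", {
  m <- load_packaged_model()
  S <- build_stoichiometric_matrix(m$network)
  expect_identical(S, m$network$S)
  # single-reaction sanity: column equals the parsed stoichiometry
  expect_equal(S[c("2-PG", "PEP"), "2"], c(`2-PG` = -1, PEP = 1))
  # carbon-weighted column sums vanish for balanced reactions
  cc <- setNames(m$network$metabolites$carbon_count,
                 m$network$metabolites$abbreviation)
  w <- cc[rownames(S)]
  expect_equal(sum(w * S[, "13"]), 0)  # Fum(4) <-> Mal(4)
  expect_equal(sum(w * S[, "48"]), 0)  # GPP(10) + 4HB(7) -> G-4HB(17)
})

test_that("carbon balance holds for all internal and maintenance reactions", {
  m <- load_packaged_model()
  rep <- carbon_balance_report(m$network)
  expect_true(all(rep$kind == "exchange"))
  full <- carbon_balance_report(m$network, nonzero_only = FALSE)
  expect_equal(full$imbalance[full$id == 5], 0)   # Pyr + CoA -> Ac-CoA + CO2
  # a deliberately imbalanced toy reaction is reported
  net <- parse_network(
    "id\tabbreviation\tname\tcarbon_count\n1\tA\ta\t1\n2\tB\tb\t2\n1000\texternal\text\t0",
    "id\tequation\tkind\n1\tA -> B\tinternal")
  expect_equal(carbon_balance_report(net)$imbalance, 1)
})

test_that("render/parse round-trip preserves the network", {
  m <- load_packaged_model()
  tmp_r <- tempfile(fileext = ".tsv")
  tmp_m <- tempfile(fileext = ".tsv")
  render_reactions_tsv(m$network,
                       fluxes = list(glucose = printed_fluxes(m$network, "glucose"),
                                     glucose_glycerol = printed_fluxes(m$network, "glucose_glycerol")),
                       file = tmp_r)
  ximflux:::render_metabolites_tsv(m$network, file = tmp_m)
  net2 <- parse_network(tmp_m, tmp_r)
  expect_identical(net2$stoichiometry, m$network$stoichiometry)
  expect_identical(net2$reactions$reversible, m$network$reactions$reversible)
  expect_identical(net2$reactions$kind, m$network$reactions$kind)
  expect_equal(net2$reactions$flux_glucose, m$network$reactions$flux_glucose)
})

test_that("boundary pseudo-reactions touch the external species or are cofactor conversions", {
  m <- load_packaged_model()
  rxn <- m$network$reactions
  for (i in which(rxn$kind != "internal")) {
    st <- m$network$stoichiometry[[as.character(rxn$id[i])]]
    if (rxn$kind[i] == "exchange") {
      expect_true("external" %in% names(st))
    } else {
      expect_true(rxn$id[i] %in% 1001:1003 && !"external" %in% names(st))
    }
  }
})
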