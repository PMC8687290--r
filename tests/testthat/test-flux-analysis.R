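# Carbon efficiency, production enhancement, and condition comparison on the
# transcribed flux columns.

test_that("carbon efficiency reproduces the headline percentages", {
  m <- load_packaged_model()
  net <- m$network

  eff_gg <- carbon_efficiency(printed_fluxes(net, "glucose_glycerol"), net)
  # 21 C x 0.07 out of 6 C x 0.69549 + 3 C x 0.43026
  expect_equal(eff_gg$product_carbon_flux, 21 * 0.07)
  expect_equal(eff_gg$source_carbon_flux, 6 * 0.69549 + 3 * 0.43026)
  expect_equal(eff_gg$efficiency_percent, 26.9048, tolerance = 1e-4)
  expect_equal(eff_gg$efficiency_reported, 27)

  eff_glc <- carbon_efficiency(printed_fluxes(net, "glucose"), net)
  expect_equal(eff_glc$efficiency_percent, 100 * 1.05 / 5.11668,
               tolerance = 1e-6)
  expect_equal(eff_glc$efficiency_percent, 20.52, tolerance = 1e-2)
})

test_that("efficiency handles degenerate inputs", {
  m <- load_packaged_model()
  u <- ximflux:::as_flux_named(printed_fluxes(m$network, "glucose"))
  u[["1018"]] <- 0
  expect_equal(carbon_efficiency(u, m$network)$efficiency_percent, 0)
  u0 <- u; u0[["1017"]] <- 0; u0[["1021"]] <- 0
  expect_error(carbon_efficiency(u0, m$network), "zero total source carbon")
  expect_error(carbon_efficiency(u, m$network, product = "nope"), "unknown product")
})

test_that("production enhancement is +40% between the printed conditions", {
  m <- load_packaged_model()
  a <- printed_fluxes(m$network, "glucose")
  b <- printed_fluxes(m$network, "glucose_glycerol")
  expect_equal(production_enhancement(a, b), 40, tolerance = 1e-9)
  expect_equal(production_enhancement(a, a), 0)
  expect_equal(production_enhancement(c(`1018` = -0.05), c(`1018` = -0.10)), 100)
  expect_error(production_enhancement(c(`1018` = 0), c(`1018` = 1)), "zero base")

  # scale invariance
  ua <- ximflux:::as_flux_named(a); ub <- ximflux:::as_flux_named(b)
  expect_equal(production_enhancement(3.7 * ua, 3.7 * ub),
               production_enhancement(ua, ub))
})

test_that("condition comparison reports the published deltas", {
  m <- load_packaged_model()
  cmp <- compare_conditions(printed_fluxes(m$network, "glucose"),
                            printed_fluxes(m$network, "glucose_glycerol"),
                            highlight = c(2, 50))
  expect_equal(cmp$delta[cmp$id == "2"], 0.91367 - 0.82659)
  expect_lt(cmp$delta[cmp$id == "74"], 0)   # glucose uptake falls
  expect_true(all(cmp$highlighted[cmp$id %in% c("2", "50")]))
  same <- compare_conditions(printed_fluxes(m$network, "glucose"),
                             printed_fluxes(m$network, "glucose"))
  expect_true(all(same$delta == 0))
  expect_error(compare_conditions(c(a = 1), c(b = 1)), "mismatched")
})

test_that("the glycerol degradation route carries the added flux", {
  m <- load_packaged_model()
  ua <- ximflux:::as_flux_named(printed_fluxes(m$network, "glucose"))
  ub <- ximflux:::as_flux_named(printed_fluxes(m$network, "glucose_glycerol"))
  # glycerol -> glycerol-3P -> DHAP -> TP -> 1,3-BPG -> 3-PG -> 2-PG -> PEP
  route <- c("39", "38", "17", "18", "19", "1", "2")
  expect_true(all(abs(ub[route]) > abs(ua[route])))
})

test_that("flux tables render with one column per condition and round-trip", {
  m <- load_packaged_model()
  fl <- list(glucose = printed_fluxes(m$network, "glucose"),
             glucose_glycerol = printed_fluxes(m$network, "glucose_glycerol"))
  lines <- render_flux_table(m$network, fl)
  expect_length(lines, 105)  # header + 104 reactions
  expect_identical(strsplit(lines[1], "\t")[[1]],
                   c("id", "equation", "kind", "flux_glucose",
                     "flux_glucose_glycerol"))
  single <- render_flux_table(m$network, fl["glucose"])
  expect_length(strsplit(single[1], "\t")[[1]], 4L)
  expect_error(render_flux_table(m$network, list()), "missing condition")

  tmp <- tempfile(fileext = ".tsv")
  render_flux_table(m$network, fl, file = tmp)
  tmp_m <- tempfile(fileext = ".tsv")
  ximflux:::render_metabolites_tsv(m$network, file = tmp_m)
  net2 <- parse_network(tmp_m, tmp)
  expect_identical(net2$stoichiometry, m$network$stoichiometry)
  expect_equal(net2$reactions$flux_glucose_glycerol,
               m$network$reactions$flux_glucose_glycerol)
})

test_that("rounding rule is round-half-up", {
  expect_equal(ximflux:::round_half_up(26.5), 27)
  expect_equal(ximflux:::round_half_up(20.49), 20)
  expect_equal(ximflux:::round_half_up(2.345, 2), 2.35)
})
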