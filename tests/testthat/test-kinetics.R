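# The generic reversible rate law and the metabolite ODE layer.

test_that("rate weights partition unity and flag degenerate input", {
  expect_equal(rate_weights(0.4, 0.4), c(f1 = 0.5, f2 = 0.5))
  expect_equal(rate_weights(1, 3), c(f1 = 0.25, f2 = 0.75))
  expect_equal(rate_weights(5, 0), c(f1 = 1, f2 = 0))
  expect_equal(sum(rate_weights(0.123, 7.7)), 1)
  expect_equal(rate_weights(1, 3, orientation = "swapped"),
               c(f1 = 0.75, f2 = 0.25))
  expect_error(rate_weights(0, 0), "both")
})

test_that("rate law reduces to irreversible Michaelis-Menten at VB = 0", {
  law <- rate_law(VF = 2, VB = 0, K_sub = 1, K_prod = 1)
  for (x in c(0, 0.3, 1, 5)) {
    expect_equal(reaction_rate(law, substrates = x, products = 0.7),
                 mm_rate(2, 1, x))
  }
  # half saturation
  expect_equal(reaction_rate(law, substrates = 1, products = 0), 1)
})

test_that("rate law vanishes at equilibrium and matches the hand oracle", {
  law_eq <- rate_law(VF = 1, VB = 1, K_sub = 1, K_prod = 1)
  expect_equal(reaction_rate(law_eq, substrates = 1, products = 1), 0)

  # two substrates, one product: direct arithmetic
  law <- rate_law(VF = 1, VB = 0.5, K_sub = c(1, 1), K_prod = 2)
  u <- reaction_rate(law, substrates = c(2, 1), products = 0.5)
  num <- 1 * 2 * 1 - 0.5 * 0.25
  den <- (2 / 3) * (3 * 2) + (1 / 3) * 1.25
  expect_equal(u, num / den)
  expect_equal(u, 0.42453, tolerance = 1e-5)
})

test_that("rate is monotone in substrates and products with the correct sign", {
  withr::with_seed(42, {
    for (i in 1:50) {
      VF <- runif(1, 0.1, 3); VB <- runif(1, 0, 3)
      law <- rate_law(VF, VB, K_sub = runif(2, 0.5, 2), K_prod = runif(1, 0.5, 2))
      A <- runif(2, 0, 4); P <- runif(1, 0, 4)
      u <- reaction_rate(law, A, P)
      # sign(u) = sign of the mass-action numerator
      num <- VF * prod(A / law$K_sub) - VB * prod(P / law$K_prod)
      expect_identical(sign(u), sign(num))
      h <- 1e-6
      for (j in 1:2) {
        Ap <- A; Ap[j] <- A[j] + h
        expect_gte(reaction_rate(law, Ap, P), u - 1e-12)
      }
      expect_lte(reaction_rate(law, A, P + h), u + 1e-12)
      # boundedness by the saturation-normalised envelope
      f12 <- rate_weights(VF, VB)
      den_min <- min(prod(1 + A / law$K_sub), prod(1 + P / law$K_prod))
      bound <- (VF * prod(A / law$K_sub) + VB * prod(P / law$K_prod)) /
        (den_min * min(f12[f12 > 0], 1))
      expect_lte(abs(u), bound + 1e-12)
    }
  })
})

test_that("time derivative is S u with pinned fluxes and buffered external species", {
  # single A <-> B, VF = 1, VB = 0, x = (1, 0): u = 0.5
  net <- parse_network(
    "id\tabbreviation\tname\tcarbon_count\n1\tA\ta\t3\n2\tB\tb\t3\n1000\texternal\text\t0",
    "id\tequation\tkind\n1\tA <-> B\tinternal")
  model <- kinetic_model(net, NULL,
                         rate_laws = list(`1` = rate_law(1, 0, K_sub = 1, K_prod = 1,
                                                         adapt_VB = FALSE)))
  f <- time_derivative(model, c(1, 0))
  expect_equal(unname(f), c(-0.5, 0.5))
  expect_false("external" %in% names(f))
  expect_error(time_derivative(model, c(-1, 0)), "negative")

  # flux vector satisfying S u = -b gives f = 0 component-wise
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  f0 <- time_derivative(chain$model, chain$x_star)
  expect_lt(max(abs(f0)), 1e-12)
})

test_that("vectorised engine agrees with the per-reaction reference on the full model", {
  m <- load_packaged_model()
  km <- kinetic_model(m$network, m$conditions$glucose)
  withr::with_seed(3, {
    x <- exp(runif(length(km$x_names), log(0.1), log(10)))
  })
  u_eng <- model_fluxes(km, x)
  for (id in km$kinetic_ids) {
    law <- km$rate_laws[[id]]
    u_ref <- reaction_rate(law,
                           substrates = ximflux:::occ_conc(x, law$sub_idx),
                           products = ximflux:::occ_conc(x, law$prod_idx))
    expect_equal(unname(u_eng[[id]]), u_ref, tolerance = 1e-12)
  }
  expect_equal(unname(u_eng[names(km$pinned)]), unname(km$pinned))
})

test_that("simulation recovers the closed-form chain steady state", {
  chain <- make_linear_chain(n = 3, drain = 1, VF = c(2, 3), K = c(1, 0.5))
  sim <- simulate_model(chain$model, t_end = 500, atol = 1e-12, rtol = 1e-10)
  expect_true(sim$steady)
  expect_lt(max(abs(sim$x_final[1:2] - chain$x_star[1:2])), 1e-6)
  # starting at a steady state stays there
  sim2 <- simulate_model(chain$model, x0 = chain$x_star, t_end = 100,
                         atol = 1e-10, rtol = 1e-8)
  expect_lt(max(abs(sim2$x_final - chain$x_star)), 10 * 1e-10 + 1e-8)
})

test_that("conserved cofactor moiety stays constant along trajectories", {
  net <- make_random_network(n_met = 5, n_rxn = 7, seed = 5)
  cond <- condition("rand", pinned = setNames(c(0.2, -0.2), c("1004", "1005")))
  model <- kinetic_model(net, cond)
  # the cofactor pair has zero row sum over every reaction
  S <- net$S
  expect_equal(max(abs(S["Cof", ] + S["CofH", ])), 0)
  sim <- simulate_model(model, t_end = 50, n_out = 21, atol = 1e-10, rtol = 1e-9)
  totals <- sim$trajectory[, "Cof"] + sim$trajectory[, "CofH"]
  expect_lt(max(abs(totals - totals[1])), 1e-6)
})
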