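# Lyapunov residual, parameter gradient, and the regulation loop.

test_that("psi is the D-weighted squared residual, zero exactly at steady states", {
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  # at the closed-form steady state f = 0, so psi = 0
  expect_equal(lyapunov_psi(chain$model, chain$x_star), 0)

  # quadratic-form arithmetic against a hand-picked D
  x <- c(2, 0.5, 1)
  f <- time_derivative(chain$model, x)
  D <- setNames(c(1, 2, 4), names(f))
  expect_equal(lyapunov_psi(chain$model, x, D), sum(f^2 / D))

  # non-negative everywhere, positive off steady state
  withr::with_seed(8, {
    for (i in 1:200) {
      xi <- exp(runif(3, log(0.05), log(20)))
      psi <- lyapunov_psi(chain$model, xi)
      expect_gte(psi, 0)
      if (max(abs(time_derivative(chain$model, xi))) > 1e-10) {
        expect_gt(psi, 0)
      }
    }
  })
})

test_that("diffusion weights are reciprocal carbon counts with unit floor", {
  m <- load_packaged_model()
  D <- diffusion_weights(m$network)
  expect_equal(unname(D["XiaA"]), 1 / 21)
  expect_equal(unname(D["CO2"]), 1)
  expect_equal(unname(D["Pi"]), 1)   # zero-carbon species get weight 1
  expect_length(D, 86)
})

test_that("analytic parameter gradient matches central finite differences", {
  net <- parse_network(
    "id\tabbreviation\tname\tcarbon_count\n1\tA\ta\t3\n2\tB\tb\t4\n1000\texternal\text\t0",
    paste("id\tequation\tkind",
          "1\tA <-> B\tinternal",
          "1004\texternal -> A\texchange",
          "1005\texternal <- B\texchange", sep = "\n"))
  cond <- condition("g", pinned = setNames(c(0.3, -0.3), c("1004", "1005")))
  model <- kinetic_model(net, cond, V_init = 0.7)
  for (x in list(c(1, 1), c(0.4, 2.3), c(3, 0.2))) {
    g <- grad_psi_parameters(model, x)
    V <- ximflux:::adaptable_V(model)
    g_fd <- vapply(names(g), function(nm) {
      h <- 1e-6 * max(abs(V[[nm]]), 1)
      Vp <- V; Vp[nm] <- V[nm] + h
      Vm <- V; Vm[nm] <- V[nm] - h
      (lyapunov_psi(ximflux:::set_adaptable_V(model, Vp), x) -
         lyapunov_psi(ximflux:::set_adaptable_V(model, Vm), x)) / (2 * h)
    }, 0)
    expect_equal(g, g_fd, tolerance = 1e-6)
  }
})

test_that("gradient vanishes at a steady state and points downhill off it", {
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  g0 <- grad_psi_parameters(chain$model, chain$x_star)
  expect_lt(max(abs(g0)), 1e-12)

  # drain 1 with VF = 1.2 leaves the first step short at x = 1: raising its
  # VF reduces the mismatch, so the gradient component is negative
  starved <- make_linear_chain(n = 2, drain = 1, VF = 1.2, K = 1)
  g <- grad_psi_parameters(starved$model, c(1, 1))
  expect_lt(g[["VF_1"]], 0)
})

test_that("coupled regulation stabilises a chain whose drain exceeds initial capacity", {
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  st <- stabilize(chain$model, regulation_config(t_end = 5000))
  expect_true(st$converged)
  expect_lt(st$max_residual, 1e-6)
  # the drain is reproduced everywhere along the chain
  u <- ximflux:::as_flux_named(st$fluxes)
  expect_equal(unname(u[c("1", "2")]), c(1, 1), tolerance = 1e-4)
  # deterministic given the seed
  st2 <- stabilize(chain$model, regulation_config(t_end = 5000))
  expect_identical(st$V_final, st2$V_final)
})

test_that("a model already at steady state keeps its parameters", {
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  # x0 = 1 everywhere is the steady state of this chain at V = 2
  st <- stabilize(chain$model, regulation_config(V_init = 2, t_end = 100))
  expect_true(st$converged)
  expect_lt(max(abs(st$V_final - 2)), 1e-6)
})

test_that("psi is non-increasing along quasi-static regulation", {
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  st <- stabilize(chain$model,
                  regulation_config(t_end = 3000, mode = "quasistatic"))
  psi <- st$psi_trace$psi
  expect_true(all(diff(psi) <= 1e-8 * psi[1] + 1e-12))
  expect_true(all(psi >= 0))
  expect_true(st$converged)
})

test_that("stability report separates decay modes from conservation zero modes", {
  # stabilised chain: all non-structural real parts negative
  chain <- make_linear_chain(n = 3, drain = 1, VF = 2, K = 1)
  st <- stabilize(chain$model, regulation_config(t_end = 5000))
  spec <- st$jacobian_spectrum
  expect_length(attr(spec, "flagged"), 0)
  non_struct <- sort(abs(spec), decreasing = TRUE)[seq_len(length(spec) - attr(spec, "n_structural"))]
  expect_true(all(non_struct > 0))

  # closed two-species moiety: exactly one structural zero eigenvalue
  net <- parse_network(
    "id\tabbreviation\tname\tcarbon_count\n1\tA\ta\t3\n2\tB\tb\t3\n1000\texternal\text\t0",
    "id\tequation\tkind\n1\tA <-> B\tinternal")
  model <- kinetic_model(net, NULL, V_init = 1)
  spec2 <- stability_report(model, c(1, 1))
  expect_identical(attr(spec2, "n_structural"), 1L)
  expect_length(attr(spec2, "flagged"), 0)
  expect_lt(sort(spec2)[1], -1e-3)  # the relaxation mode decays

  # a single drained species: strictly negative eigenvalue
  net3 <- parse_network(
    "id\tabbreviation\tname\tcarbon_count\n1\tA\ta\t3\n1000\texternal\text\t0",
    "id\tequation\tkind\n1\tA -> external\tinternal")
  model3 <- kinetic_model(net3, NULL, V_init = 1)
  spec3 <- stability_report(model3, 1)
  expect_lt(spec3[1], 0)
})
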