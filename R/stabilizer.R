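#' Diffusion-like metabolite weights
#'
#' Smaller compounds diffuse faster: the diagonal weight of a metabolite is
#' the reciprocal of its carbon count (zero-carbon species get weight 1).
#' These weights define the Lyapunov residual `psi = f' D^-1 f`, so heavy
#' metabolites (slowly diffusing, small `D`) are weighted more strongly.
#'
#' @param network a `metabolic_network`.
#' @return named numeric of diagonal entries of `D` over internal metabolites.
#' @export
diffusion_weights <- function(network) {
  met <- network$metabolites
  internal <- !met$is_external
  setNames(1 / pmax(met$carbon_count[internal], 1),
           met$abbreviation[internal])
}

#' Lyapunov residual psi
#'
#' `psi(x, V) = f' D^-1 f` with `f = dx/dt`: a weighted squared
#' steady-state residual. It is non-negative everywhere and zero exactly at
#' steady states, the two properties the parameter regulation relies on.
#' The weighting arises from the surrogate Lyapunov gradient
#' `grad_x phi = -D^-1 f` (the full potential from stochastic decomposition
#' is not identifiable from steady-state data; the surrogate is exact to
#' leading order near a steady state and is swappable via the `D` argument).
#'
#' @param model a `kinetic_model`.
#' @param x internal-metabolite concentrations.
#' @param D diagonal weights (default [diffusion_weights()] of the model's
#'   network).
#' @export
lyapunov_psi <- function(model, x, D = NULL) {
  if (is.null(D)) D <- diffusion_weights(model$network)
  f <- time_derivative(model, pmax(as.numeric(x), 0))
  sum(f^2 / D[names(f)])
}

#' Gradient of psi with respect to the maximal velocities
#'
#' `grad_V psi = 2 f' D^-1 S du/dV`, using the closed-form derivative of the
#' generic rate law. Only adaptable components (see [kinetic_model()]) are
#' returned, ordered as all `VF_<id>` then all `VB_<id>`.
#'
#' @inheritParams lyapunov_psi
#' @return named numeric gradient.
#' @export
grad_psi_parameters <- function(model, x, D = NULL) {
  if (is.null(D)) D <- diffusion_weights(model$network)
  x <- pmax(as.numeric(x), 0)
  eng <- model$engine
  dd <- engine_dudV(eng, x)
  f <- drop(model$S_kin %*% dd$u) + model$const_term
  cvec <- drop(crossprod(model$S_kin, f / D[names(f)]))
  c(setNames(2 * cvec[eng$adaptF] * dd$dVF[eng$adaptF],
             vnames("VF_", eng$ids[eng$adaptF])),
    setNames(2 * cvec[eng$adaptB] * dd$dVB[eng$adaptB],
             vnames("VB_", eng$ids[eng$adaptB])))
}

vnames <- function(prefix, ids) {
  if (length(ids)) paste0(prefix, ids) else character(0)
}

adaptable_V <- function(model) {
  eng <- model$engine
  c(setNames(eng$VF[eng$adaptF], vnames("VF_", eng$ids[eng$adaptF])),
    setNames(eng$VB[eng$adaptB], vnames("VB_", eng$ids[eng$adaptB])))
}

set_adaptable_V <- function(model, V) {
  eng <- model$engine
  nF <- sum(eng$adaptF)
  vf_names <- vnames("VF_", eng$ids[eng$adaptF])
  vb_names <- vnames("VB_", eng$ids[eng$adaptB])
  if (!all(names(V) %in% c(vf_names, vb_names))) {
    stop("unknown adaptable velocity name")
  }
  vf <- intersect(names(V), vf_names)
  vb <- intersect(names(V), vb_names)
  eng$VF[match(vf, paste0("VF_", eng$ids))] <- V[vf]
  eng$VB[match(vb, paste0("VB_", eng$ids))] <- V[vb]
  model$engine <- eng
  for (nm in vf) model$rate_laws[[sub("^VF_", "", nm)]]$VF <- V[[nm]]
  for (nm in vb) model$rate_laws[[sub("^VB_", "", nm)]]$VB <- V[[nm]]
  model
}

#' Regulation configuration
#'
#' @param D diagonal diffusion weights (default from carbon counts).
#' @param W scalar positive modulation weight (the published protocol sets
#'   it to 1; a vector over adaptable parameters is also accepted).
#' @param V_init initial maximal velocity for adaptable components.
#' @param V_min lower clamp keeping every adaptable velocity positive.
#' @param clamp_width width of the smooth boundary layer above `V_min` over
#'   which the descent rate tapers to zero (keeps the regulation
#'   right-hand side continuous at the clamp).
#' @param x_floor smooth lower bound on concentrations during coupled
#'   regulation: downhill motion tapers to zero across a layer of the same
#'   width above the floor. Two orders of magnitude below typical normalised
#'   pool sizes, the floor keeps every rate (and hence every velocity
#'   gradient) responsive while a drain transiently exceeds kinetic
#'   capacity; without it a crashed cofactor pool deadlocks the regulation.
#' @param t_end regulation horizon (the published protocol integrates to
#'   1e5 time units).
#' @param n_out sampled output points for the psi trace.
#' @param atol,rtol integrator tolerances.
#' @param method deSolve integration method for the coupled system.
#' @param maxsteps integrator step budget per output interval.
#' @param atol_steady steady-state threshold on `max(abs(f))`.
#' @param x0 `"ones"` (all concentrations 1) or `"random"` (log-uniform in
#'   \[0.1, 10\] under `seed`).
#' @param mode `"coupled"` integrates x and V simultaneously;
#'   `"quasistatic"` alternates x relaxation windows with projected gradient
#'   steps on V (used for descent-property checks).
#' @param seed integer seed, used only when `x0 = "random"`.
#' @export
regulation_config <- function(D = NULL, W = 1, V_init = 0.4, V_min = 1e-6,
                              clamp_width = 1e-3, x_floor = 0.01,
                              t_end = 1e5, n_out = 101,
                              atol = 1e-8, rtol = 1e-6, method = "bdf", maxsteps = 1e5,
                              atol_steady = 1e-6,
                              x0 = c("ones", "random"),
                              mode = c("coupled", "quasistatic"),
                              seed = 1L) {
  x0 <- match.arg(x0)
  mode <- match.arg(mode)
  stopifnot(all(W > 0), V_min > 0, t_end > 0)
  structure(list(D = D, W = W, V_init = V_init, V_min = V_min,
                 clamp_width = clamp_width, x_floor = x_floor,
                 t_end = t_end, n_out = n_out, atol = atol, rtol = rtol,
                 method = method, maxsteps = maxsteps,
                 atol_steady = atol_steady,
                 x0 = x0, mode = mode,
                 seed = as.integer(seed)),
            class = "regulation_config")
}

initial_x <- function(model, config) {
  n <- length(model$x_names)
  if (config$x0 == "random") {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(config$seed)
    x <- exp(stats::runif(n, log(0.1), log(10)))
  } else {
    x <- rep(1, n)
  }
  setNames(x, model$x_names)
}

#' Stabilise a kinetic model by Lyapunov-gradient parameter regulation
#'
#' Integrates the coupled system `dx/dt = f(x, V)`,
#' `W dV/dt = -grad_V psi(x, V)` over `[0, t_end]` with a stiff-capable
#' integrator. The regulation drives the weighted steady-state residual
#' `psi` towards zero by adapting the maximal velocities, so the network
#' settles into a steady state consistent with the pinned boundary drains.
#' Velocities are clamped below at `V_min`.
#'
#' Concentrations are kept positive by a smooth floor: downhill motion
#' tapers to zero across a thin layer above `x_floor`, so pinned drains that
#' transiently exceed kinetic capacity park the metabolite at the floor
#' instead of driving it negative, and the velocities keep adapting until
#' the drain is met. Away from the floor the dynamics are exactly
#' `dx/dt = f`.
#'
#' @param model a `kinetic_model` (all adaptable velocities are reset to
#'   `config$V_init`).
#' @param config a [regulation_config()].
#' @return object of class `stabilization_result`: `x_final`, `V_final`,
#'   `fluxes` (a `flux_vector`), `psi_trace` (data.frame `t`, `psi`),
#'   `converged`, `max_residual`, `jacobian_spectrum`, `clamp_active`,
#'   `model` (with final velocities), `config`.
#' @export
stabilize <- function(model, config = regulation_config()) {
  V0 <- adaptable_V(model)
  V0[] <- config$V_init
  model <- set_adaptable_V(model, V0)
  D <- if (is.null(config$D)) diffusion_weights(model$network) else config$D
  x0 <- initial_x(model, config)

  if (config$mode == "quasistatic") {
    return(stabilize_quasistatic(model, config, D, x0))
  }

  eng <- model$engine
  nx <- length(x0)
  nv <- length(V0)
  nF <- sum(eng$adaptF)
  nB <- sum(eng$adaptB)
  Dinv <- 1 / D[model$x_names]
  Skin <- model$S_kin
  ctx <- list(S = unname(model$S_kin),
              sub_r = eng$sub_r, sub_m = eng$sub_m, Ks = eng$Ks,
              prod_r = eng$prod_r, prod_m = eng$prod_m, Kp = eng$Kp,
              VF = eng$VF, VB = eng$VB,
              idxF = which(eng$adaptF), idxB = which(eng$adaptB),
              const_term = unname(model$const_term),
              Dinv = unname(Dinv),
              Winv = rep_len(1 / config$W, nv),
              x_floor = config$x_floor, v_min = config$V_min,
              clamp_width = config$clamp_width, swapped = eng$swapped)
  rhs <- function(t, state, parms) list(.coupled_rhs_cpp(state, ctx))
  times <- seq(0, config$t_end, length.out = config$n_out)
  state0 <- c(pmax(x0, config$x_floor), V0)
  traj <- try(deSolve::ode(y = state0, times = times, func = rhs, parms = NULL,
                           method = config$method, atol = config$atol,
                           rtol = config$rtol, maxsteps = config$maxsteps),
              silent = TRUE)
  if (inherits(traj, "try-error")) {
    stop("integrator failure during stabilisation: ", attr(traj, "condition")$message,
         call. = FALSE)
  }
  failed <- attr(traj, "istate")[1] < 0 || nrow(traj) < length(times)
  last <- traj[nrow(traj), -1]
  x_final <- pmax(last[seq_len(nx)], config$x_floor)
  V_final <- pmax(last[nx + seq_len(nv)], config$V_min)
  names(V_final) <- names(V0)
  model_f <- set_adaptable_V(model, V_final)
  f <- time_derivative(model_f, x_final)
  psi_trace <- data.frame(
    t = traj[, "time"],
    psi = apply(traj, 1, function(row) {
      xi <- pmax(row[1 + seq_len(nx)], config$x_floor)
      Vi <- pmax(row[1 + nx + seq_len(nv)], config$V_min)
      VFi <- eng$VF; VBi <- eng$VB
      VFi[eng$adaptF] <- Vi[seq_len(nF)]
      VBi[eng$adaptB] <- Vi[nF + seq_len(nB)]
      fi <- drop(Skin %*% engine_u(eng, xi, VFi, VBi)) + model$const_term
      sum(fi^2 * Dinv)
    })
  )
  finish_stabilization(model_f, x_final, V_final, f, psi_trace,
                       failed, config, D)
}

# Quasi-static regulation: alternate metabolite relaxation windows (compiled
# right-hand side, same smooth concentration floor as the coupled mode) with
# projected gradient-descent sweeps on the maximal velocities. Each V update
# uses backtracking, so psi never increases at frozen x; the adaptive step
# length plays the role of a state-dependent positive scalar modulation
# weight. Terminates early once the steady-state threshold is met.
# Quasi-static regulation: deep box-constrained quasi-Newton descent of psi
# over the maximal velocities at frozen metabolite amounts (analytic
# gradient; psi cannot increase over a sweep), alternated with metabolite
# relaxation windows using the compiled right-hand side and the same smooth
# concentration floor as the coupled mode. With more adaptable velocities
# than metabolites the frozen-x minimum of psi is typically an exact steady
# state, so the first sweep does most of the work and the relaxation windows
# verify self-consistency. The adaptive descent plays the role of a
# state-dependent positive modulation weight.
stabilize_quasistatic <- function(model, config, D, x0, n_steps = 10,
                                  n_inner = 20000) {
  eng <- model$engine
  V <- adaptable_V(model)
  x <- pmax(x0, config$x_floor)
  nv <- length(V)
  Dinv <- 1 / D[model$x_names]
  ctx <- list(S = unname(model$S_kin),
              sub_r = eng$sub_r, sub_m = eng$sub_m, Ks = eng$Ks,
              prod_r = eng$prod_r, prod_m = eng$prod_m, Kp = eng$Kp,
              VF = eng$VF, VB = eng$VB,
              idxF = which(eng$adaptF), idxB = which(eng$adaptB),
              const_term = unname(model$const_term),
              Dinv = unname(Dinv),
              Winv = rep_len(1 / config$W, max(nv, 1L)),
              x_floor = config$x_floor, v_min = config$V_min,
              clamp_width = config$clamp_width, swapped = eng$swapped)
  window <- config$t_end / n_steps
  psi_trace <- data.frame(t = numeric(0), psi = numeric(0))
  relax_x <- function(x, V) {
    VFk <- eng$VF; VBk <- eng$VB
    VFk[eng$adaptF] <- V[seq_len(sum(eng$adaptF))]
    VBk[eng$adaptB] <- V[sum(eng$adaptF) + seq_len(sum(eng$adaptB))]
    rhs <- function(t, state, parms) list(.x_rhs_cpp(state, ctx, VFk, VBk))
    # a capped step budget keeps a slow relaxation from dominating a sweep;
    # the following regulation sweep re-anchors the state
    tr <- suppressWarnings(
      deSolve::ode(y = x, times = c(0, window), func = rhs, parms = NULL,
                   method = "bdf", atol = config$atol, rtol = config$rtol,
                   maxsteps = min(config$maxsteps, 5000)))
    pmax(tr[nrow(tr), -1], config$x_floor)
  }
  for (k in seq_len(n_steps)) {
    # regulate V at frozen x: box-constrained quasi-Newton descent on psi
    # with the analytic gradient; psi cannot increase over the sweep
    psi_now <- lyapunov_psi(model, x, D)
    if (nv > 0 && psi_now > 0) {
      nFa <- sum(eng$adaptF)
      split_V <- function(p) {
        VFk <- eng$VF; VBk <- eng$VB
        VFk[eng$adaptF] <- p[seq_len(nFa)]
        VBk[eng$adaptB] <- p[nFa + seq_len(nv - nFa)]
        list(VF = VFk, VB = VBk)
      }
      fn <- function(p) {
        vv <- split_V(p)
        fi <- drop(model$S_kin %*% engine_u(eng, x, vv$VF, vv$VB)) +
          model$const_term
        sum(fi^2 * Dinv)
      }
      gr <- function(p) {
        vv <- split_V(p)
        dd <- engine_dudV(eng, x, vv$VF, vv$VB)
        fi <- drop(model$S_kin %*% dd$u) + model$const_term
        cvec <- drop(crossprod(model$S_kin, fi * Dinv))
        c(2 * cvec[eng$adaptF] * dd$dVF[eng$adaptF],
          2 * cvec[eng$adaptB] * dd$dVB[eng$adaptB]) / config$W
      }
      opt <- stats::optim(unname(V), fn, gr, method = "L-BFGS-B",
                          lower = config$V_min,
                          control = list(maxit = n_inner, factr = 10))
      if (opt$value <= psi_now) {
        V <- setNames(opt$par, names(V))
        model <- set_adaptable_V(model, V)
        psi_now <- opt$value
      }
    }
    psi_trace <- rbind(psi_trace, data.frame(t = k * window, psi = psi_now))
    if (max(abs(time_derivative(model, x))) < config$atol_steady) break
    x <- relax_x(x, V)
  }
  f <- time_derivative(model, x)
  finish_stabilization(model, x, V, f, psi_trace, FALSE, config, D)
}

finish_stabilization <- function(model, x_final, V_final, f, psi_trace,
                                 failed, config, D) {
  u <- model_fluxes(model, x_final)
  spec <- stability_report(model, x_final)
  structure(list(
    x_final = setNames(as.numeric(x_final), model$x_names),
    V_final = V_final,
    fluxes = flux_vector(u, condition = if (!is.null(model$condition)) model$condition$name),
    psi_trace = psi_trace,
    converged = !failed && max(abs(f)) < config$atol_steady,
    max_residual = max(abs(f)),
    jacobian_spectrum = spec,
    clamp_active = sum(V_final <= config$V_min),
    model = model,
    config = config
  ), class = "stabilization_result")
}

#' @export
print.stabilization_result <- function(x, ...) {
  cat(sprintf("<stabilization_result> converged = %s, max|dx/dt| = %.3g\n",
              x$converged, x$max_residual))
  cat(sprintf("  psi: %.3g -> %.3g over %d samples; %d velocities at clamp\n",
              x$psi_trace$psi[1], x$psi_trace$psi[nrow(x$psi_trace)],
              nrow(x$psi_trace), x$clamp_active))
  flagged <- attr(x$jacobian_spectrum, "flagged")
  cat(sprintf("  Jacobian: %d eigenvalues flagged non-negative (beyond %d structural zero modes)\n",
              length(flagged), attr(x$jacobian_spectrum, "n_structural")))
  invisible(x)
}

#' Local stability report at a steady state
#'
#' Real parts of the eigenvalues of the numeric Jacobian `df/dx`. Conserved
#' moieties (metabolite groups whose stoichiometric rows sum to zero over the
#' kinetic reactions) contribute structural zero eigenvalues that say nothing
#' about instability; their count is excluded before flagging non-negative
#' real parts above `tol`.
#'
#' @param model a `kinetic_model` with final velocities applied.
#' @param x steady-state concentrations.
#' @param tol flag threshold on real parts.
#' @return numeric vector of eigenvalue real parts (sorted decreasing) with
#'   attributes `n_structural` (count of conservation zero modes) and
#'   `flagged` (indices of non-structural eigenvalues with real part
#'   `>= tol`).
#' @export
stability_report <- function(model, x, tol = 1e-8) {
  x <- pmax(as.numeric(x), 0)
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (time_derivative(model, xp) - time_derivative(model, xm)) /
      (xp[j] - xm[j])
  }
  ev <- eigen(J, only.values = TRUE)$values
  re <- sort(Re(ev), decreasing = TRUE)
  # structural zero modes: left nullspace of S over kinetic columns
  sv <- svd(t(model$S_kin))
  rtol <- max(dim(model$S_kin)) * max(sv$d, 0) * .Machine$double.eps
  n_struct <- as.integer(sum(sv$d <= rtol) + max(0, nrow(model$S_kin) - length(sv$d)))
  mag_order <- order(abs(re))
  structural_idx <- mag_order[seq_len(min(n_struct, length(re)))]
  candidates <- setdiff(seq_along(re), structural_idx)
  flagged <- candidates[re[candidates] >= tol]
  structure(re, n_structural = n_struct, flagged = flagged)
}
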