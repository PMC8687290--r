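#' Rate-law weighting functions
#'
#' The generic reversible rate law weights its substrate- and product-side
#' saturation terms by two functions of the maximal velocities that sum to
#' one. The standard orientation, `f1 = VF/(VF+VB)`, `f2 = VB/(VF+VB)`,
#' reduces the rate law to irreversible Michaelis-Menten form when `VB = 0`.
#' The swapped orientation is available for sensitivity checks.
#'
#' @param VF,VB maximal forward / backward velocities (non-negative, not both
#'   zero).
#' @param orientation `"standard"` or `"swapped"`.
#' @return numeric c(f1, f2).
#' @examples
#' rate_weights(0.4, 0.4) # c(0.5, 0.5)
#' @export
rate_weights <- function(VF, VB, orientation = c("standard", "swapped")) {
  orientation <- match.arg(orientation)
  if (VF < 0 || VB < 0) stop("maximal velocities must be non-negative")
  tot <- VF + VB
  if (tot == 0) stop("VF and VB cannot both be zero")
  w <- c(VF / tot, VB / tot)
  if (orientation == "swapped") w <- rev(w)
  setNames(w, c("f1", "f2"))
}

#' Construct a rate law for one reaction
#'
#' @param VF,VB maximal velocities.
#' @param K_sub,K_prod Michaelis-like constants, one per substrate/product
#'   occurrence (a stoichiometric coefficient of n contributes n occurrences).
#' @param adapt_VF,adapt_VB whether the Lyapunov regulation may change the
#'   component (irreversible reactions keep the disallowed direction at 0).
#' @export
rate_law <- function(VF, VB, K_sub = numeric(), K_prod = numeric(),
                     adapt_VF = TRUE, adapt_VB = TRUE) {
  if (VF < 0 || VB < 0 || VF + VB <= 0) stop("need VF, VB >= 0 and VF + VB > 0")
  if (any(c(K_sub, K_prod) <= 0)) stop("all K must be > 0")
  structure(list(VF = VF, VB = VB, K_sub = K_sub, K_prod = K_prod,
                 adapt_VF = adapt_VF, adapt_VB = adapt_VB),
            class = "rate_law")
}

# core rate evaluation on expanded occurrence vectors
eval_rate <- function(VF, VB, A, Ks, P, Kp, orientation = "standard") {
  w <- rate_weights(VF, VB, orientation)
  a <- prod(A / Ks)
  p <- prod(P / Kp)
  num <- VF * a - VB * p
  den <- w[[1]] * prod(1 + A / Ks) + w[[2]] * prod(1 + P / Kp)
  num / den
}

#' Evaluate the generic enzymatic rate law
#'
#' `u = (VF * prod(A_i/K_i) - VB * prod(P_j/K_j)) /
#'      (f1 * prod(1 + A_i/K_i) + f2 * prod(1 + P_j/K_j))`
#'
#' Substrate and product concentrations are passed per occurrence: a
#' reaction consuming `2 X` lists the concentration of `X` twice.
#'
#' @param law a [rate_law()].
#' @param substrates,products non-negative concentrations per occurrence.
#' @param orientation weighting orientation, see [rate_weights()].
#' @return the net flux (positive = left-to-right).
#' @examples
#' law <- rate_law(VF = 2, VB = 0, K_sub = 1)
#' reaction_rate(law, substrates = 1) # half-saturated irreversible MM: 1
#' @export
reaction_rate <- function(law, substrates = numeric(), products = numeric(),
                          orientation = c("standard", "swapped")) {
  orientation <- match.arg(orientation)
  if (any(substrates < 0) || any(products < 0)) {
    stop("concentrations must be non-negative")
  }
  Ks <- if (length(law$K_sub)) law$K_sub else rep(1, length(substrates))
  Kp <- if (length(law$K_prod)) law$K_prod else rep(1, length(products))
  if (length(Ks) != length(substrates) || length(Kp) != length(products)) {
    stop("one K per participant occurrence is required")
  }
  eval_rate(law$VF, law$VB, substrates, Ks, products, Kp, orientation)
}

#' Assemble a kinetic model
#'
#' Every reaction carries exactly one of a rate law (internal reactions and
#' free boundary reactions) or a pinned constant flux (the condition's fixed
#' boundary drains). The buffered external pseudo-species is held at
#' concentration 1, so free uptake reactions behave as saturable imports.
#'
#' Irreversible glyphs are honoured kinetically: a `->` reaction gets
#' `VB = 0` (not adapted), a `<-` reaction `VF = 0`.
#'
#' @param network a `metabolic_network`.
#' @param condition a `ximflux_condition` (or `NULL` for no pinned fluxes,
#'   in which case every reaction gets a rate law).
#' @param V_init initial maximal velocity for every adaptable component.
#' @param K_default Michaelis-like constant applied to every occurrence.
#' @param orientation rate-law weighting orientation.
#' @param rate_laws optional named list of [rate_law()] overrides by
#'   reaction id.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(network, condition = NULL, V_init = 0.4,
                          K_default = 1,
                          orientation = c("standard", "swapped"),
                          rate_laws = list()) {
  orientation <- match.arg(orientation)
  rxn <- network$reactions
  rids <- as.character(rxn$id)
  pinned <- if (is.null(condition)) setNames(numeric(0), character(0)) else condition$pinned
  supply <- if (is.null(condition)) numeric(0) else condition$supply
  kin_ids <- setdiff(rids, names(pinned))

  met <- network$metabolites
  internal <- met$abbreviation[!met$is_external]
  x_index <- setNames(seq_along(internal), internal)

  laws <- vector("list", length(kin_ids))
  names(laws) <- kin_ids
  for (id in kin_ids) {
    st <- network$stoichiometry[[id]]
    arrow <- rxn$arrow[match(as.numeric(id), rxn$id)]
    if (!is.null(rate_laws[[id]])) {
      law <- rate_laws[[id]]
    } else {
      VF <- if (arrow == "<-") 0 else V_init
      VB <- if (arrow == "->") 0 else V_init
      law <- rate_law(VF, VB, adapt_VF = arrow != "<-", adapt_VB = arrow != "->")
    }
    subs <- -st[st < 0]
    prods <- st[st > 0]
    sub_occ <- rep(names(subs), times = as.integer(subs))
    prod_occ <- rep(names(prods), times = as.integer(prods))
    law$sub_species <- sub_occ
    law$prod_species <- prod_occ
    # index 0 marks the buffered external species (concentration fixed at 1)
    law$sub_idx <- ifelse(sub_occ == "external", 0L, x_index[sub_occ])
    law$prod_idx <- ifelse(prod_occ == "external", 0L, x_index[prod_occ])
    if (!length(law$K_sub)) law$K_sub <- rep(K_default, length(sub_occ))
    if (!length(law$K_prod)) law$K_prod <- rep(K_default, length(prod_occ))
    laws[[id]] <- law
  }

  # constant part of dx/dt: pinned boundary fluxes plus biomass supply
  const <- rep(0, length(internal))
  names(const) <- internal
  if (length(pinned)) {
    const <- const + drop(network$S[, names(pinned), drop = FALSE] %*% pinned)
  }
  if (length(supply)) {
    sp <- intersect(names(supply), internal)
    const[sp] <- const[sp] + supply[sp]
  }

  model <- structure(list(network = network,
                          condition = condition,
                          rate_laws = laws,
                          kinetic_ids = kin_ids,
                          pinned = pinned,
                          supply = supply,
                          const_term = const,
                          S_kin = network$S[, kin_ids, drop = FALSE],
                          x_names = internal,
                          orientation = orientation),
                     class = "kinetic_model")
  model$engine <- build_engine(model)
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d metabolites, %d kinetic reactions, %d pinned boundary fluxes\n",
              length(x$x_names), length(x$kinetic_ids), length(x$pinned)))
  invisible(x)
}

# concentrations per occurrence; index 0 = buffered external at 1
occ_conc <- function(x, idx) {
  out <- numeric(length(idx))
  ext <- idx == 0L
  out[ext] <- 1
  out[!ext] <- x[idx[!ext]]
  out
}

#' Fluxes of every reaction at a concentration state
#'
#' @param model a `kinetic_model`.
#' @param x named (or ordered) concentrations of the internal metabolites.
#' @return named numeric over all reaction ids (pinned values substituted
#'   verbatim).
#' @export
model_fluxes <- function(model, x) {
  x <- pmax(as.numeric(x), 0)
  u <- setNames(engine_u(model$engine, x), model$kinetic_ids)
  full <- setNames(numeric(ncol(model$network$S)), colnames(model$network$S))
  full[names(u)] <- u
  full[names(model$pinned)] <- model$pinned
  full
}

#' Metabolite time derivative dx/dt = S u + b
#'
#' Pinned boundary fluxes and biomass supply terms enter as constants; the
#' buffered external species has derivative zero by construction (it is not
#' part of the state).
#'
#' @param model a `kinetic_model`.
#' @param x concentrations of internal metabolites (non-negative).
#' @return named numeric of per-metabolite net rates.
#' @export
time_derivative <- function(model, x) {
  if (any(x < 0)) stop("negative concentration")
  engine_f(model, as.numeric(x))
}

#' Integrate the metabolite ODE system at fixed parameters
#'
#' Uses a stiff-capable implicit integrator (`deSolve::ode`, method
#' `"lsoda"`). Concentrations stepping below `-10 * atol` are clipped to
#' zero inside the right-hand side; clip events are counted in the result.
#'
#' @param model a `kinetic_model`.
#' @param x0 initial concentrations (default all 1).
#' @param t_end integration horizon.
#' @param n_out number of output time points.
#' @param atol,rtol integrator tolerances.
#' @param atol_steady steady-state threshold on `max(abs(dx/dt))`.
#' @return list with `trajectory` (deSolve matrix), `x_final`, `steady`,
#'   `max_residual`, `clip_events`.
#' @export
simulate_model <- function(model, x0 = NULL, t_end = 1e5, n_out = 101,
                           atol = 1e-10, rtol = 1e-8, atol_steady = 1e-6) {
  n <- length(model$x_names)
  if (is.null(x0)) x0 <- rep(1, n)
  if (length(x0) != n) stop("x0 must cover every internal metabolite")
  if (any(x0 < 0)) stop("negative initial concentration")
  x0 <- setNames(as.numeric(x0), model$x_names)
  clip_count <- new.env()
  clip_count$n <- 0L
  rhs <- function(t, x, parms) {
    if (any(x < -10 * atol)) clip_count$n <- clip_count$n + 1L
    x <- pmax(x, 0)
    list(time_derivative(model, x))
  }
  times <- seq(0, t_end, length.out = n_out)
  traj <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                       method = "lsoda", atol = atol, rtol = rtol)
  if (attr(traj, "istate")[1] < 0) {
    stop(sprintf("integrator failed at t = %.6g", max(traj[, "time"])), call. = FALSE)
  }
  x_final <- pmax(traj[nrow(traj), -1], 0)
  f <- time_derivative(model, x_final)
  list(trajectory = traj,
       x_final = setNames(as.numeric(x_final), model$x_names),
       steady = max(abs(f)) < atol_steady,
       max_residual = max(abs(f)),
       clip_events = clip_count$n)
}
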