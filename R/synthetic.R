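# Generators for small networks with known analytic behaviour. They exercise
# every layer (parsing, structural analysis, kinetics, regulation) without
# the full model.

toy_tables <- function(met, rxn) {
  m_lines <- c("id\tabbreviation\tname\tcarbon_count\tbiomass_glucose\tbiomass_glucose_glycerol",
               vapply(seq_len(nrow(met)), function(i) {
                 paste(met$id[i], met$abbreviation[i], met$name[i],
                       met$carbon_count[i], 0, 0, sep = "\t")
               }, ""))
  r_lines <- c("id\tequation\tkind",
               vapply(seq_len(nrow(rxn)), function(i) {
                 paste(rxn$id[i], rxn$equation[i], rxn$kind[i], sep = "\t")
               }, ""))
  parse_network(paste(m_lines, collapse = "\n"), paste(r_lines, collapse = "\n"))
}

#' Linear chain with closed-form steady state
#'
#' Builds `X1 -> X2 -> ... -> Xn` with a constant input flux `d` into `X1`
#' and a constant drain `d` out of `Xn`, irreversible Michaelis-Menten steps
#' (`VB = 0`). Each internal step carries flux `d` at steady state, giving
#' the closed form `x_i* = K_i d / (VF_i - d)` for `i < n` (the terminal
#' metabolite is held by the constant drain and keeps its initial value).
#'
#' @param n number of metabolites (>= 2).
#' @param drain steady throughput `d >= 0`; must satisfy `d < VF` on every
#'   step.
#' @param VF,K per-step (recycled) maximal velocity and Michaelis constant.
#' @return list with `model` (a `kinetic_model`), `network`, `condition`,
#'   `x_star` (closed-form steady state, terminal entry = 1), `flux_star`.
#' @export
make_linear_chain <- function(n = 3, drain = 1, VF = 2, K = 1) {
  stopifnot(n >= 2)
  VF <- rep_len(VF, n - 1)
  K <- rep_len(K, n - 1)
  if (any(drain >= VF)) {
    stop("infeasible drain: need drain < VF on every step")
  }
  mets <- paste0("X", seq_len(n))
  met <- data.frame(id = c(seq_len(n), 1000),
                    abbreviation = c(mets, "external"),
                    name = c(mets, "external"),
                    carbon_count = c(rep(3, n), 0))
  internal <- data.frame(id = seq_len(n - 1),
                         equation = paste(mets[-n], "->", mets[-1]),
                         kind = "internal")
  boundary <- data.frame(id = c(1004, 1005),
                         equation = c(paste("external ->", mets[1]),
                                      paste("external <-", mets[n])),
                         kind = "exchange")
  net <- toy_tables(met, rbind(internal, boundary))
  cond <- condition("toy", pinned = setNames(c(drain, -drain), c("1004", "1005")))
  laws <- lapply(seq_len(n - 1), function(i) {
    rate_law(VF = VF[i], VB = 0, K_sub = K[i], K_prod = 1,
             adapt_VF = TRUE, adapt_VB = FALSE)
  })
  names(laws) <- as.character(seq_len(n - 1))
  model <- kinetic_model(net, cond, rate_laws = laws)
  x_star <- setNames(c(K * drain / (VF - drain), 1), mets)
  if (drain == 0) x_star[] <- c(rep(0, n - 1), 1)
  flux_star <- setNames(rep(drain, n + 1),
                        c(as.character(seq_len(n - 1)), "1004", "1005"))
  flux_star[["1005"]] <- -drain
  list(model = model, network = net, condition = cond,
       x_star = x_star, flux_star = flux_star)
}

#' Branched toy network
#'
#' One source metabolite fed at a constant rate splits into two competing
#' branches with separate drains. With only the input pinned, the branch
#' split is structurally free (one-dimensional nullspace); pinning both
#' drains forces every flux.
#'
#' @param input total input flux.
#' @param drains length-2 drains of the two branches; `NULL` leaves them
#'   free.
#' @param VF,K branch kinetics (recycled over the two branch reactions).
#' @return list with `model`, `network`, `condition`.
#' @export
make_branched_toy <- function(input = 1, drains = c(0.5, 0.5), VF = 2, K = 1) {
  met <- data.frame(id = c(1:3, 1000),
                    abbreviation = c("S0", "B1", "B2", "external"),
                    name = c("source", "branch1", "branch2", "external"),
                    carbon_count = c(3, 3, 3, 0))
  rxn <- data.frame(id = c(1, 2, 1004, 1005, 1006),
                    equation = c("S0 -> B1", "S0 -> B2",
                                 "external -> S0",
                                 "external <- B1", "external <- B2"),
                    kind = c("internal", "internal", rep("exchange", 3)))
  net <- toy_tables(met, rxn)
  pinned <- setNames(input, "1004")
  free <- c("1005", "1006")
  if (!is.null(drains)) {
    pinned <- c(pinned, setNames(-drains, c("1005", "1006")))
    free <- character()
  }
  cond <- condition("toy_branch", pinned = pinned, free_ids = free)
  VF <- rep_len(VF, 2); K <- rep_len(K, 2)
  laws <- list(`1` = rate_law(VF[1], 0, K_sub = K[1], K_prod = 1, adapt_VB = FALSE),
               `2` = rate_law(VF[2], 0, K_sub = K[2], K_prod = 1, adapt_VB = FALSE))
  model <- kinetic_model(net, cond, rate_laws = laws)
  list(model = model, network = net, condition = cond)
}

#' Seeded random network with a conserved cofactor pair
#'
#' Generates a connected network over `n_met` primary metabolites: a chain
#' backbone guaranteeing connectivity plus random extra conversions, a
#' fraction of which are coupled to a cofactor couple (`Cof`/`CofH`) whose
#' stoichiometric rows sum to zero, giving a conserved moiety by
#' construction. Deterministic for a given seed. All primary metabolites
#' share one carbon count, so every internal reaction is carbon balanced.
#'
#' @param n_met number of primary metabolites (>= 2).
#' @param n_rxn number of internal reactions (>= `n_met - 1`).
#' @param seed integer seed for the generator's private random stream.
#' @return a `metabolic_network` with input/output exchange reactions on the
#'   chain ends (ids 1004/1005) and a cofactor regeneration reaction.
#' @export
make_random_network <- function(n_met = 6, n_rxn = 8, seed = 1L) {
  stopifnot(n_met >= 2, n_rxn >= n_met - 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))

  mets <- paste0("M", seq_len(n_met))
  met <- data.frame(id = c(seq_len(n_met), 200, 201, 1000),
                    abbreviation = c(mets, "Cof", "CofH", "external"),
                    name = c(mets, "cofactor (oxidised)", "cofactor (reduced)", "external"),
                    carbon_count = c(rep(3, n_met), 21, 21, 0))
  eqs <- paste(mets[-n_met], "<->", mets[-1])
  extra <- n_rxn - (n_met - 1)
  if (extra > 0) {
    for (k in seq_len(extra)) {
      ab <- sample(n_met, 2)
      if (k %% 2 == 1) {
        eqs <- c(eqs, sprintf("%s + Cof <-> %s + CofH", mets[ab[1]], mets[ab[2]]))
      } else {
        eqs <- c(eqs, sprintf("%s <-> %s", mets[ab[1]], mets[ab[2]]))
      }
    }
  }
  rxn <- data.frame(id = seq_along(eqs), equation = eqs, kind = "internal")
  boundary <- data.frame(id = c(100, 1004, 1005),
                         equation = c("CofH <-> Cof",
                                      paste("external ->", mets[1]),
                                      paste("external <-", mets[n_met])),
                         kind = c("internal", "exchange", "exchange"))
  toy_tables(met, rbind(rxn, boundary))
}
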