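round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Carbon conversion efficiency
#'
#' Fraction of carbon atoms taken up from the nutrient sources that leave
#' the cell in the target product per unit time:
#' `100 * carbon(product) * |u_export| / sum_s carbon(source_s) * u_s`.
#' The product flux is taken from the product's export pseudo-reaction (not
#' the terminal biosynthetic step), so scenarios with exogenous product
#' supply remain correct.
#'
#' @param fluxes a `flux_vector` or named numeric over reaction ids.
#' @param network a `metabolic_network`.
#' @param product product metabolite abbreviation (default `"XiaA"`, counted
#'   with 21 carbons: 7 from 4HB, 10 from GPP, 4 from Thr).
#' @param sources reaction ids of the carbon-source uptakes (default glucose
#'   1017 and glycerol 1021).
#' @param digits rounding for the reported percentage (round-half-up).
#' @return list of class `efficiency_report`: `product`,
#'   `product_carbon_flux`, `source_carbon_flux`, `efficiency_percent`
#'   (raw), `efficiency_reported` (rounded), `rounding`.
#' @export
carbon_efficiency <- function(fluxes, network, product = "XiaA",
                              sources = c(1017, 1021), digits = 0) {
  u <- as_flux_named(fluxes)
  met <- network$metabolites
  cc <- setNames(met$carbon_count, met$abbreviation)
  if (!product %in% names(cc)) stop("unknown product metabolite ", product)

  # the product's export pseudo-reaction: exchange touching the product
  rxn <- network$reactions
  is_export <- vapply(seq_len(nrow(rxn)), function(i) {
    st <- network$stoichiometry[[as.character(rxn$id[i])]]
    rxn$kind[i] == "exchange" && product %in% names(st)
  }, TRUE)
  if (!any(is_export)) stop("no export pseudo-reaction found for ", product)
  export_id <- as.character(rxn$id[which(is_export)[1]])

  src_carbon <- 0
  for (sid in as.character(sources)) {
    if (!sid %in% names(u)) stop("missing flux for source reaction ", sid)
    st <- network$stoichiometry[[sid]]
    sp <- setdiff(names(st), "external")
    flux <- u[[sid]]
    if (flux < 0) stop("source uptake flux must be non-negative (reaction ", sid, ")")
    src_carbon <- src_carbon + cc[[sp]] * flux
  }
  if (src_carbon == 0) stop("zero total source carbon")
  prod_carbon <- cc[[product]] * abs(u[[export_id]])
  eff <- 100 * prod_carbon / src_carbon
  structure(list(product = product,
                 product_carbon_flux = prod_carbon,
                 source_carbon_flux = src_carbon,
                 efficiency_percent = eff,
                 efficiency_reported = round_half_up(eff, digits),
                 rounding = sprintf("round-half-up to %d digit(s)", digits)),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> %s: %.4g C-flux out / %.4g C-flux in = %.2f%% (reported %g%%)\n",
              x$product, x$product_carbon_flux, x$source_carbon_flux,
              x$efficiency_percent, x$efficiency_reported))
  invisible(x)
}

#' Relative production enhancement between two flux solutions
#'
#' `100 * (|u_enhanced| - |u_base|) / |u_base|` at the product export
#' reaction. Scale-invariant: multiplying both solutions by a common factor
#' leaves the percentage unchanged.
#'
#' @param base,enhanced `flux_vector`s or named numerics.
#' @param product_export_id export pseudo-reaction id (default 1018, the
#'   xiamenmycin A export).
#' @return percent enhancement.
#' @export
production_enhancement <- function(base, enhanced, product_export_id = 1018) {
  ub <- as_flux_named(base); ue <- as_flux_named(enhanced)
  id <- as.character(product_export_id)
  if (!id %in% names(ub) || !id %in% names(ue)) {
    stop("both flux vectors must contain the export reaction ", id)
  }
  if (ub[[id]] == 0) stop("zero base production flux")
  100 * (abs(ue[[id]]) - abs(ub[[id]])) / abs(ub[[id]])
}

#' Per-reaction comparison of two conditions
#'
#' @param fluxes_a,fluxes_b `flux_vector`s over the same network.
#' @param highlight optional reaction ids to mark in the output.
#' @return data.frame `id`, `flux_a`, `flux_b`, `delta` (= b - a),
#'   `rel_delta`, `highlighted`.
#' @export
compare_conditions <- function(fluxes_a, fluxes_b, highlight = integer()) {
  ua <- as_flux_named(fluxes_a); ub <- as_flux_named(fluxes_b)
  if (!setequal(names(ua), names(ub))) stop("mismatched reaction sets")
  ids <- names(ua)
  delta <- ub[ids] - ua[ids]
  data.frame(id = ids,
             flux_a = as.numeric(ua[ids]),
             flux_b = as.numeric(ub[ids]),
             delta = as.numeric(delta),
             rel_delta = as.numeric(ifelse(ua[ids] == 0, NA, delta / abs(ua[ids]))),
             highlighted = ids %in% as.character(highlight),
             stringsAsFactors = FALSE)
}

#' Render a multi-condition flux table
#'
#' Writes the Table-style layout (id, equation, one flux column per
#' condition); the output round-trips through [parse_network()].
#'
#' @param network a `metabolic_network`.
#' @param fluxes named list of flux vectors, one per condition.
#' @param file optional output path.
#' @export
render_flux_table <- function(network, fluxes, file = NULL) {
  if (!length(fluxes)) stop("missing condition column: supply at least one flux vector")
  render_reactions_tsv(network, fluxes = fluxes, file = file)
}
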