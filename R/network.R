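#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

ARROWS <- c("<->", "->", "<-")

# Map typographic glyphs (arrows, unicode hyphens/minus, thin spaces) to ASCII
# so equations copied from typeset tables parse identically to the fixtures.
normalize_equation_text <- function(x) {
  x <- gsub("↔", "<->", x)
  x <- gsub("→", "->", x)
  x <- gsub("←", "<-", x)
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- gsub("[  ]", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

parse_side <- function(side, id) {
  terms <- strsplit(side, " \\+ ")[[1]]
  terms <- trimws(terms)
  if (length(terms) == 0L || any(!nzchar(terms))) {
    stop(sprintf("reaction %s: equation has an empty side", id), call. = FALSE)
  }
  coefs <- numeric(0)
  for (term in terms) {
    m <- regmatches(term, regexec("^([0-9]+) (.+)$", term))[[1]]
    if (length(m) == 3L) {
      k <- as.numeric(m[2]); sp <- m[3]
    } else {
      k <- 1; sp <- term
    }
    if (k <= 0) stop(sprintf("reaction %s: non-positive coefficient", id), call. = FALSE)
    coefs[sp] <- if (sp %in% names(coefs)) coefs[[sp]] + k else k
  }
  coefs
}

#' Parse a single reaction equation
#'
#' Equations follow the grammar `term (+ term)* arrow term (+ term)*` with
#' `term = [coefficient ]abbreviation`. All three arrow glyphs (`<->`, `->`,
#' `<-`, or their typeset equivalents) orient the equation left-to-right;
#' the glyph only sets the `reversible` flag. Net direction is carried by the
#' sign of the flux, so a `<-` reaction with a negative flux runs
#' right-to-left.
#'
#' @param equation character equation string.
#' @param id reaction identifier used in error messages.
#' @return list with `stoichiometry` (named numeric, substrates negative),
#'   `reversible`, and `arrow`.
#' @examples
#' parse_equation("PEP + CO2 <-> OAA + Pi", id = 3)$stoichiometry
#' @export
parse_equation <- function(equation, id = "?") {
  eq <- normalize_equation_text(equation)
  arrow <- NULL
  for (a in ARROWS) {
    pat <- paste0(" ", a, " ")
    if (grepl(pat, eq, fixed = TRUE)) { arrow <- a; break }
  }
  # sides may be empty around the arrow ("-> B"); catch before strsplit
  if (is.null(arrow)) {
    for (a in ARROWS) {
      if (grepl(a, eq, fixed = TRUE)) {
        arrow <- a
        break
      }
    }
    if (is.null(arrow)) {
      stop(sprintf("reaction %s: no arrow found in equation '%s'", id, equation),
           call. = FALSE)
    }
  }
  halves <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(halves) != 2L || !nzchar(trimws(halves[1])) || !nzchar(trimws(halves[2]))) {
    stop(sprintf("reaction %s: equation has an empty side", id), call. = FALSE)
  }
  lhs <- parse_side(trimws(halves[1]), id)
  rhs <- parse_side(trimws(halves[2]), id)
  stoich <- c(-lhs, rhs)
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- setNames(as.numeric(stoich), names(stoich))
  if (any(stoich == 0)) {
    stop(sprintf("reaction %s: species cancels to zero coefficient", id), call. = FALSE)
  }
  list(stoichiometry = stoich, reversible = arrow == "<->", arrow = arrow)
}

render_equation <- function(stoich, arrow) {
  fmt <- function(v) {
    paste(vapply(names(v), function(s) {
      k <- v[[s]]
      if (k == 1) s else paste(format(k, scientific = FALSE), s)
    }, ""), collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt(lhs), arrow, fmt(rhs))
}

#' Parse a metabolic network from metabolite and reaction tables
#'
#' @param metabolite_table path to (or literal content of) a tab-separated
#'   metabolite table with columns `id`, `abbreviation`, `name`,
#'   `carbon_count`, `biomass_glucose`, `biomass_glucose_glycerol`.
#' @param reaction_table path/content of a tab-separated reaction table with
#'   columns `id`, `equation`, `kind` and one `flux_*` column per condition.
#' @return object of class `metabolic_network`: the metabolite table, the
#'   reaction table (with parsed stoichiometries as a list column), and the
#'   stoichiometric matrix `S` over internal metabolites.
#' @export
parse_network <- function(metabolite_table, reaction_table) {
  read_tsv <- function(x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
      read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      read.delim(text = paste(x, collapse = "\n"), check.names = FALSE,
                 stringsAsFactors = FALSE)
    }
  }
  met <- read_tsv(metabolite_table)
  rxn <- read_tsv(reaction_table)

  need_m <- c("id", "abbreviation", "name", "carbon_count")
  if (!all(need_m %in% names(met))) {
    stop("metabolite table must have columns ", paste(need_m, collapse = ", "))
  }
  need_r <- c("id", "equation", "kind")
  if (!all(need_r %in% names(rxn))) {
    stop("reaction table must have columns ", paste(need_r, collapse = ", "))
  }
  met$abbreviation <- normalize_equation_text(met$abbreviation)
  if (anyDuplicated(met$id)) stop("duplicate metabolite id")
  if (anyDuplicated(met$abbreviation)) stop("duplicate metabolite abbreviation")
  if (any(met$carbon_count < 0)) stop("negative carbon count")
  met$is_external <- met$abbreviation == "external"
  if (sum(met$is_external) != 1L) {
    stop("exactly one metabolite must be the buffered 'external' pseudo-species")
  }
  if (anyDuplicated(rxn$id)) {
    stop(sprintf("duplicate reaction id %s",
                 rxn$id[duplicated(rxn$id)][1]))
  }
  if (!all(rxn$kind %in% c("internal", "maintenance", "exchange"))) {
    stop("reaction kind must be internal, maintenance or exchange")
  }

  parsed <- lapply(seq_len(nrow(rxn)), function(i) {
    parse_equation(rxn$equation[i], id = rxn$id[i])
  })
  known <- met$abbreviation
  for (i in seq_along(parsed)) {
    sp <- names(parsed[[i]]$stoichiometry)
    bad <- setdiff(sp, known)
    if (length(bad)) {
      stop(sprintf("reaction %s: unknown species token '%s'",
                   rxn$id[i], bad[1]), call. = FALSE)
    }
  }
  rxn$reversible <- vapply(parsed, `[[`, TRUE, "reversible")
  rxn$arrow <- vapply(parsed, `[[`, "", "arrow")
  stoich <- lapply(parsed, `[[`, "stoichiometry")
  names(stoich) <- as.character(rxn$id)

  net <- structure(
    list(metabolites = met, reactions = rxn, stoichiometry = stoich),
    class = "metabolic_network"
  )
  net$S <- build_stoichiometric_matrix(net)
  net
}

#' Build the stoichiometric matrix
#'
#' Rows are internal metabolites in table order (the buffered external
#' pseudo-species is excluded); columns are reactions in table order. Entries
#' are the signed stoichiometric coefficients.
#'
#' @param network a `metabolic_network`.
#' @return numeric matrix with metabolite abbreviations as rownames and
#'   reaction ids as colnames.
#' @export
build_stoichiometric_matrix <- function(network) {
  met <- network$metabolites
  internal <- met$abbreviation[!met$is_external]
  rids <- as.character(network$reactions$id)
  S <- matrix(0, nrow = length(internal), ncol = length(rids),
              dimnames = list(internal, rids))
  for (j in seq_along(rids)) {
    v <- network$stoichiometry[[rids[j]]]
    v <- v[names(v) %in% internal]
    S[names(v), j] <- v
  }
  if (any(colSums(abs(S)) == 0)) stop("stoichiometric matrix has an all-zero column")
  S
}

#' Mass-balance residuals of a flux vector
#'
#' Computes `r_m = sum_r S[m, r] * u[r] (+ supply_m)` for every internal
#' metabolite: the net production rate implied by the fluxes. At a steady
#' state consistent with the boundary drains all residuals vanish. The
#' optional `supply` term carries biomass inputs that are not represented by
#' boundary pseudo-reactions (for the packaged model: CoA, NH4 and Pi).
#'
#' @param network a `metabolic_network`.
#' @param fluxes named numeric vector of fluxes covering every reaction
#'   (names are reaction ids), or a `flux_vector`.
#' @param supply optional named numeric of constant production terms per
#'   metabolite abbreviation (a `condition$supply`).
#' @return named numeric vector of residuals over internal metabolites.
#' @export
mass_balance_residuals <- function(network, fluxes, supply = NULL) {
  S <- network$S
  u <- as_flux_named(fluxes)
  missing <- setdiff(colnames(S), names(u))
  if (length(missing)) {
    stop(sprintf("missing flux entry for reaction %s", missing[1]), call. = FALSE)
  }
  r <- drop(S %*% u[colnames(S)])
  if (!is.null(supply) && length(supply)) {
    sp <- intersect(names(supply), names(r))
    r[sp] <- r[sp] + supply[sp]
  }
  r
}

as_flux_named <- function(fluxes) {
  if (inherits(fluxes, "flux_vector")) return(fluxes$values)
  if (is.data.frame(fluxes)) return(setNames(fluxes$flux, as.character(fluxes$id)))
  if (is.null(names(fluxes))) stop("fluxes must be named by reaction id")
  fluxes
}

#' Construct a flux vector
#'
#' @param values named numeric, one entry per reaction id of the network.
#' @param condition optional condition name the fluxes belong to.
#' @param network optional network to validate coverage against.
#' @export
flux_vector <- function(values, condition = NULL, network = NULL) {
  if (!is.null(network)) {
    rids <- as.character(network$reactions$id)
    if (!setequal(names(values), rids)) {
      stop("flux vector must cover every reaction id exactly once")
    }
    values <- values[rids]
  }
  structure(list(values = values, condition = condition), class = "flux_vector")
}

#' Printed steady-state fluxes of the packaged model
#'
#' Returns the flux column transcribed from the published table for one
#' feeding condition as a `flux_vector`.
#'
#' @param network packaged `metabolic_network` (must retain `flux_*` columns).
#' @param condition `"glucose"` or `"glucose_glycerol"`.
#' @export
printed_fluxes <- function(network, condition = c("glucose", "glucose_glycerol")) {
  condition <- match.arg(condition)
  col <- paste0("flux_", condition)
  if (!col %in% names(network$reactions)) {
    stop("network has no printed flux column for condition ", condition)
  }
  flux_vector(setNames(network$reactions[[col]], as.character(network$reactions$id)),
              condition = condition, network = network)
}

#' Define a feeding condition
#'
#' A condition pins a subset of boundary pseudo-reactions to fixed fluxes
#' (growth-precursor drains, maintenance, nutrient imports with known rates)
#' and leaves the remaining boundary reactions free (uptakes and overflow
#' exports the model must predict). `supply` holds constant biomass inputs of
#' metabolites that have no pseudo-reaction of their own.
#'
#' @param name condition name.
#' @param pinned named numeric: boundary reaction id -> fixed flux.
#' @param free_ids character/numeric ids of unpinned boundary reactions.
#' @param supply named numeric: metabolite abbreviation -> constant input.
#' @export
condition <- function(name, pinned, free_ids = character(), supply = numeric()) {
  structure(list(name = name,
                 pinned = setNames(as.numeric(pinned), names(pinned)),
                 free_ids = as.character(free_ids),
                 supply = supply),
            class = "ximflux_condition")
}

# boundary ids left free per condition: nutrient uptakes and overflow exports
FREE_BOUNDARY <- list(
  glucose = c("1004", "1017", "1019"),
  glucose_glycerol = c("1004", "1017", "1019", "1021")
)

build_condition <- function(network, name) {
  rxn <- network$reactions
  boundary <- rxn$kind %in% c("maintenance", "exchange")
  col <- paste0("flux_", name)
  free <- FREE_BOUNDARY[[name]]
  pin_ids <- setdiff(as.character(rxn$id[boundary]), free)
  pinned <- setNames(rxn[[col]][match(pin_ids, as.character(rxn$id))], pin_ids)

  # Biomass entries without a boundary pseudo-reaction of their own become
  # constant supply terms. Exchange reactions cover their non-external
  # species outright (the pseudo-reaction flux is authoritative even where
  # the biomass sign disagrees, e.g. the Glu import). A maintenance reaction
  # covers a species only where its contribution at the printed flux equals
  # the biomass entry, so the Pi byproduct of ATP turnover is not mistaken
  # for the separate phosphate biomass demand.
  met <- network$metabolites
  covered <- character()
  for (i in which(boundary)) {
    st <- network$stoichiometry[[as.character(rxn$id[i])]]
    sp <- names(st)
    if (rxn$kind[i] == "exchange") {
      covered <- c(covered, setdiff(sp, "external"))
    } else {
      contrib <- st * rxn[[col]][i]
      b <- met[[paste0("biomass_", name)]][match(sp, met$abbreviation)]
      covered <- c(covered, sp[abs(contrib - b) < 1e-9])
    }
  }
  bcol <- paste0("biomass_", name)
  has_b <- !met$is_external & met[[bcol]] != 0
  supply_met <- met$abbreviation[has_b & !(met$abbreviation %in% covered)]
  supply <- setNames(met[[bcol]][match(supply_met, met$abbreviation)], supply_met)
  condition(name, pinned, free, supply)
}

#' Load the packaged xiamenmycin network model
#'
#' Returns the full transcribed model (86 internal metabolites, 82 internal
#' reactions, 3 maintenance and 19 exchange pseudo-reactions) together with
#' both feeding conditions.
#'
#' Reaction 65 as printed (`OAA + NH4 + Succ <-> Asp + Fum`) breaks mass
#' balance at five nodes of the printed flux columns; the aspartate
#' aminotransferase form (`OAA + Glu <-> Asp + a-KG`) restores balance and is
#' the default. The printed form is retained under `variant = "as_printed"`
#' for transcription auditing.
#'
#' @param variant `"corrected_r65"` (default) or `"as_printed"`.
#' @return list with elements `network` and `conditions` (a list with entries
#'   `glucose` and `glucose_glycerol`).
#' @export
load_packaged_model <- function(variant = c("corrected_r65", "as_printed")) {
  variant <- match.arg(variant)
  mfile <- system.file("extdata", "metabolites.tsv", package = "ximflux")
  rfile <- system.file("extdata", "reactions.tsv", package = "ximflux")
  rxn <- read.delim(rfile, check.names = FALSE, stringsAsFactors = FALSE)
  if (variant == "corrected_r65") {
    rxn$equation[rxn$id == 65] <- "OAA + Glu <-> Asp + a-KG"
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(rxn, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  net <- parse_network(mfile, tmp)
  net$variant <- variant
  list(network = net,
       conditions = list(
         glucose = build_condition(net, "glucose"),
         glucose_glycerol = build_condition(net, "glucose_glycerol")
       ))
}

#' Carbon balance of every reaction
#'
#' `imbalance_r = sum_m carbon(m) * S[m, r]` over internal metabolites.
#' Internal and maintenance reactions must balance; exchange reactions move
#' carbon to the zero-carbon external pseudo-species and are imbalanced by
#' construction.
#'
#' @param network a `metabolic_network`.
#' @param nonzero_only if `TRUE` (default) only reactions with a nonzero
#'   imbalance are listed.
#' @return data.frame with columns `id`, `kind`, `imbalance`.
#' @export
carbon_balance_report <- function(network, nonzero_only = TRUE) {
  met <- network$metabolites
  cc <- setNames(met$carbon_count, met$abbreviation)
  w <- cc[rownames(network$S)]
  imb <- drop(t(network$S) %*% w)
  out <- data.frame(id = network$reactions$id,
                    kind = network$reactions$kind,
                    imbalance = as.numeric(imb))
  if (nonzero_only) out <- out[abs(out$imbalance) > 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structurally forced fluxes under pinned boundary drains
#'
#' Solves the steady-state mass balance `S u + supply = 0` with the
#' condition's boundary coordinates pinned, then classifies every free
#' coordinate: a flux is *forced* when it is constant over the entire affine
#' solution set, i.e. the corresponding rows of a nullspace basis of the free
#' columns are numerically zero. Forced fluxes are kinetics-independent
#' consequences of the network structure and the drains alone.
#'
#' @param network a `metabolic_network`.
#' @param condition a `ximflux_condition`.
#' @param tol absolute nullspace-entry tolerance on unit-norm basis vectors.
#' @param feas_tol least-squares residual above which the pinned system is
#'   reported infeasible. The default allows for the 5-decimal rounding of
#'   published flux tables.
#' @return data.frame with columns `id`, `flux`, `status` in
#'   `c("pinned", "forced", "free")`; `flux` is `NA` for free coordinates.
#' @export
forced_fluxes <- function(network, condition, tol = 1e-9, feas_tol = 1e-4) {
  S <- network$S
  rids <- colnames(S)
  pin <- condition$pinned
  if (!all(names(pin) %in% rids)) stop("pinned reaction id not in network")
  free <- setdiff(rids, names(pin))
  rhs <- -drop(S[, names(pin), drop = FALSE] %*% pin)
  if (length(condition$supply)) {
    sp <- intersect(names(condition$supply), rownames(S))
    rhs[sp] <- rhs[sp] - condition$supply[sp]
  }
  A <- S[, free, drop = FALSE]
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  d <- sv$d
  rtol <- max(dim(A)) * max(d) * .Machine$double.eps
  r <- sum(d > rtol)
  dinv <- c(1 / d[seq_len(r)], rep(0, length(d) - r))
  x <- sv$v[, seq_len(r), drop = FALSE] %*%
    (dinv[seq_len(r)] * (t(sv$u[, seq_len(r), drop = FALSE]) %*% rhs))
  x <- drop(x)
  resid <- max(abs(A %*% x - rhs))
  if (resid > feas_tol) {
    stop(sprintf("pinned boundary system is infeasible (least-squares residual %.3g)",
                 resid), call. = FALSE)
  }
  if (r < ncol(A)) {
    N <- sv$v[, (r + 1):ncol(A), drop = FALSE]  # columns are unit-norm
    forced <- apply(abs(N), 1, max) < tol
  } else {
    forced <- rep(TRUE, ncol(A))
  }
  out <- data.frame(id = rids,
                    flux = NA_real_,
                    status = "free",
                    stringsAsFactors = FALSE)
  out$flux[match(names(pin), rids)] <- pin
  out$status[match(names(pin), rids)] <- "pinned"
  idx <- match(free, rids)
  out$flux[idx[forced]] <- x[forced]
  out$status[idx[forced]] <- "forced"
  rownames(out) <- NULL
  # expose the solution-set geometry so callers can test linear combinations
  # (e.g. a two-reaction cycle whose difference is forced)
  if (r < ncol(A)) {
    N <- sv$v[, (r + 1):ncol(A), drop = FALSE]
    rownames(N) <- free
  } else {
    N <- matrix(0, nrow = ncol(A), ncol = 0, dimnames = list(free, NULL))
  }
  attr(out, "nullspace") <- N
  attr(out, "particular") <- setNames(x, free)
  out
}

#' Render a network back to the reaction-table format
#'
#' @param network a `metabolic_network`.
#' @param fluxes optional named list of `flux_vector`s / named numerics, one
#'   per condition column to append.
#' @param file optional path; if `NULL` the TSV is returned as a character
#'   vector of lines.
#' @export
render_reactions_tsv <- function(network, fluxes = NULL, file = NULL) {
  rxn <- network$reactions
  df <- data.frame(id = rxn$id,
                   equation = vapply(seq_len(nrow(rxn)), function(i) {
                     render_equation(network$stoichiometry[[as.character(rxn$id[i])]],
                                     rxn$arrow[i])
                   }, ""),
                   kind = rxn$kind,
                   stringsAsFactors = FALSE)
  if (!is.null(fluxes)) {
    if (is.null(names(fluxes)) || any(!nzchar(names(fluxes)))) {
      stop("fluxes must be a named list (one name per condition column)")
    }
    for (nm in names(fluxes)) {
      u <- as_flux_named(fluxes[[nm]])
      if (!all(as.character(df$id) %in% names(u))) {
        stop("missing condition column entries for ", nm)
      }
      df[[paste0("flux_", nm)]] <- u[as.character(df$id)]
    }
  }
  if (is.null(file)) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(row) paste(trimws(row), collapse = "\t")))
  } else {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
  }
}

render_metabolites_tsv <- function(network, file = NULL) {
  met <- network$metabolites
  df <- met[, c("id", "abbreviation", "name", "carbon_count",
                intersect(c("biomass_glucose", "biomass_glucose_glycerol"),
                          names(met)))]
  if (is.null(file)) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(row) paste(trimws(row), collapse = "\t")))
  } else {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
  }
}

#' @export
print.metabolic_network <- function(x, ...) {
  met <- x$metabolites
  rxn <- x$reactions
  cat(sprintf("<metabolic_network> %d internal metabolites, %d reactions (%d internal, %d boundary)\n",
              sum(!met$is_external), nrow(rxn),
              sum(rxn$kind == "internal"), sum(rxn$kind != "internal")))
  if (!is.null(x$variant)) cat("  variant:", x$variant, "\n")
  invisible(x)
}

#' @export
print.ximflux_condition <- function(x, ...) {
  cat(sprintf("<condition> %s: %d pinned boundary fluxes, %d free (%s), %d supply terms\n",
              x$name, length(x$pinned), length(x$free_ids),
              paste(x$free_ids, collapse = ", "), length(x$supply)))
  invisible(x)
}
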