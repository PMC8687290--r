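#' Validate a transcribed model
#'
#' Runs the three transcription audits: equation parsing, carbon balance of
#' internal and maintenance reactions, and mass balance of the printed flux
#' columns under both conditions (including the condition supply terms).
#'
#' @param variant packaged model variant, or `NULL` when `metabolite_table` /
#'   `reaction_table` are given.
#' @param metabolite_table,reaction_table optional external model files.
#' @param residual_tol maximum acceptable per-metabolite residual.
#' @return list of class `validation_report`: `status` (0 = pass, 1 =
#'   balance failure, 2 = parse/read failure), `residuals` per condition,
#'   `flagged` metabolites above tolerance, `carbon` report.
#' @export
validate_model <- function(variant = c("corrected_r65", "as_printed"),
                           metabolite_table = NULL, reaction_table = NULL,
                           residual_tol = 1e-3) {
  loaded <- tryCatch({
    if (!is.null(metabolite_table) || !is.null(reaction_table)) {
      if (!file.exists(metabolite_table) || !file.exists(reaction_table)) {
        stop("model file not found")
      }
      net <- parse_network(metabolite_table, reaction_table)
      conds <- list()
      for (nm in c("glucose", "glucose_glycerol")) {
        if (paste0("flux_", nm) %in% names(net$reactions)) {
          conds[[nm]] <- build_condition(net, nm)
        }
      }
      list(network = net, conditions = conds)
    } else {
      load_packaged_model(match.arg(variant))
    }
  }, error = function(e) e)
  if (inherits(loaded, "error")) {
    return(structure(list(status = 2L, message = conditionMessage(loaded),
                          residuals = NULL, flagged = NULL, carbon = NULL),
                     class = "validation_report"))
  }
  net <- loaded$network
  carbon <- carbon_balance_report(net)
  carbon_bad <- carbon[carbon$kind != "exchange", , drop = FALSE]
  residuals <- list()
  flagged <- list()
  for (nm in names(loaded$conditions)) {
    u <- printed_fluxes(net, nm)
    r <- mass_balance_residuals(net, u, supply = loaded$conditions[[nm]]$supply)
    residuals[[nm]] <- r
    flagged[[nm]] <- sort(r[abs(r) > residual_tol], decreasing = TRUE)
  }
  ok <- nrow(carbon_bad) == 0 && all(vapply(flagged, length, 1L) == 0)
  structure(list(status = if (ok) 0L else 1L,
                 message = if (ok) "model valid" else "balance check failed",
                 residuals = residuals, flagged = flagged,
                 carbon = carbon_bad),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> status %d: %s\n", x$status, x$message))
  for (nm in names(x$flagged)) {
    fl <- x$flagged[[nm]]
    if (length(fl)) {
      cat(sprintf("  %s imbalanced nodes: %s\n", nm,
                  paste(sprintf("%s (%.3g)", names(fl), fl), collapse = ", ")))
    } else {
      cat(sprintf("  %s: max |residual| = %.3g\n", nm,
                  max(abs(x$residuals[[nm]]))))
    }
  }
  invisible(x)
}

#' Run the two-condition analysis pipeline
#'
#' For each requested condition: stabilise the kinetic model (or take the
#' printed flux column when `use_printed_fluxes = TRUE`), render the flux
#' table, cross-check the kinetic solution against the structurally forced
#' fluxes, and compute the carbon-efficiency report. With two conditions the
#' per-reaction comparison and the product-export enhancement are added.
#' All numeric outputs are written as TSV/JSON under `out_dir` together with
#' a JSON run manifest.
#'
#' @param variant packaged model variant.
#' @param conditions condition names to run.
#' @param config a [regulation_config()] for the stabilisation stage. The
#'   default uses the quasi-static regulation mode, which converges fastest
#'   on the packaged network.
#' @param use_printed_fluxes skip stabilisation and analyse the transcribed
#'   steady-state flux columns.
#' @param out_dir output directory (created); `NULL` for no files.
#' @param seed integer seed recorded in the manifest and passed to the
#'   stabiliser.
#' @return list of class `pipeline_result` with per-condition results,
#'   `comparison`, `enhancement_percent`, and `manifest`.
#' @export
run_pipeline <- function(variant = "corrected_r65",
                         conditions = c("glucose", "glucose_glycerol"),
                         config = regulation_config(mode = "quasistatic",
                                                    atol_steady = 1e-4),
                         use_printed_fluxes = FALSE,
                         out_dir = NULL, seed = 1L) {
  model_bundle <- load_packaged_model(variant)
  net <- model_bundle$network
  config$seed <- as.integer(seed)
  runs <- list()
  for (nm in conditions) {
    cond <- model_bundle$conditions[[nm]]
    if (is.null(cond)) stop("unknown condition ", nm)
    if (use_printed_fluxes) {
      fl <- printed_fluxes(net, nm)
      stab <- NULL
    } else {
      km <- kinetic_model(net, cond)
      stab <- stabilize(km, config)
      fl <- stab$fluxes
    }
    ff <- forced_fluxes(net, cond)
    forced <- ff[ff$status == "forced", , drop = FALSE]
    u <- as_flux_named(fl)
    forced$kinetic <- u[as.character(forced$id)]
    forced$deviation <- forced$kinetic - forced$flux
    eff <- carbon_efficiency(fl, net)
    runs[[nm]] <- list(condition = cond, fluxes = fl, stabilization = stab,
                       forced_check = forced, efficiency = eff)
  }
  comparison <- NULL
  enhancement <- NULL
  if (length(runs) >= 2) {
    a <- runs[[1]]; b <- runs[[2]]
    comparison <- compare_conditions(a$fluxes, b$fluxes,
                                     highlight = c(2, 50, 1018))
    enhancement <- production_enhancement(a$fluxes, b$fluxes)
  } else {
    message("single condition: comparison stage skipped")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ximflux")),
    variant = variant,
    conditions = conditions,
    seed = as.integer(seed),
    use_printed_fluxes = use_printed_fluxes,
    converged = vapply(runs, function(r) {
      if (is.null(r$stabilization)) NA else r$stabilization$converged
    }, NA),
    efficiency_percent = vapply(runs, function(r) r$efficiency$efficiency_percent, 0),
    enhancement_percent = if (is.null(enhancement)) NULL else enhancement,
    flux_hash = vapply(runs, function(r) {
      paste(format(round(unname(as_flux_named(r$fluxes)), 10), trim = TRUE),
            collapse = ",")
    }, "")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    render_flux_table(net, fluxes = lapply(runs, `[[`, "fluxes"),
                      file = file.path(out_dir, "flux_table.tsv"))
    for (nm in names(runs)) {
      utils::write.table(runs[[nm]]$forced_check,
                         file.path(out_dir, paste0("forced_check_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(runs[[nm]]$stabilization)) {
        utils::write.table(runs[[nm]]$stabilization$psi_trace,
                           file.path(out_dir, paste0("psi_trace_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(comparison)) {
      utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(runs = runs, comparison = comparison,
                 enhancement_percent = enhancement, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    cat(sprintf("  %s: efficiency %.2f%% (reported %g%%), max forced-flux deviation %.3g\n",
                nm, r$efficiency$efficiency_percent,
                r$efficiency$efficiency_reported,
                if (nrow(r$forced_check)) max(abs(r$forced_check$deviation)) else 0))
  }
  if (!is.null(x$enhancement_percent)) {
    cat(sprintf("  product-export enhancement: %+.1f%%\n", x$enhancement_percent))
  }
  invisible(x)
}
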