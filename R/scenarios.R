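## Trophic-condition scenarios and the hydrogen-production studies.

#' Define a simulation scenario
#'
#' The machine form of a trophic growth condition: exchange bound
#' overrides, a fixed growth rate, the substrate to minimize and the
#' product to maximize.
#'
#' @param condition `"autotrophic"`, `"heterotrophic"` or `"mixotrophic"`.
#' @param bound_overrides named list of `c(lower, upper)` reaction bound
#'   overrides.
#' @param fixed_growth_rate growth rate (h^-1) imposed as an equality.
#' @param substrate exchange reaction whose uptake optimization 1
#'   minimizes.
#' @param product exchange reaction optimization 2 maximizes.
#' @return an object of class `phyco_scenario`.
#' @export
scenario <- function(condition, bound_overrides = list(),
                     fixed_growth_rate = 0, substrate = NULL,
                     product = NULL) {
  condition <- match.arg(condition,
                         c("autotrophic", "heterotrophic", "mixotrophic"))
  stopifnot(fixed_growth_rate >= 0)
  for (b in bound_overrides)
    if (b[1] > b[2]) stop("override lower bound exceeds upper", call. = FALSE)
  structure(list(condition = condition, bound_overrides = bound_overrides,
                 fixed_growth_rate = fixed_growth_rate,
                 substrate = substrate, product = product),
            class = "phyco_scenario")
}

#' @export
print.phyco_scenario <- function(x, ...) {
  cat("Scenario:", x$condition, "\n")
  cat("  growth rate (fixed):", x$fixed_growth_rate, "h^-1\n")
  cat("  minimize substrate: ", x$substrate,
      " | maximize product: ", x$product, "\n", sep = "")
  if (length(x$bound_overrides)) {
    cat("  bound overrides:\n")
    for (id in names(x$bound_overrides))
      cat(sprintf("    %-12s [%g, %g]\n", id,
                  x$bound_overrides[[id]][1], x$bound_overrides[[id]][2]))
  }
  invisible(x)
}

## Minimal constraint sets for the three growth conditions. "+" opens an
## uptake, "-" closes it (secretion of CO2 stays open under heterotrophic
## growth: respiration must vent CO2). Photon uptake is "free" up to the
## constant-illumination cap built into the exchange; under mixotrophic
## growth the wild type additionally routes a fixed share of PSI flux
## through cyclic electron flow (the state-transition allocation that the
## Stm6-like knockout abolishes).
TROPHIC_PRESETS <- list(
  autotrophic = list(
    growth = 0.059, substrate = "EX_photon",
    overrides = list(EX_co2 = c(-10, FLUX_BOUND), EX_ac = c(0, FLUX_BOUND),
                     EX_photon = c(-200, 0))),
  heterotrophic = list(
    growth = 0.035, substrate = "EX_ac",
    ## dark: no photons, and the light-activated RuBisCO reactions are off
    overrides = list(EX_co2 = c(0, FLUX_BOUND), EX_ac = c(-10, FLUX_BOUND),
                     EX_photon = c(0, 0), rbc_c = c(0, 0), rbc_o = c(0, 0))),
  mixotrophic = list(
    growth = 0.066, substrate = "EX_photon",
    overrides = list(EX_co2 = c(-10, FLUX_BOUND), EX_ac = c(-10, FLUX_BOUND),
                     EX_photon = c(-200, 0), cef = c(2, FLUX_BOUND)))
)

#' Preset scenario for a trophic condition
#'
#' @param condition `"autotrophic"`, `"heterotrophic"` or `"mixotrophic"`
#'   (prefixes accepted).
#' @return a [scenario()] reproducing the minimal constraint set of the
#'   condition: carbon source switches, photon availability, the substrate
#'   minimized under optimization 1, H2 as the optimization-2 product, and
#'   the condition's fixed growth rate (0.059, 0.035 and 0.066 h^-1).
#' @export
trophic_scenario <- function(condition = c("autotrophic", "heterotrophic",
                                           "mixotrophic")) {
  condition <- match.arg(condition)
  ps <- TROPHIC_PRESETS[[condition]]
  scenario(condition, bound_overrides = ps$overrides,
           fixed_growth_rate = ps$growth, substrate = ps$substrate,
           product = "EX_h2")
}

#' Apply a trophic condition to a model
#'
#' Writes the scenario's exchange bounds onto the model and fixes the
#' growth flux to the condition's rate. Overrides that name reactions the
#' model does not carry are dropped when they are non-exchange extras
#' (e.g. the wild-type cyclic-flow floor on a model built without cyclic
#' electron flow); a missing exchange reaction is a configuration error.
#'
#' @param model a `phyco_model` with a combined biomass equation.
#' @param condition condition name or a [scenario()].
#' @return list with the constrained `model` and the `scenario`.
#' @export
apply_condition <- function(model, condition) {
  sc <- if (inherits(condition, "phyco_scenario")) condition
  else trophic_scenario(condition)
  sc$bound_overrides <- prune_overrides(model, sc$bound_overrides)
  for (id in names(sc$bound_overrides)) {
    model$reactions[[id]]$lb <- sc$bound_overrides[[id]][1]
    model$reactions[[id]]$ub <- sc$bound_overrides[[id]][2]
    if (sc$bound_overrides[[id]][1] < 0)
      model$reactions[[id]]$reversible <- TRUE
  }
  if (!is.null(model$biomass_reaction)) {
    model$reactions[[model$biomass_reaction]]$lb <- sc$fixed_growth_rate
    model$reactions[[model$biomass_reaction]]$ub <- sc$fixed_growth_rate
  }
  list(model = model, scenario = sc)
}

prune_overrides <- function(model, overrides) {
  present <- names(overrides) %in% names(model$reactions)
  missing <- names(overrides)[!present]
  ex_missing <- missing[startsWith(missing, "EX_")]
  if (length(ex_missing))
    stop("model lacks exchange reaction(s) required by the condition: ",
         paste(ex_missing, collapse = ", "), call. = FALSE)
  overrides[present]
}

#' Classify flux changes between two distributions
#'
#' A reaction is `increased` when its absolute test flux exceeds the
#' reference by more than the threshold fraction (reference fluxes below
#' the absolute floor are compared against the floor), `decreased`
#' symmetrically, `unchanged` otherwise.
#'
#' @param reference,test `flux_distribution` objects over the same
#'   reaction set.
#' @param threshold relative change classifying increase/decrease
#'   (default 0.20, i.e. more than 20 percent).
#' @param floor absolute flux floor standing in for a zero reference.
#' @return a `data.frame` (class `flux_comparison`) with reference flux,
#'   test flux and class per reaction; `threshold` kept as an attribute.
#' @export
compare_fluxes <- function(reference, test, threshold = 0.20, floor = 1e-6) {
  rv <- reference$fluxes; tv <- test$fluxes
  if (is.null(rv) || is.null(tv))
    stop("both distributions must carry flux vectors", call. = FALSE)
  if (!setequal(names(rv), names(tv)))
    stop("reaction sets differ: ",
         paste(c(setdiff(names(rv), names(tv)),
                 setdiff(names(tv), names(rv))), collapse = ", "),
         call. = FALSE)
  tv <- tv[names(rv)]
  ref_eff <- pmax(abs(rv), floor)
  cls <- ifelse(abs(tv) > (1 + threshold) * ref_eff, "increased",
                ifelse(abs(tv) < (1 - threshold) * abs(rv), "decreased",
                       "unchanged"))
  out <- data.frame(reaction = names(rv), reference = unname(rv),
                    test = unname(tv), class = unname(cls),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("flux_comparison", "data.frame")
  out
}

#' @export
print.flux_comparison <- function(x, ...) {
  counts <- table(factor(x$class, c("increased", "decreased", "unchanged")))
  cat("Flux comparison (threshold ", attr(x, "threshold") * 100, "%): ",
      counts[["increased"]], " increased, ", counts[["decreased"]],
      " decreased, ", counts[["unchanged"]], " unchanged\n", sep = "")
  invisible(x)
}

#' Summarize a flux comparison by pathway
#'
#' Aggregates total absolute flux per subsystem tag and reports the
#' direction of change, mirroring an up/down regulation table.
#'
#' @param comparison a [compare_fluxes()] result.
#' @param model the model the fluxes were computed on (for subsystem tags).
#' @param threshold direction threshold on the summed pathway flux.
#' @return `data.frame` with pathway, reference and test total flux and
#'   `direction` (`"+"`, `"-"`, `"0"`).
#' @export
pathway_directions <- function(comparison, model, threshold = 0.20) {
  ss <- vapply(model$reactions[comparison$reaction], `[[`, "", "subsystem")
  ss[!nzchar(ss)] <- "(untagged)"
  ref <- tapply(abs(comparison$reference), ss, sum)
  tst <- tapply(abs(comparison$test), ss, sum)
  floor <- 1e-6
  dir <- ifelse(pmax(ref, tst) < floor, "0",
                ifelse(tst > (1 + threshold) * pmax(ref, floor), "+",
                       ifelse(tst < (1 - threshold) * ref & ref > floor,
                              "-", "0")))
  out <- data.frame(pathway = names(ref), reference = as.numeric(ref),
                    test = as.numeric(tst), direction = as.character(dir),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$pathway), ]
}

#' Hydrogen-production study under a trophic condition
#'
#' Compares two optimality criteria: minimum energy-substrate usage at the
#' condition's growth rate (the wild type) against maximization of H2
#' secretion (the hypothetical H2 producer), optionally after knocking out
#' reactions (e.g. cyclic electron flow, the in-silico analogue of a
#' state-transition mutant). Knockouts win over any scenario bound floor
#' on the same reaction.
#'
#' @param model a `phyco_model` with a combined biomass equation.
#' @param condition condition name or [scenario()].
#' @param knockouts reaction ids to disable in the knockout arm.
#' @param product product exchange id (default `"EX_h2"`).
#' @param fix_substrate passed to [maximize_product()].
#' @return an `h2_study` object: wild-type distribution, baseline and
#'   knockout H2 maxima, fold change, flux comparison (H2 producer vs
#'   wild type) and the per-pathway direction table.
#' @export
h2_study <- function(model, condition, knockouts = character(),
                     product = "EX_h2",
                     fix_substrate = c("none", "optimum")) {
  fix_substrate <- match.arg(fix_substrate)
  sc <- if (inherits(condition, "phyco_scenario")) condition
  else trophic_scenario(condition)
  sc$bound_overrides <- prune_overrides(model, sc$bound_overrides)
  if (!product %in% names(model$reactions))
    stop("model lacks product exchange '", product, "'", call. = FALSE)
  wild <- minimize_substrate(model, sc)
  baseline <- maximize_product(model, sc, product,
                               fix_substrate = fix_substrate)
  sc_ko <- sc
  sc_ko$bound_overrides <-
    sc$bound_overrides[setdiff(names(sc$bound_overrides), knockouts)]
  ko_model <- if (length(knockouts)) knockout(model, knockouts) else model
  ko <- maximize_product(ko_model, sc_ko, product,
                         fix_substrate = fix_substrate)
  b <- baseline$objective_value; k <- ko$objective_value
  fold <- if (is.na(b) || is.na(k)) NA_real_
  else if (abs(b) <= FEAS_TOL && abs(k) <= FEAS_TOL) 1
  else if (abs(b) <= FEAS_TOL) Inf
  else k / b
  cmp <- if (wild$status == "optimal" && ko$status == "optimal")
    compare_fluxes(wild, ko) else NULL
  structure(list(
    condition = sc$condition, knockouts = knockouts,
    wild_type = wild, baseline = baseline, knockout = ko,
    baseline_h2 = b, knockout_h2 = k, fold_change = fold,
    comparison = cmp,
    directions = if (!is.null(cmp)) pathway_directions(cmp, model) else NULL
  ), class = "h2_study")
}

#' @export
print.h2_study <- function(x, ...) {
  cat("H2 production study (", x$condition, ")\n", sep = "")
  cat("  wild-type substrate uptake:",
      format(x$wild_type$substrate_uptake, digits = 5), "\n")
  cat("  max H2, baseline:", format(x$baseline_h2, digits = 5),
      "| with knockout of", if (length(x$knockouts))
        paste(x$knockouts, collapse = ", ") else "(none)", ":",
      format(x$knockout_h2, digits = 5), "\n")
  cat("  fold change:", format(x$fold_change, digits = 4), "\n")
  if (!is.null(x$directions)) {
    cat("  pathway directions (H2 producer vs wild type):\n")
    d <- x$directions[x$directions$direction != "0", ]
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-34s %s\n", d$pathway[i], d$direction[i]))
  }
  invisible(x)
}

#' Write an H2 study report
#' @param study an [h2_study()] result.
#' @param path JSON output file.
#' @return `path`, invisibly.
#' @export
write_h2_report <- function(study, path) {
  payload <- list(
    condition = study$condition, knockouts = study$knockouts,
    wild_type_substrate_uptake = study$wild_type$substrate_uptake,
    baseline_h2 = study$baseline_h2, knockout_h2 = study$knockout_h2,
    fold_change = study$fold_change,
    directions = study$directions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read or write scenario files
#'
#' Scenarios serialize to YAML (or JSON) with fields `condition`,
#' `bound_overrides`, `fixed_growth_rate`, `substrate`, `product`.
#'
#' @param path file path (`.yml`/`.yaml` or `.json`).
#' @return [scenario()] for `read_scenario`; `path` for `write_scenario`.
#' @export
read_scenario <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  scenario(obj$condition,
           bound_overrides = lapply(obj$bound_overrides, as.numeric),
           fixed_growth_rate = obj$fixed_growth_rate,
           substrate = obj$substrate, product = obj$product)
}

#' @rdname read_scenario
#' @param sc a [scenario()] to serialize.
#' @export
write_scenario <- function(sc, path) {
  obj <- unclass(sc)
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(obj, path)
  invisible(path)
}
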