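## Linear-programming core: steady-state flux balance analysis, built on
## the bounded-variable revised simplex in simplex.R.

## box standing in for infinite bounds; a solution pinned to it under an
## infinite declared bound is reported as unbounded
BIG_BOX <- 1e6
FEAS_TOL <- 1e-6     # reported feasibility / producibility tolerance

## Solve max/min obj.v subject to S v = 0, lb <= v <= ub.
## Returns list(v, value, status) with status in optimal/infeasible/unbounded.
lp_fba <- function(S, lb, ub, obj, maximize = TRUE) {
  inf_lo <- !is.finite(lb); inf_hi <- !is.finite(ub)
  lb[inf_lo] <- -BIG_BOX; ub[inf_hi] <- BIG_BOX
  res <- simplex_box(S, rep(0, nrow(S)), lb, ub, obj, maximize = maximize)
  if (!identical(res$status, "optimal"))
    return(list(v = NULL, value = NA_real_,
                status = if (identical(res$status, "infeasible"))
                  "infeasible" else res$status))
  v <- res$x
  names(v) <- colnames(S)
  at_box <- (inf_lo & v < -BIG_BOX * 0.999) | (inf_hi & v > BIG_BOX * 0.999)
  status <- if (any(at_box & obj != 0)) "unbounded" else "optimal"
  list(v = v, value = res$value, status = status)
}

## Parsimonious restriction: among flux vectors attaining the optimum,
## minimize the total absolute flux. Split v = p - q (p, q >= 0) and lock
## the objective into a thin band below (max) / above (min) the optimum
## with one slack-carrying row.
lp_parsimonious <- function(S, lb, ub, obj, opt, maximize = TRUE) {
  n <- ncol(S); m <- nrow(S)
  lb[!is.finite(lb)] <- -BIG_BOX; ub[!is.finite(ub)] <- BIG_BOX
  lock_tol <- 1e-7 * max(1, abs(opt))
  A <- rbind(cbind(S, -S, rep(0, m)),
             c(obj, -obj, if (maximize) -1 else 1))
  b <- c(rep(0, m), if (maximize) opt - lock_tol else opt + lock_tol)
  lbs <- c(pmax(lb, 0), pmax(-ub, 0), 0)
  ubs <- c(pmax(ub, 0), pmax(-lb, 0), 2 * lock_tol)
  cost <- c(rep(1, 2 * n), 0)
  res <- simplex_box(A, b, lbs, ubs, cost, maximize = FALSE)
  if (!identical(res$status, "optimal")) return(NULL)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- colnames(S)
  v
}

model_bounds <- function(model, order) {
  lb <- vapply(model$reactions[order], `[[`, 0, "lb")
  ub <- vapply(model$reactions[order], `[[`, 0, "ub")
  list(lb = lb, ub = ub)
}

apply_bound_overrides <- function(lb, ub, overrides) {
  for (id in names(overrides)) {
    if (!id %in% names(lb))
      stop("bound override names unknown reaction '", id, "'", call. = FALSE)
    lb[id] <- overrides[[id]][1]
    ub[id] <- overrides[[id]][2]
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Solves max/min of a reaction flux subject to steady state
#' (`S v = 0`) and flux bounds. Among alternate optima the reported flux
#' vector additionally minimizes the sum of absolute fluxes (parsimonious
#' resolution) so comparisons between solutions are reproducible; the
#' scalar optimum is the primary contract.
#'
#' @param model a `phyco_model`.
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @param extra_bounds named list of `c(lower, upper)` overrides applied on
#'   top of the model bounds.
#' @param parsimonious run the secondary total-flux minimization
#'   (default `TRUE`).
#' @return a `flux_distribution`: fluxes per reaction, `objective_value`,
#'   `objective_reaction` and `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`; never an exception).
#' @export
solve_fba <- function(model, objective, sense = c("max", "min"),
                      extra_bounds = NULL, parsimonious = TRUE) {
  sense <- match.arg(sense)
  if (!length(model$reactions)) stop("model has no reactions", call. = FALSE)
  if (!objective %in% names(model$reactions))
    stop("unknown objective reaction '", objective, "'", call. = FALSE)
  S <- stoichiometric_matrix(model)
  ord <- colnames(S)
  bb <- model_bounds(model, ord)
  if (!is.null(extra_bounds))
    bb <- apply_bound_overrides(bb$lb, bb$ub, extra_bounds)
  obj <- as.numeric(ord == objective)
  first <- lp_fba(S, bb$lb, bb$ub, obj, maximize = sense == "max")
  v <- first$v
  if (first$status == "optimal" && parsimonious) {
    pv <- lp_parsimonious(S, bb$lb, bb$ub, obj, first$value,
                          maximize = sense == "max")
    if (!is.null(pv)) v <- pv
  }
  flux_distribution(v, first$value, objective, first$status, S)
}

flux_distribution <- function(fluxes, objective_value, objective_reaction,
                              status, S = NULL) {
  resid <- if (!is.null(S) && !is.null(fluxes))
    max(abs(S %*% fluxes)) else NA_real_
  structure(list(
    fluxes = fluxes,
    objective_value = objective_value,
    objective_reaction = objective_reaction,
    status = status,
    steady_state_residual = resid
  ), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  cat("  objective ", x$objective_reaction, " = ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  if (!is.null(x$fluxes)) {
    nz <- sum(abs(x$fluxes) > FEAS_TOL)
    cat("  ", nz, " of ", length(x$fluxes), " reactions carry flux; ",
        "max |S v| = ", format(x$steady_state_residual, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.flux_distribution <- function(object, ...) object$fluxes

#' @export
summary.flux_distribution <- function(object, top = 10, ...) {
  print(object)
  if (!is.null(object$fluxes)) {
    v <- object$fluxes[order(-abs(object$fluxes))]
    v <- v[abs(v) > FEAS_TOL]
    cat("Largest fluxes:\n")
    print(utils::head(round(v, 6), top))
  }
  invisible(object)
}

#' Write a flux report
#' @param model the model the distribution was computed on.
#' @param fd a `flux_distribution`.
#' @param path CSV output file.
#' @return `path`, invisibly.
#' @export
write_flux_report <- function(model, fd, path) {
  ids <- names(fd$fluxes)
  tb <- data.frame(
    reaction = ids,
    name = vapply(model$reactions[ids], `[[`, "", "name"),
    subsystem = vapply(model$reactions[ids], `[[`, "", "subsystem"),
    flux = unname(fd$fluxes),
    stringsAsFactors = FALSE
  )
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

## ---- the two optimization problems ---------------------------------------

growth_bounds <- function(model, scenario) {
  gid <- model$biomass_reaction
  if (is.null(gid))
    stop("model has no combined biomass equation; add one with ",
         "add_biomass_equation()", call. = FALSE)
  stats::setNames(list(c(scenario$fixed_growth_rate,
                         scenario$fixed_growth_rate)), gid)
}

#' Minimize uptake of the key energy substrate at fixed growth
#'
#' Growth is fixed to the scenario's rate (an equality, lower bound =
#' upper bound) and the uptake of the scenario's substrate exchange is
#' minimized. Exchange fluxes are signed with uptake negative, so the LP
#' maximizes the signed exchange flux with secretion of the substrate
#' closed for the duration of the solve.
#'
#' @param model a `phyco_model` with a combined biomass equation.
#' @param scenario a [scenario()] naming the substrate exchange (photons
#'   under autotrophic/mixotrophic growth, acetate under heterotrophic).
#' @param parsimonious passed to [solve_fba()].
#' @return a `flux_distribution`; `substrate_uptake` in the result holds
#'   the minimized uptake as a positive number.
#' @export
minimize_substrate <- function(model, scenario, parsimonious = TRUE) {
  sub <- scenario$substrate
  if (is.null(sub) || !sub %in% names(model$reactions))
    stop("scenario does not name a substrate exchange present in the model",
         call. = FALSE)
  eb <- c(scenario$bound_overrides, growth_bounds(model, scenario))
  cur_lb <- if (sub %in% names(eb)) eb[[sub]][1] else model$reactions[[sub]]$lb
  eb[[sub]] <- c(cur_lb, 0)    # uptake only while minimizing
  fd <- solve_fba(model, sub, sense = "max", extra_bounds = eb,
                  parsimonious = parsimonious)
  fd$substrate_uptake <- if (is.null(fd$fluxes)) NA_real_ else -fd$fluxes[[sub]]
  fd$scenario <- scenario$condition
  fd
}

#' Maximize a product at fixed growth
#'
#' Growth is fixed as in [minimize_substrate()] and the product exchange
#' flux is maximized. Optionally the substrate uptake is first pinned to
#' its substrate-minimal optimum (the wild-type reference), reproducing a
#' fixed-uptake comparison.
#'
#' @param model a `phyco_model` with a combined biomass equation.
#' @param scenario a [scenario()].
#' @param product product exchange reaction id (e.g. hydrogen secretion).
#' @param fix_substrate `"none"` (default) leaves substrate uptake within
#'   the scenario bounds; `"optimum"` fixes it at the minimized uptake.
#' @param parsimonious passed to [solve_fba()].
#' @return a `flux_distribution`.
#' @export
maximize_product <- function(model, scenario, product,
                             fix_substrate = c("none", "optimum"),
                             parsimonious = TRUE) {
  fix_substrate <- match.arg(fix_substrate)
  if (!product %in% names(model$reactions))
    stop("unknown product reaction '", product, "'", call. = FALSE)
  eb <- c(scenario$bound_overrides, growth_bounds(model, scenario))
  if (fix_substrate == "optimum") {
    ref <- minimize_substrate(model, scenario, parsimonious = FALSE)
    if (ref$status != "optimal")
      return(flux_distribution(NULL, NA_real_, product, ref$status))
    eb[[scenario$substrate]] <- rep(ref$fluxes[[scenario$substrate]], 2)
  }
  fd <- solve_fba(model, product, sense = "max", extra_bounds = eb,
                  parsimonious = parsimonious)
  fd$scenario <- scenario$condition
  fd
}

#' Knock out reactions
#'
#' Sets the bounds of the listed reactions to `(0, 0)`. Original bounds
#' are recorded so the knockout can be reversed with
#' [restore_knockouts()].
#'
#' @param model a `phyco_model`.
#' @param ids reaction ids to disable.
#' @return the modified model.
#' @export
knockout <- function(model, ids) {
  unknown <- setdiff(ids, names(model$reactions))
  if (length(unknown))
    stop("cannot knock out unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(model$knockouts)) model$knockouts <- list()
  for (id in ids) {
    if (!id %in% names(model$knockouts))
      model$knockouts[[id]] <- c(model$reactions[[id]]$lb,
                                 model$reactions[[id]]$ub)
    model$reactions[[id]]$lb <- 0
    model$reactions[[id]]$ub <- 0
  }
  model
}

#' Reverse previous knockouts
#' @param model a `phyco_model` with recorded knockouts.
#' @param ids reactions to restore; default all recorded.
#' @return the model with original bounds back in place.
#' @export
restore_knockouts <- function(model, ids = names(model$knockouts)) {
  for (id in ids) {
    kb <- model$knockouts[[id]]
    if (is.null(kb)) next
    model$reactions[[id]]$lb <- kb[1]
    model$reactions[[id]]$ub <- kb[2]
    model$knockouts[[id]] <- NULL
  }
  if (!length(model$knockouts)) model$knockouts <- NULL
  model
}
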