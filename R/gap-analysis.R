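## Producibility screening, dead-end detection and breakpoint tracing.
##
## Producibility has two granularities:
##  * the component screen solves one LP per biomass drain (maximize the
##    drain flux under the scenario bounds), matching the drain-by-drain
##    evaluation used to validate a reconstruction;
##  * breakpoint tracing classifies every metabolite at once with a
##    flux-consistency sweep: temporary sinks are attached to all
##    metabolites and the summed sink flux is maximized repeatedly until
##    no further metabolite can carry production flux. A metabolite the
##    sweep cannot activate is non-producible even with every other sink
##    open, which is the standard gap-finding notion.

## bounds with scenario overrides applied and all biomass fluxes closed
gap_bounds <- function(model, scenario = NULL, order) {
  bb <- model_bounds(model, order)
  if (!is.null(scenario)) {
    ov <- prune_overrides(model, scenario$bound_overrides)
    bb <- apply_bound_overrides(bb$lb, bb$ub, ov)
  }
  kinds <- vapply(model$reactions[order], `[[`, "", "kind")
  drains <- order[kinds == "biomass_drain"]
  bb$lb[drains] <- 0
  bb$ub[drains] <- 0
  bb
}

## maximum production rate of one metabolite through a temporary sink
single_drain_max <- function(S, lb, ub, met) {
  dcol <- matrix(0, nrow(S), 1, dimnames = list(rownames(S), ".sink"))
  dcol[met, 1] <- -1
  S2 <- cbind(S, dcol)
  res <- lp_fba(S2, c(lb, 0), c(ub, FLUX_BOUND),
                as.numeric(colnames(S2) == ".sink"), maximize = TRUE)
  if (res$status != "optimal") 0 else res$value
}

## flux-consistency sweep: which metabolites can carry production flux
## when every metabolite has a sink available
producible_metabolites <- function(S, lb, ub, mets = rownames(S)) {
  k <- length(mets)
  if (!k) return(character(0))
  D <- matrix(0, nrow(S), k)
  D[cbind(match(mets, rownames(S)), seq_len(k))] <- -1
  colnames(D) <- paste0(".sink", seq_len(k))
  S2 <- cbind(S, D)
  lb2 <- c(lb, rep(0, k)); ub2 <- c(ub, rep(FLUX_BOUND, k))
  producible <- rep(FALSE, k)
  repeat {
    open <- which(!producible)
    obj <- c(rep(0, ncol(S)), as.numeric(!producible))
    res <- lp_fba(S2, lb2, ub2, obj, maximize = TRUE)
    if (res$status != "optimal" || res$value <= FEAS_TOL) break
    hit <- abs(res$v[ncol(S) + open]) > FEAS_TOL
    if (!any(hit)) break
    producible[open[hit]] <- TRUE
    if (all(producible)) break
  }
  mets[producible]
}

#' Screen biomass components for producibility
#'
#' Solves one LP per component and condition: maximize the component's
#' drain flux under the scenario's exchange bounds with the combined
#' biomass equation closed. Components whose maximum production rate does
#' not exceed the tolerance are flagged blocked.
#'
#' @param model a `phyco_model`.
#' @param scenario a [scenario()] (or condition name) supplying exchange
#'   bounds; `NULL` screens under the model's own bounds.
#' @param components drain reaction ids (default: the model's biomass
#'   components).
#' @param tol producibility threshold (default `1e-6`).
#' @return `data.frame` (class `gap_report`) with `component`,
#'   `metabolite`, `max_rate`, `blocked`.
#' @export
producibility_screen <- function(model, scenario = NULL,
                                 components = model$biomass_components,
                                 tol = FEAS_TOL) {
  if (is.character(scenario) && length(scenario) == 1L)
    scenario <- trophic_scenario(scenario)
  S <- stoichiometric_matrix(model)
  bb <- gap_bounds(model, scenario, colnames(S))
  rows <- lapply(components, function(cid) {
    if (!cid %in% names(model$reactions))
      stop("component drain '", cid, "' not in model", call. = FALSE)
    met <- names(model$reactions[[cid]]$stoich)
    if (length(met) != 1L)
      stop("component drain '", cid, "' must consume exactly one metabolite",
           call. = FALSE)
    rate <- single_drain_max(S, bb$lb, bb$ub, met)
    data.frame(component = cid, metabolite = met, max_rate = rate,
               blocked = rate <= tol, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gap_report", "data.frame")
  out
}

#' Find dead-end metabolites
#'
#' Structural scan of the stoichiometric matrix respecting reaction
#' directionality: a metabolite is never-produced if no reaction can carry
#' positive production flux for it given signs and bounds alone, and
#' never-consumed symmetrically.
#'
#' @param model a `phyco_model`.
#' @return list with sorted character vectors `never_produced` and
#'   `never_consumed`.
#' @export
find_dead_ends <- function(model) {
  S <- stoichiometric_matrix(model)
  if (!nrow(S)) return(list(never_produced = character(0),
                            never_consumed = character(0)))
  lb <- vapply(model$reactions[colnames(S)], `[[`, 0, "lb")
  ub <- vapply(model$reactions[colnames(S)], `[[`, 0, "ub")
  fwd <- matrix(ub > 0, nrow(S), ncol(S), byrow = TRUE)
  bwd <- matrix(lb < 0, nrow(S), ncol(S), byrow = TRUE)
  can_prod <- (S > 0 & fwd) | (S < 0 & bwd)
  can_cons <- (S < 0 & fwd) | (S > 0 & bwd)
  list(never_produced = sort(rownames(S)[rowSums(can_prod) == 0]),
       never_consumed = sort(rownames(S)[rowSums(can_cons) == 0]))
}

#' Trace the breakpoints behind a blocked biomass component
#'
#' Backward breadth-first traversal from the blocked component over
#' producing reactions. Every frontier metabolite is classified against
#' the sweep-producible set; blocked metabolites are reported in traversal
#' order with a cause:
#' \describe{
#'   \item{no_producer}{no reaction can produce it under any bounds.}
#'   \item{missing_transporter}{the same chemical is producible in another
#'     compartment but cannot reach this one.}
#'   \item{irreversibility_conflict}{producible once irreversibility
#'     constraints on internal reactions are relaxed.}
#'   \item{blocked_precursor}{blocked because an upstream precursor is.}
#' }
#' Traversal is deterministic (sorted frontiers) and cycle-safe.
#'
#' @param model a `phyco_model`.
#' @param component a blocked drain reaction id (or metabolite id).
#' @param scenario scenario or condition name for the bounds.
#' @param max_depth traversal depth cap (default 25).
#' @return `data.frame` with `metabolite`, `cause`, `depth`, ordered by
#'   discovery; errors if the component is producible.
#' @export
trace_breakpoints <- function(model, component, scenario = NULL,
                              max_depth = 25L) {
  if (is.character(scenario) && length(scenario) == 1L)
    scenario <- trophic_scenario(scenario)
  S <- stoichiometric_matrix(model)
  bb <- gap_bounds(model, scenario, colnames(S))
  met0 <- if (component %in% rownames(S)) component
  else if (component %in% names(model$reactions)) {
    st <- model$reactions[[component]]$stoich
    if (length(st) != 1L)
      stop("'", component, "' does not drain a single metabolite",
           call. = FALSE)
    names(st)
  } else stop("unknown component '", component, "'", call. = FALSE)

  producible <- producible_metabolites(S, bb$lb, bb$ub)
  if (met0 %in% producible)
    stop("component '", component, "' is producible; nothing to trace",
         call. = FALSE)
  ## producibility with irreversibility on internal reactions relaxed,
  ## queried per metabolite and cached (only terminal nodes need it)
  kinds <- vapply(model$reactions[colnames(S)], `[[`, "", "kind")
  relaxed_lb <- bb$lb
  internal <- !kinds %in% c("exchange", "biomass_drain")
  relaxed_lb[internal & relaxed_lb >= 0] <- -FLUX_BOUND
  relaxed_cache <- new.env(parent = emptyenv())
  relaxed_producible <- function(met) {
    if (!is.null(relaxed_cache[[met]])) return(relaxed_cache[[met]])
    ans <- single_drain_max(S, relaxed_lb, bb$ub, met) > FEAS_TOL
    relaxed_cache[[met]] <- ans
    ans
  }
  base_of <- function(met) sub("_[cpmxe]$", "", met)
  lbv <- bb$lb; ubv <- bb$ub

  visited <- character(0)
  queue <- data.frame(met = met0, depth = 0L, stringsAsFactors = FALSE)
  out <- list()
  while (nrow(queue)) {
    cur <- queue$met[1]; depth <- queue$depth[1]
    queue <- queue[-1, , drop = FALSE]
    if (cur %in% visited) next
    visited <- c(visited, cur)
    if (cur %in% producible) next
    ## candidate producers under the current bounds
    js <- which((S[cur, ] > 0 & ubv > 0) | (S[cur, ] < 0 & lbv < 0))
    cause <- NULL
    if (!length(js)) {
      siblings <- setdiff(
        rownames(S)[sub("_[cpmxe]$", "", rownames(S)) == base_of(cur)], cur)
      cause <- if (length(intersect(siblings, producible)))
        "missing_transporter"
      else if (any(S[cur, ] != 0) && relaxed_producible(cur))
        "irreversibility_conflict"
      else "no_producer"
    } else if (depth >= max_depth) {
      cause <- "blocked_precursor"
    } else {
      ## expand to the substrates of each producing direction
      subs <- character(0)
      for (j in js) {
        dir_fwd <- S[cur, j] > 0
        cols <- if (dir_fwd) which(S[, j] < 0) else which(S[, j] > 0)
        subs <- union(subs, rownames(S)[cols])
      }
      subs <- sort(setdiff(subs, visited))
      blocked_subs <- setdiff(subs, producible)
      if (length(blocked_subs)) {
        cause <- "blocked_precursor"
        queue <- rbind(queue, data.frame(met = blocked_subs,
                                         depth = depth + 1L,
                                         stringsAsFactors = FALSE))
      } else {
        ## every substrate is available: the block sits at this node
        cause <- if (relaxed_producible(cur)) "irreversibility_conflict"
        else "blocked_precursor"
      }
    }
    out[[length(out) + 1L]] <- data.frame(metabolite = cur, cause = cause,
                                          depth = depth,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
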