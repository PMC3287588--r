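#' @keywords internal
"_PACKAGE"

## Five compartment labels used throughout; metabolite ids carry the
## one-letter suffix (e.g. "g6p_p" = plastidic glucose 6-phosphate).
COMPARTMENTS <- c(
  cytosol = "c", plastid = "p", mitochondrion = "m",
  microbody = "x", extracellular = "e"
)

REACTION_KINDS <- c("enzymatic", "transport", "exchange", "biomass_drain",
                    "non_enzymatic_gap")
EVIDENCE_KINDS <- c("literature", "homolog", "default_cytosol",
                    "not_applicable")

## Conventional "effectively unbounded" flux box (mmol gDW^-1 h^-1).
FLUX_BOUND <- 1000

#' Create a metabolite
#'
#' A metabolite is a chemical species bound to exactly one compartment;
#' the same chemical in two compartments is two metabolites. The id must
#' end in the one-letter compartment suffix (`_c`, `_p`, `_m`, `_x`, `_e`).
#'
#' @param id unique metabolite id carrying the compartment suffix.
#' @param name human-readable name.
#' @param compartment one of `"cytosol"`, `"plastid"`, `"mitochondrion"`,
#'   `"microbody"`, `"extracellular"`. Defaults to the suffix of `id`.
#' @param formula optional elemental formula in Hill notation (`NA` if
#'   unknown; massless species such as photons use `""`).
#' @param is_boundary flag marking extracellular species drained/sourced
#'   by exchange reactions.
#' @return a one-row `data.frame` with metabolite fields.
#' @export
metabolite <- function(id, name = id, compartment = NULL, formula = NA_character_,
                       is_boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  suf <- sub(".*_", "", id)
  from_id <- names(COMPARTMENTS)[match(suf, COMPARTMENTS)]
  if (is.null(compartment)) {
    if (is.na(from_id))
      stop("metabolite id '", id, "' does not end in a compartment suffix ",
           "and no compartment was given", call. = FALSE)
    compartment <- from_id
  }
  compartment <- match.arg(compartment, names(COMPARTMENTS))
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula),
             is_boundary = isTRUE(is_boundary),
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed).
#' @param name human-readable name.
#' @param reversible logical; irreversible reactions must have `lb >= 0`.
#' @param lb,ub flux bounds (mmol gDW^-1 h^-1; growth and drain fluxes in
#'   h^-1 equivalents). Defaults: `(-1000, 1000)` reversible, `(0, 1000)`
#'   irreversible.
#' @param gpr gene association: infix boolean over gene ids with
#'   `and`/`or` and parentheses; `""` if none.
#' @param kind one of `"enzymatic"`, `"transport"`, `"exchange"`,
#'   `"biomass_drain"`, `"non_enzymatic_gap"`.
#' @param evidence compartment-evidence provenance: `"literature"`,
#'   `"homolog"`, `"default_cytosol"` or `"not_applicable"`.
#' @param subsystem free-text pathway tag.
#' @return a list of class `phyco_reaction`.
#' @export
reaction <- function(id, stoich, name = id, reversible = FALSE,
                     lb = if (reversible) -FLUX_BOUND else 0, ub = FLUX_BOUND,
                     gpr = "", kind = "enzymatic",
                     evidence = "not_applicable", subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, REACTION_KINDS)
  evidence <- match.arg(evidence, EVIDENCE_KINDS)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  stoich <- stoich[stoich != 0]
  if (length(stoich) && (is.null(names(stoich)) || any(!nzchar(names(stoich)))))
    stop("stoichiometry of '", id, "' must be a named numeric vector",
         call. = FALSE)
  if (anyDuplicated(names(stoich)))
    stop("duplicate metabolite in stoichiometry of '", id, "'", call. = FALSE)
  r <- structure(list(
    id = id, name = name, stoich = stoich,
    reversible = isTRUE(reversible), lb = as.numeric(lb), ub = as.numeric(ub),
    gpr = as.character(gpr), kind = kind, evidence = evidence,
    subsystem = subsystem
  ), class = "phyco_reaction")
  validate_reaction(r)
  r
}

validate_reaction <- function(r) {
  if (r$lb > r$ub)
    stop("reaction '", r$id, "': lower bound exceeds upper bound",
         call. = FALSE)
  if (!r$reversible && r$lb < 0)
    stop("reaction '", r$id, "': irreversible but lower bound is negative",
         call. = FALSE)
  if (r$kind == "non_enzymatic_gap" && nzchar(r$gpr))
    stop("reaction '", r$id, "': non-enzymatic gap reactions carry no ",
         "gene association", call. = FALSE)
  invisible(r)
}

#' Assemble a compartmentalized model
#'
#' @param metabolites `data.frame` of metabolites (rows as produced by
#'   [metabolite()]).
#' @param reactions list of [reaction()] objects.
#' @param biomass_components character vector of biomass drain reaction ids.
#' @param biomass_reaction id of the combined biomass equation, or `NULL`.
#' @param validate run structural invariant checks (default `TRUE`).
#' @return an object of class `phyco_model`.
#' @export
phyco_model <- function(metabolites, reactions, biomass_components = character(),
                        biomass_reaction = NULL, validate = TRUE) {
  if (is.null(metabolites))
    metabolites <- metabolite("void_c")[0, ]
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    biomass_components = biomass_components,
    biomass_reaction = biomass_reaction
  ), class = "phyco_model")
  if (validate) validate_model(m)
  m
}

#' Validate structural invariants of a model
#'
#' Checks metabolite id uniqueness and compartment labels, reaction bound
#' and kind invariants, that every referenced metabolite exists, that
#' exchange reactions touch exactly one extracellular species, and that
#' transport reactions span exactly two compartments.
#'
#' @param model a `phyco_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  bad <- !mets$compartment %in% names(COMPARTMENTS)
  if (any(bad))
    stop("unknown compartment for: ", paste(mets$id[bad], collapse = ", "),
         call. = FALSE)
  ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  comp_of <- stats::setNames(mets$compartment, mets$id)
  for (r in model$reactions) {
    validate_reaction(r)
    missing <- setdiff(names(r$stoich), mets$id)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    comps <- unique(unname(comp_of[names(r$stoich)]))
    if (r$kind == "exchange") {
      if (length(r$stoich) != 1L || comps != "extracellular")
        stop("exchange reaction '", r$id, "' must touch exactly one ",
             "extracellular metabolite", call. = FALSE)
    }
    if (r$kind == "transport" && length(comps) != 2L)
      stop("transport reaction '", r$id, "' must span exactly two ",
           "compartments, found ", length(comps), call. = FALSE)
  }
  for (b in model$biomass_components)
    if (!b %in% ids)
      stop("biomass component drain '", b, "' is not a reaction", call. = FALSE)
  if (!is.null(model$biomass_reaction) && !model$biomass_reaction %in% ids)
    stop("biomass reaction '", model$biomass_reaction, "' is not a reaction",
         call. = FALSE)
  invisible(model)
}

#' @export
print.phyco_model <- function(x, ...) {
  kinds <- table(factor(vapply(x$reactions, `[[`, "", "kind"),
                        levels = REACTION_KINDS))
  cat("Compartmentalized metabolic model\n")
  cat("  metabolites: ", nrow(x$metabolites), " in ",
      length(unique(x$metabolites$compartment)), " compartments\n", sep = "")
  cat("  reactions:   ", length(x$reactions),
      sprintf(" (%s)", paste(sprintf("%s %d", names(kinds), as.integer(kinds)),
                             collapse = ", ")), "\n", sep = "")
  if (!is.null(x$biomass_reaction))
    cat("  biomass:     ", x$biomass_reaction, " + ",
        length(x$biomass_components), " drains\n", sep = "")
  else if (length(x$biomass_components))
    cat("  biomass:     ", length(x$biomass_components), " drains\n", sep = "")
  invisible(x)
}

#' @export
summary.phyco_model <- function(object, ...) {
  s <- model_statistics(object)
  print(s)
  invisible(s)
}

#' Build the stoichiometric matrix
#'
#' Returns the metabolites-by-reactions matrix S with `S[i, j]` the signed
#' coefficient of metabolite i in reaction j. Rows and columns are sorted
#' by id so the ordering is deterministic and is reported in the dimnames.
#'
#' @param model a `phyco_model`.
#' @return a dense numeric matrix with metabolite ids as rownames and
#'   reaction ids as colnames; `0 x 0` for an empty model.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- sort(model$metabolites$id)
  rxn_ids <- sort(names(model$reactions))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    S[names(r$stoich), r$id] <- r$stoich
  }
  S
}

#' Rebuild a model from a stoichiometric matrix
#'
#' Inverse of [stoichiometric_matrix()] up to reaction metadata: bounds,
#' reversibility and kinds are taken from `template` when given, else
#' defaulted.
#'
#' @param S stoichiometric matrix with dimnames.
#' @param template optional `phyco_model` supplying reaction metadata.
#' @return a `phyco_model`.
#' @export
model_from_matrix <- function(S, template = NULL) {
  mets <- do.call(rbind, lapply(rownames(S), metabolite))
  rxns <- lapply(colnames(S), function(j) {
    st <- S[, j]
    st <- st[st != 0]
    if (!is.null(template) && j %in% names(template$reactions)) {
      tr <- template$reactions[[j]]
      reaction(j, st, name = tr$name, reversible = tr$reversible,
               lb = tr$lb, ub = tr$ub, gpr = tr$gpr, kind = tr$kind,
               evidence = tr$evidence, subsystem = tr$subsystem)
    } else reaction(j, st, reversible = TRUE)
  })
  phyco_model(mets, rxns, validate = FALSE)
}

## ---- biomass -------------------------------------------------------------

#' Define a biomass composition
#'
#' @param coefficients named non-negative numeric vector, biomass
#'   component metabolite id -> stoichiometric coefficient
#'   (mmol per gDW, so that the combined equation's flux is h^-1).
#' @param condition trophic label the composition was measured under.
#' @param atp_maintenance growth-associated ATP cost (mol ATP hydrolysed
#'   per unit biomass flux); 0 to disable.
#' @return an object of class `biomass_composition`.
#' @export
biomass_composition <- function(coefficients, condition = "autotrophic",
                                atp_maintenance = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!any(coefficients > 0))
    stop("biomass composition needs at least one positive coefficient",
         call. = FALSE)
  if (any(coefficients < 0))
    stop("biomass coefficients must be non-negative", call. = FALSE)
  structure(list(condition = condition, coefficients = coefficients,
                 atp_maintenance = atp_maintenance),
            class = "biomass_composition")
}

#' Combine biomass drains into a single biomass equation
#'
#' Appends one irreversible reaction consuming each component with its
#' coefficient (plus growth-associated ATP hydrolysis when requested).
#' Existing per-component drains remain in the model but are bounded to
#' zero: producibility screening uses the drains, growth simulation the
#' combined equation, and a scenario activates exactly one of the two.
#'
#' @param model a `phyco_model`.
#' @param composition a [biomass_composition()]. Component ids must be
#'   metabolite ids present in the model.
#' @param id id for the new reaction.
#' @return the model with `biomass_reaction` set.
#' @export
add_biomass_equation <- function(model, composition, id = "biomass") {
  stopifnot(inherits(composition, "biomass_composition"))
  comp <- composition$coefficients
  missing <- setdiff(names(comp), model$metabolites$id)
  if (length(missing))
    stop("biomass components not in model: ", paste(missing, collapse = ", "),
         call. = FALSE)
  st <- -comp
  gam <- composition$atp_maintenance
  if (gam > 0) {
    need <- c(atp_c = -gam, h2o_c = -gam, adp_c = gam, pi_c = gam)
    for (mid in names(need)) {
      if (!mid %in% model$metabolites$id)
        stop("ATP maintenance requires metabolite '", mid, "'", call. = FALSE)
      st[mid] <- if (mid %in% names(st)) st[mid] + need[mid] else need[mid]
    }
  }
  rx <- reaction(id, st, name = "biomass synthesis", reversible = FALSE,
                 kind = "biomass_drain",
                 subsystem = paste0("biomass (", composition$condition, ")"))
  ## close the individual drains; the combined equation is now the growth flux
  for (d in model$biomass_components) {
    model$reactions[[d]]$lb <- 0
    model$reactions[[d]]$ub <- 0
  }
  model$reactions[[id]] <- rx
  model$biomass_reaction <- id
  validate_model(model)
}

## ---- elemental balance ---------------------------------------------------

#' Parse a Hill-notation elemental formula
#'
#' @param formula a string like `"C6H12O6"`; `""` parses to a massless
#'   species (no atoms); `NA` returns `NULL` (unknown).
#' @return named integer-ish numeric vector of element counts, or `NULL`.
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula)) return(NULL)
  if (!nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  el <- sub("[0-9]+$", "", toks)
  n <- as.numeric(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1
  tapply(n, el, sum)[unique(el)]
}

#' Audit the elemental balance of reactions
#'
#' Computes the per-element residual (products minus substrates) of each
#' reaction given metabolite formulas. Exchange, biomass-drain and
#' demand-style reactions are intrinsically unbalanced and reported as
#' `"exempt"`; reactions with any participant of unknown formula are
#' reported `"unknown"`, never `"unbalanced"`.
#'
#' @param model a `phyco_model`.
#' @param formulas optional named character vector metabolite id -> Hill
#'   formula; defaults to the formulas stored on the model's metabolites.
#' @param tol absolute residual below which an element counts as balanced.
#' @return `data.frame` with columns `reaction`, `status` (one of
#'   `"balanced"`, `"unbalanced"`, `"unknown"`, `"exempt"`) and `residual`
#'   (a list column of named per-element residual vectors).
#' @export
elemental_balance_audit <- function(model, formulas = NULL, tol = 1e-8) {
  if (is.null(formulas))
    formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  out <- lapply(model$reactions, function(r) {
    if (r$kind %in% c("exchange", "biomass_drain"))
      return(list(status = "exempt", residual = numeric(0)))
    res <- numeric(0)
    for (mid in names(r$stoich)) {
      f <- parse_formula(formulas[[mid]])
      if (is.null(f)) return(list(status = "unknown", residual = NULL))
      for (el in names(f)) {
        res[el] <- (if (el %in% names(res)) res[el] else 0) +
          r$stoich[[mid]] * f[[el]]
      }
    }
    status <- if (length(res) && any(abs(res) > tol)) "unbalanced" else "balanced"
    list(status = status, residual = res[abs(res) > tol])
  })
  data.frame(
    reaction = names(model$reactions),
    status = vapply(out, `[[`, "", "status"),
    residual = I(lapply(out, `[[`, "residual")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## internal helpers used across modules
rxn_ids <- function(model) names(model$reactions)

met_compartment <- function(model, ids) {
  stats::setNames(model$metabolites$compartment,
                  model$metabolites$id)[ids]
}

## canonical key of a reaction's stoichiometry (for duplicate detection)
stoich_key <- function(stoich, reversible = FALSE) {
  o <- order(names(stoich))
  s <- stoich[o]
  key <- paste(names(s), format(s, digits = 12, trim = TRUE),
               sep = ":", collapse = ";")
  ## a reversible reaction equals its mirror image; canonicalize the sign
  if (reversible) {
    first_sign <- sign(s[[1]])
    if (first_sign < 0) {
      s2 <- -s
      key2 <- paste(names(s2), format(s2, digits = 12, trim = TRUE),
                    sep = ":", collapse = ";")
      key <- key2
    }
  }
  key
}
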