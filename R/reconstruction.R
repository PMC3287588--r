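## Curation pipeline: duplicate-compound resolution, polymer rewriting,
## compartment assignment from evidence and manual transporter addition.

#' Resolve duplicate compound labels
#'
#' Rewrites every metabolite reference through a synonym table mapping
#' non-canonical compound ids to canonical ones (e.g. specific versus
#' non-specific sugar stereoisomer labels). Coefficients of references
#' merging inside one reaction are summed (and dropped when they cancel);
#' reactions whose stoichiometry becomes identical to an earlier one are
#' collapsed with their gene associations OR-combined.
#'
#' @param model a `phyco_model`.
#' @param synonyms named character vector, non-canonical id -> canonical
#'   id. Must be idempotent after one application (no chains or cycles).
#' @return list with `model` and `report` (`data.frame` of compound
#'   rewrites and reaction merges).
#' @export
merge_duplicate_compounds <- function(model, synonyms) {
  if (!length(synonyms))
    return(list(model = model,
                report = data.frame(type = character(0), from = character(0),
                                    to = character(0))))
  chained <- intersect(unname(synonyms), names(synonyms))
  chained <- chained[synonyms[chained] != chained]
  if (length(chained))
    stop("synonym table is not idempotent; chained/cyclic entries: ",
         paste(chained, collapse = ", "), call. = FALSE)
  canon <- function(ids) ifelse(ids %in% names(synonyms), synonyms[ids], ids)
  report <- list()
  for (from in names(synonyms))
    if (from %in% model$metabolites$id)
      report[[length(report) + 1L]] <-
        data.frame(type = "compound", from = from,
                   to = unname(synonyms[[from]]))
  ## rewrite metabolites table
  mets <- model$metabolites
  mets$id <- unname(canon(mets$id))
  mets <- mets[!duplicated(mets$id), , drop = FALSE]
  ## rewrite reactions, then collapse duplicates
  seen <- character(0)
  keep <- list()
  for (r in model$reactions) {
    st <- r$stoich
    names(st) <- canon(names(st))
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))  # drop array attrs
    st <- st[st != 0]
    r$stoich <- st
    key <- stoich_key(st, r$reversible)
    hit <- match(key, seen)
    if (is.na(hit)) {
      seen <- c(seen, key)
      keep[[length(keep) + 1L]] <- r
    } else {
      first <- keep[[hit]]
      keep[[hit]]$gpr <- or_join(first$gpr, r$gpr)
      report[[length(report) + 1L]] <-
        data.frame(type = "reaction", from = r$id, to = first$id)
    }
  }
  report <- if (length(report)) do.call(rbind, report)
  else data.frame(type = character(0), from = character(0), to = character(0))
  list(model = phyco_model(mets, keep,
                           biomass_components = model$biomass_components,
                           biomass_reaction = model$biomass_reaction),
       report = report)
}

or_join <- function(a, b) {
  if (!nzchar(a)) return(b)
  if (!nzchar(b) || identical(a, b)) return(a)
  wrap <- function(x) if (grepl("\\b(and|or)\\b", x, ignore.case = TRUE))
    paste0("(", x, ")") else x
  paste(wrap(a), "or", wrap(b))
}

#' Rewrite polymer pseudo-reactions as monomer accumulation
#'
#' Degenerate polymer-elongation entries of the form
#' `polymer(n) + monomer -> polymer(n+1)` are rewritten in terms of the
#' polymer's monomer unit: the `(n)`/`(n+1)` pair is removed and one unit
#' of the mapped monomer species is produced instead. Species carrying the
#' generic "R" group are rejected rather than silently kept.
#'
#' @param model a `phyco_model`.
#' @param monomer_map named character vector, polymer base id (the id
#'   before the `(n)` marker, without compartment suffix) -> monomer-unit
#'   base id.
#' @return the rewritten model.
#' @export
expand_polymer_reactions <- function(model, monomer_map = character()) {
  is_rgroup <- function(mid) {
    f <- model$metabolites$formula[match(mid, model$metabolites$id)]
    if (!is.na(f)) {
      els <- tryCatch(names(parse_formula(f)), error = function(e) NULL)
      if ("R" %in% els) return(TRUE)
    }
    grepl("^R[-_]", mid)
  }
  poly_pat <- "^(.*)\\(n(\\+1)?\\)(_[cpmxe])?$"
  new_mets <- model$metabolites
  changed <- FALSE
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    rg <- names(r$stoich)[vapply(names(r$stoich), is_rgroup, TRUE)]
    if (length(rg))
      stop("reaction '", rid, "' uses generic R-group species: ",
           paste(rg, collapse = ", "), call. = FALSE)
    ids <- names(r$stoich)
    hits <- grepl(poly_pat, ids)
    if (!any(hits)) next
    base <- sub(poly_pat, "\\1", ids[hits])
    comp <- sub(poly_pat, "\\3", ids[hits])
    for (b in unique(base)) {
      if (!b %in% names(monomer_map))
        stop("polymer '", b, "' in reaction '", rid,
             "' has no monomer mapping", call. = FALSE)
      sel <- hits & base[match(ids, ids)] %in% b
      sel <- which(hits)[base == b]
      units <- sum(r$stoich[sel])   # net polymer growth, usually +1 - 1 = 0
      grown <- grepl("\\(n\\+1\\)", ids[sel])
      n_units <- sum(r$stoich[sel][grown])
      mono <- paste0(monomer_map[[b]], comp[base == b][1])
      r$stoich <- r$stoich[-sel]
      if (abs(units) > 1e-12)
        stop("polymer '", b, "' in reaction '", rid,
             "' does not cancel between (n) and (n+1) forms", call. = FALSE)
      r$stoich[mono] <- (if (mono %in% names(r$stoich)) r$stoich[[mono]]
                         else 0) + n_units
      if (!mono %in% new_mets$id) {
        cmp <- names(COMPARTMENTS)[match(sub("^_", "", comp[base == b][1]),
                                         COMPARTMENTS)]
        if (is.na(cmp)) cmp <- new_mets$compartment[match(ids[sel][1],
                                                          new_mets$id)]
        new_mets <- rbind(new_mets,
                          metabolite(mono, compartment = cmp))
      }
      changed <- TRUE
    }
    model$reactions[[rid]] <- r
  }
  if (changed) {
    used <- unique(unlist(lapply(model$reactions,
                                 function(r) names(r$stoich))))
    new_mets <- new_mets[new_mets$id %in% used, , drop = FALSE]
    model$metabolites <- new_mets
  }
  validate_model(model)
}

#' Assign compartments to reactions from localization evidence
#'
#' Applies the evidence precedence literature > homolog > cytosol default,
#' per reaction. Every metabolite of a reaction is suffixed into the
#' assigned compartment and the winning source is recorded as the
#' reaction's `compartment_evidence`. Multiple literature claims for one
#' reaction produce one compartmental copy per claimed compartment (a
#' reaction may legitimately occur in several compartments).
#'
#' @param model a `phyco_model` whose metabolite ids carry no compartment
#'   suffix yet (as read with `read_reaction_table(compartmentalized =
#'   FALSE)`); exchange and transport reactions are left untouched.
#' @param evidence evidence `data.frame` as from [read_evidence_table()].
#' @return a compartmentalized `phyco_model`.
#' @export
assign_compartments <- function(model, evidence) {
  out <- list()
  for (r in model$reactions) {
    already <- all(grepl("_[cpmxe]$", names(r$stoich)))
    if (already || r$kind %in% c("exchange", "transport", "biomass_drain")) {
      out[[length(out) + 1L]] <- r   # compartmentalized reactions pass through
      next
    }
    ev <- evidence[evidence$reaction_id == r$id, , drop = FALSE]
    lit <- unique(ev$compartment[ev$source == "literature"])
    hom <- unique(ev$compartment[ev$source == "homolog"])
    if (length(lit)) { comps <- lit; src <- "literature" }
    else if (length(hom)) { comps <- hom; src <- "homolog" }
    else { comps <- "cytosol"; src <- "default_cytosol" }
    comps <- sort(comps)
    for (cc in comps) {
      r2 <- r
      suffix <- paste0("_", COMPARTMENTS[[cc]])
      names(r2$stoich) <- paste0(names(r$stoich), suffix)
      r2$evidence <- src
      if (length(comps) > 1L) r2$id <- paste0(r$id, suffix)
      out[[length(out) + 1L]] <- r2
    }
  }
  base <- model$metabolites
  used <- unique(unlist(lapply(out, function(r) names(r$stoich))))
  mets <- do.call(rbind, lapply(sort(used), function(id) {
    suf <- sub(".*_", "", id)
    cmp <- names(COMPARTMENTS)[match(suf, COMPARTMENTS)]
    raw <- sub("_[cpmxe]$", "", id)
    i <- match(raw, base$id)
    if (is.na(cmp)) {          # untouched (already-compartmentalized) id
      if (!is.na(i)) return(base[i, , drop = FALSE])
      return(metabolite(id))
    }
    metabolite(id, name = if (!is.na(i)) base$name[i] else id,
               compartment = cmp,
               formula = if (!is.na(i)) base$formula[i] else NA_character_,
               is_boundary = cmp == "extracellular")
  }))
  phyco_model(mets, out, biomass_components = model$biomass_components,
              biomass_reaction = model$biomass_reaction)
}

#' Add membrane transporters from a curated table
#'
#' Appends one transport reaction per table row, moving the species
#' between the two named compartments (with optional cotransport terms).
#' Both compartmental forms of the species must already exist in the
#' model unless `create = TRUE`.
#'
#' @param model a `phyco_model`.
#' @param transporters `data.frame` as from [read_transporter_table()].
#' @param create create missing compartmental species instead of erroring.
#' @return the model with transporters appended.
#' @export
add_transporters <- function(model, transporters, create = FALSE) {
  if (!nrow(transporters)) return(model)
  for (i in seq_len(nrow(transporters))) {
    row <- transporters[i, ]
    ca <- match.arg(row$compartment_a, names(COMPARTMENTS))
    cb <- match.arg(row$compartment_b, names(COMPARTMENTS))
    ida <- paste0(row$species_id, "_", COMPARTMENTS[[ca]])
    idb <- paste0(row$species_id, "_", COMPARTMENTS[[cb]])
    for (mid in c(ida, idb)) {
      if (!mid %in% model$metabolites$id) {
        if (!create)
          stop("transporter for '", row$species_id, "' references '", mid,
               "', which is absent from the model", call. = FALSE)
        model$metabolites <- rbind(model$metabolites, metabolite(mid))
      }
    }
    st <- stats::setNames(c(-1, 1), c(ida, idb))
    if (nzchar(row$cotransport)) {
      extra <- parse_equation(paste(row$cotransport,
                                    if (!grepl("-->|<=>", row$cotransport))
                                      "-->" else ""))$stoich
      for (mid in names(extra))
        st[mid] <- (if (mid %in% names(st)) st[mid] else 0) + extra[mid]
    }
    rid <- paste0("t_", row$species_id, "_", COMPARTMENTS[[ca]],
                  COMPARTMENTS[[cb]])
    if (rid %in% names(model$reactions))
      stop("transporter '", rid, "' already exists", call. = FALSE)
    model$reactions[[rid]] <- reaction(
      rid, st, name = paste0(row$species_id, " transport ", ca, "/", cb),
      reversible = row$reversible, kind = "transport",
      evidence = "literature", subsystem = "transport")
  }
  validate_model(model)
}

#' Run the full curation pipeline
#'
#' Convenience wrapper: duplicate-compound resolution, polymer rewriting,
#' compartment assignment, transporter addition. The pipeline is
#' idempotent: applying it twice equals applying it once.
#'
#' @param model raw gene-centric `phyco_model` (uncompartmentalized).
#' @param synonyms synonym table (may be empty).
#' @param monomer_map polymer monomer map (may be empty).
#' @param evidence evidence `data.frame`.
#' @param transporters transporter `data.frame` (may be zero rows).
#' @param create_transport_species passed to [add_transporters()].
#' @return list with the curated `model` and the `merge_report`.
#' @export
reconstruct_model <- function(model, synonyms = character(),
                              monomer_map = character(),
                              evidence = data.frame(reaction_id = character(0),
                                                    compartment = character(0),
                                                    source = character(0)),
                              transporters = NULL,
                              create_transport_species = FALSE) {
  merged <- merge_duplicate_compounds(model, synonyms)
  m <- expand_polymer_reactions(merged$model, monomer_map)
  m <- assign_compartments(m, evidence)
  if (!is.null(transporters) && nrow(transporters))
    m <- add_transporters(m, transporters,
                          create = create_transport_species)
  list(model = m, merge_report = merged$report)
}
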