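## SBML import/export. Writes Level 3 Version 1 with flux bounds as global
## parameters and gene associations in reaction notes ("GENE_ASSOCIATION:"
## lines, the conventional notes-based encoding); reads Level 2 or 3
## tolerantly, including kineticLaw-parameter bounds.

XHTML_NS <- "http://www.w3.org/1999/xhtml"

sanitize_sid <- function(id) {
  ok <- grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)
  out <- id
  out[!ok] <- gsub("[^A-Za-z0-9_]", "_", id[!ok])
  bad_start <- !grepl("^[A-Za-z_]", out)
  out[bad_start] <- paste0("_", out[bad_start])
  out
}

num_attr <- function(x) sprintf("%.15g", x)

#' Write a model as SBML
#'
#' Emits SBML Level 3 Version 1: one species per metabolite with its
#' compartment (and its formula in the species notes), one reaction per
#' reaction with reversibility flag, flux bounds as global parameters
#' (`lb_<id>`/`ub_<id>`), and the gene association, kind, evidence and
#' subsystem serialized as notes lines on the reaction. Ids that are not
#' valid SBML SIds are sanitized deterministically; the mapping is
#' attached as the `"id_map"` attribute of the return value.
#'
#' @param model a `phyco_model`.
#' @param path output file, or `NULL` to return the document as a string.
#' @return the path (or the SBML string), invisibly when written to file.
#' @export
write_sbml <- function(model, path = NULL) {
  validate_model(model)
  mets <- model$metabolites[order(model$metabolites$id), , drop = FALSE]
  rids <- sort(names(model$reactions))
  sids <- sanitize_sid(mets$id)
  rsids <- sanitize_sid(rids)
  id_map <- c(stats::setNames(sids, mets$id), stats::setNames(rsids, rids))
  if (anyDuplicated(c(sids, rsids)))
    stop("id sanitization produced duplicate SBML ids", call. = FALSE)
  smap <- stats::setNames(sids, mets$id)

  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "model")
  if (!is.null(model$biomass_reaction) || length(model$biomass_components)) {
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    if (!is.null(model$biomass_reaction))
      xml2::xml_add_child(body, "p",
                          paste0("BIOMASS_REACTION: ",
                                 id_map[[model$biomass_reaction]]))
    if (length(model$biomass_components))
      xml2::xml_add_child(body, "p",
                          paste0("BIOMASS_COMPONENTS: ",
                                 paste(id_map[model$biomass_components],
                                       collapse = ",")))
  }
  comps <- sort(unique(unname(COMPARTMENTS[mets$compartment])))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cc in comps)
    xml2::xml_add_child(lc, "compartment", id = cc,
                        name = names(COMPARTMENTS)[COMPARTMENTS == cc],
                        constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(mets))) {
    sp <- xml2::xml_add_child(
      ls, "species", id = smap[[mets$id[i]]], name = mets$name[i],
      compartment = unname(COMPARTMENTS[mets$compartment[i]]),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (mets$is_boundary[i]) "true" else "false",
      constant = "false")
    if (!is.na(mets$formula[i])) {
      notes <- xml2::xml_add_child(sp, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
      xml2::xml_add_child(body, "p", paste0("FORMULA: ", mets$formula[i]))
    }
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (rid in rids) {
    r <- model$reactions[[rid]]
    xml2::xml_add_child(lp, "parameter", id = paste0("lb_", id_map[[rid]]),
                        value = num_attr(r$lb), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("ub_", id_map[[rid]]),
                        value = num_attr(r$ub), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rid in rids) {
    r <- model$reactions[[rid]]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = id_map[[rid]], name = r$name,
      reversible = if (r$reversible) "true" else "false", fast = "false")
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    if (nzchar(r$gpr))
      xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", r$gpr))
    xml2::xml_add_child(body, "p", paste0("KIND: ", r$kind))
    xml2::xml_add_child(body, "p", paste0("EVIDENCE: ", r$evidence))
    if (nzchar(r$subsystem))
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    st <- r$stoich[order(names(r$stoich))]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (mid in names(reac))
        xml2::xml_add_child(lre, "speciesReference", species = smap[[mid]],
                            stoichiometry = num_attr(-reac[[mid]]),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (mid in names(prod))
        xml2::xml_add_child(lpr, "speciesReference", species = smap[[mid]],
                            stoichiometry = num_attr(prod[[mid]]),
                            constant = "true")
    }
  }
  if (is.null(path)) {
    out <- as.character(doc)
    attr(out, "id_map") <- id_map
    return(out)
  }
  xml2::write_xml(doc, path)
  invisible(structure(path, id_map = id_map))
}

note_lines <- function(node) {
  ps <- xml2::xml_find_all(node, "./notes//p")
  trimws(xml2::xml_text(ps))
}

note_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "\\s*:"), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(paste0("^", key, "\\s*:"), "", hit[1]))
}

match_compartment <- function(cid, cname) {
  if (cid %in% COMPARTMENTS) return(names(COMPARTMENTS)[COMPARTMENTS == cid])
  lc <- tolower(paste(cid, cname))
  hit <- c(cytosol = "cytosol|cytoplasm", plastid = "plastid|chloroplast",
           mitochondrion = "mitochond", microbody = "microbody|peroxisome|glyoxysome",
           extracellular = "extracellular|external|boundary|medium")
  for (k in names(hit)) if (grepl(hit[[k]], lc)) return(k)
  NA_character_
}

#' Read a model from SBML
#'
#' Inverse of [write_sbml()] on documents it produced; foreign Level 2/3
#' documents are read tolerantly: bounds are taken from global
#' `lb_`/`ub_` parameters, then from COBRA-style kineticLaw parameters
#' (`LOWER_BOUND`/`UPPER_BOUND`), and finally default to the
#' reversibility-derived box `(-1000, 1000)` / `(0, 1000)`. Gene
#' associations are recovered from `GENE_ASSOCIATION` notes lines;
#' reaction kinds missing from the notes are inferred structurally.
#'
#' @param path SBML file (or a literal SBML string).
#' @return a `phyco_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, "./model")
  if (inherits(mdl, "xml_missing"))
    stop("no <model> element found", call. = FALSE)
  cnodes <- xml2::xml_find_all(mdl, "./listOfCompartments/compartment")
  cmap <- character(0)
  for (cn in cnodes) {
    cid <- xml2::xml_attr(cn, "id")
    cmap[cid] <- match_compartment(cid, xml2::xml_attr(cn, "name"))
    if (is.na(cmap[cid]))
      stop("cannot map compartment '", cid, "' to a known label",
           call. = FALSE)
  }
  snodes <- xml2::xml_find_all(mdl, "./listOfSpecies/species")
  mets <- vector("list", length(snodes))
  for (i in seq_along(snodes)) {
    sn <- snodes[[i]]
    cid <- xml2::xml_attr(sn, "compartment")
    if (!cid %in% names(cmap))
      stop("species '", xml2::xml_attr(sn, "id"),
           "' references unknown compartment '", cid, "'", call. = FALSE)
    lines <- note_lines(sn)
    form <- note_value(lines, "FORMULA")
    mets[[i]] <- metabolite(
      xml2::xml_attr(sn, "id"),
      name = xml2::xml_attr(sn, "name", default = xml2::xml_attr(sn, "id")),
      compartment = cmap[[cid]],
      formula = if (is.null(form)) NA_character_ else form,
      is_boundary = identical(xml2::xml_attr(sn, "boundaryCondition"), "true"))
  }
  mets <- do.call(rbind, mets)
  params <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  pv <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))
  comp_of <- stats::setNames(mets$compartment, mets$id)
  rnodes <- xml2::xml_find_all(mdl, "./listOfReactions/reaction")
  rxns <- vector("list", length(rnodes))
  for (i in seq_along(rnodes)) {
    rn <- rnodes[[i]]
    rid <- xml2::xml_attr(rn, "id")
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry", default = "1"))
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) - co
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry", default = "1"))
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) + co
    }
    getp <- function(key) if (key %in% names(pv)) pv[[key]] else NULL
    lb <- getp(paste0("lb_", rid)); ub <- getp(paste0("ub_", rid))
    if (is.null(lb) || is.null(ub)) {
      kl <- xml2::xml_find_all(
        rn, "./kineticLaw//parameter | ./kineticLaw//localParameter")
      if (length(kl)) {
        kv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                              xml2::xml_attr(kl, "id"))
        if (is.null(lb) && "LOWER_BOUND" %in% names(kv)) lb <- kv[["LOWER_BOUND"]]
        if (is.null(ub) && "UPPER_BOUND" %in% names(kv)) ub <- kv[["UPPER_BOUND"]]
      }
    }
    if (is.null(lb)) lb <- if (rev) -FLUX_BOUND else 0
    if (is.null(ub)) ub <- FLUX_BOUND
    lines <- note_lines(rn)
    gpr <- note_value(lines, "GENE[_ ]?ASSOCIATION")
    kind <- note_value(lines, "KIND")
    evid <- note_value(lines, "EVIDENCE")
    subs <- note_value(lines, "SUBSYSTEM")
    if (is.null(kind)) {
      comps <- unique(unname(comp_of[names(st)]))
      kind <- if (length(st) == 1L && identical(comps, "extracellular"))
        "exchange"
      else if (length(comps) == 2L) "transport"
      else if (all(st < 0) && grepl("^(dm_|DM_|biomass)", rid))
        "biomass_drain"
      else "enzymatic"
    }
    rxns[[i]] <- reaction(
      rid, st, name = xml2::xml_attr(rn, "name", default = rid),
      reversible = rev, lb = lb, ub = ub,
      gpr = if (is.null(gpr)) "" else gpr, kind = kind,
      evidence = if (is.null(evid)) "not_applicable" else evid,
      subsystem = if (is.null(subs)) "" else subs)
  }
  mlines <- note_lines(mdl)
  bio <- note_value(mlines, "BIOMASS_REACTION")
  comp <- note_value(mlines, "BIOMASS_COMPONENTS")
  phyco_model(mets, rxns,
              biomass_components = if (is.null(comp)) character(0)
              else strsplit(comp, ",")[[1]],
              biomass_reaction = bio)
}

## ---- model statistics ----------------------------------------------------

gpr_genes <- function(gpr) {
  if (!nzchar(gpr)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", gpr), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Model statistics
#'
#' Counts the headline characteristics of a reconstruction: gene-reaction
#' association entries (one per gene-reaction pair), unique reactions,
#' unique ORFs, metabolites, cellular compartments (extracellular
#' excluded), biomass drains, intercellular (cytosol-extracellular) and
#' inter-organelle transporters, and non-enzymatic gap reactions. All
#' counts are invariant under reaction reordering.
#'
#' @param model a `phyco_model`.
#' @param unique_reactions `"id"` (default) counts compartmental copies of
#'   a transformation as distinct; `"stoichiometry"` collapses reactions
#'   with identical compartment-stripped stoichiometry.
#' @return an object of class `model_statistics`.
#' @export
model_statistics <- function(model, unique_reactions = c("id", "stoichiometry")) {
  unique_reactions <- match.arg(unique_reactions)
  rxns <- model$reactions
  genes_per <- lapply(rxns, function(r) gpr_genes(r$gpr))
  kinds <- vapply(rxns, `[[`, "", "kind")
  comp_of <- stats::setNames(model$metabolites$compartment,
                             model$metabolites$id)
  n_unique <- if (unique_reactions == "id") length(rxns) else {
    keys <- vapply(rxns, function(r) {
      st <- r$stoich
      names(st) <- sub("_[cpmxe]$", "", names(st))
      st <- tapply(st, names(st), sum)
      st <- st[st != 0]
      ## pure translocations cancel entirely once compartments are
      ## stripped; keep those distinct by their full stoichiometry
      if (!length(st)) stoich_key(r$stoich, r$reversible)
      else stoich_key(st, r$reversible)
    }, "")
    length(unique(keys))
  }
  trans <- names(rxns)[kinds == "transport"]
  spans_e <- vapply(rxns[trans], function(r)
    "extracellular" %in% comp_of[names(r$stoich)], TRUE)
  drains <- setdiff(names(rxns)[kinds == "biomass_drain"],
                    model$biomass_reaction)
  n_gap <- sum(kinds == "non_enzymatic_gap")
  if (n_gap == 0L)   # untagged models: empty-GPR internal reactions as proxy
    n_gap <- sum(kinds == "enzymatic" &
                   !vapply(rxns, function(r) nzchar(r$gpr), TRUE))
  structure(list(
    gene_reaction_associations = sum(lengths(genes_per)),
    unique_reactions = n_unique,
    unique_orfs = length(unique(unlist(genes_per))),
    metabolites = nrow(model$metabolites),
    compartments = length(setdiff(unique(model$metabolites$compartment),
                                  "extracellular")),
    biomass_drains = length(drains),
    intercellular_transporters = sum(spans_e),
    interorganelle_transporters = sum(!spans_e),
    gap_reactions = n_gap
  ), class = "model_statistics")
}

#' @export
print.model_statistics <- function(x, ...) {
  rows <- c(
    "Gene-reaction-association entries" = x$gene_reaction_associations,
    "Unique metabolic reactions" = x$unique_reactions,
    "Unique ORFs" = x$unique_orfs,
    "Metabolites" = x$metabolites,
    "Cellular compartments" = x$compartments,
    "Biomass drains" = x$biomass_drains,
    "Intercellular transporters" = x$intercellular_transporters,
    "Inter-organelle transporters" = x$interorganelle_transporters,
    "Gaps (non-enzymatic reactions)" = x$gap_reactions
  )
  cat("Model characteristics\n")
  for (i in seq_along(rows))
    cat(sprintf("  %-34s %d\n", names(rows)[i], rows[i]))
  invisible(x)
}

#' Write model statistics as JSON
#' @param stats a [model_statistics()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_statistics <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
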