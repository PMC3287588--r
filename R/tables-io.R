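## Tab-delimited external interfaces: gene-centric reaction tables,
## formula tables, evidence tables and transporter tables.

#' Parse a textual reaction equation
#'
#' Equations use compartment-suffixed metabolite ids, `+` between terms,
#' optional leading coefficients, and `<=>` (reversible) or `-->`
#' (irreversible) as the arrow. One side may be empty (exchange/drain),
#' e.g. `"ac_e <=>"` or `"--> co2_e"`.
#'
#' @param equation equation string.
#' @return list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>"
  else if (grepl("-->", equation, fixed = TRUE)) "-->"
  else stop("equation has no '<=>' or '-->' arrow: ", equation, call. = FALSE)
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))[1:2]
  term_coefs <- function(side, sgn) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    ## split on space-padded plus only, so ids like "x(n+1)" stay intact
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    st <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) next
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term '", tm, "'", call. = FALSE)
        id <- parts[2]
      } else if (length(parts) == 1L) {
        coef <- 1; id <- parts[1]
      } else stop("cannot parse term '", tm, "'", call. = FALSE)
      st[id] <- (if (id %in% names(st)) st[id] else 0) + sgn * coef
    }
    st
  }
  lhs <- term_coefs(sides[1], -1)
  rhs <- term_coefs(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  list(stoich = st[st != 0], reversible = arrow == "<=>")
}

#' Render a reaction's stoichiometry as an equation string
#' @param r a `phyco_reaction`.
#' @return equation string in the format accepted by [parse_equation()].
#' @export
format_equation <- function(r) {
  st <- r$stoich[order(names(r$stoich))]
  fmt <- function(v) {
    paste(vapply(names(v), function(id) {
      co <- abs(v[[id]])
      if (co == 1) id else paste(format(co, digits = 10, trim = TRUE), id)
    }, ""), collapse = " + ")
  }
  lhs <- fmt(st[st < 0]); rhs <- fmt(st[st > 0])
  arrow <- if (r$reversible) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}

#' Read a gene-centric reaction table
#'
#' Columns: `reaction_id`, `name`, `equation`, `gene_association`, `kind`,
#' `evidence`, `subsystem` (header required; extra columns ignored).
#' Metabolites are created from the ids appearing in equations; formulas
#' can be attached afterwards via a formula table.
#'
#' @param path tab-delimited file.
#' @param formulas optional named character vector (or a file readable by
#'   [read_formula_table()]) of metabolite formulas.
#' @param compartmentalized set to `FALSE` for raw gene-centric tables
#'   whose metabolite ids carry no compartment suffix yet (all species are
#'   provisionally placed in the cytosol until [assign_compartments()]).
#' @return a `phyco_model` with no biomass annotation.
#' @export
read_reaction_table <- function(path, formulas = NULL,
                                compartmentalized = TRUE) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("reaction_id", "equation")
  if (!all(need %in% names(tb)))
    stop("reaction table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  opt <- function(col, default) if (col %in% names(tb)) tb[[col]] else
    rep(default, nrow(tb))
  if (is.character(formulas) && length(formulas) == 1L && file.exists(formulas))
    formulas <- read_formula_table(formulas)
  rxns <- vector("list", nrow(tb))
  met_ids <- character(0)
  nm <- opt("name", ""); ga <- opt("gene_association", "")
  kd <- opt("kind", "enzymatic"); ev <- opt("evidence", "not_applicable")
  ss <- opt("subsystem", "")
  for (i in seq_len(nrow(tb))) {
    eq <- parse_equation(tb$equation[i])
    rxns[[i]] <- reaction(tb$reaction_id[i], eq$stoich,
                          name = if (nzchar(nm[i])) nm[i] else tb$reaction_id[i],
                          reversible = eq$reversible, gpr = ga[i],
                          kind = kd[i], evidence = ev[i], subsystem = ss[i])
    met_ids <- union(met_ids, names(eq$stoich))
  }
  mets <- do.call(rbind, lapply(sort(met_ids), function(id) {
    f <- if (!is.null(formulas) && id %in% names(formulas)) formulas[[id]]
    else NA_character_
    metabolite(id, formula = f,
               compartment = if (compartmentalized) NULL else "cytosol",
               is_boundary = compartmentalized && endsWith(id, "_e"))
  }))
  phyco_model(mets, rxns)
}

#' Write a model as a gene-centric reaction table
#' @param model a `phyco_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(model, path) {
  tb <- data.frame(
    reaction_id = names(model$reactions),
    name = vapply(model$reactions, `[[`, "", "name"),
    equation = vapply(model$reactions, format_equation, ""),
    gene_association = vapply(model$reactions, `[[`, "", "gpr"),
    kind = vapply(model$reactions, `[[`, "", "kind"),
    evidence = vapply(model$reactions, `[[`, "", "evidence"),
    subsystem = vapply(model$reactions, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolite formula table
#' @param path tab-delimited file with columns `metabolite_id`, `formula`.
#' @return named character vector id -> Hill formula.
#' @export
read_formula_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stats::setNames(tb$formula, tb$metabolite_id)
}

#' Write a metabolite formula table
#' @param formulas named character vector id -> formula.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_formula_table <- function(formulas, path) {
  tb <- data.frame(metabolite_id = names(formulas),
                   formula = unname(formulas), stringsAsFactors = FALSE)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compartment-evidence table
#'
#' Mirrors a curated localization sheet: one row per (reaction, claimed
#' compartment), with `source` either `"literature"` or `"homolog"` and a
#' free-text `citation`.
#'
#' @param path tab-delimited file with columns `reaction_id`,
#'   `compartment`, `source` and optionally `citation`.
#' @return `data.frame` of evidence records.
#' @export
read_evidence_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("reaction_id", "compartment", "source") %in% names(tb)))
    stop("evidence table needs columns reaction_id, compartment, source",
         call. = FALSE)
  if (!"citation" %in% names(tb)) tb$citation <- ""
  bad <- !tb$source %in% c("literature", "homolog")
  if (any(bad))
    stop("evidence source must be 'literature' or 'homolog' (got: ",
         paste(unique(tb$source[bad]), collapse = ", "), ")", call. = FALSE)
  bad <- !tb$compartment %in% names(COMPARTMENTS)
  if (any(bad))
    stop("unknown compartment in evidence table: ",
         paste(unique(tb$compartment[bad]), collapse = ", "), call. = FALSE)
  tb[c("reaction_id", "compartment", "source", "citation")]
}

#' Read a transporter table
#'
#' @param path tab-delimited file with columns `species_id` (bare chemical
#'   id without compartment suffix), `compartment_a`, `compartment_b`,
#'   `reversible` (`TRUE`/`FALSE`) and optional `cotransport` (an equation
#'   fragment added to the transport reaction, may be empty).
#' @return `data.frame` of transporter entries.
#' @export
read_transporter_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("species_id", "compartment_a", "compartment_b", "reversible")
  if (!all(need %in% names(tb)))
    stop("transporter table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"cotransport" %in% names(tb)) tb$cotransport <- ""
  tb$reversible <- toupper(tb$reversible) %in% c("TRUE", "T", "1", "YES")
  tb
}
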