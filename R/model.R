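# Data model for compartmentalised constraint-based metabolic networks.
# A model holds a metabolite table, a reaction table, per-reaction sparse
# stoichiometry, parsed GPR trees and the gene catalogue; the
# stoichiometric matrix S is assembled on demand.

#' The eight subcellular compartments
#'
#' Compartment vocabulary used throughout: full names are stored in the
#' metabolite table, single-letter codes appear as `[c]`-style suffixes on
#' metabolite ids in the tabular dialect.
#'
#' @format named character vector mapping full name to code.
#' @export
COMPARTMENTS <- c(
  nucleus = "n", cytosol = "c", ER = "r", Golgi = "g",
  peroxisome = "p", lysosome = "l", mitochondria = "m", extracellular = "e"
)

compartment_from_code <- function(code) {
  nm <- names(COMPARTMENTS)[match(code, COMPARTMENTS)]
  if (anyNA(nm)) stop("unknown compartment code(s): ",
                      paste(code[is.na(nm)], collapse = ", "))
  nm
}

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id` (unique, conventionally
#'   carrying a `[c]`-style compartment suffix), `name`, `compartment`
#'   (full name from [COMPARTMENTS]) and optionally `formula` (elemental
#'   formula string, `NA` if unknown).
#' @param reactions data.frame with columns `id` (unique), `reversible`
#'   (logical) and optionally `is_exchange` (logical; inferred as
#'   "touches exactly one metabolite" when missing), `gpr` (rule string),
#'   `subsystem`.
#' @param stoichiometry named list (one entry per reaction id) of named
#'   numeric vectors: metabolite id -> signed coefficient (negative =
#'   substrate in the canonical direction).
#' @param genes optional character vector of gene ids; defaults to the
#'   union of GPR leaves.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  stoichiometry <- stoichiometry[reactions$id]
  if (is.null(reactions$is_exchange)) {
    reactions$is_exchange <- vapply(stoichiometry, length, 1L) == 1L
  }
  gprs <- lapply(reactions$gpr, parse_gpr)
  names(gprs) <- reactions$id
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(gprs, gpr_genes))))
  }
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, gprs = gprs,
         genes = as.character(genes)),
    class = "metabolic_model"
  )
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, compartment vocabulary, that every stoichiometry
#' entry references a declared metabolite with a nonzero coefficient, that
#' every GPR leaf is in the gene catalogue, and the exchange-reaction
#' invariant (an exchange touches exactly one metabolite).
#'
#' @param m a `metabolic_model`.
#' @return `m`, invisibly; errors name the offending entity.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (anyDuplicated(m$metabolites$id)) {
    stop("duplicate metabolite id: ",
         m$metabolites$id[duplicated(m$metabolites$id)][1])
  }
  if (anyDuplicated(m$reactions$id)) {
    stop("duplicate reaction id: ",
         m$reactions$id[duplicated(m$reactions$id)][1])
  }
  bad_comp <- setdiff(unique(m$metabolites$compartment), names(COMPARTMENTS))
  if (length(bad_comp)) {
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "))
  }
  met_ids <- m$metabolites$id
  for (rid in m$reactions$id) {
    st <- m$stoichiometry[[rid]]
    if (is.null(st) || length(st) == 0) {
      stop("reaction '", rid, "' has empty stoichiometry")
    }
    if (any(st == 0)) stop("reaction '", rid, "' has zero coefficient")
    missing <- setdiff(names(st), met_ids)
    if (length(missing)) {
      stop("reaction '", rid, "' references undeclared metabolite '",
           missing[1], "'")
    }
  }
  exch <- m$reactions$id[m$reactions$is_exchange]
  for (rid in exch) {
    if (length(m$stoichiometry[[rid]]) != 1L) {
      stop("exchange reaction '", rid,
           "' must touch exactly one metabolite")
    }
  }
  bad_genes <- setdiff(unlist(lapply(m$gprs, gpr_genes)), m$genes)
  if (length(bad_genes)) {
    stop("GPR references gene(s) not in catalogue: ",
         paste(bad_genes, collapse = ", "))
  }
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions (",
      sum(x$reactions$is_exchange), "exchange ),",
      length(x$genes), "genes\n")
  invisible(x)
}

internal_metabolites <- function(m) {
  m$metabolites$id[m$metabolites$compartment != "extracellular"]
}

#' Assemble the stoichiometric matrix S
#'
#' Entry `(j, i)` is the coefficient of metabolite `j` in reaction `i`;
#' `S %*% v` gives the per-metabolite net production rates for a flux
#' vector `v`.
#'
#' @param m a `metabolic_model`.
#' @param internal_only drop rows of extracellular metabolites.
#' @return a sparse `dgCMatrix` with metabolite/reaction dimnames.
#' @export
stoichiometric_matrix <- function(m, internal_only = FALSE) {
  mets <- if (internal_only) internal_metabolites(m) else m$metabolites$id
  rxns <- m$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_idx <- stats::setNames(seq_along(mets), mets)
  for (k in seq_along(rxns)) {
    st <- m$stoichiometry[[rxns[k]]]
    keep <- names(st) %in% mets
    st <- st[keep]
    if (length(st)) {
      ii <- c(ii, met_idx[names(st)])
      jj <- c(jj, rep.int(k, length(st)))
      xx <- c(xx, unname(st))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Subset a model to a set of reactions
#'
#' @param m a `metabolic_model`.
#' @param rxn_ids reaction ids to keep.
#' @param drop_orphans drop metabolites no longer referenced by any kept
#'   reaction.
#' @return a `metabolic_model`.
#' @export
model_subset <- function(m, rxn_ids, drop_orphans = TRUE) {
  keep <- m$reactions$id %in% rxn_ids
  rx <- m$reactions[keep, , drop = FALSE]
  st <- m$stoichiometry[rx$id]
  mets <- m$metabolites
  if (drop_orphans) {
    used <- unique(unlist(lapply(st, names)))
    mets <- mets[mets$id %in% used, , drop = FALSE]
  }
  metabolic_model(mets, rx, st)
}

# ---- reaction equation strings ------------------------------------------

parse_equation <- function(eq) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<=>", fixed = TRUE)[[1]]
           else strsplit(eq, "=>", fixed = TRUE)[[1]]
  if (!rev && !grepl("=>", eq, fixed = TRUE)) {
    stop("equation lacks '=>' or '<=>': '", eq, "'")
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  lhs <- parse_equation_side(sides[1])
  rhs <- parse_equation_side(sides[2])
  st <- c(-lhs, rhs)
  # collapse duplicated metabolites across sides
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    st <- stats::setNames(as.numeric(st), names(st))
  }
  list(stoichiometry = st, reversible = rev)
}

parse_equation_side <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  coef <- numeric(length(terms)); met <- character(length(terms))
  for (k in seq_along(terms)) {
    mm <- regmatches(terms[k],
                     regexec("^([0-9]*\\.?[0-9]+\\s+)?(\\S+)$", terms[k]))[[1]]
    if (length(mm) == 0) stop("cannot parse equation term '", terms[k], "'")
    coef[k] <- if (nzchar(trimws(mm[2]))) as.numeric(trimws(mm[2])) else 1
    met[k] <- mm[3]
  }
  stats::setNames(coef, met)
}

format_equation <- function(st, reversible) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
  }
  lhs <- -st[st < 0]; rhs <- st[st > 0]
  arrow <- if (reversible) "<=>" else "=>"
  trimws(paste(side(lhs), arrow, side(rhs)))
}

# ---- tabular (TSV) dialect ----------------------------------------------

#' Read a metabolic model
#'
#' Two on-disk formats are supported. `"tsv"` reads `reactions.tsv`
#' (columns `id`, `equation`, `gpr`, `subsystem`, optional `is_exchange`)
#' and `metabolites.tsv` (columns `id`, `name`, `compartment`, optional
#' `formula`) from a directory; equations use `"=>"`/`"<=>"` arrows and
#' an empty side for exchange reactions (e.g. `"glc[e] <=>"`). `"sbml"`
#' reads the SBML Level 3 subset written by [write_model()] (gene
#' associations and formulas carried in notes fields).
#'
#' @param path directory (tsv) or file (sbml).
#' @param format `"tsv"` or `"sbml"`.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "tsv") read_model_tsv(path) else read_model_sbml(path)
}

#' Write a metabolic model
#'
#' Round-trips with [read_model()]: reaction/metabolite sets,
#' stoichiometric coefficients, reversibility and GPR truth tables are
#' preserved.
#'
#' @param m a `metabolic_model`.
#' @param path output directory (tsv) or file (sbml).
#' @param format `"tsv"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  validate_model(m)
  if (format == "tsv") write_model_tsv(m, path) else write_model_sbml(m, path)
  invisible(path)
}

read_model_tsv <- function(dir) {
  rfile <- file.path(dir, "reactions.tsv")
  mfile <- file.path(dir, "metabolites.tsv")
  if (!file.exists(rfile) || !file.exists(mfile)) {
    stop("expected reactions.tsv and metabolites.tsv under '", dir, "'")
  }
  rx <- utils::read.delim(rfile, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  mets <- utils::read.delim(mfile, stringsAsFactors = FALSE, quote = "",
                            comment.char = "", colClasses = "character")
  if (nrow(mets)) mets$formula[!nzchar(trimws(
    if (is.null(mets$formula)) rep("", nrow(mets)) else mets$formula))] <- NA
  st <- list(); revs <- logical(nrow(rx))
  for (k in seq_len(nrow(rx))) {
    pe <- tryCatch(parse_equation(rx$equation[k]), error = function(e) {
      stop("reaction '", rx$id[k], "': ", conditionMessage(e))
    })
    st[[rx$id[k]]] <- pe$stoichiometry
    revs[k] <- pe$reversible
  }
  reactions <- data.frame(id = rx$id, reversible = revs,
                          stringsAsFactors = FALSE)
  if (!is.null(rx$is_exchange)) {
    reactions$is_exchange <- tolower(rx$is_exchange) %in% c("true", "1", "yes")
  }
  reactions$gpr <- if (is.null(rx$gpr)) "" else rx$gpr
  reactions$subsystem <- if (is.null(rx$subsystem)) NA_character_
                         else rx$subsystem
  metabolic_model(mets, reactions, st)
}

write_model_tsv <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rx <- data.frame(
    id = m$reactions$id,
    equation = vapply(m$reactions$id, function(rid) {
      format_equation(m$stoichiometry[[rid]],
                      m$reactions$reversible[m$reactions$id == rid])
    }, character(1)),
    gpr = vapply(m$gprs, deparse_gpr, character(1)),
    subsystem = ifelse(is.na(m$reactions$subsystem), "",
                       m$reactions$subsystem),
    is_exchange = m$reactions$is_exchange,
    stringsAsFactors = FALSE
  )
  mets <- m$metabolites
  mets$formula[is.na(mets$formula)] <- ""
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mets[, c("id", "name", "compartment", "formula")],
                     file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

# ---- SBML Level 3 subset -------------------------------------------------
# Ids are sanitised into SIds; original ids, formulas, gene associations
# and subsystems travel in <notes> using the COBRA-style KEY: value
# convention, which keeps the files readable by generic SBML tooling.

make_sid <- function(prefix, id) {
  paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))
}

sbml_notes <- function(kv) {
  kv <- kv[!is.na(kv) & nzchar(kv)]
  if (!length(kv)) return(NULL)
  paste0("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
         paste0("<p>", names(kv), ": ", kv, "</p>", collapse = ""),
         "</body></notes>")
}

write_model_sbml <- function(m, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
           " level=\"3\" version=\"1\">"),
    "<model id=\"model\">",
    "<listOfCompartments>"
  )
  for (comp in unique(m$metabolites$compartment)) {
    lines <- c(lines, paste0("<compartment id=\"", COMPARTMENTS[[comp]],
                             "\" name=\"", comp, "\" constant=\"true\"/>"))
  }
  lines <- c(lines, "</listOfCompartments>", "<listOfSpecies>")
  for (k in seq_len(nrow(m$metabolites))) {
    row <- m$metabolites[k, ]
    notes <- sbml_notes(c(
      ORIGINAL_ID = esc(row$id),
      FORMULA = if (is.na(row$formula)) "" else esc(row$formula)))
    lines <- c(lines, paste0(
      "<species id=\"", make_sid("M_", row$id), "\" name=\"",
      esc(row$name), "\" compartment=\"", COMPARTMENTS[[row$compartment]],
      "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
      " constant=\"false\"",
      if (is.null(notes)) "/>" else paste0(">", notes, "</species>")))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfReactions>")
  sid_of <- stats::setNames(make_sid("M_", m$metabolites$id),
                            m$metabolites$id)
  for (k in seq_len(nrow(m$reactions))) {
    row <- m$reactions[k, ]
    st <- m$stoichiometry[[row$id]]
    gpr <- deparse_gpr(m$gprs[[row$id]])
    notes <- sbml_notes(c(
      ORIGINAL_ID = esc(row$id),
      GENE_ASSOCIATION = esc(gpr),
      SUBSYSTEM = if (is.na(row$subsystem)) "" else esc(row$subsystem),
      EXCHANGE = if (row$is_exchange) "true" else ""))
    ref <- function(v) paste0(
      "<speciesReference species=\"", sid_of[names(v)],
      "\" stoichiometry=\"", abs(unname(v)), "\" constant=\"true\"/>",
      collapse = "")
    lhs <- st[st < 0]; rhs <- st[st > 0]
    body <- paste0(
      if (is.null(notes)) "" else notes,
      if (length(lhs)) paste0("<listOfReactants>", ref(lhs),
                              "</listOfReactants>") else "",
      if (length(rhs)) paste0("<listOfProducts>", ref(rhs),
                              "</listOfProducts>") else "")
    lines <- c(lines, paste0(
      "<reaction id=\"", make_sid("R_", row$id), "\" reversible=\"",
      tolower(row$reversible), "\" fast=\"false\">", body, "</reaction>"))
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
}

sbml_note_value <- function(node, key) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='p']")
  for (p in ps) {
    txt <- xml2::xml_text(p)
    if (startsWith(txt, paste0(key, ": "))) {
      return(substring(txt, nchar(key) + 3L))
    }
  }
  NA_character_
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  comp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='compartment']")
  comp_name <- stats::setNames(
    xml2::xml_attr(comp_nodes, "name"), xml2::xml_attr(comp_nodes, "id"))
  mets <- data.frame(
    sid = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = unname(comp_name[xml2::xml_attr(sp_nodes, "compartment")]),
    stringsAsFactors = FALSE)
  mets$id <- vapply(seq_along(sp_nodes), function(k) {
    orig <- sbml_note_value(sp_nodes[[k]], "ORIGINAL_ID")
    if (is.na(orig)) mets$sid[k] else orig
  }, character(1))
  mets$formula <- vapply(sp_nodes, sbml_note_value, character(1),
                         key = "FORMULA")
  sid_to_id <- stats::setNames(mets$id, mets$sid)
  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  ids <- character(length(rx_nodes)); revs <- logical(length(rx_nodes))
  gprs <- character(length(rx_nodes)); subs <- character(length(rx_nodes))
  exch <- logical(length(rx_nodes)); st <- list()
  for (k in seq_along(rx_nodes)) {
    node <- rx_nodes[[k]]
    orig <- sbml_note_value(node, "ORIGINAL_ID")
    ids[k] <- if (is.na(orig)) xml2::xml_attr(node, "id") else orig
    revs[k] <- tolower(xml2::xml_attr(node, "reversible")) == "true"
    g <- sbml_note_value(node, "GENE_ASSOCIATION")
    gprs[k] <- if (is.na(g)) "" else g
    subs[k] <- sbml_note_value(node, "SUBSYSTEM")
    ex <- sbml_note_value(node, "EXCHANGE")
    exch[k] <- !is.na(ex) && ex == "true"
    side <- function(tag, sign) {
      refs <- xml2::xml_find_all(node, paste0(
        ".//*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      sids <- xml2::xml_attr(refs, "species")
      mids <- sid_to_id[sids]
      if (anyNA(mids)) {
        stop("reaction '", ids[k], "' references undeclared species '",
             sids[is.na(mids)][1], "'")
      }
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      unname(mids))
    }
    st[[ids[k]]] <- c(side("listOfReactants", -1), side("listOfProducts", 1))
  }
  reactions <- data.frame(id = ids, reversible = revs, is_exchange = exch,
                          gpr = gprs, subsystem = subs,
                          stringsAsFactors = FALSE)
  metabolic_model(mets[, c("id", "name", "compartment", "formula")],
                  reactions, st)
}
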