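# Curation pipeline turning a raw merged reconstruction into a connected,
# flux-consistent template: generic-metabolite blacklist, elemental
# balance, directionality filter, dead-end (unconnected) removal, and
# LP-based flux-consistency pruning. Preprocessing LPs use the strict
# steady state (S v = 0); the accumulation relaxation is specific to the
# extraction MILP.

#' Parse an elemental formula
#'
#' @param x formula string such as `"C6H12O6"`; multi-letter elements
#'   (`Na`, `Cl`, ...) are supported.
#' @return named integer vector element -> count.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (is.na(x) || !nzchar(x)) return(stats::setNames(integer(0), character(0)))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", x)) {
    stop("malformed formula: '", x, "'")
  }
  mm <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  el <- sub("[0-9]*$", "", mm)
  ct <- as.integer(ifelse(grepl("[0-9]", mm), sub("^[A-Za-z]+", "", mm), 1L))
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Remove reactions touching blacklisted (generic) metabolites
#'
#' Metabolites are matched by full id, by base id (compartment suffix
#' stripped) and by name, case-insensitively for names. All reactions
#' touching a blacklisted metabolite are removed, then the blacklisted
#' and any newly orphaned metabolites.
#'
#' @param model a `metabolic_model`.
#' @param blacklist character vector of metabolite ids or names.
#' @return list with elements `model` and `removed` (data.frame
#'   `reaction`, `reason`).
#' @export
remove_blacklisted <- function(model, blacklist) {
  if (!length(blacklist)) {
    return(list(model = model,
                removed = data.frame(reaction = character(0),
                                     reason = character(0))))
  }
  base_id <- sub("\\[[a-z]\\]$", "", model$metabolites$id)
  hit <- model$metabolites$id %in% blacklist |
    base_id %in% blacklist |
    tolower(model$metabolites$name) %in% tolower(blacklist)
  bad_mets <- model$metabolites$id[hit]
  touched <- vapply(model$reactions$id, function(rid) {
    any(names(model$stoichiometry[[rid]]) %in% bad_mets)
  }, logical(1))
  keep <- model$reactions$id[!touched]
  out <- if (length(keep)) model_subset(model, keep) else
    empty_model_like(model)
  list(model = out,
       removed = data.frame(reaction = model$reactions$id[touched],
                            reason = rep("generic_metabolite", sum(touched)),
                            stringsAsFactors = FALSE))
}

empty_model_like <- function(model) {
  metabolic_model(model$metabolites[0, , drop = FALSE],
                  model$reactions[0, , drop = FALSE],
                  stats::setNames(list(), character(0)))
}

#' Check elemental balance of reactions
#'
#' A reaction is unbalanced iff any element other than hydrogen has a
#' nonzero net coefficient; hydrogen imbalance alone is tolerated
#' (protonation states are unreliable and proton exchange is free).
#' Reactions involving a metabolite without a formula are uncheckable,
#' not unbalanced. Exchange reactions are never checked (they are
#' unbalanced by design).
#'
#' @param model a `metabolic_model`.
#' @return list with character vectors `unbalanced` and `uncheckable`.
#' @export
check_mass_balance <- function(model) {
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  parsed <- lapply(formulas, function(f) {
    if (is.na(f)) NULL else parse_formula(f)
  })
  unbalanced <- character(0); uncheckable <- character(0)
  for (rid in model$reactions$id) {
    if (model$reactions$is_exchange[model$reactions$id == rid]) next
    st <- model$stoichiometry[[rid]]
    fl <- parsed[names(st)]
    if (any(vapply(fl, is.null, logical(1)))) {
      uncheckable <- c(uncheckable, rid)
      next
    }
    net <- stats::setNames(numeric(0), character(0))
    for (k in seq_along(st)) {
      f <- fl[[k]]
      for (el in names(f)) {
        net[el] <- (if (el %in% names(net)) net[el] else 0) +
          st[k] * f[[el]]
      }
    }
    net <- net[names(net) != "H"]
    if (any(abs(net) > 1e-9)) unbalanced <- c(unbalanced, rid)
  }
  list(unbalanced = unbalanced, uncheckable = uncheckable)
}

# flux bounds for preprocessing LPs; exchange handling per flag
preprocess_bounds <- function(model, open_all_exchanges, close_uptake,
                              M = 1000) {
  n <- nrow(model$reactions)
  lb <- ifelse(model$reactions$reversible, -M, 0)
  ub <- rep(M, n)
  if (open_all_exchanges) {
    lb[model$reactions$is_exchange] <- -M
    ub[model$reactions$is_exchange] <- M
  }
  if (close_uptake) {
    for (k in which(model$reactions$is_exchange)) {
      coef <- model$stoichiometry[[model$reactions$id[k]]][1]
      # uptake produces the metabolite: forbid coef * v > 0
      if (coef > 0) ub[k] <- 0 else lb[k] <- 0
    }
  }
  list(lb = lb, ub = ub)
}

#' Leak test: can the closed network create metabolites from nothing?
#'
#' With every exchange restricted to secretion, each test metabolite's
#' net production is maximised (all other internal metabolites at steady
#' state). Any metabolite with attainable production above `tol` is
#' flagged: it indicates an unbalanced cycle gaining mass, energy or
#' redox power.
#'
#' @param model a `metabolic_model`.
#' @param metabolites metabolite ids to test (default: all internal).
#' @param tol production threshold.
#' @param M flux bound.
#' @return data.frame `metabolite`, `max_production`, `leaky`.
#' @export
leak_test <- function(model, metabolites = NULL, tol = 1e-6, M = 1000) {
  ints <- internal_metabolites(model)
  if (is.null(metabolites)) metabolites <- ints
  missing <- setdiff(metabolites, ints)
  if (length(missing)) stop("not internal metabolite(s): ",
                            paste(missing, collapse = ", "))
  S <- stoichiometric_matrix(model, internal_only = TRUE)
  b <- preprocess_bounds(model, open_all_exchanges = FALSE,
                         close_uptake = TRUE, M = M)
  tasks <- lapply(metabolites, function(mid) {
    j <- match(mid, rownames(S))
    rlb <- rep(0, nrow(S)); rub <- rep(0, nrow(S))
    rub[j] <- Inf
    milp_task(c = as.numeric(S[j, ]), A = S, rlb = rlb, rub = rub,
              lb = b$lb, ub = b$ub, sense = "max", id = mid)
  })
  res <- milp_batch(tasks)
  prod <- vapply(res, function(r) {
    if (r$status == "optimal") r$objective else NA_real_
  }, numeric(1))
  bad_status <- vapply(res, function(r)
    !(r$status %in% c("optimal", "infeasible")), logical(1))
  if (any(bad_status)) {
    stop("leak-test LP failed for: ",
         paste(metabolites[bad_status], collapse = ", "))
  }
  data.frame(metabolite = metabolites, max_production = prod,
             leaky = !is.na(prod) & prod > tol,
             stringsAsFactors = FALSE)
}

#' Drop reactions lacking directionality information
#'
#' @param model a `metabolic_model`.
#' @param directionality_known reaction ids with known directionality;
#'   `NULL` means all are known.
#' @return list `model`, `removed`.
#' @export
remove_no_directionality <- function(model, directionality_known = NULL) {
  if (is.null(directionality_known)) {
    return(list(model = model,
                removed = data.frame(reaction = character(0),
                                     reason = character(0))))
  }
  bad <- setdiff(model$reactions$id, directionality_known)
  keep <- setdiff(model$reactions$id, bad)
  out <- if (length(keep)) model_subset(model, keep) else
    empty_model_like(model)
  list(model = out,
       removed = data.frame(reaction = bad, reason = rep("no_directionality", length(bad)),
                            stringsAsFactors = FALSE))
}

# producibility closure: a metabolite is producible if it can be imported
# or is the product of a reaction all of whose substrates are producible
producible_closure <- function(model) {
  producible <- character(0)
  orients <- list()
  for (k in seq_len(nrow(model$reactions))) {
    st <- model$stoichiometry[[model$reactions$id[k]]]
    orients[[length(orients) + 1L]] <-
      list(sub = names(st)[st < 0], prod = names(st)[st > 0])
    if (model$reactions$reversible[k]) {
      orients[[length(orients) + 1L]] <-
        list(sub = names(st)[st > 0], prod = names(st)[st < 0])
    }
  }
  repeat {
    added <- FALSE
    for (o in orients) {
      if (all(o$sub %in% producible)) {
        new <- setdiff(o$prod, producible)
        if (length(new)) {
          producible <- c(producible, new)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  producible
}

#' Remove unconnected (dead-end-substrate) reactions
#'
#' A reaction is kept iff in at least one of its allowed directions every
#' substrate is producible, where producibility is the closure of
#' "importable through an exchange or producible by a supported
#' reaction". Products that merely accumulate do not block a reaction.
#'
#' @param model a `metabolic_model`.
#' @return list `model`, `removed`, `producible`.
#' @export
remove_unconnected <- function(model) {
  producible <- producible_closure(model)
  supported <- vapply(seq_len(nrow(model$reactions)), function(k) {
    st <- model$stoichiometry[[model$reactions$id[k]]]
    fwd <- all(names(st)[st < 0] %in% producible)
    bwd <- model$reactions$reversible[k] &&
      all(names(st)[st > 0] %in% producible)
    fwd || bwd
  }, logical(1))
  keep <- model$reactions$id[supported]
  out <- if (length(keep)) model_subset(model, keep) else
    empty_model_like(model)
  list(model = out,
       removed = data.frame(reaction = model$reactions$id[!supported],
                            reason = rep("unconnected", sum(!supported)),
                            stringsAsFactors = FALSE),
       producible = producible)
}

#' Remove reactions unable to carry flux
#'
#' Keeps exactly the reactions for which some steady-state flux
#' distribution (all exchanges open) attains `|v| >= tau`. Implemented as
#' per-reaction flux maximisation (and minimisation for reversible
#' reactions), batched into one solver call; the maximising flux vector
#' is stored as a certificate for every retained reaction.
#'
#' @param model a `metabolic_model`.
#' @param open_all_exchanges open every exchange in both directions.
#' @param tau minimum detectable flux.
#' @param M flux bound.
#' @return list `model`, `removed`, `certificates` (list reaction ->
#'   flux vector).
#' @export
flux_consistent <- function(model, open_all_exchanges = TRUE, tau = 1e-4,
                            M = 1000) {
  n <- nrow(model$reactions)
  if (n == 0) {
    return(list(model = model,
                removed = data.frame(reaction = character(0),
                                     reason = character(0)),
                certificates = list()))
  }
  S <- stoichiometric_matrix(model, internal_only = TRUE)
  b <- preprocess_bounds(model, open_all_exchanges, close_uptake = FALSE,
                         M = M)
  rlb <- rep(0, nrow(S)); rub <- rep(0, nrow(S))
  tasks <- list()
  for (k in seq_len(n)) {
    cc <- rep(0, n); cc[k] <- 1
    tasks[[length(tasks) + 1L]] <-
      milp_task(c = cc, A = S, rlb = rlb, rub = rub, lb = b$lb, ub = b$ub,
                sense = "max", id = paste0("max:", k))
    if (b$lb[k] < 0) {
      tasks[[length(tasks) + 1L]] <-
        milp_task(c = cc, A = S, rlb = rlb, rub = rub, lb = b$lb,
                  ub = b$ub, sense = "min", id = paste0("min:", k))
    }
  }
  res <- milp_batch(tasks)
  ok <- logical(n)
  certificates <- vector("list", n)
  for (r in res) {
    if (r$status != "optimal") next
    parts <- strsplit(r$id, ":", fixed = TRUE)[[1]]
    k <- as.integer(parts[2])
    hit <- (parts[1] == "max" && r$objective >= tau * (1 - 1e-6)) ||
      (parts[1] == "min" && r$objective <= -tau * (1 - 1e-6))
    if (hit && !ok[k]) {
      ok[k] <- TRUE
      certificates[[k]] <- stats::setNames(r$x, model$reactions$id)
    }
  }
  keep <- model$reactions$id[ok]
  names(certificates) <- model$reactions$id
  out <- if (length(keep)) model_subset(model, keep) else
    empty_model_like(model)
  list(model = out,
       removed = data.frame(reaction = model$reactions$id[!ok],
                            reason = rep("flux_inconsistent", sum(!ok)),
                            stringsAsFactors = FALSE),
       certificates = certificates[ok])
}

model_counts <- function(model) {
  genes <- unique(unlist(lapply(model$gprs, gpr_genes)))
  c(reactions = nrow(model$reactions),
    metabolites = nrow(model$metabolites),
    genes = length(genes))
}

#' Build a connected, flux-consistent template model
#'
#' Applies the curation stages in order: (1) generic-metabolite blacklist
#' and elemental-balance filter (with optional curated replacement
#' reactions applied first), (2) directionality filter, (3)+(4)
#' dead-end removal and flux-consistency pruning iterated to a joint
#' fixed point (a flux-inconsistency removal can create new dead ends).
#' Idempotent: running the result through again removes nothing.
#'
#' @param model a `metabolic_model`.
#' @param blacklist metabolite ids/names to ban.
#' @param directionality_known reaction ids with known directionality
#'   (`NULL`: all).
#' @param replacements optional `metabolic_model` whose reactions replace
#'   same-id reactions before the balance check (curated fixes).
#' @param tau minimum detectable flux for the consistency stage.
#' @param M flux bound.
#' @return list `model` (the template) and `report` (a
#'   `curation_report`).
#' @export
build_template <- function(model, blacklist = character(),
                           directionality_known = NULL,
                           replacements = NULL, tau = 1e-4, M = 1000) {
  stages <- list()
  counts <- list(input = model_counts(model))
  if (!is.null(replacements)) {
    for (rid in intersect(replacements$reactions$id, model$reactions$id)) {
      model$stoichiometry[[rid]] <- replacements$stoichiometry[[rid]]
      model$reactions[model$reactions$id == rid, "reversible"] <-
        replacements$reactions$reversible[replacements$reactions$id == rid]
    }
    validate_model(model)
  }
  st1 <- remove_blacklisted(model, blacklist)
  model <- st1$model
  bal <- check_mass_balance(model)
  removed_bal <- data.frame(reaction = bal$unbalanced, reason = rep("unbalanced", length(bal$unbalanced)),
                            stringsAsFactors = FALSE)
  if (length(bal$unbalanced)) {
    keep <- setdiff(model$reactions$id, bal$unbalanced)
    model <- if (length(keep)) model_subset(model, keep) else
      empty_model_like(model)
  }
  stages$blacklist_balance <- rbind(st1$removed, removed_bal)
  counts$blacklist_balance <- model_counts(model)
  st2 <- remove_no_directionality(model, directionality_known)
  model <- st2$model
  stages$directionality <- st2$removed
  counts$directionality <- model_counts(model)
  unconnected_rm <- data.frame(reaction = character(0),
                               reason = character(0))
  inconsistent_rm <- data.frame(reaction = character(0),
                                reason = character(0))
  repeat {
    st3 <- remove_unconnected(model)
    model <- st3$model
    unconnected_rm <- rbind(unconnected_rm, st3$removed)
    st4 <- flux_consistent(model, open_all_exchanges = TRUE, tau = tau,
                           M = M)
    model <- st4$model
    inconsistent_rm <- rbind(inconsistent_rm, st4$removed)
    if (nrow(st3$removed) == 0 && nrow(st4$removed) == 0) break
    if (nrow(model$reactions) == 0) break
  }
  stages$unconnected <- unconnected_rm
  counts$unconnected <- NULL  # joint stage; counts reported together
  stages$flux_consistency <- inconsistent_rm
  counts$connected_consistent <- model_counts(model)
  if (nrow(model$reactions) == 0) {
    warning("template is empty after preprocessing")
  }
  report <- structure(list(stages = stages,
                           counts = do.call(rbind, counts)),
                      class = "curation_report")
  list(model = model, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation_report\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-20s removed %d reaction(s)\n", s, nrow(x$stages[[s]])))
  }
  cat("counts (reactions / metabolites / genes):\n")
  print(x$counts)
  invisible(x)
}

#' Serialise a curation report to JSON
#'
#' @param report a `curation_report`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
curation_report_json <- function(report, path = NULL) {
  obj <- list(
    stages = lapply(report$stages, function(df) {
      list(removed = df$reaction, reasons = df$reason)
    }),
    counts = as.data.frame(report$counts))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
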