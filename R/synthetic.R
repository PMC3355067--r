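# Synthetic stoichiometric networks with planted active subnetworks and
# simulated evidence. The generator grows a bipartite metabolite-reaction
# graph from a set of exchanged seed metabolites so that every reaction's
# substrates are producible by construction; secretion outlets are added
# until the network (and the planted subnetwork on its own) is
# flux-consistent. The planted reactions are generated first and form the
# ground-truth active network used to score recovery.

#' Specification of a synthetic benchmark instance
#'
#' Defaults describe the stated world used across the test-suite: a
#' 40-metabolite, 50-reaction connected network, 30% reversible
#' reactions, seed exchanges on 15% of the metabolites, half the
#' reactions planted as the active subnetwork, a 5% evidence mislabeling
#' rate, lognormal expression noise (sigma 0.5) over 8 tissues.
#'
#' @param n_metabolites,n_reactions network size; requires
#'   `n_reactions >= n_metabolites / 3` for connectivity.
#' @param reversible_fraction probability a reaction is reversible.
#' @param exchange_fraction fraction of metabolites with seed exchanges.
#' @param planted_fraction fraction of reactions in the active set.
#' @param hpa_noise_rate probability a gene's staining label is flipped
#'   (planted -> absent or absent -> positive).
#' @param expression_lognormal_sigma sdlog of the expression model.
#' @param n_tissues number of simulated tissues.
#' @param seed integer; fixes all randomness downstream.
#' @return a list with class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 40, n_reactions = 50,
                           reversible_fraction = 0.3,
                           exchange_fraction = 0.15,
                           planted_fraction = 0.5,
                           hpa_noise_rate = 0.05,
                           expression_lognormal_sigma = 0.5,
                           n_tissues = 8, seed = 1L) {
  fracs <- c(reversible_fraction, exchange_fraction, planted_fraction,
             hpa_noise_rate)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            n_metabolites >= 3, n_tissues >= 1,
            expression_lognormal_sigma >= 0)
  if (n_reactions < n_metabolites / 3) {
    stop("need n_reactions >= n_metabolites / 3 for connectivity")
  }
  structure(list(n_metabolites = n_metabolites, n_reactions = n_reactions,
                 reversible_fraction = reversible_fraction,
                 exchange_fraction = exchange_fraction,
                 planted_fraction = planted_fraction,
                 hpa_noise_rate = hpa_noise_rate,
                 expression_lognormal_sigma = expression_lognormal_sigma,
                 n_tissues = n_tissues, seed = as.integer(seed)),
            class = "synthetic_spec")
}

add_exchanges <- function(model, met_ids) {
  met_ids <- setdiff(met_ids, unlist(lapply(
    model$stoichiometry[model$reactions$id[model$reactions$is_exchange]],
    names)))
  if (!length(met_ids)) return(model)
  rx <- model$reactions
  st <- model$stoichiometry
  for (mid in met_ids) {
    rid <- paste0("EX_", sub("\\[[a-z]\\]$", "", mid))
    while (rid %in% rx$id) rid <- paste0(rid, "x")
    rx <- rbind(rx, data.frame(id = rid, reversible = TRUE,
                               is_exchange = TRUE, gpr = "",
                               subsystem = NA_character_,
                               stringsAsFactors = FALSE))
    st[[rid]] <- stats::setNames(-1, mid)
  }
  metabolic_model(model$metabolites, rx, st)
}

exchange_ids <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

# add secretion outlets until every reaction in scope can carry flux
make_consistent <- function(model, scope, tau = 1e-4, M = 1000,
                            max_rounds = 5) {
  for (round in seq_len(max_rounds)) {
    sub <- model_subset(model, union(scope, exchange_ids(model)))
    fc <- flux_consistent(sub, open_all_exchanges = TRUE, tau = tau, M = M)
    blocked <- intersect(fc$removed$reaction, scope)
    if (!length(blocked)) return(model)
    mets <- unique(unlist(lapply(model$stoichiometry[blocked], names)))
    model <- add_exchanges(model, mets)
  }
  stop("could not make the network flux-consistent; ",
       "increase exchange_fraction")
}

#' Generate a random connected stoichiometric network
#'
#' @param spec a [synthetic_spec()].
#' @param verify LP-verify (and repair with additional exchanges) that
#'   the planted subnetwork and the full network are flux-consistent.
#' @return list `model` (a `metabolic_model` with one gene per
#'   non-exchange reaction), `planted` (reaction ids of the active
#'   subnetwork).
#' @export
generate_network <- function(spec, verify = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nm <- spec$n_metabolites
  mets <- data.frame(
    id = sprintf("m%03d[c]", seq_len(nm)),
    name = sprintf("metabolite %d", seq_len(nm)),
    compartment = "cytosol", formula = NA_character_,
    stringsAsFactors = FALSE)
  n_seed <- max(2L, ceiling(spec$exchange_fraction * nm))
  seed_mets <- mets$id[seq_len(n_seed)]
  rx <- data.frame(id = character(0), reversible = logical(0),
                   is_exchange = logical(0), gpr = character(0),
                   subsystem = character(0), stringsAsFactors = FALSE)
  st <- list()
  for (mid in seed_mets) {
    rid <- paste0("EX_", sub("\\[[a-z]\\]$", "", mid))
    rx <- rbind(rx, data.frame(id = rid, reversible = TRUE,
                               is_exchange = TRUE, gpr = "",
                               subsystem = NA_character_,
                               stringsAsFactors = FALSE))
    st[[rid]] <- stats::setNames(-1, mid)
  }
  producible <- seed_mets
  unproduced <- setdiff(mets$id, seed_mets)
  n_planted <- max(1L, round(spec$planted_fraction * spec$n_reactions))
  for (r in seq_len(spec$n_reactions)) {
    rid <- sprintf("r%03d", r)
    ns <- sample(1:2, 1)
    subs <- sample(producible, min(ns, length(producible)))
    np <- sample(1:2, 1)
    pool_new <- sample(unproduced)
    prods <- utils::head(pool_new, np)
    if (length(prods) < np) {
      extra <- setdiff(mets$id, c(subs, prods))
      prods <- c(prods, sample(extra, min(np - length(prods),
                                          length(extra))))
    }
    prods <- setdiff(prods, subs)
    if (!length(prods)) prods <- sample(setdiff(mets$id, subs), 1)
    coefs <- c(-sample(c(1, 2), length(subs), replace = TRUE,
                       prob = c(0.85, 0.15)),
               sample(c(1, 2), length(prods), replace = TRUE,
                      prob = c(0.85, 0.15)))
    st[[rid]] <- stats::setNames(coefs, c(subs, prods))
    rx <- rbind(rx, data.frame(
      id = rid,
      reversible = stats::runif(1) < spec$reversible_fraction,
      is_exchange = FALSE, gpr = paste0("g_", rid),
      subsystem = NA_character_, stringsAsFactors = FALSE))
    producible <- union(producible, prods)
    unproduced <- setdiff(unproduced, prods)
  }
  model <- metabolic_model(mets, rx, st)
  planted <- sprintf("r%03d", seq_len(n_planted))
  # secretion outlets for terminal products keep steady-state flux open
  consumed <- unique(unlist(lapply(
    model$stoichiometry[!model$reactions$is_exchange],
    function(s) names(s)[s < 0])))
  produced <- unique(unlist(lapply(
    model$stoichiometry[!model$reactions$is_exchange],
    function(s) names(s)[s > 0])))
  model <- add_exchanges(model, setdiff(produced, consumed))
  if (verify) {
    model <- make_consistent(model, planted)
    non_exch <- model$reactions$id[!model$reactions$is_exchange]
    model <- make_consistent(model, non_exch)
  }
  list(model = model, planted = planted)
}

#' Simulate per-gene evidence for a generated network
#'
#' Genes of planted reactions are labelled with a positive staining
#' level in the target tissue (mixture `level_mix`), all others
#' `"absent"`; labels flip with probability `hpa_noise_rate`. Expression
#' signals are lognormal in every tissue with a 4-fold elevated mean for
#' planted genes in the target tissue.
#'
#' @param model a generated `metabolic_model`.
#' @param planted planted reaction ids.
#' @param spec the [synthetic_spec()] used for generation.
#' @param target_tissue tissue receiving the planted signal.
#' @param level_mix named probabilities over `high`/`medium`/`low` for
#'   planted genes.
#' @return an [evidence_table()] with staining calls in the target
#'   tissue and expression signals in all tissues.
#' @export
simulate_evidence <- function(model, planted, spec,
                              target_tissue = "t1",
                              level_mix = c(high = 1/3, medium = 1/3,
                                            low = 1/3)) {
  set.seed(spec$seed + 1L)
  tissues <- paste0("t", seq_len(spec$n_tissues))
  stopifnot(target_tissue %in% tissues)
  ne <- model$reactions$id[!model$reactions$is_exchange]
  gene_of <- vapply(ne, function(rid) {
    g <- gpr_genes(model$gprs[[rid]])
    if (length(g)) g[1] else NA_character_
  }, character(1))
  genes <- unique(stats::na.omit(unname(gene_of)))
  planted_genes <- unique(stats::na.omit(unname(gene_of[planted])))
  rows <- list()
  for (g in genes) {
    is_planted <- g %in% planted_genes
    lvl <- if (is_planted) {
      sample(names(level_mix), 1, prob = level_mix)
    } else "absent"
    if (stats::runif(1) < spec$hpa_noise_rate) {
      lvl <- if (lvl == "absent") {
        sample(names(level_mix), 1, prob = level_mix)
      } else "absent"
    }
    meanlog <- log(100) +
      ifelse(tissues == target_tissue & is_planted, log(4), 0)
    sig <- stats::rlnorm(length(tissues), meanlog = meanlog,
                         sdlog = spec$expression_lognormal_sigma)
    rows[[g]] <- data.frame(
      gene = g, tissue = tissues,
      hpa_level = ifelse(tissues == target_tissue, lvl, NA_character_),
      expression_signal = sig, stringsAsFactors = FALSE)
  }
  evidence_table(do.call(rbind, rows))
}

#' Simulate two groups of extracted-style networks
#'
#' All networks share the planted core; `n_differential_features` decoy
#' reactions are present in group a with probability `p_in_a` and in
#' group b with probability `p_in_b`; the remaining decoys appear
#' independently in every network with probability `p_background`.
#'
#' @param spec a [synthetic_spec()].
#' @param n_group_a,n_group_b group sizes.
#' @param n_differential_features number of planted group differences
#'   (at most the number of decoy reactions).
#' @param p_in_a,p_in_b,p_background presence probabilities.
#' @return list `models` (named list), `groups` (named character vector
#'   label -> `"a"`/`"b"`), `truth` (differential reaction ids),
#'   `truth_genes`, `base` (the template).
#' @export
simulate_network_groups <- function(spec, n_group_a = 16, n_group_b = 24,
                                    n_differential_features = 10,
                                    p_in_a = 0.95, p_in_b = 0.05,
                                    p_background = 0.5) {
  gen <- generate_network(spec, verify = FALSE)
  base <- gen$model
  core <- gen$planted
  decoys <- setdiff(base$reactions$id[!base$reactions$is_exchange], core)
  if (n_differential_features > length(decoys)) {
    stop("n_differential_features exceeds the ", length(decoys),
         " available decoy reactions")
  }
  set.seed(spec$seed + 2L)
  diff_feats <- if (n_differential_features)
    sample(decoys, n_differential_features) else character(0)
  bg <- setdiff(decoys, diff_feats)
  labels <- c(paste0("a", seq_len(n_group_a)),
              paste0("b", seq_len(n_group_b)))
  groups <- stats::setNames(rep(c("a", "b"), c(n_group_a, n_group_b)),
                            labels)
  models <- stats::setNames(vector("list", length(labels)), labels)
  for (lab in labels) {
    p_diff <- if (groups[[lab]] == "a") p_in_a else p_in_b
    keep <- c(core,
              diff_feats[stats::runif(length(diff_feats)) < p_diff],
              bg[stats::runif(length(bg)) < p_background])
    models[[lab]] <- model_subset(base, union(keep, exchange_ids(base)))
  }
  truth_genes <- unlist(lapply(diff_feats, function(rid) {
    gpr_genes(base$gprs[[rid]])
  }))
  list(models = models, groups = groups, truth = diff_feats,
       truth_genes = unique(truth_genes), base = base)
}
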