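# Comparative analysis across sets of extracted networks: binary
# presence matrices, hypergeometric enrichment, Reporter Metabolite
# scoring, bootstrapped average-linkage clustering, and core/unique
# feature statistics.

#' Feature-by-network presence matrix
#'
#' @param models named list of `metabolic_model`s (names are the network
#'   labels; duplicates are an error).
#' @param feature_kind `"gene"` or `"reaction"`.
#' @param groups optional named character vector label -> group tag.
#' @return binary matrix (features x networks) with class
#'   `presence_matrix`; `attr(, "feature_kind")`, `attr(, "groups")`.
#' @export
presence_matrix <- function(models, feature_kind = c("gene", "reaction"),
                            groups = NULL) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(length(models) >= 1)
  labels <- names(models)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("network", seq_along(models))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate network label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  feats <- lapply(models, function(m) {
    if (feature_kind == "gene") m$genes else m$reactions$id
  })
  all_feats <- sort(unique(unlist(feats)))
  M <- matrix(0L, nrow = length(all_feats), ncol = length(models),
              dimnames = list(all_feats, labels))
  for (k in seq_along(models)) M[feats[[k]], k] <- 1L
  structure(M, feature_kind = feature_kind, groups = groups,
            class = c("presence_matrix", class(M)))
}

#' One-sided hypergeometric enrichment between two network groups
#'
#' For each feature present in `k_a` of the `n_a` group-a networks and
#' `k_b` of the `n_b` group-b networks, the p-value is the upper tail
#' `P(X >= k_a)` for `X` hypergeometric with `k_a + k_b` successes among
#' `n_a + n_b` draws of size `n_a`: the probability of so strong a
#' concentration in group a by chance. Benjamini-Hochberg q-values are
#' reported alongside the fixed raw cutoff.
#'
#' @param pm a [presence_matrix()].
#' @param group_a,group_b disjoint character vectors of network labels.
#' @param p_cutoff raw p-value threshold for `flagged`.
#' @return data.frame `feature`, `count_a`, `count_b`, `p_value`,
#'   `q_value`, `flagged`.
#' @export
group_enrichment <- function(pm, group_a, group_b, p_cutoff = 1e-4) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1,
            !length(intersect(group_a, group_b)))
  miss <- setdiff(c(group_a, group_b), colnames(pm))
  if (length(miss)) stop("unknown network label(s): ",
                         paste(miss, collapse = ", "))
  ka <- rowSums(pm[, group_a, drop = FALSE])
  kb <- rowSums(pm[, group_b, drop = FALSE])
  na_ <- length(group_a); nb_ <- length(group_b)
  p <- stats::phyper(ka - 1, ka + kb, na_ + nb_ - (ka + kb), na_,
                     lower.tail = FALSE)
  p <- pmin(p, 1)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = rownames(pm), count_a = as.integer(ka),
             count_b = as.integer(kb), p_value = p, q_value = q,
             flagged = p < p_cutoff, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric overlap test between a model's genes and a reference
#'
#' P-value of drawing at least the observed overlap when a random gene
#' set of the model's size is drawn from a universe of `universe_size`
#' genes containing the reference set.
#'
#' @param model_genes character vector.
#' @param reference_genes non-empty character vector.
#' @param universe_size total genes in the universe (>= union size).
#' @return list `overlap`, `p_value`.
#' @export
overlap_test <- function(model_genes, reference_genes, universe_size) {
  stopifnot(length(reference_genes) >= 1)
  model_genes <- unique(model_genes)
  reference_genes <- unique(reference_genes)
  if (universe_size < length(union(model_genes, reference_genes))) {
    stop("universe smaller than the union of the two sets")
  }
  k <- length(intersect(model_genes, reference_genes))
  if (k > min(length(model_genes), length(reference_genes))) {
    stop("impossible overlap")  # unreachable with set inputs
  }
  p <- stats::phyper(k - 1, length(reference_genes),
                     universe_size - length(reference_genes),
                     length(model_genes), lower.tail = FALSE)
  list(overlap = k, p_value = min(p, 1))
}

#' Reporter Metabolite scores
#'
#' Aggregates per-gene p-values onto metabolites of the template: each
#' metabolite's neighbour genes are the genes of the reactions producing
#' or consuming it (direction-agnostic); their z-scores
#' `z = qnorm(1 - p)` are summed and divided by `sqrt(k)`, then
#' corrected by the mean and standard deviation of the same statistic
#' for random size-`k` gene sets drawn from all scored genes.
#'
#' @param template a `metabolic_model`.
#' @param gene_pvalues named numeric in (0,1); values at 0/1 are clamped
#'   to `p_clamp`/`1 - p_clamp` with a warning.
#' @param n_null_samples random gene sets per distinct `k`.
#' @param seed RNG seed for the null sampling.
#' @param p_clamp clamp bound.
#' @return data.frame `metabolite`, `k`, `z_raw`, `z_corrected`,
#'   `p_value`, sorted by decreasing `z_corrected`.
#' @export
reporter_metabolites <- function(template, gene_pvalues,
                                 n_null_samples = 1000, seed = 1L,
                                 p_clamp = 1e-10) {
  stopifnot(!is.null(names(gene_pvalues)))
  p <- gene_pvalues
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0/1 clamped to [", p_clamp, ", 1 - ", p_clamp, "]")
    p <- pmin(pmax(p, p_clamp), 1 - p_clamp)
  }
  z <- stats::qnorm(1 - p)
  # neighbour relation: genes of reactions touching the metabolite
  rxn_genes <- lapply(template$gprs, gpr_genes)
  met_ids <- internal_metabolites(template)
  neigh <- stats::setNames(vector("list", length(met_ids)), met_ids)
  for (rid in template$reactions$id) {
    g <- intersect(rxn_genes[[rid]], names(z))
    if (!length(g)) next
    for (mid in intersect(names(template$stoichiometry[[rid]]), met_ids)) {
      neigh[[mid]] <- c(neigh[[mid]], g)
    }
  }
  neigh <- lapply(neigh, unique)
  kk <- vapply(neigh, length, 1L)
  scored <- names(neigh)[kk >= 1L]
  if (!length(scored)) {
    return(data.frame(metabolite = character(0), k = integer(0),
                      z_raw = numeric(0), z_corrected = numeric(0),
                      p_value = numeric(0)))
  }
  zraw <- vapply(scored, function(mid) {
    sum(z[neigh[[mid]]]) / sqrt(length(neigh[[mid]]))
  }, numeric(1))
  set.seed(seed)
  null_mom <- list()
  for (k in sort(unique(kk[scored]))) {
    draws <- vapply(seq_len(n_null_samples), function(i) {
      sum(sample(z, k)) / sqrt(k)
    }, numeric(1))
    null_mom[[as.character(k)]] <- c(mean = mean(draws), sd = stats::sd(draws))
  }
  zc <- vapply(scored, function(mid) {
    mom <- null_mom[[as.character(length(neigh[[mid]]))]]
    if (mom["sd"] < 1e-12) return(0)  # degenerate null (identical p-values)
    (zraw[mid] - mom["mean"]) / mom["sd"]
  }, numeric(1))
  out <- data.frame(metabolite = scored, k = as.integer(kk[scored]),
                    z_raw = unname(zraw), z_corrected = unname(zc),
                    p_value = stats::pnorm(unname(zc), lower.tail = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$z_corrected), , drop = FALSE]
}

jaccard_distance_matrix <- function(pm) {
  n <- ncol(pm)
  X <- pm > 0
  inter <- crossprod(X)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  D <- 1 - ifelse(uni > 0, inter / uni, 1)
  diag(D) <- 0
  stats::as.dist(D)
}

hclust_clades <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  members <- vector("list", nrow(hc$merge))
  clades <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    take <- function(v) if (v < 0) labs[-v] else members[[v]]
    members[[k]] <- sort(c(take(hc$merge[k, 1]), take(hc$merge[k, 2])))
    clades[k] <- paste(members[[k]], collapse = "\r")
  }
  clades
}

#' Average-linkage clustering of networks with bootstrap support
#'
#' Networks are clustered on the Jaccard distance between their binary
#' feature profiles (average linkage). Support for each internal node is
#' the fraction of trees built from feature-resampled (ordinary,
#' non-multiscale) bootstrap replicates that contain the same clade.
#'
#' @param pm a [presence_matrix()] with at least 3 networks.
#' @param n_bootstrap bootstrap replicates.
#' @param seed RNG seed.
#' @return list `hclust`, `phylo` (an `ape::phylo` whose node labels are
#'   supports), `support` (data.frame clade/support).
#' @export
cluster_networks <- function(pm, n_bootstrap = 1000, seed = 1L) {
  stopifnot(ncol(pm) >= 3)
  pm <- pm[, sort(colnames(pm)), drop = FALSE]  # order-invariant topology
  hc <- stats::hclust(jaccard_distance_matrix(pm), method = "average")
  hc$labels <- colnames(pm)
  ref_clades <- hclust_clades(hc)
  hits <- stats::setNames(numeric(length(ref_clades)), ref_clades)
  set.seed(seed)
  nf <- nrow(pm)
  for (b in seq_len(n_bootstrap)) {
    rows <- sample.int(nf, nf, replace = TRUE)
    hb <- stats::hclust(jaccard_distance_matrix(pm[rows, , drop = FALSE]),
                        method = "average")
    hb$labels <- colnames(pm)
    bc <- hclust_clades(hb)
    seen <- intersect(ref_clades, bc)
    hits[seen] <- hits[seen] + 1
  }
  support <- unname(hits[ref_clades]) / n_bootstrap
  phy <- ape::as.phylo(hc)
  # ape node numbering: root is n+1 and corresponds to the last merge;
  # map hclust merge rows onto phylo internal nodes via clade membership
  phy$node.label <- rep(NA_character_, phy$Nnode)
  for (k in seq_along(ref_clades)) {
    tips <- strsplit(ref_clades[k], "\r", fixed = TRUE)[[1]]
    node <- ape::getMRCA(phy, tips)
    phy$node.label[node - length(phy$tip.label)] <-
      formatC(support[k], format = "f", digits = 3)
  }
  list(hclust = hc, phylo = phy,
       support = data.frame(
         clade = vapply(strsplit(ref_clades, "\r", fixed = TRUE),
                        paste, character(1), collapse = ","),
         support = support, stringsAsFactors = FALSE))
}

#' Core and unique feature counts across networks
#'
#' @param pm a [presence_matrix()].
#' @return list `n_features`, `n_core` (present in every network),
#'   `n_unique` (present in exactly one), `frac_core`, `frac_unique`.
#' @export
core_unique_stats <- function(pm) {
  rs <- rowSums(pm > 0)
  n <- ncol(pm)
  list(n_features = nrow(pm),
       n_core = sum(rs == n),
       n_unique = sum(rs == 1),
       frac_core = sum(rs == n) / nrow(pm),
       frac_unique = sum(rs == 1) / nrow(pm))
}

#' Write a presence matrix as TSV
#'
#' @param pm a [presence_matrix()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  df <- data.frame(feature = rownames(pm), as.data.frame(unclass(pm)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
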