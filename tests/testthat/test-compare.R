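test_that("presence matrices reflect membership exactly", {
  spec <- synthetic_spec(n_metabolites = 12, n_reactions = 10, seed = 81)
  m <- generate_network(spec, verify = FALSE)$model
  half <- model_subset(m, c(m$reactions$id[m$reactions$is_exchange],
                            "r001", "r002", "r003"))
  pm <- presence_matrix(list(full = m, twin = m, half = half),
                        feature_kind = "reaction")
  expect_identical(pm[, "full"], pm[, "twin"])
  expect_equal(unname(colSums(pm)), vapply(
    list(m, m, half), function(x) nrow(x$reactions), numeric(1)))
  pg <- presence_matrix(list(a = m, b = half), feature_kind = "gene")
  expect_equal(unname(colSums(pg)),
               c(length(m$genes), length(half$genes)))
  expect_error(presence_matrix(stats::setNames(list(m, m), c("x", "x"))),
               "duplicate")
  # disjoint models give orthogonal columns
  m1 <- model_subset(m, c("r001", "r002"))
  m2 <- model_subset(m, c("r003", "r004"))
  pd <- presence_matrix(list(p = m1, q = m2), feature_kind = "reaction")
  expect_equal(sum(pd[, 1] * pd[, 2]), 0)
})

test_that("group enrichment equals exact combinatorial summation", {
  set.seed(9)
  mk <- function(n, k) sample(rep(c(1L, 0L), c(k, n - k)))
  na_ <- 16; nb_ <- 24
  feats <- t(sapply(1:40, function(i) c(mk(na_, sample(0:na_, 1)),
                                        mk(nb_, sample(0:nb_, 1)))))
  rownames(feats) <- paste0("f", 1:40)
  colnames(feats) <- c(paste0("a", 1:na_), paste0("b", 1:nb_))
  pm <- structure(feats, class = c("presence_matrix", "matrix"))
  res <- group_enrichment(pm, paste0("a", 1:na_), paste0("b", 1:nb_))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 hyper_tail_exact(res$count_a[i],
                                  res$count_a[i] + res$count_b[i],
                                  na_ + nb_, na_),
                 tolerance = 1e-10, info = res$feature[i])
  }
  # fully group-a-specific feature: p = 1 / C(40, 16)
  full <- rbind(spec1 = c(rep(1L, na_), rep(0L, nb_)))
  colnames(full) <- colnames(feats)
  pm2 <- structure(full, class = c("presence_matrix", "matrix"))
  res2 <- group_enrichment(pm2, paste0("a", 1:na_), paste0("b", 1:nb_))
  expect_equal(res2$p_value, 1 / choose(40, 16), tolerance = 1e-10)
  expect_true(res2$flagged)
  # feature in every network: p = 1, never flagged
  allp <- rbind(core = rep(1L, 40))
  colnames(allp) <- colnames(feats)
  res3 <- group_enrichment(structure(allp, class = class(pm2)),
                           paste0("a", 1:na_), paste0("b", 1:nb_))
  expect_equal(res3$p_value, 1)
  # equal proportions in a symmetric design are not enriched
  sym <- rbind(even = c(rep(1L, 8), rep(0L, 8), rep(1L, 12), rep(0L, 12)))
  colnames(sym) <- colnames(feats)
  res4 <- group_enrichment(structure(sym, class = class(pm2)),
                           paste0("a", 1:na_), paste0("b", 1:nb_))
  expect_gte(res4$p_value, 0.5)
})

test_that("overlap test matches the closed form and its limits", {
  # identical sets: the minimal attainable p for those sizes
  r <- overlap_test(paste0("g", 1:20), paste0("g", 1:20), 1000)
  expect_equal(r$overlap, 20)
  expect_equal(r$p_value, hyper_tail_exact(20, 20, 1000, 20),
               tolerance = 1e-10)
  # disjoint tiny reference in a huge universe: p ~ 1
  r2 <- overlap_test(paste0("g", 1:20), paste0("h", 1:3), 10000)
  expect_equal(r2$overlap, 0)
  expect_equal(r2$p_value, 1)
  # independence-sized overlap sits near the median
  r3 <- overlap_test(paste0("g", 1:50), paste0("g", 41:90), 500)
  expect_equal(r3$p_value, hyper_tail_exact(10, 50, 500, 50),
               tolerance = 1e-10)
  expect_error(overlap_test(paste0("g", 1:50), paste0("g", 1:40), 45),
               "universe")
})

test_that("reporter scores aggregate neighbour gene significance", {
  # star template: one reaction per metabolite, known gene sets
  n_met <- 30
  set.seed(11)
  genes <- paste0("g", 1:15)
  neigh <- lapply(1:n_met, function(i) sample(genes, sample(1:4, 1)))
  mets <- data.frame(id = sprintf("m%02d[c]", 1:n_met),
                     name = sprintf("m%02d", 1:n_met),
                     compartment = "cytosol", formula = NA_character_)
  rx <- data.frame(id = sprintf("r%02d", 1:n_met), reversible = FALSE,
                   is_exchange = FALSE,
                   gpr = vapply(neigh, paste, character(1),
                                collapse = " or "),
                   subsystem = NA_character_)
  st <- stats::setNames(lapply(1:n_met, function(i) {
    stats::setNames(-1, sprintf("m%02d[c]", i))
  }), rx$id)
  tpl <- metabolic_model(mets, rx, st)
  p <- stats::setNames(stats::runif(length(genes), 0.01, 0.99), genes)
  res <- reporter_metabolites(tpl, p, n_null_samples = 400, seed = 5)
  expect_equal(nrow(res), n_met)
  # k = 1 metabolites: raw Z equals the gene's z-score
  k1 <- res[res$k == 1, ]
  for (i in seq_len(nrow(k1))) {
    g <- neigh[[match(k1$metabolite[i], mets$id)]]
    expect_equal(k1$z_raw[i], stats::qnorm(1 - p[[g]]), tolerance = 1e-12)
  }
  # the metabolite with the single most significant gene set tops the list
  p2 <- p; p2[neigh[[7]]] <- 1e-6
  res2 <- reporter_metabolites(tpl, p2, n_null_samples = 400, seed = 5)
  expect_equal(res2$metabolite[1], mets$id[7])
  # identical p-values degenerate to corrected Z = 0
  p3 <- stats::setNames(rep(0.5, length(genes)), genes)
  res3 <- reporter_metabolites(tpl, p3, n_null_samples = 200, seed = 5)
  expect_true(all(abs(res3$z_corrected) < 3 / sqrt(200)))
  # out-of-range p-values are clamped with a warning
  p4 <- p; p4[1] <- 0
  expect_warning(reporter_metabolites(tpl, p4, n_null_samples = 50,
                                      seed = 5), "clamped")
})

test_that("clustering groups similar networks with high support and is
           order-invariant", {
  set.seed(3)
  base <- rbinom(200, 1, 0.5)
  near <- base; flip <- sample(200, 20); near[flip] <- 1 - near[flip]
  far <- rbinom(200, 1, 0.5)
  M <- cbind(n1 = base, n2 = near, n3 = far)
  rownames(M) <- paste0("f", 1:200)
  pm <- structure(M, class = c("presence_matrix", "matrix"))
  cl <- cluster_networks(pm, n_bootstrap = 200, seed = 4)
  pair <- cl$support[cl$support$clade == "n1,n2", ]
  expect_equal(nrow(pair), 1)
  expect_gt(pair$support, 0.95)
  # identical columns merge at distance zero with support 1
  M2 <- cbind(M, n4 = base)
  pm2 <- structure(M2, class = c("presence_matrix", "matrix"))
  cl2 <- cluster_networks(pm2, n_bootstrap = 100, seed = 4)
  twin <- cl2$support[cl2$support$clade == "n1,n4", ]
  expect_equal(twin$support, 1)
  expect_equal(min(cl2$hclust$height), 0)
  # permuting network order leaves topology and supports unchanged
  perm <- structure(M[, c(3, 1, 2)],
                    class = c("presence_matrix", "matrix"))
  clp <- cluster_networks(perm, n_bootstrap = 200, seed = 4)
  expect_equal(clp$support[order(clp$support$clade), ],
               cl$support[order(cl$support$clade), ],
               ignore_attr = TRUE)
  # newick export carries support labels
  nwk <- ape::write.tree(cl$phylo)
  expect_match(nwk, "n1")
})

test_that("core/unique statistics match direct row-sum recounts", {
  spec <- synthetic_spec(n_metabolites = 12, n_reactions = 10, seed = 91)
  grp <- simulate_network_groups(spec, n_group_a = 4, n_group_b = 4,
                                 n_differential_features = 2)
  pm <- presence_matrix(grp$models, feature_kind = "reaction")
  st <- core_unique_stats(pm)
  rs <- rowSums(pm)
  expect_equal(st$n_core, sum(rs == ncol(pm)))
  expect_equal(st$n_unique, sum(rs == 1))
  expect_equal(st$frac_core + st$frac_unique,
               (st$n_core + st$n_unique) / st$n_features)
  # identical models: everything core; disjoint models: everything unique
  m <- grp$base
  pid <- presence_matrix(list(x = m, y = m), feature_kind = "reaction")
  expect_equal(core_unique_stats(pid)$n_core, nrow(pid))
  expect_equal(core_unique_stats(pid)$n_unique, 0)
})
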