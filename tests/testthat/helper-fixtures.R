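# Fixtures are built in code; no binary data.

# linear chain  EX_A <=> A -r1-> B -r2-> C  (all irreversible core)
chain_model <- function() {
  mets <- data.frame(
    id = c("A[c]", "B[c]", "C[c]"),
    name = c("A", "B", "C"),
    compartment = "cytosol",
    formula = NA_character_,
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_A", "r1", "r2"),
    reversible = c(TRUE, FALSE, FALSE),
    is_exchange = c(TRUE, FALSE, FALSE),
    gpr = c("", "g1", "g2"),
    subsystem = NA_character_,
    stringsAsFactors = FALSE)
  st <- list(
    EX_A = c("A[c]" = -1),
    r1 = c("A[c]" = -1, "B[c]" = 1),
    r2 = c("B[c]" = -1, "C[c]" = 1))
  metabolic_model(mets, rx, st)
}

# toy model with formulas for balance checks
balance_model <- function() {
  mets <- data.frame(
    id = c("glc[c]", "lac[c]", "mal[c]", "pyr[c]", "mys[c]"),
    name = c("glucose", "lactate", "malformed-partner", "pyruvate",
             "mystery"),
    compartment = "cytosol",
    formula = c("C6H12O6", "C3H6O3", "C2H4", "C3H4O3", NA),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("split", "h_only", "c_loss", "unknowable"),
    reversible = FALSE, is_exchange = FALSE, gpr = "",
    subsystem = NA_character_, stringsAsFactors = FALSE)
  st <- list(
    split = c("glc[c]" = -1, "lac[c]" = 2),           # balanced
    h_only = c("lac[c]" = -1, "pyr[c]" = 1),          # H off by 2 only
    c_loss = c("mal[c]" = -1, "lac[c]" = 1),          # C gained
    unknowable = c("mys[c]" = -1, "lac[c]" = 1))
  metabolic_model(mets, rx, st)
}

random_weights <- function(model, seed, lo = -10, hi = 20) {
  ne <- model$reactions$id[!model$reactions$is_exchange]
  set.seed(seed)
  stats::setNames(stats::runif(length(ne), lo, hi), ne)
}

# exact hypergeometric upper tail by direct summation (log-space)
hyper_tail_exact <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(exp(lchoose(K, k:hi) + lchoose(N - K, n - (k:hi)) - lchoose(N, n)))
}

# reachability oracle for dead-end removal: dense iterative marking,
# independent of the packaged closure implementation
reachability_oracle <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  rev <- model$reactions$reversible
  producible <- rep(FALSE, nrow(S))
  names(producible) <- rownames(S)
  repeat {
    before <- producible
    for (i in seq_len(ncol(S))) {
      col <- S[, i]
      fwd_ok <- all(producible[col < 0])
      bwd_ok <- rev[i] && all(producible[col > 0])
      if (fwd_ok) producible[col > 0] <- TRUE
      if (bwd_ok) producible[col < 0] <- TRUE
    }
    if (identical(before, producible)) break
  }
  keep <- vapply(seq_len(ncol(S)), function(i) {
    col <- S[, i]
    all(producible[col < 0]) || (rev[i] && all(producible[col > 0]))
  }, logical(1))
  model$reactions$id[keep]
}

# per-reaction LP oracle for flux consistency: dense formulation, one
# minimisation task per direction, built independently of flux_consistent
fva_oracle <- function(model, tau = 1e-4, M = 1000) {
  S <- as.matrix(stoichiometric_matrix(model, internal_only = TRUE))
  n <- ncol(S)
  lb <- ifelse(model$reactions$reversible | model$reactions$is_exchange,
               -M, 0)
  ub <- rep(M, n)
  tasks <- list()
  for (i in seq_len(n)) {
    cc <- rep(0, n); cc[i] <- -1            # minimise -v  (max v)
    tasks[[length(tasks) + 1L]] <- milp_task(
      c = cc, A = S, rlb = rep(0, nrow(S)), rub = rep(0, nrow(S)),
      lb = lb, ub = ub, sense = "min", id = paste0("f", i))
    cc[i] <- 1                               # minimise v   (max -v)
    tasks[[length(tasks) + 1L]] <- milp_task(
      c = cc, A = S, rlb = rep(0, nrow(S)), rub = rep(0, nrow(S)),
      lb = lb, ub = ub, sense = "min", id = paste0("b", i))
  }
  res <- milp_batch(tasks)
  keep <- rep(FALSE, n)
  for (r in res) {
    i <- as.integer(substring(r$id, 2))
    if (r$status != "optimal") next
    if (abs(r$objective) >= tau * (1 - 1e-6)) keep[i] <- TRUE
  }
  model$reactions$id[keep]
}
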