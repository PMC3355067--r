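test_that("chain extraction keeps supported reactions and drops
           unsupported ones", {
  m <- chain_model()
  w <- c(r1 = 10, r2 = -8)
  sol <- solve_init(build_init_problem(m, w))
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$y["r1"]), 1L)
  expect_equal(unname(sol$y["r2"]), 0L)
  # oracle agrees on the full enumeration
  orc <- brute_force_oracle(m, w)
  expect_equal(sol$objective, orc$objective, tolerance = 1e-9)
  expect_equal(orc$subset, "r1")
  net <- extract_network(m, sol)
  expect_setequal(net$reactions$id[!net$reactions$is_exchange], "r1")
  expect_true("EX_A" %in% net$reactions$id)
})

test_that("metabolome forcing drags negative-evidence reactions in", {
  m <- chain_model()
  w <- c(r1 = 10, r2 = -8)
  sol <- solve_init(build_init_problem(m, w, present_metabolites = "C[c]"))
  expect_equal(unname(sol$y[c("r1", "r2")]), c(1L, 1L))
  expect_gte(unname(sol$b["C[c]"]), 1 - 1e-6)
  orc <- brute_force_oracle(m, w, present_metabolites = "C[c]")
  expect_equal(sol$objective, orc$objective, tolerance = 1e-9)
  # unknown metabolite is rejected up front
  expect_error(build_init_problem(m, w, present_metabolites = "nope[c]"),
               "nope")
  # unsatisfiable forcing reports infeasible, does not throw
  m2 <- model_subset(m, c("EX_A", "r1"), drop_orphans = FALSE)
  sol2 <- solve_init(build_init_problem(m2, c(r1 = 10),
                                        present_metabolites = "C[c]"))
  expect_equal(sol2$status, "infeasible")
})

test_that("all-negative evidence with no forcing yields the empty
           network", {
  m <- chain_model()
  sol <- solve_init(build_init_problem(m, c(r1 = -5, r2 = -8)))
  expect_equal(sum(sol$y), 0)
  expect_equal(sol$objective, 0)
  net <- extract_network(m, sol)
  expect_equal(sum(!net$reactions$is_exchange), 0)
})

test_that("an included reversible reaction must carry net flux", {
  # A <=> B with no exchanges: inclusion needs |v| >= eps, which would
  # drive one of the accumulations negative -> exclusion is optimal
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "cytosol", formula = NA_character_)
  rx <- data.frame(id = "rab", reversible = TRUE, is_exchange = FALSE,
                   gpr = "", subsystem = NA_character_)
  m <- metabolic_model(mets, rx, list(rab = c("A[c]" = -1, "B[c]" = 1)))
  sol <- solve_init(build_init_problem(m, c(rab = 50)))
  expect_equal(unname(sol$y["rab"]), 0L)
  expect_equal(brute_force_oracle(m, c(rab = 50))$objective,
               sol$objective, tolerance = 1e-9)
})

test_that("solver matches the subset-enumeration oracle on random mixed
           instances", {
  n_eq <- 0
  for (s in 1:25) {
    spec <- synthetic_spec(n_metabolites = 10, n_reactions = 7,
                           reversible_fraction = 0.4, seed = 3000 + s)
    m <- generate_network(spec, verify = FALSE)$model
    w <- random_weights(m, seed = 4000 + s)
    ints <- internal_metabolites(m)
    set.seed(5000 + s)
    pres <- if (stats::runif(1) < 0.4) sample(ints, 1) else character(0)
    sol <- solve_init(build_init_problem(m, w, pres))
    orc <- brute_force_oracle(m, w, pres)
    if (sol$status == "infeasible") {
      expect_equal(orc$status, "infeasible")
      n_eq <- n_eq + 1
    } else {
      expect_lt(abs(sol$objective - orc$objective), 1e-6)
      n_eq <- n_eq + 1
    }
  }
  expect_equal(n_eq, 25)
})

test_that("raising a weight never expels that reaction from a unique
           optimum", {
  for (s in 1:3) {
    spec <- synthetic_spec(n_metabolites = 10, n_reactions = 6,
                           seed = 6000 + s)
    m <- generate_network(spec, verify = FALSE)$model
    w <- random_weights(m, seed = 6100 + s)
    orc <- brute_force_oracle(m, w)
    if (orc$status != "optimal" || !length(orc$subset)) next
    rid <- orc$subset[1]
    w2 <- w; w2[rid] <- w2[rid] + 5
    orc2 <- brute_force_oracle(m, w2)
    expect_true(rid %in% orc2$subset)
  }
})

test_that("oracle refuses oversized instances", {
  spec <- synthetic_spec(n_metabolites = 20, n_reactions = 20, seed = 1)
  m <- generate_network(spec, verify = FALSE)$model
  expect_error(brute_force_oracle(m, random_weights(m, 1), cap = 12),
               "exceeds cap")
})

test_that("weight sensitivity reports 1.0 under zero perturbation and on
           single-reaction templates", {
  spec <- synthetic_spec(n_metabolites = 12, n_reactions = 10,
                         hpa_noise_rate = 0.1, seed = 71)
  gen <- generate_network(spec)
  ev <- simulate_evidence(gen$model, gen$planted, spec)
  wv <- reaction_weights(gen$model, ev, "t1")
  rep0 <- weight_sensitivity(gen$model, wv, perturbation = 0)
  expect_true(all(rep0$jaccard == 1))
  # single positive-weight reaction: sign never flips under 20%
  m1 <- chain_model()
  m1s <- model_subset(m1, c("EX_A", "r1"))
  ev1 <- evidence_table(data.frame(gene = "g1", tissue = "t1",
                                   hpa_level = "high",
                                   expression_signal = NA_real_))
  wv1 <- reaction_weights(m1s, ev1, "t1")
  rep1 <- weight_sensitivity(m1s, wv1)
  expect_true(all(rep1$jaccard == 1))
})

test_that("solution reports serialise to valid JSON", {
  m <- chain_model()
  prob <- build_init_problem(m, c(r1 = 10, r2 = -8))
  sol <- solve_init(prob)
  js <- solution_report_json(prob, sol)
  expect_true(jsonlite::validate(js))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$status, "optimal")
  expect_equal(sort(parsed$reactions$reaction), c("r1", "r2"))
})
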