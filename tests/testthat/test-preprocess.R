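test_that("formula parsing handles counts, multi-letter elements, errors", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("NaCl"), c(Cl = 1L, Na = 1L))
  expect_equal(parse_formula("CH3COOH"),
               c(C = 2L, H = 4L, O = 2L))
  expect_error(parse_formula("c6h12"), "malformed")
  expect_error(parse_formula("C6-H12"), "malformed")
})

test_that("mass balance tolerates protons and flags element gain", {
  res <- check_mass_balance(balance_model())
  expect_false("split" %in% res$unbalanced)    # C6H12O6 -> 2 C3H6O3
  expect_false("h_only" %in% res$unbalanced)   # only H differs
  expect_true("c_loss" %in% res$unbalanced)    # carbon not conserved
  expect_true("unknowable" %in% res$uncheckable)
  expect_false("unknowable" %in% res$unbalanced)
})

test_that("blacklisted generic metabolites remove their reactions", {
  m <- chain_model()
  m$metabolites$name[2] <- "Lipid"
  res <- remove_blacklisted(m, "lipid")
  expect_setequal(res$removed$reaction, c("r1", "r2"))
  expect_false("B[c]" %in% res$model$metabolites$id)
  # empty blacklist: untouched
  expect_equal(nrow(remove_blacklisted(m, character(0))$removed), 0)
  # full blacklist: empty model
  res2 <- remove_blacklisted(m, m$metabolites$id)
  expect_equal(nrow(res2$model$reactions), 0)
})

test_that("directionality filter removes exactly the unflagged reactions", {
  m <- chain_model()
  expect_equal(nrow(remove_no_directionality(m, NULL)$removed), 0)
  res <- remove_no_directionality(m, c("EX_A", "r1"))
  expect_equal(res$removed$reaction, "r2")
  expect_setequal(res$model$reactions$id, c("EX_A", "r1"))
})

test_that("dead-end substrates block reactions; accumulating products
           do not", {
  m <- chain_model()
  # append D => E with D unproducible
  m2 <- metabolic_model(
    rbind(m$metabolites,
          data.frame(id = c("D[c]", "E[c]"), name = c("D", "E"),
                     compartment = "cytosol", formula = NA_character_)),
    rbind(m$reactions,
          data.frame(id = "rDE", reversible = FALSE, is_exchange = FALSE,
                     gpr = "", subsystem = NA_character_)),
    c(m$stoichiometry, list(rDE = c("D[c]" = -1, "E[c]" = 1))))
  res <- remove_unconnected(m2)
  expect_equal(res$removed$reaction, "rDE")
  # chain retained although C only accumulates
  expect_true(all(c("r1", "r2") %in% res$model$reactions$id))
  # isolated 2-cycle with no input is removed at the fixed point
  mets <- data.frame(id = c("X[c]", "Y[c]"), name = c("X", "Y"),
                     compartment = "cytosol", formula = NA_character_)
  rx <- data.frame(id = c("xy", "yx"), reversible = FALSE,
                   is_exchange = FALSE, gpr = "",
                   subsystem = NA_character_)
  st <- list(xy = c("X[c]" = -1, "Y[c]" = 1),
             yx = c("Y[c]" = -1, "X[c]" = 1))
  cyc <- metabolic_model(mets, rx, st)
  expect_setequal(remove_unconnected(cyc)$removed$reaction, c("xy", "yx"))
})

test_that("dead-end removal matches the reachability oracle on random
           fixtures", {
  for (s in 1:8) {
    spec <- synthetic_spec(n_metabolites = 12, n_reactions = 10,
                           seed = 400 + s)
    m <- generate_network(spec, verify = FALSE)$model
    # break the construction guarantee: delete a random non-exchange rxn
    set.seed(s)
    drop <- sample(m$reactions$id[!m$reactions$is_exchange], 2)
    m <- model_subset(m, setdiff(m$reactions$id, drop))
    expect_setequal(remove_unconnected(m)$model$reactions$id,
                    reachability_oracle(m))
  }
})

test_that("flux consistency matches the per-reaction LP oracle", {
  for (s in 1:5) {
    spec <- synthetic_spec(n_metabolites = 20, n_reactions = 30,
                           seed = 500 + s)
    m <- generate_network(spec, verify = FALSE)$model
    set.seed(s)
    drop <- sample(m$reactions$id[!m$reactions$is_exchange], 3)
    m <- model_subset(m, setdiff(m$reactions$id, drop))
    got <- flux_consistent(m)$model$reactions$id
    expect_setequal(got, fva_oracle(m))
  }
})

test_that("flux-consistency certificates actually carry the flux", {
  spec <- synthetic_spec(n_metabolites = 20, n_reactions = 25, seed = 77)
  m <- generate_network(spec, verify = FALSE)$model
  fc <- flux_consistent(m)
  S <- stoichiometric_matrix(m, internal_only = TRUE)
  for (rid in names(fc$certificates)) {
    v <- fc$certificates[[rid]]
    expect_lt(max(abs(as.numeric(S %*% v[colnames(S)]))), 1e-6)
    expect_gte(abs(v[rid]), 1e-4 * (1 - 1e-6))
  }
})

test_that("leak test flags free generators and passes clean models", {
  m <- chain_model()
  expect_false(any(leak_test(m)$leaky))
  # a reaction creating ATP from nothing (net stoichiometry)
  mets <- rbind(m$metabolites,
                data.frame(id = "atp[c]", name = "ATP",
                           compartment = "cytosol",
                           formula = NA_character_))
  rx <- rbind(m$reactions,
              data.frame(id = "magic", reversible = FALSE,
                         is_exchange = FALSE, gpr = "",
                         subsystem = NA_character_))
  st <- c(m$stoichiometry, list(magic = c("atp[c]" = 1)))
  leaky <- metabolic_model(mets, rx, st)
  lt <- leak_test(leaky)
  expect_true(lt$leaky[lt$metabolite == "atp[c]"])
  # stoichiometric typo: 1 B in, 2 B out around a cycle leaks B
  mets2 <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                      compartment = "cytosol", formula = NA_character_)
  rx2 <- data.frame(id = c("ab", "ba"), reversible = FALSE,
                    is_exchange = FALSE, gpr = "",
                    subsystem = NA_character_)
  st2 <- list(ab = c("A[c]" = -1, "B[c]" = 2),
              ba = c("B[c]" = -1, "A[c]" = 1))
  typo <- metabolic_model(mets2, rx2, st2)
  lt2 <- leak_test(typo)
  expect_true(any(lt2$leaky))
})

test_that("build_template attributes removals to the right stage and is
           idempotent", {
  spec <- synthetic_spec(n_metabolites = 15, n_reactions = 12, seed = 31)
  m <- generate_network(spec, verify = FALSE)$model
  # inject one defect of each class
  mets <- rbind(m$metabolites, data.frame(
    id = c("lipid[c]", "D[c]", "E[c]"),
    name = c("Lipid", "D", "E"),
    compartment = "cytosol", formula = NA_character_))
  rx <- rbind(m$reactions, data.frame(
    id = c("r_generic", "r_nodir", "r_deadend"),
    reversible = FALSE, is_exchange = FALSE, gpr = "",
    subsystem = NA_character_))
  st <- c(m$stoichiometry, list(
    r_generic = setNames(c(-1, 1), c("lipid[c]", m$metabolites$id[1])),
    r_nodir = setNames(c(-1, 1), m$metabolites$id[1:2]),
    r_deadend = c("D[c]" = -1, "E[c]" = 1)))
  defective <- metabolic_model(mets, rx, st)
  bt <- build_template(defective, blacklist = "lipid",
                       directionality_known =
                         setdiff(defective$reactions$id, "r_nodir"))
  stg <- bt$report$stages
  expect_true("r_generic" %in% stg$blacklist_balance$reaction)
  expect_true("r_nodir" %in% stg$directionality$reaction)
  expect_true("r_deadend" %in% stg$unconnected$reaction)
  # idempotence
  bt2 <- build_template(bt$model)
  expect_setequal(bt2$model$reactions$id, bt$model$reactions$id)
  expect_equal(nrow(bt2$report$stages$flux_consistency), 0)
  # counts monotone non-increasing
  expect_true(all(diff(bt$report$counts[, "reactions"]) <= 0))
  # report serialises
  expect_true(jsonlite::validate(curation_report_json(bt$report)))
})
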