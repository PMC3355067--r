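test_that("equation strings parse and format round-trip", {
  pe <- parse_equation("2 A[c] + B[c] => C[c]")
  expect_equal(pe$stoichiometry, c("A[c]" = -2, "B[c]" = -1, "C[c]" = 1))
  expect_false(pe$reversible)
  expect_true(parse_equation("A[c] <=>")$reversible)
  expect_equal(parse_equation("A[e] <=>")$stoichiometry, c("A[e]" = -1))
  expect_error(parse_equation("A[c] B[c]"), "lacks")
  st <- c("A[c]" = -2, "B[c]" = -1, "C[c]" = 1)
  expect_equal(parse_equation(format_equation(st, TRUE))$stoichiometry, st)
})

test_that("model validation names the offending entity", {
  m <- chain_model()
  expect_silent(validate_model(m))
  bad <- m
  bad$stoichiometry$r1 <- c("A[c]" = -1, "ZZZ[c]" = 1)
  expect_error(validate_model(bad), "ZZZ\\[c\\]")
  bad2 <- m
  bad2$reactions$is_exchange[2] <- TRUE
  expect_error(validate_model(bad2), "exactly one metabolite")
})

test_that("stoichiometric matrix matches dense construction and products", {
  spec <- synthetic_spec(n_metabolites = 20, n_reactions = 25, seed = 7)
  m <- generate_network(spec, verify = FALSE)$model
  S <- stoichiometric_matrix(m)
  dense <- matrix(0, nrow(m$metabolites), nrow(m$reactions),
                  dimnames = list(m$metabolites$id, m$reactions$id))
  for (rid in m$reactions$id) {
    st <- m$stoichiometry[[rid]]
    dense[names(st), rid] <- st
  }
  expect_equal(as.matrix(S), dense)
  # unit flux on a conversion accumulates (-1, +1)
  cm <- chain_model()
  Sc <- stoichiometric_matrix(cm)
  v <- c(EX_A = 0, r1 = 1, r2 = 0)
  acc <- as.numeric(Sc %*% v[colnames(Sc)])
  expect_equal(acc, c(-1, 1, 0))
  # internal_only drops extracellular rows
  m2 <- chain_model()
  m2$metabolites$compartment[3] <- "extracellular"
  expect_equal(rownames(stoichiometric_matrix(m2, internal_only = TRUE)),
               c("A[c]", "B[c]"))
})

test_that("tsv round-trip preserves the model", {
  spec <- synthetic_spec(n_metabolites = 15, n_reactions = 14, seed = 9)
  m <- generate_network(spec, verify = FALSE)$model
  m$reactions$gpr[2] <- "(gA and gB) or gC"
  m$gprs[[m$reactions$id[2]]] <- parse_gpr("(gA and gB) or gC")
  m$genes <- union(m$genes, c("gA", "gB", "gC"))
  dir <- withr::local_tempdir()
  write_model(m, dir, format = "tsv")
  m2 <- read_model(dir, format = "tsv")
  expect_setequal(m2$reactions$id, m$reactions$id)
  expect_setequal(m2$metabolites$id[m2$metabolites$id %in%
                                      unlist(lapply(m$stoichiometry, names))],
                  unique(unlist(lapply(m$stoichiometry, names))))
  for (rid in m$reactions$id) {
    expect_equal(sort(m2$stoichiometry[[rid]]),
                 sort(m$stoichiometry[[rid]]), info = rid)
  }
  expect_equal(m2$reactions$reversible[match(m$reactions$id,
                                             m2$reactions$id)],
               m$reactions$reversible)
  expect_true(eval_gpr(m2$gprs[[m$reactions$id[2]]], c("gA", "gB")))
  expect_false(eval_gpr(m2$gprs[[m$reactions$id[2]]], c("gA")))
})

test_that("sbml round-trip preserves the model including GPR truth tables", {
  m <- chain_model()
  m$metabolites$formula <- c("C3H6O3", "C3H6O3", "C3H6O3")
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, format = "sbml")
  m2 <- read_model(path, format = "sbml")
  expect_setequal(m2$reactions$id, m$reactions$id)
  for (rid in m$reactions$id) {
    expect_equal(sort(m2$stoichiometry[[rid]]), sort(m$stoichiometry[[rid]]))
  }
  expect_equal(m2$reactions$reversible[match(m$reactions$id, m2$reactions$id)],
               m$reactions$reversible)
  expect_equal(m2$metabolites$formula[match("A[c]", m2$metabolites$id)],
               "C3H6O3")
  expect_true(m2$reactions$is_exchange[m2$reactions$id == "EX_A"])
  expect_true(eval_gpr(m2$gprs[["r1"]], "g1"))
  # empty GPR: no gene association emitted
  expect_false(grepl("GENE_ASSOCIATION", paste(readLines(path)[
    grep("EX_A", readLines(path))], collapse = "")))
})

test_that("degenerate and invalid SBML inputs are handled", {
  m0 <- metabolic_model(
    data.frame(id = character(0), name = character(0),
               compartment = character(0), formula = character(0)),
    data.frame(id = character(0), reversible = logical(0),
               is_exchange = logical(0), gpr = character(0),
               subsystem = character(0)),
    stats::setNames(list(), character(0)))
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m0, path, format = "sbml")
  m0b <- read_model(path, format = "sbml")
  expect_equal(nrow(m0b$reactions), 0)
  # undeclared species reference
  bad <- c(
    "<?xml version=\"1.0\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
    " level=\"3\" version=\"1\"><model id=\"m\">",
    "<listOfCompartments><compartment id=\"c\" name=\"cytosol\"",
    " constant=\"true\"/></listOfCompartments>",
    "<listOfSpecies><species id=\"M_A\" name=\"A\" compartment=\"c\"",
    " constant=\"false\"/></listOfSpecies>",
    "<listOfReactions><reaction id=\"R_1\" reversible=\"false\">",
    "<listOfReactants><speciesReference species=\"M_GHOST\"",
    " stoichiometry=\"1\" constant=\"true\"/></listOfReactants>",
    "</reaction></listOfReactions></model></sbml>")
  bp <- withr::local_tempfile(fileext = ".xml")
  writeLines(bad, bp)
  expect_error(read_model(bp, format = "sbml"), "M_GHOST")
})
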