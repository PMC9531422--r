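# Model construction, IO, validation and stoichiometric reduction.

test_that("the packaged reduced model has the expected cardinalities", {
  m <- ecoli_trp_model()
  expect_equal(nrow(m$reactions), 53L)
  expect_equal(nrow(m$metabolites), 59L)
  expect_equal(sum(m$metabolites$measured), 45L)
  expect_identical(m$objective_id, "growth")
  expect_equal(nrow(validate_model(m)), 0L)
  # S columns reproduce each reaction's stoichiometry on balanced species
  bal <- rownames(m$S)
  for (j in seq_len(nrow(m$reactions))) {
    s <- m$reactions$stoich[[j]]
    s <- s[names(s) %in% bal]
    col <- m$S[, j]
    expect_equal(unname(col[names(s)]), unname(s))
    expect_equal(sum(col != 0), length(s))
  }
})

test_that("equation parsing handles coefficients, sides and reversibility", {
  p <- parse_equation("2 A + B -> C")
  expect_equal(p$stoich[c("A", "B", "C")], c(A = -2, B = -1, C = 1))
  expect_false(p$reversible)
  expect_true(parse_equation("A <-> B")$reversible)
  expect_equal(parse_equation("-> co2_e")$stoich, c(co2_e = 1))
  expect_equal(parse_equation("o2_e ->")$stoich, c(o2_e = -1))
  expect_error(parse_equation("A -> B -> C"), "parse")
})

test_that("toy chain model assembles the expected 2x3 stoichiometric matrix", {
  m <- chain_model()
  expect_equal(unname(m$S), rbind(c(1, -1, 0), c(0, 1, -1)))
})

test_that("constructor rejects invalid models", {
  mets <- tibble::tibble(id = "A", name = "A", compartment = "cytosol",
                         conc_lb = 1e-6, conc_ub = 1e-2,
                         is_balanced = TRUE, measured = TRUE)
  expect_error(network_model(mets, mets[0, ]), "zero reactions")
  rxns <- tibble::tibble(id = "r", enzyme_label = "r",
                         stoich = list(c(A = -1, Z = 1)), reversible = FALSE,
                         lb = 0, ub = 1, dg0_prime = NA_real_,
                         is_exchange = FALSE)
  expect_error(network_model(mets, rxns), "unknown metabolites: Z")
})

test_that("validate_model reports orphans and inverted bounds", {
  m <- chain_model()
  m$metabolites <- dplyr::bind_rows(
    m$metabolites,
    tibble::tibble(id = "Q", name = "Q", compartment = "cytosol",
                   conc_lb = 1e-6, conc_ub = 1e-2, is_balanced = FALSE,
                   measured = FALSE))
  rep <- validate_model(m)
  expect_true("orphan_metabolite" %in% rep$type)
  m2 <- chain_model()
  m2$reactions$lb[2] <- 5; m2$reactions$ub[2] <- 1
  expect_true("inverted_bounds" %in% validate_model(m2)$type)
})

test_that("tabular round trip reproduces the model exactly", {
  m <- ecoli_trp_model()
  dir <- withr::local_tempdir()
  write_model_tabular(m, dir)
  m2 <- load_model(dir, "tabular")
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$dg0_prime, m$reactions$dg0_prime)
  for (j in seq_len(nrow(m$reactions))) {
    a <- sort(m$reactions$stoich[[j]]); b <- sort(m2$reactions$stoich[[j]])
    expect_equal(a, b[names(a)])
  }
  expect_equal(m2$S, m$S)
})

test_that("SBML level-3 import resolves species and stoichiometries", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="mini">
  <listOfSpecies>
   <species id="A" compartment="c"/>
   <species id="B" compartment="c"/>
   <species id="S_ext" compartment="e"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_S" reversible="false">
    <listOfReactants><speciesReference species="S_ext" stoichiometry="1"/></listOfReactants>
   </reaction>
   <reaction id="r1" reversible="true">
    <listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- load_model(f, "sbml")
  expect_equal(nrow(m$reactions), 2L)
  expect_equal(m$reactions$stoich[[2]], c(A = -2, B = 1))
  expect_true(m$reactions$reversible[2])
  expect_true(m$reactions$is_exchange[1])
  expect_error(load_model(withr::local_tempfile(fileext = ".xml"), "sbml"),
               "missing")
})

test_that("reduction returns identity link for full-rank stoichiometries", {
  m <- chain_model()
  red <- reduce_stoichiometry(m)
  expect_equal(red$S_R, m$S)
  expect_equal(unname(red$L), diag(2))
  expect_length(red$dependent_ids, 0L)
})

test_that("a conserved pair yields exactly one dependent row", {
  # 4x3 fixture with m4 = -(m1 + m2): a conserved couple
  S <- rbind(m1 = c(1, -1, 0), m2 = c(0, 1, -1),
             m3 = c(0, 0, 1), m4 = c(-1, 0, 1))
  red <- reduce_stoichiometry(S)
  expect_equal(red$dependent_ids, "m4")
  # oracle: explicit multiplication reconstructs S
  expect_lt(max(abs(red$L %*% red$S_R - S)), 1e-10)
})

test_that("a duplicated metabolite row is moved to the dependent set", {
  S <- rbind(m1 = c(1, -1, 0), m2 = c(0, 1, -1), m3 = c(1, -1, 0))
  red <- reduce_stoichiometry(S)
  expect_equal(red$dependent_ids, "m3")
  expect_equal(nrow(red$S_R), rank_by_minors(S))
})

test_that("reduction preserves rank and reconstructs S on random networks", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n_met <- sample(3:8, 1); n_rxn <- sample(3:10, 1)
      S <- random_small_model(n_met, n_rxn, seed = 1000 + i)
      # inject a dependency: append a random combination of existing rows
      w <- sample(-2:2, n_met, replace = TRUE)
      S2 <- rbind(S, colSums(S * w))
      rownames(S2) <- paste0("m", seq_len(nrow(S2)))
      red <- reduce_stoichiometry(S2)
      expect_lt(max(abs(red$L %*% red$S_R - S2)), 1e-10)
      sv <- svd(S2)$d
      expect_equal(nrow(red$S_R), sum(sv > 1e-9 * max(sv, 1)))
    }
  })
})
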