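# core assembly, release, motif matching, rule application, enumeration

ket <- function(lab = "mal") module_substrate(aa_mod("AT"), lab, monolib)
hydrox <- function(lab = "mal")
  module_substrate(aa_mod(c("AT", "KR")), lab, monolib)

test_that("condensation chaining reproduces hand-drawn products", {
  # a single mal unit released as the free acid is acetic... the beta-keto
  # block itself: CH3-CHO as block, acid form CH3-COOH
  one <- assemble_core(list(ket()))
  acid <- release_products(one, te_present = FALSE)[[1]]
  expect_equal(mg_formula(acid$mg), "C2H4O2")
  # two beta-keto mal units -> acetoacetic acid C4H6O3
  two <- assemble_core(list(ket(), ket()))
  diketide <- release_products(two, te_present = FALSE)[[1]]
  expect_equal(mg_formula(diketide$mg), "C4H6O3")
  expect_equal(mg_to_smiles(diketide$mg),
               mg_to_smiles(mg_from_smiles("CC(=O)CC(=O)O")))
})

test_that("the monomer trace counts one alpha carbon per unit", {
  for (m in 1:4) {
    chain <- assemble_core(rep(list(ket("mmal")), m))
    expect_length(chain$alpha_atoms, m)
    expect_equal(sort(unique(chain$trace)), seq_len(m))
    # each unit contributes its block's atoms to the trace
    expect_equal(sum(chain$trace == 1L), length(ket("mmal")$mg$atoms))
  }
  expect_error(assemble_core(list(list(mg = ket()$mg))), "attachment-atom")
})

test_that("release yields the linear acid plus one lactone per eligible hydroxyl", {
  # no hydroxyls: TE or not, only the linear acid
  chain <- assemble_core(list(ket(), ket(), ket()))
  expect_length(release_products(chain, te_present = TRUE), 1L)
  # two hydroxyl-bearing units early in the chain: 3 cores
  chain2 <- assemble_core(list(hydrox(), hydrox(), ket(), ket()))
  cores <- release_products(chain2, te_present = TRUE)
  expect_length(cores, 3L)
  expect_equal(cores[[1]]$provenance, "linear")
  h2o <- 18.0105646863
  for (i in 2:3)
    expect_equal(mg_mass(cores[[i]]$mg), mg_mass(cores[[1]]$mg) - h2o,
                 tolerance = 1e-6)
  # without TE the lactones disappear
  expect_length(release_products(chain2, te_present = FALSE), 1L)
})

test_that("motif matching collapses automorphisms and orders deterministically", {
  prop <- mg_from_smiles("CCC")
  rC <- list(motif = mg_from_smiles("C"), require_h = NULL)
  expect_length(match_motif(prop, rC), 3L)
  tol <- mg_from_smiles("CC1=CC=CC=C1")
  rB <- list(motif = mg_from_smiles("C1=CC=CC=C1"), require_h = NULL)
  expect_length(match_motif(tol, rB), 1L)  # one unique atom set
  rN <- list(motif = mg_from_smiles("N"), require_h = NULL)
  expect_length(match_motif(tol, rN), 0L)
  m1 <- match_motif(prop, rC)
  m2 <- match_motif(prop, rC)
  expect_identical(m1, m2)
})

test_that("rule application follows formula arithmetic and inverts cleanly", {
  gt <- moddb[[which(vapply(moddb, `[[`, "", "enzyme_tag") == "GT-glucosyl")]]
  sub <- mg_from_smiles("CCO")
  site <- match_motif(sub, gt)[[1]]
  prod <- apply_rule(sub, gt, site)
  hexose_minus_water <- 162.052824
  expect_equal(mg_mass(prod), mg_mass(sub) + hexose_minus_water,
               tolerance = 1e-4)
  # empty edit script: identity
  id_rule <- structure(list(enzyme_tag = "noop", motif = mg_from_smiles("C"),
                            edits = list(), require_h = NULL),
                       class = "modification_rule")
  m <- mg_from_smiles("CCO")
  expect_equal(mg_to_smiles(apply_rule(m, id_rule, 1L)), mg_to_smiles(m))
  # adding then removing a bond restores the canonical form
  cyc <- structure(list(enzyme_tag = "cyc", motif = mg_from_smiles("CCCCC"),
                        edits = list(
                          list(op = "add_bond", a = 1L, b = 5L, order = 1L),
                          list(op = "remove_bond", a = 1L, b = 5L)),
                        require_h = NULL),
                   class = "modification_rule")
  pent <- mg_from_smiles("CCCCC")
  expect_equal(mg_to_smiles(apply_rule(pent, cyc, 1:5)), mg_to_smiles(pent))
  # valence-violating edits fail with the offending step named
  bad <- structure(list(enzyme_tag = "bad", motif = mg_from_smiles("C"),
                        edits = list(
                          list(op = "add_atom", element = "O", attach = 1L,
                               order = 3L)),
                        require_h = NULL),
                   class = "modification_rule")
  expect_error(apply_rule(mg_from_smiles("CC"), bad, 1L), "valence|order")
})

test_that("the packaged modification database loads 78 validated rules", {
  expect_s3_class(moddb, "modification_db")
  expect_length(moddb, 78L)
  tags <- vapply(moddb, `[[`, "", "enzyme_tag")
  expect_false(anyDuplicated(tags) > 0)
  # every motif is a parsed molgraph and self-application succeeded at load
  for (r in moddb) expect_s3_class(r$motif, "molgraph")
})

test_that("duplicate (motif, edits) rules warn but are kept", {
  tf <- tempfile(fileext = ".json")
  rule <- list(enzyme_tag = "a", motif = "CO",
               edits = list(list(op = "add_atom", element = "C",
                                 attach = 2L, order = 1L)),
               citation = "x")
  rule2 <- rule; rule2$enzyme_tag <- "b"
  jsonlite::write_json(list(rule, rule2), tf, auto_unbox = TRUE)
  expect_warning(db <- load_modification_db(tf), "duplicate")
  expect_length(db, 2L)
  bad <- rule; bad$edits <- list(list(op = "explode"))
  jsonlite::write_json(list(bad), tf, auto_unbox = TRUE)
  expect_error(load_modification_db(tf), "invalid modification rule")
})

test_that("candidate counts follow the closed form k x prod(m_i + 1)", {
  core1 <- release_products(assemble_core(list(hydrox(), ket())),
                            te_present = FALSE)[[1]]
  # no enzymes: one candidate per core
  e0 <- enumerate_candidates(list(core1), character(0), moddb)
  expect_length(e0$candidates, 1L)
  expect_equal(e0$report$raw_count, 1)
  # OMT-hydroxyl has m sites on this core; check against the formula
  e1 <- enumerate_candidates(list(core1), c("OMT-hydroxyl", "ST-sulfo"),
                             moddb)
  m <- e1$report$site_counts[[1]]
  expect_equal(e1$report$raw_count, prod(m + 1))
  expect_equal(e1$report$raw_count, enumeration_oracle(m))
  expect_warning(
    enumerate_candidates(list(core1), "no-such-enzyme", moddb),
    "no modification rule")
  expect_error(enumerate_candidates(list(core1), character(0), moddb,
                                    cap = 0), "cap")
})

test_that("randomised enumeration counts match the recursive oracle", {
  set.seed(31)
  tags <- c("OMT-hydroxyl", "AcT-acetyl", "ST-sulfo", "PT-kinase",
            "HAL-aromatic-Cl", "P450-methyl-OH")
  for (i in 1:12) {
    n_units <- sample(2:4, 1)
    units <- lapply(seq_len(n_units), function(j)
      if (runif(1) < 0.5) hydrox(sample(c("mal", "mmal"), 1))
      else ket(sample(c("mal", "mmal"), 1)))
    cores <- release_products(assemble_core(units),
                              te_present = runif(1) < 0.5)
    picked <- sample(tags, sample(1:3, 1))
    e <- suppressMessages(enumerate_candidates(cores, picked, moddb,
                                               cap = 1e4))
    oracle <- sum(vapply(e$report$site_counts, enumeration_oracle, 0))
    expect_equal(e$report$raw_count, oracle)
    expect_length(e$candidates,
                  as.integer(e$report$raw_count - e$report$failed_count))
    # full stream agreement with the independent depth-first generator
    rules <- lapply(picked, function(tg)
      moddb[[match(tg, vapply(moddb, `[[`, "", "enzyme_tag"))]])
    oracle_keys <- brute_force_candidates(cores, rules)
    expect_equal(sort(vapply(e$candidates, `[[`, "", "key")),
                 sort(oracle_keys))
  }
})

test_that("candidate masses recompute from their graphs", {
  core <- release_products(assemble_core(list(hydrox(), ket(), ket())),
                           te_present = TRUE)
  e <- enumerate_candidates(core, c("OMT-hydroxyl"), moddb)
  for (cand in e$candidates)
    expect_equal(cand$mass, mg_mass(cand$mg), tolerance = 1e-4)
  # determinism: two runs give identical streams
  e2 <- enumerate_candidates(core, c("OMT-hydroxyl"), moddb)
  expect_identical(vapply(e$candidates, `[[`, "", "key"),
                   vapply(e2$candidates, `[[`, "", "key"))
})
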