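# MGF I/O, fragmentation, exact and variable scoring, decoys, FDR

test_that("MGF files round-trip and malformed records are skipped", {
  s1 <- pks_spectrum(200.1, 1L, c(50.5, 120.2, 80.1), c(10, 30, 20),
                     id = "a")
  s2 <- pks_spectrum(300.2, 2L, c(150.1, 90.3), c(5, 8), id = "b")
  tf <- tempfile(fileext = ".mgf")
  write_mgf(list(s1, s2), tf)
  back <- read_mgf(tf)
  expect_length(back, 2L)
  expect_equal(back[[1]]$precursor_mz, 200.1)
  expect_equal(back[[2]]$charge, 2L)
  # peaks sorted on load
  expect_equal(back[[1]]$mz, sort(c(50.5, 120.2, 80.1)))
  # record without precursor is skipped with a warning
  writeLines(c("BEGIN IONS", "TITLE=broken", "100.1 5", "END IONS",
               "BEGIN IONS", "TITLE=ok", "PEPMASS=222.2", "CHARGE=1+",
               "111.1 9", "END IONS"), tf)
  expect_warning(out <- read_mgf(tf), "missing PEPMASS")
  expect_length(out, 1L)
  expect_equal(out[[1]]$id, "ok")
  writeLines(c("BEGIN IONS", "TITLE=x", "END IONS"), tf)
  expect_warning(expect_error(read_mgf(tf), "no spectra"))
})

test_that("spectra without charge default to 1 with a message", {
  tf <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=nc", "PEPMASS=500.5", "100 1",
               "END IONS"), tf)
  expect_message(out <- read_mgf(tf), "defaulted")
  expect_equal(out[[1]]$charge, 1L)
})

test_that("fragmentation matches hand enumeration on a 3-atom chain", {
  m <- mg_from_smiles("CCO")  # C-C-O, two acyclic single bonds
  fr <- fragment(m, 1L)
  # parent plus the four cut products: CH4, CH3OH-ish? cuts give
  # {C},{C-O} and {C-C},{O}: masses CH4, CH3OH, C2H6, H2O
  expect_equal(nrow(fr), 5L)
  expect_true(any(fr$depth == 0L))
  h <- 1.00782503207
  expected <- sort(c(12 + 4 * h,                    # CH4
                     18.0105646863,                # H2O
                     2 * 12 + 6 * h,               # C2H6
                     12 + 15.9949146196 + 4 * h,   # CH4O
                     mg_mass(m)))
  expect_equal(fr$mass, expected, tolerance = 1e-6)
})

test_that("ring fragmentation enumerates all two-bond cuts of benzene", {
  b <- mg_from_smiles("C1=CC=CC=C1")
  fr <- fragment(b, 1L)
  # all C(6,2)=15 cuts disconnect the ring into two paths; the distinct
  # fragment compositions are C1..C5 with H counts set by internal bonds
  expect_true(all(fr$n_atoms[fr$depth == 1L] < 6L))
  expect_gte(nrow(fr), 6L)
  # depth-2 fragments extend the set and keep the parent
  fr2 <- fragment(b, 2L)
  expect_gte(nrow(fr2), nrow(fr))
  expect_true(any(fr2$depth == 0L))
})

test_that("fragment masses are invariant to input atom ordering", {
  a <- mg_from_smiles("CC(=O)CC(O)CC(=O)O")
  b <- mg_from_smiles(mg_to_smiles(a))  # canonical re-ordering
  expect_equal(fragment(a, 2L)$mass, fragment(b, 2L)$mass, tolerance = 1e-9)
})

test_that("exact scoring gates on precursor and counts matched peaks", {
  m <- mg_from_smiles("CC(=O)CC(O)CC(=O)O")
  # synthetic spectrum from the molecule's own fragments
  sp <- make_spectrum(m, seed = 1)
  sm <- score_exact(m, sp)
  expect_equal(sm$score, length(sp$mz))
  expect_equal(sm$shift, 0)
  # empty spectrum scores zero
  empty <- pks_spectrum(mg_mass(m) + 1.007276466, 1L)
  expect_equal(score_exact(m, empty)$score, 0L)
  # precursor off by more than the tolerance: no match
  off <- pks_spectrum(mg_mass(m) + 1.007276466 + 5, 1L, c(100), c(1))
  expect_null(score_exact(m, off))
})

test_that("variable mode reduces to exact at zero shift", {
  m <- mg_from_smiles("CC(=O)CC(O)CC(=O)O")
  corpus <- lapply(1:10, function(s) make_spectrum(m, seed = s,
                                                   n_decoy_peaks = 3,
                                                   id = paste0("s", s)))
  for (sp in corpus) {
    ex <- score_exact(m, sp)
    va <- score_variable(m, sp, max_shift = 0)
    expect_equal(va$score, ex$score)
    expect_equal(va$shift, 0)
    expect_equal(va$matched_mz, ex$matched_mz)
  }
})

test_that("a removed appendage is recovered as the mass shift", {
  whole <- mg_from_smiles("CCCCCCCC(=O)OC(=O)CCCCC")  # has a cleavable ester
  # candidate = molecule lacking a 100.089-Da hexanoyl-ish appendage:
  # compare a molecule against the spectrum of a heavier relative
  core <- mg_from_smiles("CCCCCCCC(=O)O")
  sp <- make_spectrum(whole, seed = 2)
  delta_true <- mg_mass(whole) - mg_mass(core)
  va <- score_variable(core, sp, max_shift = 400)
  expect_equal(va$shift, delta_true, tolerance = 1e-6)
  expect_gt(va$score, 0)
  # gate: shift beyond max_shift rejects
  expect_null(score_variable(core, sp, max_shift = abs(delta_true) - 1))
})

test_that("a constructed 100-Da appendage is recovered with full self-match score", {
  base <- mg_from_smiles("CC(=O)CC(O)CC(=O)O")
  # append a 100.0-Da dummy: C4H8N2O (100.0637) close, use exact graph math:
  # spectrum built from base then precursor shifted by exactly 100
  sp <- make_spectrum(base, seed = 3)
  sp_shift <- pks_spectrum(sp$precursor_mz + 100.0, sp$charge, sp$mz,
                           sp$intensity, id = "shifted")
  va <- score_variable(base, sp_shift, max_shift = 400)
  expect_equal(va$shift, 100.0, tolerance = 1e-9)
  # unshifted fragment ions still match: same score as the intact self-match
  expect_equal(va$score, score_exact(base, sp)$score)
})

test_that("edge-switching decoys preserve composition and connectivity", {
  m <- mg_from_smiles("CC(=O)CC(O)CC(=O)OC1CCCCC1")
  expect_identical(mg_to_smiles(generate_decoy(m, steps = 0)),
                   mg_to_smiles(m))
  multideg <- function(mg) sort(mg_bond_order_sums(mg)[order(mg$atoms)])
  for (s in 1:20) {
    d <- generate_decoy(m, steps = 25, seed = s)
    expect_equal(mg_formula(d), mg_formula(m))  # heavy atoms + H untouched
    expect_equal(sort(d$atoms), sort(m$atoms))
    expect_equal(multideg(d), multideg(m))      # degree sequence preserved
    expect_true(pksline:::mg_is_connected(d))
  }
  expect_error(generate_decoy(molgraph("C"), steps = 5), ">= 2 bonds")
})

test_that("decoys are filtered against the target key set", {
  m <- mg_from_smiles("CCCO")
  # with every possible decoy listed as a target, generation must fail
  all_keys <- c(mg_inchikey(m),
                vapply(1:50, function(s)
                  mg_inchikey(generate_decoy(m, steps = 1, seed = s)), ""))
  expect_error(
    generate_decoy(m, steps = 1, seed = 1, targets = unique(all_keys),
                   max_regen = 3),
    "retry budget|failed")
})

test_that("FDR follows the decoy/target ratio and is monotone", {
  expect_equal(estimate_fdr(rep(10, 10), numeric(0), 5)$fdr, 0)
  expect_equal(estimate_fdr(rep(10, 50), rep(10, 5), 10)$fdr, 0.1)
  r <- estimate_fdr(numeric(0), rep(10, 5), 1)
  expect_true(r$undefined)
  expect_true(is.nan(r$fdr))
  # decoys stochastically dominated by targets: fdr declines with threshold
  target <- 1:100; decoy <- floor(target / 2)
  th <- 1:50
  f <- vapply(th, function(t) estimate_fdr(target, decoy, t)$fdr, 0)
  defined <- !is.nan(f)
  expect_true(all(diff(f[defined]) <= 1e-12))
  # counts never increase with the threshold
  nt <- vapply(th, function(t) estimate_fdr(target, decoy, t)$n_target, 0L)
  nd <- vapply(th, function(t) estimate_fdr(target, decoy, t)$n_decoy, 0L)
  expect_true(all(diff(nt) <= 0) && all(diff(nd) <= 0))
})
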