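# Isotope mass model: residue carbons, labelled masses, state
# enumeration, fragment conventions.

sch <- label_scheme("K")

test_that("residue carbon counts match elemental formulas", {
  expect_identical(residue_carbon_count("K"), 6L)
  expect_identical(residue_carbon_count("G"), 2L)
  expect_identical(residue_carbon_count("W"), 11L)
  expect_error(residue_carbon_count("X"), "unknown residue")
})

test_that("free lysine masses reproduce the MRM transition table", {
  heavy <- species_mass("K", TRUE, empty_scheme("K"),
                        as_free_amino_acid = TRUE)
  expect_equal(heavy, oracle_peptide_mass("K", 1L), tolerance = 1e-9)
  expect_equal(heavy, 146.10552 + 6 * 1.0033548, tolerance = 1e-4)
  tab <- free_lysine_transitions()
  expect_equal(tab$precursor_nominal, c(147L, 153L))
  expect_equal(tab$product_nominal, c(84L, 89L))
})

test_that("species mass equals the element-count oracle", {
  # identity case: all-light pattern, no fixed labels
  expect_equal(species_mass("KYSLAPVAKE", c(FALSE, FALSE),
                            empty_scheme("K")),
               oracle_peptide_mass("KYSLAPVAKE"), tolerance = 1e-9)
  # dipeptide GK with fixed-labelled G and heavy K: + (2+6) carbons
  gk <- label_scheme("K", fixed_labelled_residues = "G")
  expect_equal(species_mass("GK", TRUE, gk),
               oracle_peptide_mass("GK") + 8 * 1.0033548378,
               tolerance = 1e-9)
  expect_equal(species_mass("GK", TRUE, gk),
               oracle_peptide_mass("GK", heavy_positions = 1:2),
               tolerance = 1e-9)
  expect_error(species_mass("GK", c(TRUE, TRUE), gk), "pattern length")
})

test_that("mass differences between patterns are exact multiples of the shift", {
  pep <- "KYSLAPVAKE"
  pats <- enumerate_states(pep, sch)
  masses <- vapply(pats, function(p) species_mass(pep, p, sch), 0)
  for (a in seq_along(pats)) for (b in seq_along(pats)) {
    expected <- 6 * dilac_constants[["c13_shift"]] *
      (sum(pats[[a]]) - sum(pats[[b]]))
    expect_equal(masses[a] - masses[b], expected, tolerance = 1e-12)
  }
})

test_that("state enumeration is complete, unique and lexicographic", {
  pats <- enumerate_states("KYSLAPVAKE", sch)
  expect_length(pats, 4L)
  expect_identical(pats[[1]], c(FALSE, FALSE))
  expect_identical(pats[[2]], c(FALSE, TRUE))
  expect_identical(pats[[3]], c(TRUE, FALSE))
  expect_identical(pats[[4]], c(TRUE, TRUE))
  expect_identical(enumerate_states("AVLE", sch), list(logical(0)))
  pats3 <- enumerate_states("KAKAKE", sch)
  expect_length(pats3, 8L)
  expect_identical(anyDuplicated(vapply(pats3, paste, "",
                                        collapse = "")), 0L)
})

test_that("m/z follows the charge convention", {
  m <- species_mass("KYSLAPVAKE", c(TRUE, TRUE), sch)
  expect_equal(mz_from_mass(m, 1L) - dilac_constants[["proton"]], m)
  expect_lt(mz_from_mass(m, 2L), mz_from_mass(m, 1L))
  sp <- labelled_species("KYSLAPVAKE", c(TRUE, TRUE), sch, charge = 2L)
  expect_equal(sp$mz, (m + 2 * dilac_constants[["proton"]]) / 2)
})

test_that("fragment species restrict the pattern to covered sites", {
  # y5 of KYSLAPVAKE is PVAKE, covering the second lysine only
  hv <- fragment_species("KYSLAPVAKE", "y", 5, c(FALSE, TRUE), sch)
  lt <- fragment_species("KYSLAPVAKE", "y", 5, c(FALSE, FALSE), sch)
  expect_identical(hv$sequence, "PVAKE")
  expect_identical(hv$n_target_sites, 1L)
  expect_equal(hv$mass - lt$mass, 6 * 1.0033548378, tolerance = 1e-9)
  # y3 (AKE) under a scheme with no fixed labels is independent of the
  # first site
  a <- fragment_species("KYSLAPVAKE", "y", 3, c(TRUE, TRUE),
                        empty_scheme("K"))
  b <- fragment_species("KYSLAPVAKE", "y", 3, c(FALSE, TRUE),
                        empty_scheme("K"))
  expect_equal(a$mass, b$mass)
  # neutral-mass conventions against the oracle (unlabelled)
  y5 <- fragment_species("KYSLAPVAKE", "y", 5, c(FALSE, FALSE),
                         empty_scheme("K"))
  expect_equal(y5$mass, oracle_peptide_mass("PVAKE"), tolerance = 1e-9)
  b3 <- fragment_species("KYSLAPVAKE", "b", 3, c(FALSE, FALSE),
                         empty_scheme("K"))
  expect_equal(b3$mass,
               oracle_peptide_mass("KYS") -
                 2 * oracle_elements[["H"]] - oracle_elements[["O"]],
               tolerance = 1e-9)
  expect_error(fragment_species("KYSLAPVAKE", "y", 10, c(FALSE, FALSE),
                                sch), "out of range")
})

test_that("y/b fragment site counts partition the peptide's sites", {
  for (pep in c("KYSLAPVAKE", "KAKAKE", "AVLKPE")) {
    n_tot <- lengths(regmatches(pep, gregexpr("K", pep)))
    pat <- rep(FALSE, n_tot)
    for (k in 1:(nchar(pep) - 1L)) {
      y <- fragment_species(pep, "y", k, pat, sch)
      b <- fragment_species(pep, "b", nchar(pep) - k, pat, sch)
      expect_identical(y$n_target_sites + b$n_target_sites, n_tot)
    }
  }
})
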