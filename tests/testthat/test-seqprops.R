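test_that("chain masses match hand-computed residue sums", {
  expect_equal(round(average_mass("G"), 2), 75.07)
  expect_equal(round(average_mass("GG"), 2), 132.12)
  expect_equal(round(monoisotopic_mass("G"), 4), 75.0320)
  expect_equal(round(monoisotopic_mass("AG"), 4), 146.0691)
  expect_error(average_mass("GXG"), "X")
  expect_equal(average_mass("GXG", allow_x = TRUE), average_mass("GG"))
})

test_that("mass additivity under concatenation holds to 1e-6 Da", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:20) {
    a <- paste(sample(aas, sample(3:15, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:15, 1), replace = TRUE), collapse = "")
    expect_equal(average_mass(paste0(a, b)),
                 average_mass(a) + average_mass(b) - 18.01528,
                 tolerance = 1e-6 / average_mass(paste0(a, b)))
    expect_equal(monoisotopic_mass(paste0(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b) - 18.010565,
                 tolerance = 1e-6 / monoisotopic_mass(paste0(a, b)))
    # monoisotopic below average for any chain of length > 1
    expect_lt(monoisotopic_mass(a), average_mass(a))
  }
})

test_that("adding a residue strictly increases mass", {
  base <- "ACDE"
  for (aa in strsplit("GASPV", "")[[1L]]) {
    expect_gt(monoisotopic_mass(paste0(base, aa)), monoisotopic_mass(base))
  }
})

test_that("isoelectric point zeroes the net charge and matches a grid scan", {
  seqs <- c("GG", "DDDD", "KKKK", "KCQQDSGEEPSEE", "ACDEFGHIKLMNPQRSTVWY")
  for (s in seqs) {
    pi_ <- isoelectric_point(s)
    expect_lt(abs(net_charge(s, pi_)), 1e-3)
    # independent oracle: fine-grid scan for the sign change
    grid <- seq(0, 14, by = 1e-3)
    qc <- net_charge(s, grid)
    cross <- grid[which(diff(sign(qc)) != 0)[1L]]
    expect_equal(pi_, cross, tolerance = 2e-3)
  }
  expect_lt(isoelectric_point("DDDD"), 4.5)
})

test_that("net charge decreases strictly with pH", {
  q <- net_charge("ACDEFGHIKLMNPQRSTVWY", seq(1, 13, by = 0.5))
  expect_true(all(diff(q) < 0))
})

test_that("maturation strips the signal peptide and conserves mass", {
  s <- protein_sequence("pre", "MKKAA", cleavage_site = 3)
  m <- mature_sequence(s)
  expect_equal(m$residues, "AA")
  expect_equal(m$id, "pre_mature")
  signal <- protein_sequence("sig", substr(s$residues, 1, 3))
  expect_equal(average_mass(s) - average_mass(m),
               average_mass(signal) - 18.01528, tolerance = 1e-9)
  expect_error(mature_sequence(protein_sequence("x", "MKKAA")),
               "cleavage")
  # cleaving at the end would leave an empty mature chain
  expect_error(protein_sequence("x", "MKKAA", cleavage_site = 5),
               "inside")
})

test_that("global-alignment identity behaves like an identity", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:5) {
    a <- paste(sample(aas, 20, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 15, replace = TRUE), collapse = "")
    ab <- pairwise_identity(a, b)
    expect_equal(ab, pairwise_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 100)
    expect_lt(pairwise_identity(a, b), 100) # distinct random sequences
  }
})

test_that("coverage is the union of exact peptide matches", {
  prot <- "ACDEFGHIKL"
  expect_equal(as.numeric(sequence_coverage("ACDEF", prot)), 50)
  expect_equal(as.numeric(sequence_coverage(c("ACDEFG", "EFGHIKL"), prot)),
               100)
  expect_warning(cov0 <- sequence_coverage("WWW", prot), "not found")
  expect_equal(as.numeric(cov0), 0)
  # invariant to order and duplication
  expect_equal(as.numeric(sequence_coverage(c("EFGHIKL", "ACDEFG",
                                              "ACDEFG"), prot)), 100)
})

test_that("gel migration mass estimation is log-linear in Rm", {
  std <- data.frame(mass_kda = c(97, 14), rm = c(0.1, 0.9))
  # the fitted line passes through the standards
  expect_equal(mass_from_relative_migration(0.1, std), 97)
  expect_equal(mass_from_relative_migration(0.9, std), 14)
  # log-linear midpoint is the geometric mean
  expect_equal(mass_from_relative_migration(0.5, std), sqrt(97 * 14),
               tolerance = 1e-9)
  expect_equal(round(mass_from_relative_migration(0.5, std), 2), 36.85)
  # monotone decreasing for a negative slope
  ms <- mass_from_relative_migration(seq(0.1, 0.9, 0.1), std)
  expect_true(all(diff(ms) < 0))
  expect_error(mass_from_relative_migration(0.5,
               data.frame(mass_kda = 97, rm = 0.1)), ">= 2")
  expect_error(mass_from_relative_migration(1.5, std), "rm")
})
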