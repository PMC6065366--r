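synthetic_construct <- function() {
  read_fasta(system.file("extdata", "RGG_x_RGG_synthetic.fasta",
                         package = "dropletkit"))[[1]]
}

test_that("protease digestion applies the recognition rules", {
  expect_identical(digest("MAENLYFQGHKL", "TEV"), c("MAENLYFQ", "GHKL"))
  expect_identical(digest("AALVPRGSKK", "thrombin"), c("AALVPR", "GSKK"))
  expect_identical(digest("AALEVLFQGPKK", "HRV3C"), c("AALEVLFQ", "GPKK"))
  # no motif: sequence unchanged (specificity)
  expect_identical(digest("MGRGGRGG", c("TEV", "thrombin", "HRV3C")),
                   "MGRGGRGG")
  # motif without the required C-side residue is not cut
  expect_identical(digest("MAENLYFQAHKL", "TEV"), "MAENLYFQAHKL")
  expect_error(digest("MAENLYFQG", "pepsin"), "unknown protease")
  expect_error(digest("MAB", "TEV"), "non-standard residue 'B' at position 3")
})

test_that("multi-site digestion yields single and tandem fragments", {
  # triplet with TEV between 1-2 and HRV3C between 2-3
  s <- paste0("MRGGYRGGA", "ENLYFQG", "SRGGYRGGA", "LEVLFQGP", "SRGGYRGGA")
  expect_identical(length(digest(s, "TEV")), 2L)
  expect_identical(length(digest(s, "HRV3C")), 2L)
  expect_identical(length(digest(s, c("TEV", "HRV3C"))), 3L)
  # digestion is idempotent
  fr <- digest(s, c("TEV", "HRV3C"))
  expect_identical(unlist(lapply(fr, digest, proteases = c("TEV", "HRV3C"))),
                   fr)
})

test_that("average masses match an independent elemental-composition oracle", {
  # frozen reference values computed from atomic composition (average
  # atomic weights), an independent route to the same quantity
  expect_equal(average_mass("G"), 75.0667, tolerance = 0.001)
  expect_equal(average_mass("GS"), 162.1441, tolerance = 0.001)
  expect_equal(average_mass("MAENLYFQGHKL"), 1450.6627, tolerance = 0.02)
  expect_equal(average_mass("ACDEFGHIKLMNPQRSTVWY"), 2395.7174, tolerance = 0.05)
  expect_error(average_mass("GSX"), "position 3")
})

test_that("mass is conserved across digestion up to one water per cut", {
  seqs <- c(synthetic_construct(),
            "MRGGYRGGAENLYFQGSRGGYRGGALEVLFQGPSRGGYRGGA",
            "AALVPRGSENLYFQGKK")
  for (s in seqs) {
    for (prot in list("TEV", c("TEV", "thrombin", "HRV3C"))) {
      fr <- digest(s, prot)
      n_cuts <- length(fr) - 1
      expect_equal(sum(vapply(fr, average_mass, numeric(1))),
                   average_mass(s) + 18.0153 * n_cuts, tolerance = 0.01)
    }
  }
})

test_that("the tandem construct digests into the reported fragment masses", {
  s <- synthetic_construct()
  fr <- digest(s, "TEV")
  expect_identical(length(fr), 2L)
  masses <- vapply(fr, average_mass, numeric(1))
  expect_equal(unname(masses[1]), 17843, tolerance = 1 / 17843)
  expect_equal(unname(masses[2]), 17907, tolerance = 1 / 17907)
})

test_that("species census tracks valency, tags and masses through digestion", {
  tandem <- construct_spec("RGG-x-RGG", c("RGG", "TEV", "RGG"))
  cs <- species_census(tandem, "TEV")
  expect_identical(nrow(cs), 2L)
  expect_equal(cs$valency, c(1, 1))

  mbp <- construct_spec("MBP-RGG-RGG", c("MBP", "HRV3C", "RGG", "RGG"))
  cs0 <- species_census(mbp, character())
  expect_identical(nrow(cs0), 1L)
  expect_equal(cs0$valency, 2)
  expect_true(cs0$has_MBP)
  cs1 <- species_census(mbp, "HRV3C")
  expect_identical(nrow(cs1), 2L)
  expect_equal(cs1$valency, c(0, 2))
  expect_identical(cs1$has_MBP, c(TRUE, FALSE))
  # a protease without a site is a no-op
  expect_identical(species_census(mbp, "TEV"), cs0)

  # with sequences, fragment masses follow the scissile-bond split
  seqs <- c("MRGGYRGG", NA, "ARGGYRGG", "ARGGYRGG")
  seqs[2] <- "ENLYFQG"
  tandem_seq <- construct_spec("t", c("RGG", "TEV", "RGG", "RGG"), seqs)
  css <- species_census(tandem_seq, "TEV")
  expect_identical(css$sequence, c("MRGGYRGGENLYFQ", "GARGGYRGGARGGYRGG"))
  expect_equal(css$mass, vapply(css$sequence, average_mass, numeric(1)),
               ignore_attr = TRUE)

  # adding a protease never increases any fragment's valency
  triplet <- construct_spec("RGG-x-RGG-y-RGG",
                            c("RGG", "TEV", "RGG", "HRV3C", "RGG"))
  expect_lte(max(species_census(triplet, c("TEV", "HRV3C"))$valency),
             max(species_census(triplet, "TEV")$valency))
})

test_that("phase-state rules reproduce the protease AND gate", {
  triplet <- construct_spec("RGG-x-RGG-y-RGG",
                            c("RGG", "TEV", "RGG", "HRV3C", "RGG"))
  expected <- list(list(character(), "turbid", 50),
                   list("TEV", "turbid", 40),
                   list("HRV3C", "turbid", 40),
                   list(c("TEV", "HRV3C"), "soluble", 15))
  for (case in expected) {
    ps <- predict_phase_state(species_census(triplet, case[[1]]), 25)
    expect_identical(ps$state, case[[2]])
    expect_equal(ps$threshold, case[[3]])
  }

  # MBP-triggered assembly: soluble until HRV3C liberates the scaffold
  mbp <- construct_spec("MBP-RGG-RGG", c("MBP", "HRV3C", "RGG", "RGG"))
  expect_identical(predict_phase_state(species_census(mbp), 25)$state, "soluble")
  expect_identical(predict_phase_state(species_census(mbp, "HRV3C"), 25)$state,
                   "turbid")

  # transition temperatures in the table must increase with valency
  expect_error(phase_rule_table(c("1" = 40, "2" = 30)), "diff")
  # valency beyond the table is refused, not extrapolated
  quad <- construct_spec("4x", c("RGG", "RGG", "RGG", "RGG"))
  expect_error(predict_phase_state(species_census(quad), 25), "valency")
})

test_that("recruitment rules reproduce the reported cargo classes", {
  scaffold <- construct_spec("RGG-RGG", c("RGG", "RGG"))
  sz_scaffold <- construct_spec("SZ1-RGG-RGG", c("SZ1", "RGG", "RGG"))

  # untagged cargo is excluded
  rfp <- construct_spec("RFP", "cargo")
  expect_identical(predict_recruitment(scaffold, rfp)$class, "excluded")
  expect_lt(predict_recruitment(scaffold, rfp)$ei, 1)

  # single RGG: weak (EI ~4); double RGG: strong (EI ~27)
  one <- construct_spec("RFP-RGG", c("cargo", "RGG"))
  expect_equal(predict_recruitment(scaffold, one)$ei, 4)
  two <- construct_spec("RGG-RFP-RGG", c("RGG", "cargo", "RGG"))
  expect_equal(predict_recruitment(scaffold, two)$ei, 27)

  # SZ2 cargo needs an SZ1 scaffold (EI ~20, else excluded)
  sz2 <- construct_spec("RFP-SZ2", c("cargo", "SZ2"))
  expect_equal(predict_recruitment(sz_scaffold, sz2)$ei, 20)
  expect_identical(predict_recruitment(scaffold, sz2)$class, "excluded")

  # TEV on a cleavable tag releases cargo; scaffold droplets persist
  sz2_cut <- construct_spec("RFP-x-SZ2", c("cargo", "TEV", "SZ2"))
  pr <- predict_recruitment(sz_scaffold, sz2_cut, proteases = "TEV")
  expect_true(pr$released)
  expect_true(pr$droplets_intact)

  # two-step multi-cargo release: TEV frees cargo2 (droplets intact),
  # thrombin then frees cargo1 and dissolves the droplets
  sc2 <- construct_spec("SZ1-RGG-x-cargo1-x-RGG",
                        c("SZ1", "RGG", "thrombin", "cargo", "thrombin", "RGG"))
  cargo2 <- construct_spec("cargo2-x-SZ2", c("cargo", "TEV", "SZ2"))
  step1 <- predict_recruitment(sc2, cargo2, proteases = "TEV")
  expect_true(step1$released)
  expect_true(step1$droplets_intact)
  step2 <- predict_recruitment(sc2, cargo2, proteases = c("TEV", "thrombin"))
  expect_false(step2$droplets_intact)
  cs <- species_census(sc2, "thrombin")
  cargo_species <- cs[grepl("cargo", cs$tags), ]
  expect_equal(cargo_species$valency, 0)   # cargo1 liberated from both RGGs

  # scaffold that cannot phase separate is rejected up front
  mbp <- construct_spec("MBP-RGG-RGG", c("MBP", "HRV3C", "RGG", "RGG"))
  expect_error(predict_recruitment(mbp, rfp), "does not phase separate")
})
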