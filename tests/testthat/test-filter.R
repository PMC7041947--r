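cavmr <- filterSequence("TLEGWVD", 183, "CavMr")
navpp <- filterSequence("TLEDWTD", 1, "NavPp")

test_that("filter windows renumber bijectively between parent and local", {
  expect_equal(localPosition(cavmr, 183), 1L)  # Thr183 -> Thr1
  expect_equal(localPosition(cavmr, 189), 7L)  # Asp189 -> Asp7
  expect_error(localPosition(cavmr, 190), "outside the filter window")
  expect_error(localPosition(cavmr, 182), "outside the filter window")
  for (p in 1:7)
    expect_equal(localPosition(cavmr, parentPosition(cavmr, p)), p)
  expect_error(parentPosition(cavmr, 8), "1-7")
})

test_that("filter sequences validate residues and length", {
  expect_error(filterSequence("TLEGWV"), "7-character")
  expect_error(filterSequence("TLEGWVZ"), "invalid residue")
  expect_equal(filterResidues(filterSequence("tlegwvd")), "TLEGWVD")
})

test_that("mutation codes apply, compose, and reject mismatches", {
  expect_equal(filterResidues(applyMutation(navpp, "T6S")), "TLEDWSD")
  expect_equal(filterResidues(applyMutation(navpp, "T6A")), "TLEDWAD")
  expect_equal(filterResidues(applyMutation(cavmr, "D7M")), "TLEGWVM")
  # swap mutations compose left to right
  expect_equal(filterResidues(applyMutation(cavmr, "G4D/V6T")), "TLEDWTD")
  expect_error(applyMutation(cavmr, "G5D"), "reference mismatch")
  expect_error(applyMutation(cavmr, "G4"), "malformed")
  # parent numbering requires the window offset
  expect_equal(filterResidues(applyMutation(cavmr, "G186A",
                                            numbering = "parent")),
               "TLEAWVD")
  expect_error(applyMutation(cavmr, "G240A", numbering = "parent"),
               "outside the filter window")
})

test_that("mutations are invertible by the reverse code", {
  withr::local_seed(2)
  for (i in 1:10) {
    pos <- sample(1:7, 1)
    orig <- substr(cavmr@residues, pos, pos)
    alt <- sample(setdiff(Biostrings::AA_STANDARD, orig), 1)
    fwd <- applyMutation(cavmr, paste0(orig, pos, alt))
    back <- applyMutation(fwd, paste0(alt, pos, orig))
    expect_equal(filterResidues(back), filterResidues(cavmr))
  }
})

test_that("charge accounting reproduces the published assembly counts", {
  cc <- chargeCount("TLEGWVD")        # CavMr homotetramer
  expect_equal(cc$netNegativePerAssembly, 8)
  expect_equal(cc$aspartatesPerAssembly, 4)
  expect_equal(cc$acidicPerSubunit, 2)

  expect_equal(chargeCount("TLDDWSD")$netNegativePerAssembly, 12)  # CavAb
  expect_equal(chargeCount("TLDDWSD")$aspartatesPerAssembly, 12)
  expect_equal(chargeCount("TLSSWAS")$netNegativePerAssembly, 0)

  # additive over subunits; order within the window is irrelevant
  expect_equal(chargeCount("TLEGWVD", nSubunits = 1)$netNegativePerAssembly * 4,
               chargeCount("TLEGWVD", nSubunits = 4)$netNegativePerAssembly)
  expect_equal(chargeCount("DVWGELT")$netNegativePerAssembly,
               chargeCount("TLEGWVD")$netNegativePerAssembly)

  # heteromeric assembly: four distinct filters, one subunit each
  het <- chargeCount(list("TLEGWVD", "TLEDWTD", "TLSSWAS", "TLDDWSD"))
  expect_equal(het$netNegativePerAssembly, 2 + 3 + 0 + 3)
  expect_equal(het$aspartatesPerAssembly, 1 + 2 + 0 + 3)
})

test_that("frequency matrices are column-normalized relative frequencies", {
  single <- frequencyMatrix(list(cavmr))
  expect_true(all(abs(colSums(single) - 1) < 1e-12))
  expect_equal(single["T", 1], 1)
  expect_equal(single["D", 7], 1)

  two <- frequencyMatrix(list("TLEGWVD", "TLEDWTD"))
  expect_equal(two["G", 4], 0.5)
  expect_equal(two["D", 4], 0.5)
  expect_true(all(abs(colSums(two) - 1) < 1e-12))

  # n copies of one sequence equal a single copy
  rep5 <- frequencyMatrix(rep(list("TLEGWVD"), 5))
  expect_equal(unclass(rep5)[, ], unclass(single)[, ])
  expect_equal(attr(rep5, "n_sequences"), 5)
  expect_error(frequencyMatrix(list()), "empty")
})

test_that("builtin filters and FASTA window extraction agree", {
  expect_equal(filterResidues(builtinFilters("CavMr")), "TLEGWVD")
  expect_equal(parentOffset(builtinFilters("CavMr")), 183L)
  expect_equal(filterResidues(builtinFilters("NavPp")), "TLEDWTD")
  expect_equal(filterResidues(builtinFilters("CatSper3")), "TVDGWTD")
  expect_error(builtinFilters("nope"), "Available")

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chanA", "MKKLLATLEGWVDPQRS", ">chanB", "MATLEDWTDKK"), fa)
  fs <- readFilterFasta(fa, offset = c(7, 3))
  expect_equal(filterResidues(fs[["chanA"]]), "TLEGWVD")
  expect_equal(filterResidues(fs[["chanB"]]), "TLEDWTD")
  expect_equal(parentOffset(fs[["chanA"]]), 7L)

  csv <- tempfile(fileext = ".csv")
  writeFrequencyMatrixCsv(frequencyMatrix(fs), csv)
  back <- utils::read.csv(csv, row.names = 1)
  expect_equal(back["G", "pos4"], 0.5)
})
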