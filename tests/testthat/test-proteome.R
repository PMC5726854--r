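# Proteome-scale distributions, GO filtering, file round trips.

test_that("GO filter retains exactly the constructed cytoplasmic subset", {
  gp <- generateProteome(nProteins = 40, fractionCytoplasmic = 0.3, seed = 5)
  expect_message(kept <- filterCytoplasmic(gp$proteome), "12 of 40")
  expect_length(kept, 12L)
  # records without terms are dropped; one with the cytosol term is kept
  meta <- S4Vectors::mcols(gp$proteome)
  expect_true(all(meta$go_terms[1:12] == "GO:0005829"))
  expect_error(filterCytoplasmic(Biostrings::AAStringSet(c(a = "GKD"))),
               "go_terms")
})

test_that("single protein yields unit histogram mass in its bin", {
  prot <- Biostrings::AAStringSet(c(p1 = "GKDKEKRKAG"))
  S4Vectors::mcols(prot) <- S4Vectors::DataFrame(go_terms = "",
                                                 copy_number = 1)
  h <- proteomeDistribution(prot)
  expect_equal(sum(h$charge$count), 1)
  expect_equal(sum(h$pi$count), 1)
  z <- h$table$net_charge[1]
  expect_equal(h$charge$count[h$charge$mid == round(z)], 1)
})

test_that("copy-number weighting equals record duplication", {
  s <- c(a = "GKDKEKRKAG", b = "DDEEGGKK")
  dup <- Biostrings::AAStringSet(c(s, s))
  S4Vectors::mcols(dup) <- S4Vectors::DataFrame(
    go_terms = rep("", 4), copy_number = rep(1, 4))
  wt <- Biostrings::AAStringSet(s)
  S4Vectors::mcols(wt) <- S4Vectors::DataFrame(
    go_terms = rep("", 2), copy_number = c(2, 2))
  hDup <- proteomeDistribution(dup, weighting = "none")
  hWt <- proteomeDistribution(wt, weighting = "copy_number")
  expect_equal(hWt$charge$count, hDup$charge$count)
  expect_equal(hWt$pi$count, hDup$pi$count)
})

test_that("weighting without copy numbers is rejected", {
  prot <- Biostrings::AAStringSet(c(p1 = "GKD"))
  S4Vectors::mcols(prot) <- S4Vectors::DataFrame(go_terms = "",
                                                 copy_number = NA_real_)
  expect_error(proteomeDistribution(prot, weighting = "copy_number"),
               "absent")
})

test_that("generator hits the target mean net charge in expectation", {
  gp <- generateProteome(nProteins = 500, compositionBias = 0, seed = 21)
  z <- proteomeChargeTable(gp$proteome)$net_charge
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - 0), 3 * se)
  # a biased proteome shifts accordingly
  gpNeg <- generateProteome(nProteins = 300, compositionBias = -5, seed = 22)
  zNeg <- proteomeChargeTable(gpNeg$proteome)$net_charge
  seNeg <- sd(zNeg) / sqrt(length(zNeg))
  expect_lt(abs(mean(zNeg) - (-5)), 3 * seNeg)
})

test_that("generator serialisation is byte-identical per seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateProteome(nProteins = 30, seed = 9, dir = d1)
  generateProteome(nProteins = 30, seed = 9, dir = d2)
  for (f in c("proteome.fasta", "go.tsv", "copy_number.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  gpOther <- generateProteome(nProteins = 30, seed = 10, dir = NULL)
  expect_false(identical(
    as.character(gpOther$proteome),
    as.character(generateProteome(nProteins = 30, seed = 9)$proteome)))
})

test_that("readProteome round-trips FASTA with GO and copy annotations", {
  d <- withr::local_tempdir()
  gp <- generateProteome(nProteins = 25, fractionCytoplasmic = 0.4,
                         seed = 13, dir = d)
  back <- readProteome(file.path(d, "proteome.fasta"),
                       goTsv = file.path(d, "go.tsv"),
                       copyTsv = file.path(d, "copy_number.tsv"))
  expect_identical(as.character(back), as.character(gp$proteome))
  expect_identical(S4Vectors::mcols(back)$copy_number,
                   as.numeric(S4Vectors::mcols(gp$proteome)$copy_number))
  expect_length(suppressMessages(filterCytoplasmic(back)), 10L)
})
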