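test_that("arm features match hand counts", {
  f <- armFeatures(c("AAAAATT", "GCGCG", "AAAATATA"))
  expect_equal(f$atContent, c(1, 0, 1))
  expect_equal(f$tractOcc, c(5 / 7, 0, 0.5))
  expect_equal(f$altOcc, c(2 / 7, 0, 0.5))

  # alternating stretches count complete dinucleotide units only
  expect_equal(armFeatures("ATA")$altOcc, 2 / 3)
  expect_equal(armFeatures("TATAT")$altOcc, 4 / 5)
  # runs shorter than minTract score zero
  expect_equal(armFeatures("AATTAAC")$tractOcc, 0)
  expect_equal(armFeatures("AATTAAC", minTract = 2L)$tractOcc, 2 / 7)

  expect_error(armFeatures("AANAT"), "N")
  expect_error(armFeatures(""), "empty")
})

test_that("feature invariants hold on random arms", {
  set.seed(5)
  for (i in 1:200) {
    arm <- randomSeq(sample(5:17, 1), runif(1, 0.2, 0.9))
    f <- armFeatures(arm)
    L <- nchar(arm)
    expect_true(all(unlist(f) >= 0 & unlist(f) <= 1))
    expect_equal(f$tractOcc * L, round(f$tractOcc * L))
    alt_len <- f$altOcc * L
    expect_equal(alt_len %% 2, 0)   # whole (AT)/(TA) units
  }
})

test_that("the seven-type mapping follows the three predicates", {
  arms <- c(I = "AAATAT",      # tract 3/6, alt 4/6, AT-rich
            II = "AAAAATT",    # tract-rich only
            III = "ATATAT",    # alternating-rich only
            IV = "AATTA",      # AT-rich, neither occupancy
            V = "AAAGGC",      # tract-rich, not AT-rich
            VI = "ATATGCG",    # alternating-rich, not AT-rich
            VII = "GCGCG")     # none of the three
  got <- as.character(classifyArmFeatures(armFeatures(unname(arms))))
  expect_equal(got, names(arms))

  # AT-rich arm with sub-threshold occupancies lands in IV
  both <- armFeatures("ATATATAAAGGCGCG")  # at 9/15, alt 6/15, tract 3/15
  expect_equal(as.character(classifyArmFeatures(both)), "IV")
  # VI absorbs both non-AT-rich alternating-rich combinations
  f <- data.frame(atContent = 0.5, tractOcc = 0.6, altOcc = 0.6)
  expect_equal(as.character(classifyArmFeatures(f)), "VI")
})

test_that("every arm gets exactly one type and thresholds are boundary-inclusive", {
  set.seed(9)
  arms <- vapply(1:300, function(i) randomSeq(sample(5:17, 1),
                                              runif(1, 0.1, 0.95)),
                 character(1))
  types <- classifyArmFeatures(armFeatures(arms))
  expect_false(any(is.na(types)))
  expect_true(all(as.character(types) %in% c("I", "II", "III", "IV", "V",
                                             "VI", "VII")))
  # boundary: exactly 0.6 AT and exactly 0.5 occupancies are "rich"
  f <- data.frame(atContent = 0.6, tractOcc = 0.5, altOcc = 0.5)
  expect_equal(as.character(classifyArmFeatures(f)), "I")
  f2 <- data.frame(atContent = 0.599, tractOcc = 0.499, altOcc = 0.499)
  expect_equal(as.character(classifyArmFeatures(f2)), "VII")
})

test_that("classification is symmetric in the two arms", {
  set.seed(13)
  for (i in 1:100) {
    arm <- randomSeq(sample(5:14, 1), runif(1, 0.3, 0.9))
    left <- classifyArmFeatures(armFeatures(arm))
    right <- classifyArmFeatures(armFeatures(revcompStr(arm)))
    expect_equal(as.character(left), as.character(right))
  }
})

test_that("classifyIRs annotates an IRSet in place", {
  x <- findMaximalIRs("CCCCATATATATATATCCCC")
  x <- classifyIRs(x)
  expect_equal(as.character(irType(x)), rep("III", length(x)))
  expect_true(all(mcols(x)$atContent == 1))
  # empty set keeps the schema
  e <- classifyIRs(findMaximalIRs("AAAAAAAAAAAAAAA"))
  expect_true("typeId" %in% colnames(mcols(e)))
  expect_equal(length(e), 0L)
})
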