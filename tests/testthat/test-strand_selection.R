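test_that("the twin-drive formula behaves at its limit cases", {
  params <- twinDriveParams()
  expect_equal(unname(predictLnRatio(5, 5, "U", "U", params)), 0)

  # k = 0: prediction reduces to the 5'-nucleotide preference U > A > G > C
  p0 <- params; p0$k <- 0
  lnU <- predictLnRatio(1, 9, "U", "C", p0)
  lnA <- predictLnRatio(1, 9, "A", "C", p0)
  lnG <- predictLnRatio(1, 9, "G", "C", p0)
  lnC <- predictLnRatio(1, 9, "C", "C", p0)
  expect_true(lnU > lnA && lnA > lnG && lnG > lnC)
  expect_equal(unname(lnC), 0)

  expect_error(predictLnRatio(1, 1, "N", "U", params), "no N value")
})

test_that("an easier-to-unwind 5p end raises the predicted 5p dominance", {
  params <- twinDriveParams()
  base <- predictLnRatio(3, 3, "U", "U", params)
  easier <- predictLnRatio(1, 3, "U", "U", params)  # lower 5p unwinding cost
  expect_gt(easier, base)
})

test_that("let-7 end energies and 5' nucleotides point at the 5p guide", {
  prof <- memo("let7prof",
               computeUnwindingProfile(let7Set(), "mfe_pinned", cfg20))
  set <- let7Set()
  ln <- predictLnRatio(ddG(prof)["5p_end", "n4"], ddG(prof)["3p_end", "n4"],
                       substr(set@seq5p, 1, 1), substr(set@seq3p, 1, 1),
                       twinDriveParams())
  expect_gt(ln, 0)   # predicted 5p dominant, the annotated guide arm
})

test_that("predictions join end energies blind to the annotation", {
  tbl <- data.frame(name = rep(c("a", "b"), each = 4),
                    end = rep(c("5p_end", "3p_end"), 4),
                    width = rep(rep(1:2, each = 2), 2),
                    ddG = c(1, 4, 2, 8, 4, 1, 8, 2))
  set <- MirnaSet(c("a", "b"), seq5p = c("UGAG", "CGAG"),
                  seq3p = c("CUAU", "UUAU"), guideArm = c("5p", "3p"))
  pred <- predictStrands(tbl, set, method = "mfe_pinned")
  expect_equal(nrow(pred), 4L)
  # record a: 5p end easier + U start -> 5p; record b is its mirror image
  expect_equal(pred$predicted_arm[pred$name == "a"], c("5p", "5p"))
  expect_equal(pred$predicted_arm[pred$name == "b"], c("3p", "3p"))
  expect_true(all(pred$correct))

  # a zero log-ratio is ambiguous and scored incorrect
  tbl0 <- data.frame(name = "z", end = c("5p_end", "3p_end"), width = 1,
                     ddG = c(2, 2))
  set0 <- MirnaSet("z", "AGAG", "AUAU", guideArm = "5p")
  pred0 <- predictStrands(tbl0, set0, method = "mfe_pinned")
  expect_equal(pred0$predicted_arm, "ambiguous")
  expect_false(pred0$correct)
})

test_that("scoring is permutation-invariant and counts ambiguous as wrong", {
  co <- smallCohort()
  pred <- smallAnalysis()$predictions
  sc <- scorePredictions(pred)
  shuffled <- pred[sample(nrow(pred)), ]
  expect_equal(scorePredictions(shuffled), sc)
  expect_true(all(sc$accuracy >= 0 & sc$accuracy <= 1))
  expect_true(all(sc$n_correct <= sc$n))

  allRight <- pred[pred$correct, ]
  expect_true(all(scorePredictions(allRight)$accuracy == 1))
})

test_that("stratification by asymmetry sign partitions every prediction", {
  pred <- smallAnalysis()$predictions
  strat <- stratifyByAsymmetry(pred)
  sc <- scorePredictions(pred)
  for (m in unique(sc$method)) {
    for (w in unique(sc$width)) {
      tot <- sum(strat$n[strat$method == m & strat$width == w])
      expect_equal(tot, sc$n[sc$method == m & sc$width == w])
    }
  }
  # the negative stratum (guide end easier to unwind) is the easy one
  neg <- strat[strat$stratum == "negative", ]
  non <- strat[strat$stratum == "non_negative", ]
  expect_gt(mean(neg$accuracy), mean(non$accuracy))
})

test_that("always/never tallies cover all records once", {
  pred <- smallAnalysis()$predictions
  tally <- alwaysNeverCorrect(pred)
  expect_setequal(tally$name, unique(pred$name))
  expect_true(all(!(tally$always_correct & tally$never_correct)))
  expect_equal(tally$n_predictions,
               rep(length(unique(paste(pred$method, pred$width))),
                   nrow(tally)))
})

test_that("packaged constants carry provenance and the N ordering", {
  params <- twinDriveParams()
  expect_match(attr(params, "provenance"), "twin-drive")
  expect_true(params$N["U"] > params$N["A"])
  expect_true(params$N["A"] > params$N["G"])
  expect_true(params$N["G"] > params$N["C"])
  expect_lt(params$k, 0)   # unwinding-cost scale: stable 5p end lowers 5p use
})
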