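test_that("dot-bracket parsing produces the expected pair tables", {
  expect_equal(parseDotBracket("((..))"),
               c(6L, 5L, NA, NA, 2L, 1L))
  expect_true(all(is.na(parseDotBracket("...."))))
  # '&' is skipped: pair table in duplex coordinates
  expect_equal(parseDotBracket("((&))"), c(4L, 3L, 2L, 1L))
  expect_error(parseDotBracket("(()"), "unbalanced '\\(' at position 1")
  expect_error(parseDotBracket("())"), "unbalanced '\\)' at position 3")
  expect_error(parseDotBracket("(a)"), "invalid.*position 2")
})

test_that("parse and render are inverse on generated structures", {
  for (s in 1:10) {
    fx <- makeDuplex(fixtureSpec(seed = s, nMismatch = s %% 4,
                                 nBulge = s %% 2))
    p <- pairTable(fx$structure)
    db <- pairsToDotBracket(p, strandBreak = strandBreak(fx$structure))
    expect_identical(db, dotBracket(fx$structure))
    expect_identical(parseDotBracket(db), p)
  }
})

test_that("end windows take n nucleotides from both strands and nest", {
  lens <- c(22L, 22L)
  expect_equal(endWindow(lens, "5p_end", 2), c(1L, 2L, 43L, 44L))
  expect_equal(endWindow(lens, "3p_end", 2), c(21L, 22L, 23L, 24L))
  for (n in 1:3) {
    expect_true(all(endWindow(lens, "5p_end", n) %in%
                    endWindow(lens, "5p_end", n + 1)))
    expect_length(intersect(endWindow(lens, "5p_end", n),
                            endWindow(lens, "3p_end", 4)), 0)
  }
})

test_that("hairpin-embedded duplex keeps exactly the intra-arm pairs", {
  # perfect 10-bp stem: arms are the two stem strands
  stem <- "GGCAGGCGCC"                     # pairs its reverse complement
  arm2 <- "GGCGCCUGCC"
  hp <- paste0(stem, "AAAA", arm2)
  fold <- secondaryStructure(hp, "((((((((((....))))))))))")
  set <- locateMatureInHairpin(
    MirnaSet("stem", seq5p = stem, seq3p = arm2, hairpin = hp))
  dup <- extractHairpinDuplex(set, fold)
  expect_s4_class(dup, "DuplexStructure")
  expect_identical(dotBracket(dup), "((((((((((&))))))))))")

  # an arm nucleotide paired to a loop nucleotide becomes unpaired
  hp2 <- "GGGAAACCCUUU"
  #       123456789012  pairs: 1-9, 2-8, 3-7 ; arm2 = 8..12, pos 7 in loop
  fold2 <- secondaryStructure(hp2, "(((...)))...")
  set2 <- new("MirnaSet", name = "loopy", hairpin = hp2,
              seq5p = "GGG", seq3p = "CCUUU",
              pos5p = IRanges::IRanges(1, 3),
              pos3p = IRanges::IRanges(8, 12),
              guideArm = "unknown")
  dup2 <- extractHairpinDuplex(set2, fold2)
  # hairpin pair 3-7 has partner 7 outside the arms -> position 3 unpaired
  expect_identical(dotBracket(dup2), "((.&))...")
})

test_that("extraction never creates a pair absent from the hairpin fold", {
  co <- makeCohort(8, seed = 3)
  folds <- foldHairpins(stats::setNames(co$set@hairpin, names(co$set)),
                        cfg20)
  for (i in seq_along(folds)) {
    hpPairs <- pairTable(folds[[i]])
    rec <- co$set[i]
    dup <- extractHairpinDuplex(rec, folds[[i]])
    arm <- c(IRanges::start(rec@pos5p):IRanges::end(rec@pos5p),
             IRanges::start(rec@pos3p):IRanges::end(rec@pos3p))
    dp <- pairTable(dup)
    idx <- which(!is.na(dp))
    # every duplex pair maps back to a hairpin pair
    expect_true(all(hpPairs[arm[idx]] == arm[dp[idx]]))
  }
})

test_that("extracting the planted hairpin fold recovers the planted duplex", {
  for (s in c(4, 12, 30)) {
    spec <- fixtureSpec(seed = s, nMismatch = 2, nBulge = 1)
    hp <- makeHairpin(spec, flank5 = 2, flank3 = 4)
    set <- new("MirnaSet", name = "x", hairpin = hp$hairpin,
               seq5p = hp$duplex$seq5p, seq3p = hp$duplex$seq3p,
               pos5p = hp$pos5p, pos3p = hp$pos3p, guideArm = "unknown")
    dup <- extractHairpinDuplex(set, hp$structure)
    expect_identical(dotBracket(dup), dotBracket(hp$duplex$structure))
  }
})

test_that("a duplex region with no inter-arm pairs warns, not errors", {
  hp <- "GGGAAACCCAAAGGG"
  fold <- secondaryStructure(hp, "(((...)))......")
  set <- new("MirnaSet", name = "deg", hairpin = hp,
             seq5p = "AAA", seq3p = "AAA",
             pos5p = IRanges::IRanges(4, 6),
             pos3p = IRanges::IRanges(10, 12), guideArm = "unknown")
  expect_warning(extractHairpinDuplex(set, fold), "zero inter-arm pairs")
})

test_that("loop annotation distinguishes mismatches, bulges and overhangs", {
  # perfect duplex with 2-nt 3' overhangs: no internal features
  fx <- perfectFixture()
  expect_equal(nrow(annotateLoops(fx$structure)), 0L)

  # hand-built single bulge
  d <- secondaryStructure("GGCAGGC&GCCGCC", "(((.(((&))))))")
  loops <- annotateLoops(d)
  expect_equal(loops$kind, "bulge")
  expect_equal(loops$positions, "4")

  # hand-built mismatch
  d2 <- secondaryStructure("GGCAGGC&GCCAGCC", "(((.(((&))).)))")
  loops2 <- annotateLoops(d2)
  expect_equal(loops2$kind, "mismatch")
  expect_equal(loops2$size5p, 1L)
  expect_equal(loops2$size3p, 1L)
})

test_that("loop annotation recovers all planted features", {
  recovered <- 0L
  total <- 0L
  for (s in 1:1000) {
    nMis <- s %% 4
    nBul <- s %% 2
    fx <- makeDuplex(fixtureSpec(seed = s, strandLength = 22,
                                 nMismatch = nMis, nBulge = nBul))
    ann <- annotateLoops(fx$structure)
    total <- total + 1L
    ok <- sum(ann$kind == "mismatch") == nMis &&
      sum(ann$kind == "bulge") == nBul &&
      setequal(
        vapply(strsplit(ann$positions, ","), function(p) min(as.integer(p)),
               integer(1)),
        fx$features$pos5p)
    recovered <- recovered + ok
  }
  expect_equal(recovered, total)
})

test_that("difference classification partitions terminal vs central", {
  a <- secondaryStructure("GGCGGCCGCC&GGCGGCCGCC",
                          "((((((((((&))))))))))")
  expect_identical(classifyDifference(a, a), "identical")

  # difference only at position 1 (margin 4) -> terminal
  b <- secondaryStructure("GGCGGCCGCC&GGCGGCCGCC",
                          ".(((((((((&))))))))).")
  expect_identical(classifyDifference(a, b, terminalMargin = 4), "terminal")
  # symmetric in its arguments
  expect_identical(classifyDifference(b, a, terminalMargin = 4), "terminal")

  # central difference: pairing change in the middle only
  c1 <- secondaryStructure("GGCGGCCGCC&GGCGGCCGCC",
                           "(((((.((((&)))).)))))")
  expect_identical(classifyDifference(a, c1, terminalMargin = 4), "central")

  # both zones affected
  d1 <- secondaryStructure("GGCGGCCGCC&GGCGGCCGCC",
                           ".((((.((((&)))).)))).")
  expect_identical(classifyDifference(a, d1, terminalMargin = 4), "both")

  expect_error(
    classifyDifference(a, secondaryStructure("GGCGGCCGCC&GGCGGCCGCA",
                                             "((((((((((&))))))))))")),
    "same|share")
})

test_that("hairpin terminal zone includes the apical loop", {
  h1 <- secondaryStructure("GGCGGCAAAAUGCCGCC", "((((((.....))))))")
  h2 <- secondaryStructure("GGCGGCAAAAUGCCGCC", "(((((.......)))))")
  # the lost pair closes the terminal loop -> terminal, not central
  expect_identical(classifyDifference(h1, h2, terminalMargin = 2),
                   "terminal")
})
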