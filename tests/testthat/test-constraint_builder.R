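test_that("pinning transcribes a structure into unique constraints", {
  d <- secondaryStructure("GGCC&GGCC", "((..&..))")
  cs <- pinStructure(d)
  expect_identical(cs@constraint, "((xx&xx))")
  expect_identical(cs@regime, "mfe_pinned")
  expect_equal(cs@width, 0L)
})

test_that("end unwinding forbids the window on both strands and releases pins", {
  # perfect 17+17 duplex (15 bp core, 2-nt overhangs)
  fx <- makeDuplex(fixtureSpec(seed = 2, strandLength = 17))
  d <- fx$structure
  base <- pinStructure(d)
  cs <- unwindEnd(base, d, "5p_end", 2)
  ch <- strsplit(gsub("&", "", cs@constraint, fixed = TRUE), "")[[1]]
  lens <- c(strandBreak(d), nchar(gsub("&", "", d@sequence)) - strandBreak(d))
  win <- endWindow(lens, "5p_end", 2)
  expect_true(all(ch[win] == "x"))
  # released partners: pinned pairs touching the window are freed on both sides
  p <- pairTable(d)
  partners <- p[win][!is.na(p[win])]
  expect_true(all(ch[partners] == "x"))
  # remaining pins unchanged
  keep <- setdiff(which(!is.na(p)), c(win, partners))
  orig <- strsplit(gsub("&", "", dotBracket(d), fixed = TRUE), "")[[1]]
  expect_identical(ch[keep], orig[keep])
})

test_that("no emitted constraint set contains a dangling half-pin", {
  for (s in c(1, 6, 13)) {
    fx <- makeDuplex(fixtureSpec(seed = s, nMismatch = 2, nBulge = 1))
    base <- pinStructure(fx$structure)
    for (end in c("5p_end", "3p_end")) {
      for (n in 1:4) {
        cs <- unwindEnd(base, fx$structure, end, n)
        # brackets must still parse into a valid (symmetric) pair set that
        # is a subset of the reference structure's pairs
        pinned <- parseDotBracket(chartr("x", ".", cs@constraint))
        ref <- pairTable(fx$structure)
        idx <- which(!is.na(pinned))
        expect_true(all(ref[idx] == pinned[idx]))
      }
    }
  }
})

test_that("nested windows give nested forbidden sets", {
  fx <- makeDuplex(fixtureSpec(seed = 4))
  base <- pinStructure(fx$structure)
  for (end in c("5p_end", "3p_end")) {
    for (n in 1:3) {
      a <- forbiddenPositions(unwindEnd(base, fx$structure, end, n))
      b <- forbiddenPositions(unwindEnd(base, fx$structure, end, n + 1))
      expect_true(all(a %in% b))
    }
  }
})

test_that("window widths are validated", {
  fx <- makeDuplex(fixtureSpec(seed = 1))
  expect_error(unwindEnd(NULL, fx$structure, "5p_end", 0), "1\\.\\.4")
  expect_error(unwindEnd(NULL, fx$structure, "5p_end", 5), "1\\.\\.4")
  # wider windows need the explicit flag
  wide <- unwindEnd(NULL, fx$structure, "5p_end", 6, allowWide = TRUE)
  expect_equal(wide@width, 6L)
  # a short duplex cannot keep a foldable core
  short <- secondaryStructure("GGCGGC&GCCGCC", "((((((&))))))")
  expect_error(unwindEnd(NULL, short, "5p_end", 2), "foldable core")
})

test_that("ends-only constrained energies are non-decreasing in width", {
  fx <- makeDuplex(fixtureSpec(seed = 10, nMismatch = 1))
  mfe <- cofoldDuplex(fx$seq5p, fx$seq3p, cfg20)
  for (end in c("5p_end", "3p_end")) {
    prev <- freeEnergy(mfe)
    for (n in 1:4) {
      cs <- unwindEnd(NULL, mfe, end, n)
      e <- freeEnergy(cofoldDuplex(fx$seq5p, fx$seq3p, cfg20,
                                   constraint = cs))
      expect_gte(e, prev - 1e-9)
      prev <- e
    }
  }
})

test_that("constraint files round-trip and diff against a reference corpus", {
  fx <- lapply(1:3, function(s) makeDuplex(fixtureSpec(seed = s)))
  names <- paste0("dup", 1:3)
  seqs <- vapply(fx, function(f) paste0(f$seq5p, "&", f$seq3p), character(1))
  cons <- lapply(fx, function(f) pinStructure(f$structure))
  path <- tempfile(fileext = ".txt")
  writeConstraintFasta(names, seqs, cons, path)
  back <- readConstraintFasta(path)
  expect_identical(back$name, names)
  expect_identical(back$constraint,
                   vapply(cons, function(x) x@constraint, character(1)))

  # a curated corpus that disagrees at one position is reported, not
  # silently overridden
  ref <- back
  substr(ref$constraint[2], 1, 1) <- "."
  d <- diffConstraints(back, ref)
  expect_equal(d$name, "dup2")
  expect_equal(d$differing, "1")
  expect_equal(nrow(diffConstraints(back, back)), 0L)
})
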