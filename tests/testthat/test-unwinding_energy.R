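test_that("profiles have the stated shape and arithmetic", {
  prof <- computeUnwindingProfile(let7Set(), "mfe_pinned", cfg20)
  expect_s4_class(prof, "UnwindingProfile")
  expect_identical(rownames(ddG(prof)), c("5p_end", "3p_end"))
  expect_equal(dim(ddG(prof)), c(2L, 4L))
  expect_equal(ddG(prof), prof@dGUnwound - dGWound(prof))
  expect_equal(asymmetry(prof, 4),
               ddG(prof)["5p_end", "n4"] - ddG(prof)["3p_end", "n4"])
})

test_that("unwinding energies are non-negative against the MFE reference", {
  co <- smallCohort()
  for (regime in c("mfe_pinned", "ends_only")) {
    tbl <- smallAnalysis()$tables[[regime]]
    expect_true(all(tbl$ddG >= -0.005))
  }
})

test_that("ddG is zero exactly when the window is already unpaired", {
  co <- smallCohort()
  set <- co$set
  mfe <- smallAnalysis()$mfe_structures
  tbl <- smallAnalysis()$tables$mfe_pinned
  for (i in seq_len(length(set))) {
    p <- pairTable(mfe[[i]])
    lens <- c(strandBreak(mfe[[i]]), length(p) - strandBreak(mfe[[i]]))
    for (end in c("5p_end", "3p_end")) {
      for (n in 1:4) {
        win <- endWindow(lens, end, n)
        open <- all(is.na(p[win]))
        val <- tbl$ddG[tbl$name == names(set)[i] & tbl$end == end &
                       tbl$width == n]
        if (open) {
          expect_equal(val, 0)
        } else {
          expect_gte(val, 0)
        }
      }
    }
  }
})

test_that("relaxing the pins can only stabilize the unwound duplex", {
  # the ends_only feasible set contains the pinned structure
  res <- smallAnalysis()
  pin <- res$tables$mfe_pinned
  free <- res$tables$ends_only
  key <- paste(pin$name, pin$end, pin$width)
  m <- match(key, paste(free$name, free$end, free$width))
  expect_true(all(free$dG_unwound[m] <= pin$dG_unwound + 1e-9))
})

test_that("the hairpin-derived wound state is never below the duplex MFE", {
  res <- smallAnalysis()
  mfeW <- res$tables$mfe_pinned
  hpW <- res$tables$hairpin_pinned
  m <- match(paste(hpW$name, hpW$end, hpW$width),
             paste(mfeW$name, mfeW$end, mfeW$width))
  expect_true(all(mfeW$dG_wound[m] <= hpW$dG_wound + 1e-9))
})

test_that("a palindromic duplex has zero asymmetry", {
  # the duplex is invariant under swapping the strands
  s <- "GCGCGCGCGCGCAA"
  set <- MirnaSet("pal", s, s, guideArm = "unknown")
  prof <- computeUnwindingProfile(set, "mfe_pinned", cfg20)
  for (n in 1:4) expect_equal(asymmetry(prof, n), 0)
})

test_that("profile tables flatten and write with provenance", {
  prof <- computeUnwindingProfiles(let7Set(), "mfe_pinned", cfg20)
  tbl <- profilesToTable(prof)
  expect_equal(nrow(tbl), 8L)
  expect_setequal(colnames(tbl),
                  c("name", "regime", "temperature", "end", "width",
                    "dG_wound", "dG_unwound", "ddG"))
  path <- tempfile(fileext = ".tsv")
  writeUnwindingTable(tbl, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# unwindR .*engine")
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(back), 8L)
})

test_that("guide/passenger statistics use an equal-variance t-test", {
  tbl <- data.frame(
    name = rep(c("a", "b", "c", "d"), each = 2),
    end = rep(c("5p_end", "3p_end"), 4),
    width = 1,
    ddG = c(1, 2, 3, 4, 1, 2, 3, 4))
  set <- MirnaSet(c("a", "b", "c", "d"),
                  seq5p = rep("ACGU", 4), seq3p = rep("ACGU", 4),
                  guideArm = c("5p", "5p", "5p", "5p"))
  # guide ends (all 5p) carry 1,3,1,3; passengers 2,4,2,4: same variance
  st <- groupStats(tbl, set)
  expect_equal(st$n, 4L)
  ref <- stats::t.test(c(1, 3, 1, 3), c(2, 4, 2, 4), var.equal = TRUE)
  expect_equal(st$p_value, ref$p.value)

  # identical groups: p = 1
  tbl2 <- tbl
  tbl2$ddG <- rep(c(1, 1, 3, 3), 2)
  expect_equal(groupStats(tbl2, set)$p_value, 1)
})

test_that("unknown guide arms are excluded with a message", {
  tbl <- data.frame(name = rep(c("a", "b", "c"), each = 2),
                    end = rep(c("5p_end", "3p_end"), 3),
                    width = 1, ddG = c(1, 2, 1.5, 2.5, 9, 9))
  set <- MirnaSet(c("a", "b", "c"), rep("ACGU", 3), rep("ACGU", 3),
                  guideArm = c("5p", "3p", "unknown"))
  expect_message(st <- groupStats(tbl, set), "excluding 2 rows")
  expect_equal(st$n, 2L)
})

test_that("empirical t-test power matches the analytic oracle", {
  # shifted normals with known delta: simulate, then compare with the
  # closed-form power of the two-sample equal-variance t-test
  delta <- 1; n <- 20; reps <- 400
  set.seed(99)
  hits <- mean(replicate(reps, {
    stats::t.test(rnorm(n), rnorm(n, mean = delta),
                  var.equal = TRUE)$p.value < 0.05
  }))
  want <- stats::power.t.test(n = n, delta = delta, sd = 1,
                              sig.level = 0.05)$power
  mcErr <- 3 * sqrt(want * (1 - want) / reps)
  expect_lt(abs(hits - want), mcErr + 0.01)
})
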