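# Shared fixtures and memoized expensive computations. Everything is
# generated in code from fixed seeds; nothing is read from disk except
# the packaged extdata.

cfg20 <- engineConfig(temperature = 20)
cfg37 <- engineConfig(temperature = 37)

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# the packaged cel-let-7 duplex as a single-record annotated set
let7Set <- function() {
  memo("let7", {
    fa <- readRnaFasta(system.file("extdata", "cel-let-7_duplex.fa",
                                   package = "unwindR"))
    arms <- splitDuplexRecord(fa[[1]])
    MirnaSet(names(fa), arms["seq5p"], arms["seq3p"], guideArm = "5p")
  })
}

# small engine-facing cohort shared by several test files
smallCohort <- function() memo("cohort24", makeCohort(24, seed = 11))

smallAnalysis <- function() {
  memo("analysis24", runUnwindingAnalysis(smallCohort()$set, cfg20))
}

# a perfect high-GC duplex fixture whose planted helix dominates the MFE
perfectFixture <- function(seed = 3, strandLength = 22) {
  makeDuplex(fixtureSpec(seed = seed, strandLength = strandLength,
                         gcFraction = 0.8))
}
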