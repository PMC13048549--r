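# Deterministic generator of synthetic miRNA-like duplexes and hairpins
# with planted structure: a reverse-complementary core with a chosen GC
# fraction, 0-3 internal mismatches, 0-1 bulges, 2-nt 3' overhangs on both
# strands, and hairpins assembled as arm + loop + arm with optional
# flanks. Planted features are recorded so structure-recovery can be
# tested against ground truth. Every fixture is reproducible from a
# single integer seed.

.complement <- c(A = "U", U = "A", G = "C", C = "G")
.nonPairing <- list(A = c("A", "C", "G"), U = c("C", "U"),
                    G = c("A", "G"), C = c("A", "C", "U"))

#' Specification of one synthetic fixture
#'
#' @param seed integer seed driving one reproducible pseudo-random stream.
#' @param strandLength length of the 5p strand in nt (>= 12 so unwinding
#'   windows keep a foldable core).
#' @param nMismatch number of planted internal mismatches (0-3).
#' @param nBulge number of planted single-nucleotide bulges (0-1; planted
#'   as an unpaired 5p-strand base).
#' @param overhang 3' overhang length on each strand (default 2, the
#'   Dicer signature).
#' @param gcFraction GC fraction of the complementary core (default 0.6;
#'   GC-rich cores make the planted helix dominate the MFE landscape, so
#'   engine-dependent tests are deterministic in practice).
#' @param loopLength hairpin loop length in nt.
#' @param easyEnd "none", "5p_end" or "3p_end": when set, the terminal
#'   three core pairs of that end are A/U and those of the other end G/C,
#'   planting a thermodynamic end asymmetry.
#' @return a list of class "FixtureSpec".
#' @export
fixtureSpec <- function(seed = 1L, strandLength = 22L, nMismatch = 0L,
                        nBulge = 0L, overhang = 2L, gcFraction = 0.6,
                        loopLength = 10L, easyEnd = "none") {
  spec <- list(seed = as.integer(seed),
               strandLength = as.integer(strandLength),
               nMismatch = as.integer(nMismatch),
               nBulge = as.integer(nBulge),
               overhang = as.integer(overhang),
               gcFraction = gcFraction,
               loopLength = as.integer(loopLength),
               easyEnd = easyEnd)
  class(spec) <- "FixtureSpec"
  K <- spec$strandLength - spec$overhang
  if (spec$strandLength < 12L) stop("spec error: strandLength must be >= 12")
  if (spec$overhang < 0L) stop("spec error: negative overhang")
  if (!easyEnd %in% c("none", .ENDS)) stop("spec error: unknown easyEnd")
  if (gcFraction < 0 || gcFraction > 1) stop("spec error: gcFraction")
  # features live in the core interior, >= 3 columns from either core end,
  # pairwise separated by >= 2 columns
  nFeat <- spec$nMismatch + spec$nBulge
  if (nFeat > 0L && K < 3L * nFeat + 4L) {
    stop("spec error: ", nFeat, " features exceed a core of ", K, " bp")
  }
  spec
}

# sample one base; gc controls the G/C vs A/U balance
.sampleBases <- function(n, gc) {
  strong <- stats::runif(n) < gc
  out <- character(n)
  out[strong] <- sample(c("G", "C"), sum(strong), replace = TRUE)
  out[!strong] <- sample(c("A", "U"), sum(!strong), replace = TRUE)
  out
}

# Build a duplex from the current RNG stream (no seeding here).
.buildDuplex <- function(spec) {
  K <- spec$strandLength - spec$overhang
  top <- .sampleBases(K, spec$gcFraction)
  if (spec$easyEnd != "none") {
    easyCols <- if (spec$easyEnd == "5p_end") 1:3 else (K - 2L):K
    hardCols <- if (spec$easyEnd == "5p_end") (K - 2L):K else 1:3
    top[easyCols] <- sample(c("A", "U"), 3, replace = TRUE)
    top[hardCols] <- sample(c("G", "C"), 3, replace = TRUE)
  }
  bottom <- unname(.complement[top])      # bottom base in column i pairs top[i]

  # choose interior feature columns with pairwise gaps >= 2: sample from a
  # compressed lattice, then spread by 3 (always feasible per fixtureSpec)
  nFeat <- spec$nMismatch + spec$nBulge
  featCols <- integer(0)
  if (nFeat > 0L) {
    lo <- 4L
    hi <- (K - 3L) - 2L * (nFeat - 1L)
    base <- lo + sort(sample.int(hi - lo + 1L, nFeat)) - 1L
    featCols <- base + 2L * (seq_len(nFeat) - 1L)
  }
  kinds <- rep("mismatch", spec$nMismatch)
  kinds <- c(kinds, rep("bulge", spec$nBulge))
  if (length(kinds)) kinds <- sample(kinds)   # interleave feature kinds

  for (f in seq_along(featCols)) {
    col <- featCols[f]
    if (kinds[f] == "mismatch") {
      choices <- .nonPairing[[top[col]]]
      bottom[col] <- if (length(choices) == 1L) choices else
        sample(choices, 1L)
    } else {
      bottom[col] <- NA_character_          # deleted: 5p-strand bulge
    }
  }

  ov5 <- .sampleBases(spec$overhang, 0.3)
  ov3 <- .sampleBases(spec$overhang, 0.3)
  seq5p <- paste(c(top, ov5), collapse = "")
  keep <- which(!is.na(bottom))
  seq3p <- paste(c(rev(bottom[keep]), ov3), collapse = "")
  L1 <- K + spec$overhang
  K2 <- length(keep)
  L2 <- K2 + spec$overhang

  pairs <- rep(NA_integer_, L1 + L2)
  paired <- setdiff(keep, featCols)         # columns that stay paired
  for (col in paired) {
    j3 <- K2 - match(col, keep) + 1L        # position in seq3p
    pairs[col] <- L1 + j3
    pairs[L1 + j3] <- col
  }
  db <- pairsToDotBracket(pairs, strandBreak = L1)
  structure_ <- secondaryStructure(paste0(seq5p, "&", seq3p), db)
  features <- if (length(featCols)) {
    data.frame(kind = kinds, column = featCols,
               pos5p = featCols,
               pos3p = ifelse(kinds == "mismatch",
                              L1 + K2 - match(featCols, keep) + 1L,
                              NA_integer_))
  } else {
    data.frame(kind = character(0), column = integer(0),
               pos5p = integer(0), pos3p = integer(0))
  }
  list(seq5p = seq5p, seq3p = seq3p, structure = structure_,
       features = features)
}

#' Generate a synthetic duplex with planted structure
#'
#' @param spec a [fixtureSpec()].
#' @return list with `seq5p`, `seq3p`, the planted
#'   [DuplexStructure-class] and a `features` data.frame (kind and duplex
#'   coordinates of each planted mismatch/bulge). Deterministic per seed.
#' @examples
#' fx <- makeDuplex(fixtureSpec(seed = 1, strandLength = 20))
#' fx$structure
#' @export
makeDuplex <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .withSeed(spec$seed, .buildDuplex(spec))
}

# Build a hairpin around the duplex: flank5 + 5p arm + loop + 3p arm + flank3.
.buildHairpin <- function(spec, flank5 = 0L, flank3 = 0L) {
  dup <- .buildDuplex(spec)
  loop <- sample(c("A", "A", "U", "C"), spec$loopLength, replace = TRUE)
  f5 <- if (flank5 > 0L) .sampleBases(flank5, 0.3) else character(0)
  f3 <- if (flank3 > 0L) .sampleBases(flank3, 0.3) else character(0)
  hairpin <- paste(c(f5, dup$seq5p, loop, dup$seq3p, f3), collapse = "")
  L1 <- nchar(dup$seq5p)
  pos5p <- IRanges::IRanges(flank5 + 1L, width = L1)
  pos3p <- IRanges::IRanges(flank5 + L1 + spec$loopLength + 1L,
                            width = nchar(dup$seq3p))
  # planted hairpin pairs: duplex pairs lifted into hairpin coordinates
  dpairs <- pairTable(dup$structure)
  n <- nchar(hairpin)
  pairs <- rep(NA_integer_, n)
  lift <- c(flank5 + seq_len(L1),
            flank5 + L1 + spec$loopLength + seq_len(nchar(dup$seq3p)))
  idx <- which(!is.na(dpairs))
  pairs[lift[idx]] <- lift[dpairs[idx]]
  list(hairpin = hairpin, pos5p = pos5p, pos3p = pos3p,
       structure = secondaryStructure(hairpin, pairsToDotBracket(pairs)),
       duplex = dup)
}

#' Generate a synthetic hairpin with planted structure
#'
#' Arm + loop + reverse-complementary arm (plus optional flanks), built
#' around [makeDuplex()] of the same spec so cross-module consistency can
#' be tested: extracting the duplex embedded in the planted hairpin fold
#' recovers the planted duplex structure.
#'
#' @param spec a [fixtureSpec()].
#' @param flank5,flank3 flanking nucleotides outside the arms.
#' @return list with `hairpin`, arm intervals `pos5p`/`pos3p`
#'   ([IRanges::IRanges]), the planted hairpin
#'   [SecondaryStructure-class], and the underlying `duplex` fixture.
#' @export
makeHairpin <- function(spec, flank5 = 0L, flank3 = 0L) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .withSeed(spec$seed, .buildHairpin(spec, flank5, flank3))
}

# run expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic miRNA cohort
#'
#' Builds `n` miRNA records emulating the features of a real duplex
#' catalogue: strand lengths 19-24 nt, 0-3 internal mismatches, 0-1
#' bulges, 2-nt 3' overhangs, hairpins with 8-14 nt loops and short
#' flanks. Each duplex gets a planted thermodynamic end asymmetry (one
#' A/U-rich "easy" end, one G/C-rich "hard" end) and the guide arm is the
#' strand whose 5' terminus sits at the easy end -- except for a fraction
#' `exceptionRate` of records whose annotation defies the planted
#' thermodynamics, reflecting the observed share of miRNAs (roughly a
#' fifth to a quarter) whose strand choice the 5'-nucleotide and
#' end-stability guidelines fail to explain.
#'
#' @param n number of records (default 190).
#' @param seed integer seed; one stream drives the whole cohort.
#' @param exceptionRate fraction of guide annotations flipped against the
#'   planted asymmetry (default 0.225).
#' @param gcFraction core GC fraction (default 0.6).
#' @return list with `set` (a [MirnaSet-class] with hairpins, arm
#'   positions and guide annotations) and `truth` (data.frame of planted
#'   ground truth per record: easy end, favoured arm, whether the
#'   annotation was flipped, feature counts).
#' @export
makeCohort <- function(n = 190L, seed = 1L, exceptionRate = 0.225,
                       gcFraction = 0.6) {
  .withSeed(seed, {
    name <- sprintf("syn-mir-%03d", seq_len(n))
    seq5p <- seq3p <- hairpin <- character(n)
    pos5p <- pos3p <- IRanges::IRanges()
    easyEnd <- favoured <- guide <- character(n)
    flipped <- logical(n)
    nMis <- nBul <- integer(n)
    for (i in seq_len(n)) {
      easyEnd[i] <- sample(.ENDS, 1L)
      nMis[i] <- sample(0:3, 1L, prob = c(0.3, 0.35, 0.25, 0.1))
      nBul[i] <- sample(0:1, 1L, prob = c(0.7, 0.3))
      spec <- fixtureSpec(
        seed = NA, strandLength = sample(19:24, 1L),
        nMismatch = nMis[i], nBulge = nBul[i],
        gcFraction = gcFraction, loopLength = sample(8:14, 1L),
        easyEnd = easyEnd[i])
      hp <- .buildHairpin(spec, flank5 = sample(0:5, 1L),
                          flank3 = sample(0:5, 1L))
      seq5p[i] <- hp$duplex$seq5p
      seq3p[i] <- hp$duplex$seq3p
      hairpin[i] <- hp$hairpin
      pos5p <- c(pos5p, hp$pos5p)
      pos3p <- c(pos3p, hp$pos3p)
      favoured[i] <- if (easyEnd[i] == "5p_end") "5p" else "3p"
      flipped[i] <- stats::runif(1) < exceptionRate
      guide[i] <- if (flipped[i]) setdiff(c("5p", "3p"), favoured[i])
                  else favoured[i]
    }
    set <- new("MirnaSet", name = name, hairpin = hairpin,
               seq5p = seq5p, seq3p = seq3p,
               pos5p = pos5p, pos3p = pos3p, guideArm = guide)
    validObject(set)
    truth <- data.frame(name = name, easy_end = easyEnd,
                        favoured_arm = favoured, guide_arm = guide,
                        flipped = flipped, n_mismatch = nMis,
                        n_bulge = nBul)
    list(set = set, truth = truth)
  })
}
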