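# Thin adapter around the ViennaRNA command-line tools. All folding is
# batched: one engine process per call handles any number of records read
# from a FASTA stream, which keeps full-cohort runs fast. Energies and
# structures are deterministic for a fixed engine version and config.

.engineTools <- c("RNAfold", "RNAcofold", "RNAeval")

#' Is the folding engine available?
#'
#' @return `TRUE` when RNAfold, RNAcofold and RNAeval are all on the PATH.
#' @export
engineAvailable <- function() {
  all(nzchar(Sys.which(.engineTools)))
}

.checkEngine <- function() {
  missing <- .engineTools[!nzchar(Sys.which(.engineTools))]
  if (length(missing)) {
    stop("folding engine unavailable: ", paste(missing, collapse = ", "),
         " not found on PATH. Install the ViennaRNA package ",
         "(https://www.tbi.univie.ac.at/RNA/) and ensure its binaries ",
         "are on the PATH.")
  }
}

#' Folding engine version string
#'
#' Recorded in report headers: printed free energies are sensitive to the
#' engine version and parameter set.
#'
#' @return version string, e.g. "2.7.2".
#' @export
engineVersion <- function() {
  .checkEngine()
  out <- suppressWarnings(system2("RNAfold", "--version", stdout = TRUE,
                                  stderr = TRUE))
  sub("^RNAfold\\s+", "", out[1])
}

# Run one engine tool over a FASTA input stream; returns stdout lines.
# Benign constraint-bookkeeping warnings on stderr are discarded; a
# non-zero exit status is an error.
.viennaRun <- function(tool, args, inputLines) {
  .checkEngine()
  inFile <- tempfile(fileext = ".fa")
  errFile <- tempfile(fileext = ".err")
  on.exit(unlink(c(inFile, errFile)), add = TRUE)
  writeLines(inputLines, inFile)
  owd <- setwd(tempdir())         # engines may drop .ps files in cwd
  on.exit(setwd(owd), add = TRUE)
  out <- suppressWarnings(
    system2(tool, args, stdin = inFile, stdout = TRUE, stderr = errFile))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    err <- tryCatch(readLines(errFile), error = function(e) character(0))
    stop(tool, " failed (status ", status, "): ",
         paste(utils::tail(err, 3), collapse = " | "))
  }
  out
}

# Parse ">name / sequence / structure (energy)" triples from engine output.
.parseEngineOutput <- function(lines, expectNames) {
  hdr <- grep("^>", lines)
  if (length(hdr) != length(expectNames)) {
    stop("engine returned ", length(hdr), " records, expected ",
         length(expectNames))
  }
  res <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    nm <- sub("^>\\s*", "", lines[hdr[k]])
    if (nm != expectNames[k]) {
      stop("engine record order mismatch: got '", nm, "', expected '",
           expectNames[k], "'")
    }
    seqLine <- lines[hdr[k] + 1L]
    stLine <- lines[hdr[k] + 2L]
    m <- regmatches(stLine,
                    regexec("^([().&]+)\\s+\\(\\s*(-?[0-9]+\\.?[0-9]*)\\)\\s*$",
                            stLine))[[1]]
    if (length(m) != 3L) {
      stop("cannot parse engine output line: '", stLine, "'")
    }
    res[[k]] <- list(name = nm, sequence = seqLine, dotbracket = m[2],
                     energy = as.numeric(m[3]))
  }
  res
}

#' Fold single-strand RNAs at a given temperature
#'
#' Batch MFE folding with RNAfold. Use [foldHairpin()] for one sequence.
#'
#' @param seqs named character vector of RNA sequences (no "&").
#' @param cfg an [EngineConfig-class].
#' @return list of [SecondaryStructure-class], in input order.
#' @export
foldHairpins <- function(seqs, cfg = engineConfig()) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(grepl("&", seqs, fixed = TRUE))) {
    stop("single-strand folding cannot take '&'-joined input")
  }
  seqs[] <- normalizeRna(seqs, what = names(seqs))
  inp <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  out <- .viennaRun("RNAfold", c("-T", cfg@temperature, "--noPS"), inp)
  recs <- .parseEngineOutput(out, names(seqs))
  lapply(recs, function(r) {
    secondaryStructure(r$sequence, r$dotbracket, r$energy, cfg@temperature)
  })
}

#' @rdname foldHairpins
#' @param seq a single RNA sequence.
#' @examples
#' if (engineAvailable()) {
#'   foldHairpin("GGGGAAAACCCC", engineConfig(temperature = 37))
#' }
#' @export
foldHairpin <- function(seq, cfg = engineConfig()) {
  foldHairpins(c(hairpin = seq), cfg)[[1]]
}

#' Cofold duplex strand pairs, optionally under hard constraints
#'
#' Batch two-strand MFE folding with RNAcofold. When constraints are
#' supplied, each record carries a constraint line in the engine dialect
#' ("." free, "x" unpaired, "()" pinned pair) and the returned structure is
#' the MFE over all structures satisfying it. The standard pipeline uses
#' forbid-only ("x") constraints; pinned reference structures are scored
#' directly with [evalStructure()] instead, because a fully pinned
#' constraint set admits exactly one structure.
#'
#' @param seq5p,seq3p character vectors of strand sequences.
#' @param cfg an [EngineConfig-class].
#' @param constraints `NULL`, or a list/vector of constraint strings (or
#'   [ConstraintSet-class] objects) aligned to "seq5p&seq3p" per record.
#' @param names record names.
#' @return list of [DuplexStructure-class], in input order.
#' @export
cofoldDuplexes <- function(seq5p, seq3p, cfg = engineConfig(),
                           constraints = NULL,
                           names = paste0("dup", seq_along(seq5p))) {
  stopifnot(length(seq5p) == length(seq3p))
  seq5p <- normalizeRna(seq5p, what = names)
  seq3p <- normalizeRna(seq3p, what = names)
  joined <- paste0(seq5p, "&", seq3p)
  args <- c("-T", cfg@temperature, "--noPS")
  if (!is.null(constraints)) {
    cs <- vapply(constraints, function(x) {
      if (is(x, "ConstraintSet")) x@constraint else as.character(x)
    }, character(1))
    if (length(cs) != length(joined)) {
      stop("need one constraint per duplex record")
    }
    bad <- which(nchar(cs) != nchar(joined))
    if (length(bad)) {
      stop("record '", names[bad[1]], "': constraint length ",
           nchar(cs[bad[1]]), " does not match sequence length ",
           nchar(joined[bad[1]]))
    }
    args <- c(args, "-C",
              if (cfg@enforceConstraints) "--enforceConstraint")
    inp <- as.vector(rbind(paste0(">", names), joined, cs))
  } else {
    inp <- as.vector(rbind(paste0(">", names), joined))
  }
  out <- .viennaRun("RNAcofold", args, inp)
  recs <- .parseEngineOutput(out, names)
  lapply(recs, function(r) {
    secondaryStructure(r$sequence, r$dotbracket, r$energy, cfg@temperature)
  })
}

#' @rdname cofoldDuplexes
#' @param constraint a single constraint string or [ConstraintSet-class].
#' @examples
#' if (engineAvailable()) {
#'   cofoldDuplex("GGGGGGGAAAA", "UUUUCCCCCCC", engineConfig(20))
#' }
#' @export
cofoldDuplex <- function(seq5p, seq3p, cfg = engineConfig(),
                         constraint = NULL) {
  cofoldDuplexes(seq5p, seq3p, cfg,
                 constraints = if (!is.null(constraint)) list(constraint),
                 names = "duplex")[[1]]
}

#' Evaluate the free energy of fixed structures
#'
#' Nearest-neighbour energy of exactly the given structure(s), via
#' RNAeval, using the same model settings as the folding calls. For a
#' fully pinned constraint set, the constrained-fold energy equals the
#' evaluated energy of the pinned structure.
#'
#' @param sequences character vector (may contain "&").
#' @param dotbrackets matching structure strings (with "&" at the same
#'   position when present).
#' @param cfg an [EngineConfig-class].
#' @return numeric vector of energies in kcal/mol.
#' @export
evalStructures <- function(sequences, dotbrackets, cfg = engineConfig()) {
  stopifnot(length(sequences) == length(dotbrackets))
  sequences <- normalizeRna(sequences, allowAmp = TRUE)
  nm <- paste0("ev", seq_along(sequences))
  for (i in seq_along(sequences)) {
    .checkCanonical(sequences[i], dotbrackets[i])
  }
  inp <- as.vector(rbind(paste0(">", nm), unname(sequences), dotbrackets))
  out <- .viennaRun("RNAeval", c("-T", cfg@temperature), inp)
  recs <- .parseEngineOutput(out, nm)
  vapply(recs, `[[`, numeric(1), "energy")
}

#' @rdname evalStructures
#' @param sequence,dotbracket a single sequence/structure pair, or a
#'   [SecondaryStructure-class] as `sequence` (then `dotbracket` is taken
#'   from the object).
#' @export
evalStructure <- function(sequence, dotbracket = NULL,
                          cfg = engineConfig()) {
  if (is(sequence, "SecondaryStructure")) {
    dotbracket <- dotBracket(sequence)
    sequence <- sequence@sequence
  }
  evalStructures(sequence, dotbracket, cfg)
}

# every paired position must form a canonical (AU/GC/GU) pair
.checkCanonical <- function(sequence, dotbracket) {
  core <- gsub("&", "", sequence, fixed = TRUE)
  pairs <- parseDotBracket(dotbracket)
  ch <- strsplit(core, "")[[1]]
  idx <- which(!is.na(pairs) & seq_along(pairs) < pairs)
  for (i in idx) {
    step <- paste0(ch[i], ch[pairs[i]])
    if (!step %in% .CANONICAL_PAIRS) {
      stop("evaluation error: non-canonical pair ", step, " at positions ",
           i, ":", pairs[i])
    }
  }
  invisible(TRUE)
}
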