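# Automatic generation of the hard-constraint strings for the three
# folding regimes: full-structure pinning (MFE or hairpin-derived
# reference) and ends-only unwinding, with progressive 1-4 nt end windows.

#' Pin a duplex structure as a hard-constraint set
#'
#' Transcribes a reference duplex structure into the engine's constraint
#' dialect so that the satisfying structure is unique and equal to the
#' input: paired positions emit matched "(" / ")" and unpaired positions
#' emit "x" (forbidden). Forbidding rather than leaving unpaired positions
#' unconstrained matters: "." would let the engine add new pairs, whereas
#' the unwinding energy is defined against the fixed reference structure.
#'
#' @param duplex a [DuplexStructure-class].
#' @param regime "mfe_pinned" or "hairpin_pinned" (a provenance label for
#'   the reference structure).
#' @return a [ConstraintSet-class] of width 0.
#' @examples
#' d <- secondaryStructure("GGCC&GGCC", "((..&..))")
#' pinStructure(d)   # "((xx&xx))"
#' @export
pinStructure <- function(duplex, regime = c("mfe_pinned", "hairpin_pinned")) {
  stopifnot(is(duplex, "DuplexStructure"))
  regime <- match.arg(regime)
  ch <- strsplit(dotBracket(duplex), "")[[1]]
  ch[ch == "."] <- "x"
  new("ConstraintSet", constraint = paste(ch, collapse = ""),
      regime = regime, end = "none", width = 0L)
}

#' Unwind a duplex end within a constraint set
#'
#' Sets every position of the end window W(end, n) -- the terminal n
#' nucleotides of *both* strands at that duplex end -- to "x" (forbidden to
#' pair). Restricting both strands is essential: forbidding only one
#' nucleotide of a base pair would let the partner re-pair elsewhere. In
#' the pinned regimes, any pinned pair with at least one partner inside the
#' window is released and both partners are forced unpaired; all other
#' positions keep their pinned symbol. With `base = NULL` (the ends_only
#' regime) all positions outside the window stay unconstrained (".").
#'
#' @param base a width-0 [ConstraintSet-class] from [pinStructure()], or
#'   `NULL` for the ends_only regime.
#' @param duplex the [DuplexStructure-class] the constraints refer to
#'   (supplies strand lengths and, for pinned regimes, the pair table).
#' @param end "5p_end" or "3p_end".
#' @param n window width, 1-4 (wider windows only with `allowWide`).
#' @param allowWide permit n > 4.
#' @return a [ConstraintSet-class].
#' @export
unwindEnd <- function(base = NULL, duplex, end = c("5p_end", "3p_end"), n,
                      allowWide = FALSE) {
  end <- match.arg(end)
  stopifnot(is(duplex, "DuplexStructure"))
  n <- as.integer(n)
  if (n < 1L || (!allowWide && n > 4L)) {
    stop("window width must be in 1..4 (use allowWide for wider windows)")
  }
  lens <- .strandLengths(duplex)
  if (n > min(lens) - 5L) {
    stop("window width ", n, " leaves no foldable core on strands of ",
         "length ", lens[1], "+", lens[2])
  }
  win <- endWindow(lens, end, n)
  other <- endWindow(lens, setdiff(.ENDS, end), min(4L, min(lens) - 5L))
  if (length(intersect(win, other))) {
    stop("end windows collide on strands of length ", lens[1], "+", lens[2])
  }
  L1 <- lens[1]
  if (is.null(base)) {
    ch <- rep(".", sum(lens))
    regime <- "ends_only"
  } else {
    stopifnot(is(base, "ConstraintSet"))
    if (base@width != 0L) stop("base constraint set must have width 0")
    ch <- strsplit(gsub("&", "", base@constraint, fixed = TRUE), "")[[1]]
    regime <- base@regime
    # release pinned pairs touching the window -- both partners
    p <- pairTable(duplex)
    touched <- win[!is.na(p[win])]
    ch[p[touched]] <- "x"
  }
  ch[win] <- "x"
  new("ConstraintSet",
      constraint = paste(append(ch, "&", after = L1), collapse = ""),
      regime = regime, end = end, width = n)
}

#' Forbidden positions of a constraint set
#'
#' @param cs a [ConstraintSet-class].
#' @return integer positions (duplex coordinates) marked "x".
#' @export
forbiddenPositions <- function(cs) {
  stopifnot(is(cs, "ConstraintSet"))
  which(strsplit(gsub("&", "", cs@constraint, fixed = TRUE), "")[[1]] == "x")
}

#' Write constraint records in the engine input dialect
#'
#' One record is a header line, the "SEQ5P&SEQ3P" sequence line and a
#' constraint line of equal length -- the dialect consumed by
#' `RNAcofold -C`.
#'
#' @param names record names.
#' @param sequences "&"-joined duplex sequences.
#' @param constraints constraint strings or [ConstraintSet-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConstraintFasta <- function(names, sequences, constraints, path) {
  cs <- vapply(constraints, function(x) {
    if (is(x, "ConstraintSet")) x@constraint else as.character(x)
  }, character(1))
  stopifnot(length(names) == length(sequences),
            length(cs) == length(sequences),
            all(nchar(cs) == nchar(sequences)))
  writeLines(as.vector(rbind(paste0(">", names), sequences, cs)), path)
  invisible(path)
}

#' Read constraint records in the engine input dialect
#'
#' @param path constraint file (header / sequence / constraint triples).
#' @return data.frame with columns `name`, `sequence`, `constraint`.
#' @export
readConstraintFasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr) || any(diff(hdr) != 3L) ||
      hdr[length(hdr)] + 2L != length(lines)) {
    stop("format error: expected header/sequence/constraint triples")
  }
  data.frame(name = sub("^>\\s*", "", lines[hdr]),
             sequence = lines[hdr + 1L],
             constraint = lines[hdr + 2L],
             stringsAsFactors = FALSE)
}

#' Diff generated constraints against a reference corpus
#'
#' Manually curated constraint files, when available, act as a validation
#' corpus: generated constraints are compared against them and mismatches
#' are reported, never silently overridden.
#'
#' @param generated data.frame as from [readConstraintFasta()] (or built
#'   from generated [ConstraintSet-class] objects).
#' @param reference data.frame as from [readConstraintFasta()].
#' @return data.frame of mismatching records with both constraint strings
#'   and the differing positions; zero rows when all match.
#' @export
diffConstraints <- function(generated, reference) {
  m <- match(generated$name, reference$name)
  out <- data.frame(name = character(0), generated = character(0),
                    reference = character(0), differing = character(0))
  for (i in seq_along(generated$name)) {
    if (is.na(m[i])) {
      out <- rbind(out, data.frame(name = generated$name[i],
                                   generated = generated$constraint[i],
                                   reference = NA_character_,
                                   differing = "absent from reference"))
      next
    }
    g <- generated$constraint[i]
    r <- reference$constraint[m[i]]
    if (identical(g, r)) next
    gc <- strsplit(g, "")[[1]]; rc <- strsplit(r, "")[[1]]
    if (length(gc) == length(rc)) {
      d <- paste(which(gc != rc), collapse = ",")
    } else {
      d <- "length mismatch"
    }
    out <- rbind(out, data.frame(name = generated$name[i], generated = g,
                                 reference = r, differing = d))
  }
  out
}
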