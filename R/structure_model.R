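# Dot-bracket parsing, structure construction, duplex extraction from a
# hairpin fold, loop annotation and structure-difference classification.

#' Parse a dot-bracket string into a pair table
#'
#' @param db dot-bracket string over "().&". The "&" strand separator is
#'   skipped: the returned table is indexed over duplex coordinates (the
#'   string with "&" removed, 1-based).
#' @return integer vector; element i is the partner of position i, `NA` if
#'   unpaired. A symmetric involution.
#' @examples
#' parseDotBracket("((..))")   # 1<->6, 2<->5
#' parseDotBracket("....")     # all NA
#' @export
parseDotBracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "")[[1]]
  bad <- which(!ch %in% c("(", ")", ".", "&", "x"))
  if (length(bad)) {
    stop("invalid dot-bracket character '", ch[bad[1]], "' at position ",
         bad[1])
  }
  ch <- ch[ch != "&"]
  n <- length(ch)
  pairs <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[length(stack)])
  pairs
}

#' Render a pair table as a dot-bracket string
#'
#' Inverse of [parseDotBracket()] for non-crossing pair tables.
#'
#' @param pairs integer pair table (duplex coordinates).
#' @param strandBreak optional length of strand 1; when given, an "&" is
#'   inserted after that position.
#' @return dot-bracket string.
#' @export
pairsToDotBracket <- function(pairs, strandBreak = NA_integer_) {
  n <- length(pairs)
  ch <- rep(".", n)
  idx <- which(!is.na(pairs) & seq_len(n) < pairs)
  ch[idx] <- "("
  ch[pairs[idx]] <- ")"
  if (!is.na(strandBreak)) {
    ch <- append(ch, "&", after = strandBreak)
  }
  paste(ch, collapse = "")
}

#' Construct a SecondaryStructure
#'
#' @param sequence RNA string, optionally containing one "&".
#' @param dotbracket structure string of equal length.
#' @param energy free energy in kcal/mol (`NA` if not evaluated).
#' @param temperature degrees C.
#' @return a [SecondaryStructure-class] (or [DuplexStructure-class] when
#'   the sequence contains an "&").
#' @export
secondaryStructure <- function(sequence, dotbracket, energy = NA_real_,
                               temperature = 20) {
  sequence <- normalizeRna(sequence, allowAmp = TRUE)
  pairs <- parseDotBracket(dotbracket)
  amp <- regexpr("&", sequence, fixed = TRUE)
  if (amp > 0L) {
    new("DuplexStructure", sequence = sequence, dotbracket = dotbracket,
        pairs = pairs, energy = as.numeric(energy),
        temperature = as.numeric(temperature),
        strandBreak = as.integer(amp - 1L))
  } else {
    new("SecondaryStructure", sequence = sequence, dotbracket = dotbracket,
        pairs = pairs, energy = as.numeric(energy),
        temperature = as.numeric(temperature))
  }
}

# Sequence of a structure in duplex coordinates (no '&').
.coreSeq <- function(x) gsub("&", "", x@sequence, fixed = TRUE)

# strand lengths of a DuplexStructure
.strandLengths <- function(x) {
  L <- nchar(.coreSeq(x))
  c(x@strandBreak, L - x@strandBreak)
}

#' Positions forming a duplex end window
#'
#' A duplex end is formed by both strands, so the window of width `n` at
#' the 5p end comprises the first `n` positions of the 5p strand plus the
#' last `n` positions of the 3p strand; the 3p end window comprises the
#' last `n` of the 5p strand plus the first `n` of the 3p strand.
#' Nucleotides of a 3' overhang count as window members (they are terminal
#' nucleotides that happen to be unpaired already, which is what makes the
#' unwinding energy of an already-open end exactly zero).
#'
#' @param duplex a [DuplexStructure-class], or a length-2 integer vector of
#'   strand lengths.
#' @param end "5p_end" or "3p_end".
#' @param n window width in nucleotides (1-4 in standard use).
#' @return integer positions in duplex coordinates.
#' @export
endWindow <- function(duplex, end = c("5p_end", "3p_end"), n) {
  end <- match.arg(end)
  lens <- if (is(duplex, "DuplexStructure")) .strandLengths(duplex)
          else as.integer(duplex)
  stopifnot(length(lens) == 2L, n >= 1L)
  L1 <- lens[1]; L2 <- lens[2]
  if (n > min(L1, L2)) stop("window width exceeds strand length")
  if (end == "5p_end") {
    c(seq_len(n), (L1 + L2 - n + 1L):(L1 + L2))
  } else {
    c((L1 - n + 1L):L1, L1 + seq_len(n))
  }
}

#' Extract the hairpin-embedded duplex structure
#'
#' Given a miRNA whose mature arms have been located in the hairpin and the
#' hairpin MFE fold, returns the duplex structure formed by keeping exactly
#' those base pairs with *both* partners inside the two arm intervals,
#' re-indexed to duplex coordinates. Arm nucleotides paired to the loop or
#' flanking regions in the hairpin become unpaired in the duplex.
#'
#' @param record a single-record [MirnaSet-class] (or an index into a
#'   larger set via `record[i]`), with `pos5p`/`pos3p` filled.
#' @param hairpinFold [SecondaryStructure-class] of the full hairpin.
#' @return a [DuplexStructure-class] (energy `NA`; evaluate it with
#'   [evalStructure()] if needed). Emits a warning when the duplex region
#'   retains no inter-arm pair at all.
#' @export
extractHairpinDuplex <- function(record, hairpinFold) {
  stopifnot(is(record, "MirnaSet"), length(record) == 1L,
            is(hairpinFold, "SecondaryStructure"))
  if (IRanges::width(record@pos5p) == 0L || IRanges::width(record@pos3p) == 0L) {
    stop("record ", record@name, ": arm positions not set; run ",
         "locateMatureInHairpin() first")
  }
  if (.coreSeq(hairpinFold) != record@hairpin) {
    stop("hairpin fold does not cover the record's hairpin sequence")
  }
  s5 <- IRanges::start(record@pos5p); e5 <- IRanges::end(record@pos5p)
  s3 <- IRanges::start(record@pos3p); e3 <- IRanges::end(record@pos3p)
  arm <- c(s5:e5, s3:e3)
  # map hairpin position -> duplex coordinate
  dcoord <- integer(nchar(record@hairpin))
  dcoord[arm] <- seq_along(arm)
  hp <- pairTable(hairpinFold)
  L1 <- e5 - s5 + 1L
  n <- length(arm)
  pairs <- rep(NA_integer_, n)
  for (k in seq_along(arm)) {
    p <- hp[arm[k]]
    if (!is.na(p) && p %in% arm) pairs[k] <- dcoord[p]
  }
  inter <- which(!is.na(pairs) & seq_len(n) <= L1 & pairs > L1)
  if (!length(inter)) {
    warning("record ", record@name,
            ": degenerate duplex with zero inter-arm pairs")
  }
  db <- pairsToDotBracket(pairs, strandBreak = L1)
  secondaryStructure(paste0(record@seq5p, "&", record@seq3p), db,
                     energy = NA_real_,
                     temperature = foldTemperature(hairpinFold))
}

#' Annotate internal mismatches and bulges of a duplex
#'
#' Classifies every maximal run of unpaired interior positions: unpaired on
#' both strands between the same flanking pairs is a mismatch (internal
#' loop), unpaired on one strand only is a bulge. Unpaired runs at the
#' strand termini outside the outermost inter-strand pair are 3' overhangs
#' and are excluded, matching the convention that terminal overhangs are
#' not scored as internal features.
#'
#' @param duplex a [DuplexStructure-class].
#' @return data.frame with columns `kind` ("mismatch"/"bulge"),
#'   `positions` (comma-separated duplex coordinates), `size5p`, `size3p`
#'   (number of unpaired nucleotides contributed by each strand).
#' @export
annotateLoops <- function(duplex) {
  stopifnot(is(duplex, "DuplexStructure"))
  p <- pairTable(duplex)
  L1 <- duplex@strandBreak
  n <- length(p)
  # inter-strand pairs ordered along strand 1
  i1 <- which(!is.na(p) & seq_len(n) <= L1 & p > L1)
  out <- data.frame(kind = character(0), positions = character(0),
                    size5p = integer(0), size3p = integer(0))
  if (length(i1) < 1L) return(out)
  i1 <- sort(i1)
  for (k in seq_len(length(i1) - 1L)) {
    a <- i1[k]; b <- i1[k + 1L]
    ja <- p[a]; jb <- p[b]          # partners on strand 2, ja > jb
    gap1 <- if (b - a > 1L) (a + 1L):(b - 1L) else integer(0)
    gap2 <- if (ja - jb > 1L) (jb + 1L):(ja - 1L) else integer(0)
    # positions inside the gaps that are themselves paired (intra-strand
    # helix inserted in the loop) still interrupt the duplex; only count
    # unpaired ones as mismatch/bulge material
    gap1 <- gap1[is.na(p[gap1])]
    gap2 <- gap2[is.na(p[gap2])]
    if (!length(gap1) && !length(gap2)) next
    kind <- if (length(gap1) && length(gap2)) "mismatch" else "bulge"
    out <- rbind(out, data.frame(
      kind = kind,
      positions = paste(sort(c(gap1, gap2)), collapse = ","),
      size5p = length(gap1), size3p = length(gap2)))
  }
  out
}

# Positions belonging to any hairpin (terminal) loop of a single-strand
# structure: maximal unpaired runs directly closed by a pair.
.hairpinLoopPositions <- function(pairs) {
  n <- length(pairs)
  out <- integer(0)
  idx <- which(!is.na(pairs) & seq_len(n) < pairs)
  for (i in idx) {
    j <- pairs[i]
    if (j - i > 1L && all(is.na(pairs[(i + 1L):(j - 1L)]))) {
      out <- c(out, (i + 1L):(j - 1L))
    }
  }
  out
}

#' Classify the difference between two structures of one sequence
#'
#' Positions whose pairing status differs between the two structures are
#' partitioned into a terminal zone (within `terminalMargin` nucleotides of
#' any strand terminus; for single-strand hairpins the terminal loop runs
#' of either structure are also terminal) and a central zone. The category
#' is "identical" when the dot-bracket strings are equal, otherwise
#' "terminal", "central" or "both" according to which zones are occupied.
#' Symmetric in its two arguments.
#'
#' @param a,b [SecondaryStructure-class] objects over the same sequence.
#' @param terminalMargin width of the terminal zone in nucleotides
#'   (default 4, the maximum unwinding window).
#' @return one of "identical", "terminal", "central", "both".
#' @export
classifyDifference <- function(a, b, terminalMargin = 4L) {
  stopifnot(is(a, "SecondaryStructure"), is(b, "SecondaryStructure"))
  if (.coreSeq(a) != .coreSeq(b)) {
    stop("structures must share one underlying sequence")
  }
  if (dotBracket(a) == dotBracket(b)) return("identical")
  pa <- pairTable(a); pb <- pairTable(b)
  diff <- which((is.na(pa) != is.na(pb)) |
                (!is.na(pa) & !is.na(pb) & pa != pb))
  n <- length(pa)
  if (is(a, "DuplexStructure")) {
    L1 <- strandBreak(a)
    term <- c(seq_len(min(terminalMargin, L1)),
              L1 - seq_len(min(terminalMargin, L1)) + 1L,
              L1 + seq_len(min(terminalMargin, n - L1)),
              n - seq_len(min(terminalMargin, n - L1)) + 1L)
  } else {
    term <- c(seq_len(min(terminalMargin, n)),
              n - seq_len(min(terminalMargin, n)) + 1L,
              .hairpinLoopPositions(pa), .hairpinLoopPositions(pb))
  }
  inTerm <- diff %in% term
  if (all(inTerm)) "terminal" else if (!any(inTerm)) "central" else "both"
}
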