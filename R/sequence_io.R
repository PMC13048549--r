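# Reading and writing the sequence and annotation formats the pipeline
# touches: plain FASTA for hairpins, the cofold "SEQ5P&SEQ3P" FASTA
# dialect for duplexes, and the tab-separated annotation table.

#' Normalize an RNA sequence
#'
#' Upper-cases and converts DNA T to RNA U (a common repository export
#' artifact); any remaining non-ACGU character is an error.
#'
#' @param x character vector of sequences.
#' @param allowAmp allow one "&" strand separator per sequence.
#' @param what label used in error messages.
#' @return normalized character vector.
#' @export
normalizeRna <- function(x, allowAmp = FALSE, what = names(x)) {
  if (is.null(what)) what <- seq_along(x)
  x <- chartr("t", "u", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  ok <- c(.RNA_ALPHABET, if (allowAmp) "&")
  for (i in seq_along(x)) {
    ch <- strsplit(x[i], "")[[1]]
    bad <- which(!ch %in% ok)
    if (length(bad)) {
      stop("record '", what[i], "': invalid character '", ch[bad[1]],
           "' at position ", bad[1])
    }
    if (allowAmp && sum(ch == "&") > 1L) {
      stop("record '", what[i], "': more than one '&' separator")
    }
  }
  x
}

#' Read a (possibly cofold-dialect) FASTA file
#'
#' Reads FASTA records and normalizes the sequences to uppercase RNA.
#' Sequences may contain one "&" strand separator (the RNAcofold input
#' dialect used for duplex files). Order is preserved.
#'
#' @param path FASTA file.
#' @return named character vector of normalized sequences.
#' @examples
#' fa <- system.file("extdata", "cel-let-7_duplex.fa", package = "unwindR")
#' readRnaFasta(fa)
#' @export
readRnaFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("format error: no FASTA records in ", path)
  nm <- names(set)
  if (any(!nzchar(nm))) stop("format error: empty FASTA header in ", path)
  nm <- sub("\\s.*$", "", nm)   # first word of the header
  seqs <- as.character(set)
  stats::setNames(normalizeRna(seqs, allowAmp = TRUE, what = nm), nm)
}

#' Write sequences as FASTA
#'
#' @param x named character vector (may contain "&"-joined duplexes).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRnaFasta <- function(x, path) {
  stopifnot(!is.null(names(x)))
  lines <- as.vector(rbind(paste0(">", names(x)), unname(x)))
  writeLines(lines, path)
  invisible(path)
}

#' Split a cofold-dialect duplex record
#'
#' The first sequence is the 5p arm and the second the 3p arm, matching
#' the orientation of duplex figures (5p strand on top).
#'
#' @param sequence string containing exactly one "&".
#' @return character vector `c(seq5p, seq3p)`.
#' @examples
#' splitDuplexRecord("AAGG&CCUU")
#' @export
splitDuplexRecord <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  parts <- strsplit(sequence, "&", fixed = TRUE)[[1]]
  nAmp <- nchar(sequence) - nchar(gsub("&", "", sequence, fixed = TRUE))
  if (nAmp != 1L) {
    stop("format error: expected exactly one '&', found ", nAmp)
  }
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop("format error: both duplex strands must be non-empty")
  }
  c(seq5p = parts[1], seq3p = parts[2])
}

#' Construct a MirnaSet
#'
#' @param name record identifiers.
#' @param seq5p,seq3p mature arm sequences (normalized on input).
#' @param hairpin optional hairpin sequences (`NA` where unavailable).
#' @param guideArm "5p", "3p" or "unknown" per record.
#' @return a [MirnaSet-class].
#' @export
MirnaSet <- function(name, seq5p, seq3p, hairpin = NA_character_,
                     guideArm = "unknown") {
  n <- length(name)
  hairpin <- rep_len(as.character(hairpin), n)
  guideArm <- rep_len(guideArm, n)
  hp <- hairpin
  hp[!is.na(hp)] <- normalizeRna(hp[!is.na(hp)], what = name[!is.na(hp)])
  new("MirnaSet",
      name = as.character(name),
      hairpin = hp,
      seq5p = normalizeRna(seq5p, what = name),
      seq3p = normalizeRna(seq3p, what = name),
      pos5p = IRanges::IRanges(rep(1L, n), width = 0L),
      pos3p = IRanges::IRanges(rep(1L, n), width = 0L),
      guideArm = as.character(guideArm))
}

#' Read miRNA records from duplex FASTA and annotation table
#'
#' Assembles a [MirnaSet-class] from a cofold-dialect duplex FASTA
#' ("SEQ5P&SEQ3P" records), an optional hairpin FASTA keyed by the same
#' record names, and an optional tab-separated annotation table with
#' columns `name`, `seq5p`, `seq3p`, `guide_arm`. Records present in the
#' duplex file define the set; only miRNAs with both arms annotated can
#' form a duplex, which is why the duplex file is the anchor.
#'
#' @param duplexFasta path to the duplex FASTA.
#' @param hairpinFasta optional path to a hairpin FASTA.
#' @param annotationTsv optional path to the annotation table.
#' @return a [MirnaSet-class].
#' @export
readMirnaSet <- function(duplexFasta, hairpinFasta = NULL,
                         annotationTsv = NULL) {
  dup <- readRnaFasta(duplexFasta)
  parts <- vapply(dup, splitDuplexRecord, character(2))
  set <- MirnaSet(name = names(dup), seq5p = parts[1, ], seq3p = parts[2, ])
  if (!is.null(hairpinFasta)) {
    hp <- readRnaFasta(hairpinFasta)
    if (any(grepl("&", hp, fixed = TRUE))) {
      stop("format error: hairpin FASTA must not contain '&'")
    }
    idx <- match(set@name, names(hp))
    set@hairpin <- unname(hp[idx])
  }
  if (!is.null(annotationTsv)) {
    ann <- readAnnotationTable(annotationTsv)
    idx <- match(set@name, ann$name)
    ga <- ann$guide_arm[idx]
    ga[is.na(ga)] <- "unknown"
    set@guideArm <- ga
  }
  validObject(set)
  set
}

#' Read a guide-arm annotation table
#'
#' Tab-separated, columns `name`, `seq5p`, `seq3p`, `guide_arm` (the guide
#' arm as annotated from read counts: "5p", "3p" or "unknown").
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readAnnotationTable <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("name", "seq5p", "seq3p", "guide_arm")
  miss <- setdiff(need, colnames(ann))
  if (length(miss)) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ann$seq5p <- normalizeRna(ann$seq5p, what = ann$name)
  ann$seq3p <- normalizeRna(ann$seq3p, what = ann$name)
  bad <- !ann$guide_arm %in% c("5p", "3p", "unknown")
  if (any(bad)) {
    stop("invalid guide_arm value(s): ",
         paste(unique(ann$guide_arm[bad]), collapse = ", "))
  }
  ann
}

#' Locate the mature arms within the hairpin
#'
#' Fills `pos5p`/`pos3p` with the 1-based closed interval at which each
#' mature sequence occurs in the hairpin. A mature sequence that is absent
#' is a lookup error; one that occurs more than once is an ambiguity error
#' listing all start positions, because silently taking the first match
#' could misplace the hairpin-embedded duplex.
#'
#' @param set a [MirnaSet-class] with hairpins available.
#' @return the set with positions filled.
#' @export
locateMatureInHairpin <- function(set) {
  stopifnot(is(set, "MirnaSet"))
  locate1 <- function(mature, hairpin, name, arm) {
    hits <- Biostrings::matchPattern(mature, Biostrings::RNAString(hairpin))
    st <- IRanges::start(hits)
    if (length(st) == 0L) {
      stop("record '", name, "': ", arm, " arm not found in hairpin")
    }
    if (length(st) > 1L) {
      stop("record '", name, "': ", arm, " arm occurs ", length(st),
           " times in hairpin (starts: ", paste(st, collapse = ", "), ")")
    }
    IRanges::IRanges(st, width = nchar(mature))
  }
  p5 <- set@pos5p; p3 <- set@pos3p
  for (i in seq_along(set@name)) {
    if (is.na(set@hairpin[i])) next
    p5[i] <- locate1(set@seq5p[i], set@hairpin[i], set@name[i], "5p")
    p3[i] <- locate1(set@seq3p[i], set@hairpin[i], set@name[i], "3p")
  }
  set@pos5p <- p5
  set@pos3p <- p3
  validObject(set)
  set
}

#' Write the duplex strands of a MirnaSet as cofold-dialect FASTA
#'
#' @param set a [MirnaSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDuplexFasta <- function(set, path) {
  stopifnot(is(set, "MirnaSet"))
  writeRnaFasta(stats::setNames(paste0(set@seq5p, "&", set@seq3p),
                                set@name), path)
}
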