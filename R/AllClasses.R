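#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.RNA_ALPHABET <- c("A", "C", "G", "U")
.CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")
.ENDS <- c("5p_end", "3p_end")
.REGIMES <- c("mfe_pinned", "hairpin_pinned", "ends_only")

#' Engine configuration
#'
#' Settings passed to the thermodynamic folding engine (ViennaRNA). The
#' pipeline's standard runs vary only the temperature (15, 20, 25 or 37
#' degrees C); all other fields are recorded for provenance.
#'
#' @slot temperature folding temperature in degrees Celsius. Default 20,
#'   the common *C. elegans* culture temperature.
#' @slot paramSet identifier of the nearest-neighbour parameter table the
#'   engine uses ("turner2004", the engine default).
#' @slot dangles dangling-end treatment identifier; "default" keeps the
#'   engine's own default (d2), recorded rather than guessed.
#' @slot enforceConstraints whether bracket constraints should be enforced
#'   as pairs rather than merely permitted. The standard pipeline never
#'   needs enforcement (pinned reference structures are evaluated directly,
#'   see [evalStructure()]), so this defaults to `FALSE`.
#'
#' @seealso [engineConfig()]
#' @export
setClass("EngineConfig", representation(
  temperature = "numeric",
  paramSet = "character",
  dangles = "character",
  enforceConstraints = "logical"
))

setValidity("EngineConfig", function(object) {
  t <- object@temperature
  if (length(t) != 1L || !is.finite(t)) {
    return("temperature must be a single finite number")
  }
  if (t <= 0 || t >= 100) {
    return("temperature must be in (0, 100) degrees C for supported use")
  }
  TRUE
})

#' Create an engine configuration
#'
#' @param temperature folding temperature in degrees Celsius (default 20).
#' @param paramSet parameter-set identifier (default "turner2004").
#' @param dangles dangle-treatment identifier (default "default").
#' @param enforceConstraints logical; see [EngineConfig-class].
#' @return an [EngineConfig-class] object.
#' @examples
#' cfg <- engineConfig(temperature = 20)
#' @export
engineConfig <- function(temperature = 20, paramSet = "turner2004",
                         dangles = "default", enforceConstraints = FALSE) {
  new("EngineConfig", temperature = as.numeric(temperature),
      paramSet = paramSet, dangles = dangles,
      enforceConstraints = enforceConstraints)
}

#' Secondary structure of an RNA
#'
#' A sequence together with its dot-bracket structure, pair table and free
#' energy at a given temperature. Two-strand (cofolded) structures carry
#' one "&" separator in both the sequence and the dot-bracket string; the
#' pair table is indexed over *duplex coordinates*, i.e. the concatenated
#' sequence with the "&" removed, 1-based.
#'
#' @slot sequence RNA string over A/C/G/U, optionally with one "&".
#' @slot dotbracket structure string over "().&", same length as sequence.
#' @slot pairs integer vector, `pairs[i]` is the partner of position i in
#'   duplex coordinates, `NA` if unpaired; a symmetric involution.
#' @slot energy free energy in kcal/mol (`NA` when not evaluated).
#' @slot temperature temperature in degrees C the structure refers to.
#' @export
setClass("SecondaryStructure", representation(
  sequence = "character",
  dotbracket = "character",
  pairs = "integer",
  energy = "numeric",
  temperature = "numeric"
))

setValidity("SecondaryStructure", function(object) {
  s <- object@sequence
  d <- object@dotbracket
  if (length(s) != 1L || length(d) != 1L) {
    return("sequence and dotbracket must be single strings")
  }
  if (nchar(s) != nchar(d)) {
    return("sequence and dotbracket must have equal length")
  }
  samp <- which(strsplit(s, "")[[1]] == "&")
  damp <- which(strsplit(d, "")[[1]] == "&")
  if (!identical(samp, damp)) {
    return("'&' positions in sequence and dotbracket must align")
  }
  if (length(samp) > 1L) return("at most one '&' separator is allowed")
  chars <- setdiff(strsplit(s, "")[[1]], c(.RNA_ALPHABET, "&"))
  if (length(chars)) {
    return(paste0("invalid sequence characters: ",
                  paste(unique(chars), collapse = ", ")))
  }
  p <- object@pairs
  n <- nchar(gsub("&", "", s, fixed = TRUE))
  if (length(p) != n) return("pairs must have one entry per nucleotide")
  idx <- which(!is.na(p))
  if (any(p[idx] < 1L | p[idx] > n)) return("pair partner out of range")
  if (any(p[idx] == idx)) return("self-pairs are not allowed")
  if (!identical(p[p[idx]], idx)) return("pairs must be a symmetric involution")
  TRUE
})

#' Two-strand duplex structure
#'
#' A [SecondaryStructure-class] over "seq5p&seq3p" with the strand break
#' index recorded. By convention the first strand is the 5p arm. The two
#' duplex ends are composed of both strands: the 5p end pairs the 5'
#' terminus of the 5p strand with the 3' terminus of the 3p strand, and
#' vice versa for the 3p end (see [endWindow()]).
#'
#' @slot strandBreak integer, length of strand 1 (the 5p arm); positions
#'   1..strandBreak are strand 1, the rest strand 2, in duplex coordinates.
#' @export
setClass("DuplexStructure", contains = "SecondaryStructure",
         representation(strandBreak = "integer"))

setValidity("DuplexStructure", function(object) {
  if (length(object@strandBreak) != 1L || is.na(object@strandBreak)) {
    return("strandBreak must be a single integer")
  }
  amp <- regexpr("&", object@sequence, fixed = TRUE)
  if (amp < 0L) return("a DuplexStructure requires an '&' strand separator")
  if (object@strandBreak != amp - 1L) {
    return("strandBreak must equal the position before '&'")
  }
  TRUE
})

#' Hard-constraint set for constrained cofolding
#'
#' A per-position constraint string aligned to "seq5p&seq3p" in the engine
#' dialect: "." unconstrained, "x" forbidden to pair, "(" / ")" pinned to a
#' specific pair; the "&" carries no constraint. Three regimes are used:
#' `mfe_pinned` and `hairpin_pinned` transcribe a reference structure
#' (pairs pinned, unpaired positions forbidden) before end unwinding, and
#' `ends_only` forbids pairing only within the unwound end window.
#'
#' @slot constraint constraint string including the "&".
#' @slot regime one of "mfe_pinned", "hairpin_pinned", "ends_only".
#' @slot end which duplex end is unwound: "5p_end", "3p_end" or "none".
#' @slot width unwinding window width, 0 (no unwinding) to 4.
#' @export
setClass("ConstraintSet", representation(
  constraint = "character",
  regime = "character",
  end = "character",
  width = "integer"
))

setValidity("ConstraintSet", function(object) {
  ch <- strsplit(object@constraint, "")[[1]]
  bad <- setdiff(ch, c(".", "x", "(", ")", "&"))
  if (length(bad)) {
    return(paste0("invalid constraint characters: ", paste(bad, collapse = ",")))
  }
  if (sum(ch == "(") != sum(ch == ")")) return("unbalanced pinned brackets")
  if (!object@regime %in% .REGIMES) return("unknown regime")
  if (!object@end %in% c(.ENDS, "none")) return("unknown end")
  w <- object@width
  if (length(w) != 1L || w < 0L) return("width must be a single non-negative integer")
  if (w == 0L && object@end != "none") return("width 0 implies end 'none'")
  TRUE
})

#' A set of miRNA records
#'
#' Column-oriented container holding, per miRNA: the hairpin (precursor)
#' sequence when available, the mature 5p and 3p arm sequences, their
#' 1-based closed intervals within the hairpin once located (see
#' [locateMatureInHairpin()]), and the annotated guide arm ("5p", "3p" or
#' "unknown"; in the source data the guide is the strand with the most
#' reported reads).
#'
#' @slot name character, record identifiers (unique).
#' @slot hairpin character, hairpin sequences or `NA`.
#' @slot seq5p,seq3p character, mature arm sequences.
#' @slot pos5p,pos3p [IRanges::IRanges] of arm locations in the hairpin
#'   (zero-width placeholder until located).
#' @slot guideArm character, "5p", "3p" or "unknown".
#' @export
setClass("MirnaSet", representation(
  name = "character",
  hairpin = "character",
  seq5p = "character",
  seq3p = "character",
  pos5p = "IRanges",
  pos3p = "IRanges",
  guideArm = "character"
))

setValidity("MirnaSet", function(object) {
  n <- length(object@name)
  lens <- c(length(object@hairpin), length(object@seq5p),
            length(object@seq3p), length(object@guideArm),
            length(object@pos5p), length(object@pos3p))
  if (any(lens != n)) return("all slots must have one entry per record")
  if (anyDuplicated(object@name)) return("record names must be unique")
  if (!all(object@guideArm %in% c("5p", "3p", "unknown"))) {
    return("guideArm must be '5p', '3p' or 'unknown'")
  }
  # located arms must match the hairpin subsequence and be ordered
  w5 <- IRanges::width(object@pos5p)
  w3 <- IRanges::width(object@pos3p)
  chk <- which(w5 > 0L & w3 > 0L & !is.na(object@hairpin))
  for (i in chk) {
    h <- object@hairpin[i]
    s5 <- IRanges::start(object@pos5p)[i]; e5 <- IRanges::end(object@pos5p)[i]
    s3 <- IRanges::start(object@pos3p)[i]; e3 <- IRanges::end(object@pos3p)[i]
    if (substr(h, s5, e5) != object@seq5p[i]) {
      return(sprintf("record %s: pos5p does not match seq5p", object@name[i]))
    }
    if (substr(h, s3, e3) != object@seq3p[i]) {
      return(sprintf("record %s: pos3p does not match seq3p", object@name[i]))
    }
    if (e5 >= s3) {
      return(sprintf("record %s: 5p arm must lie upstream of the 3p arm",
                     object@name[i]))
    }
  }
  TRUE
})

#' Unwinding-energy profile of one duplex
#'
#' Free energies of the fully wound reference structure and of the
#' partially unwound structures (1-4 terminal nucleotides forced unpaired
#' on each duplex end, on both strands), under one folding regime. The
#' unwinding energy is ddG = dG(unwound) - dG(wound): the energy cost of
#' opening that end, so positive values mean a stable end. Under the
#' `mfe_pinned` and `ends_only` regimes the wound reference is the global
#' MFE and ddG is non-negative; under `hairpin_pinned` the reference is the
#' hairpin-embedded structure and negative ddG marks ends that are
#' energetically favoured to unwind once the duplex leaves the hairpin.
#'
#' @slot name record identifier.
#' @slot regime folding regime the profile was computed under.
#' @slot temperature degrees C.
#' @slot dGWound energy of the wound reference structure, kcal/mol.
#' @slot dGUnwound 2 x W matrix (rows "5p_end","3p_end"), kcal/mol.
#' @slot ddG 2 x W matrix of unwinding energies, kcal/mol.
#' @export
setClass("UnwindingProfile", representation(
  name = "character",
  regime = "character",
  temperature = "numeric",
  dGWound = "numeric",
  dGUnwound = "matrix",
  ddG = "matrix"
))

setValidity("UnwindingProfile", function(object) {
  if (!object@regime %in% .REGIMES) return("unknown regime")
  for (m in list(object@dGUnwound, object@ddG)) {
    if (!identical(rownames(m), .ENDS)) {
      return("matrices must have rows '5p_end', '3p_end'")
    }
  }
  if (!isTRUE(all.equal(object@ddG, object@dGUnwound - object@dGWound,
                        tolerance = 1e-6, check.attributes = FALSE))) {
    return("ddG must equal dGUnwound - dGWound")
  }
  if (object@regime %in% c("mfe_pinned", "ends_only") &&
      any(object@ddG < -0.005, na.rm = TRUE)) {
    return("ddG must be non-negative when the wound reference is the MFE")
  }
  TRUE
})
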