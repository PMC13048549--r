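# Accessors and show methods for the core classes.

#' @rdname SecondaryStructure-class
#' @aliases dotBracket,SecondaryStructure-method
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotbracket)

#' @rdname SecondaryStructure-class
#' @aliases pairTable,SecondaryStructure-method
setMethod("pairTable", "SecondaryStructure", function(x) x@pairs)

#' @rdname SecondaryStructure-class
#' @aliases freeEnergy,SecondaryStructure-method
setMethod("freeEnergy", "SecondaryStructure", function(x) x@energy)

#' @rdname SecondaryStructure-class
#' @aliases foldTemperature,SecondaryStructure-method
setMethod("foldTemperature", "SecondaryStructure", function(x) x@temperature)

#' @rdname DuplexStructure-class
#' @aliases strandBreak,DuplexStructure-method
setMethod("strandBreak", "DuplexStructure", function(x) x@strandBreak)

#' @rdname MirnaSet-class
#' @aliases guideArm,MirnaSet-method
setMethod("guideArm", "MirnaSet", function(x) {
  stats::setNames(x@guideArm, x@name)
})

#' @rdname UnwindingProfile-class
#' @aliases ddG,UnwindingProfile-method
setMethod("ddG", "UnwindingProfile", function(x) x@ddG)

#' @rdname UnwindingProfile-class
#' @aliases dGWound,UnwindingProfile-method
setMethod("dGWound", "UnwindingProfile", function(x) x@dGWound)

#' @rdname MirnaSet-class
#' @aliases length,MirnaSet-method
setMethod("length", "MirnaSet", function(x) length(x@name))

#' @rdname MirnaSet-class
#' @aliases names,MirnaSet-method
setMethod("names", "MirnaSet", function(x) x@name)

#' @rdname MirnaSet-class
#' @param i index (integer, logical or name).
#' @param j,...,drop ignored.
#' @aliases [,MirnaSet-method
setMethod("[", "MirnaSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@name)
  new("MirnaSet",
      name = x@name[i], hairpin = x@hairpin[i],
      seq5p = x@seq5p[i], seq3p = x@seq3p[i],
      pos5p = x@pos5p[i], pos3p = x@pos3p[i],
      guideArm = x@guideArm[i])
})

setMethod("show", "EngineConfig", function(object) {
  cat(sprintf("EngineConfig: T = %g C, params = %s, dangles = %s%s\n",
              object@temperature, object@paramSet, object@dangles,
              if (object@enforceConstraints) ", enforce" else ""))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("%s at %g C\n  %s\n  %s (%.2f kcal/mol)\n",
              class(object), object@temperature,
              object@sequence, object@dotbracket, object@energy))
})

setMethod("show", "ConstraintSet", function(object) {
  cat(sprintf("ConstraintSet [%s, end = %s, width = %d]\n  %s\n",
              object@regime, object@end, object@width, object@constraint))
})

setMethod("show", "MirnaSet", function(object) {
  n <- length(object)
  cat(sprintf("MirnaSet with %d record%s (%d with hairpin, guide arm: %s)\n",
              n, if (n == 1) "" else "s",
              sum(!is.na(object@hairpin)),
              paste(sprintf("%s=%d", names(table(object@guideArm)),
                            table(object@guideArm)), collapse = ", ")))
  if (n > 0) {
    show <- utils::head(object@name, 5)
    cat("  ", paste(show, collapse = ", "),
        if (n > 5) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "UnwindingProfile", function(object) {
  cat(sprintf("UnwindingProfile '%s' [%s, %g C]\n  dG(wound) = %.2f kcal/mol\n",
              object@name, object@regime, object@temperature, object@dGWound))
  cat("  ddG (kcal/mol):\n")
  m <- round(object@ddG, 2)
  colnames(m) <- paste0("n=", seq_len(ncol(m)))
  print(m)
})
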