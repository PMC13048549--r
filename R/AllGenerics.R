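#' @rdname SecondaryStructure-class
#' @param object,x an object.
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("foldTemperature", function(x) standardGeneric("foldTemperature"))

#' @rdname DuplexStructure-class
#' @param x an object.
#' @export
setGeneric("strandBreak", function(x) standardGeneric("strandBreak"))

#' @rdname MirnaSet-class
#' @param x an object.
#' @export
setGeneric("guideArm", function(x) standardGeneric("guideArm"))

#' @rdname UnwindingProfile-class
#' @param x an object.
#' @export
setGeneric("ddG", function(x) standardGeneric("ddG"))

#' @rdname UnwindingProfile-class
#' @export
setGeneric("dGWound", function(x) standardGeneric("dGWound"))
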