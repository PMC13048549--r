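# Twin-drive prediction of miRNA strand selection: combines the
# thermodynamic asymmetry of the duplex ends (G-drive) with the identity
# of each strand's 5'-terminal nucleotide (N-drive) into a predicted
# log-ratio of strand levels, and scores predictions against annotated
# guide strands.

#' Load twin-drive constants
#'
#' Reads `k` and the four 5'-nucleotide drive values N_U, N_A, N_G, N_C
#' from a TSV with a provenance header. The packaged default preserves the
#' published sign structure of the twin-drive model on the unwinding-cost
#' energy scale (see the file's header); supply your own file to use a
#' specific publication's fitted constants.
#'
#' @param path TSV with columns `constant`, `value`; default the packaged
#'   file.
#' @return list with elements `k` (numeric) and `N` (named numeric over
#'   U, A, G, C), plus a `provenance` attribute.
#' @export
twinDriveParams <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "twin_drive_constants.tsv",
                        package = "unwindR", mustWork = TRUE)
  }
  hdr <- grep("^#", readLines(path, n = 30), value = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$value, tab$constant)
  need <- c("k", "N_U", "N_A", "N_G", "N_C")
  miss <- setdiff(need, names(vals))
  if (length(miss)) {
    stop("constants file lacks: ", paste(miss, collapse = ", "))
  }
  out <- list(k = unname(vals["k"]),
              N = stats::setNames(unname(vals[c("N_U", "N_A", "N_G", "N_C")]),
                                  c("U", "A", "G", "C")))
  attr(out, "provenance") <- paste(sub("^#\\s?", "", hdr), collapse = " ")
  out
}

#' Twin-drive log strand ratio
#'
#' ln(5p/3p) = k * (dG5p - dG3p) + N\[nt5p\] - N\[nt3p\], where dG5p/dG3p
#' are the end energies of the 5p and 3p duplex ends computed by one
#' method at one width (blind to which arm is the guide) and nt5p/nt3p are
#' the 5'-terminal nucleotides of the respective strands.
#'
#' @param dG5p,dG3p end energies, kcal/mol (unwinding-cost scale).
#' @param nt5p,nt3p 5'-terminal bases of the 5p and 3p strands.
#' @param params constants from [twinDriveParams()].
#' @return numeric ln(5p/3p); positive predicts 5p dominance.
#' @export
predictLnRatio <- function(dG5p, dG3p, nt5p, nt3p,
                           params = twinDriveParams()) {
  nt5p <- toupper(nt5p); nt3p <- toupper(nt3p)
  bad <- setdiff(unique(c(nt5p, nt3p)), names(params$N))
  if (length(bad)) {
    stop("config error: no N value for 5' nucleotide ",
         paste(bad, collapse = ", "))
  }
  params$k * (dG5p - dG3p) + params$N[nt5p] - params$N[nt3p]
}

#' Predict strand selection for a set of duplexes
#'
#' Builds one prediction per (miRNA, width) from a long energy table. The
#' 5p-end and 3p-end energies enter as-is regardless of which arm is the
#' guide; annotations are used only for scoring, keeping the prediction
#' blind to the answer. A log-ratio of exactly 0 is "ambiguous" and scored
#' incorrect.
#'
#' @param tbl long table with columns name, end, width, ddG (from
#'   [profilesToTable()] or [nnEnergyTable()]).
#' @param set a [MirnaSet-class] (sequences give the 5' nucleotides,
#'   guide-arm annotations the truth labels).
#' @param method label recorded in the output (e.g. "mfe_pinned",
#'   "nearest_neighbor").
#' @param params constants from [twinDriveParams()].
#' @return data.frame with columns name, method, width,
#'   ddG_5p_minus_3p, nt5p, nt3p, ln_ratio, predicted_arm, annotated_arm,
#'   correct.
#' @export
predictStrands <- function(tbl, set, method, params = twinDriveParams()) {
  stopifnot(is(set, "MirnaSet"))
  nt5 <- stats::setNames(substr(set@seq5p, 1, 1), set@name)
  nt3 <- stats::setNames(substr(set@seq3p, 1, 1), set@name)
  arm <- guideArm(set)
  wide <- merge(
    tbl[tbl$end == "5p_end", c("name", "width", "ddG")],
    tbl[tbl$end == "3p_end", c("name", "width", "ddG")],
    by = c("name", "width"), suffixes = c("_5p", "_3p"))
  ln <- predictLnRatio(wide$ddG_5p, wide$ddG_3p,
                       nt5[wide$name], nt3[wide$name], params)
  pred <- ifelse(ln > 0, "5p", ifelse(ln < 0, "3p", "ambiguous"))
  out <- data.frame(
    name = wide$name, method = method, width = wide$width,
    ddG_5p_minus_3p = wide$ddG_5p - wide$ddG_3p,
    nt5p = unname(nt5[wide$name]), nt3p = unname(nt3[wide$name]),
    ln_ratio = unname(ln), predicted_arm = pred,
    annotated_arm = unname(arm[wide$name]),
    correct = pred == unname(arm[wide$name]),
    row.names = NULL)
  out[order(out$width, match(out$name, set@name)), ]
}

#' Score strand predictions
#'
#' Counts and fraction correct per (method, width). Ambiguous predictions
#' count as incorrect; records without a 5p/3p annotation are excluded.
#' Invariant to the order of the input rows.
#'
#' @param predictions data.frame from [predictStrands()] (several methods
#'   may be rbind-ed together).
#' @return data.frame with columns method, width, n, n_correct, accuracy.
#' @export
scorePredictions <- function(predictions) {
  p <- predictions[predictions$annotated_arm %in% c("5p", "3p"), ]
  agg <- stats::aggregate(correct ~ method + width, data = p,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(method = agg$method, width = agg$width,
                    n = agg$correct[, "n"], n_correct = agg$correct[, "k"])
  out$accuracy <- out$n_correct / out$n
  out[order(out$method, out$width), ]
}

#' Stratify prediction accuracy by guide-passenger asymmetry sign
#'
#' Computes ddG(guide end) - ddG(passenger end) per prediction (using the
#' annotated arm) and reports accuracy separately for miRNAs whose guide
#' end is strictly easier to unwind (negative asymmetry) and for the rest.
#' A strongly negative stratum is where thermodynamics alone points at the
#' annotated guide.
#'
#' @param predictions data.frame from [predictStrands()].
#' @return data.frame with columns method, width, stratum
#'   ("negative"/"non_negative"), n, n_correct, accuracy.
#' @export
stratifyByAsymmetry <- function(predictions) {
  p <- predictions[predictions$annotated_arm %in% c("5p", "3p"), ]
  sgn <- ifelse(p$annotated_arm == "5p", 1, -1)
  guideMinusPassenger <- sgn * p$ddG_5p_minus_3p
  p$stratum <- ifelse(guideMinusPassenger < 0, "negative", "non_negative")
  agg <- stats::aggregate(correct ~ method + width + stratum, data = p,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(method = agg$method, width = agg$width,
                    stratum = agg$stratum,
                    n = agg$correct[, "n"], n_correct = agg$correct[, "k"])
  out$accuracy <- out$n_correct / out$n
  out[order(out$method, out$width, out$stratum), ]
}

#' Per-miRNA always/never-correct tally
#'
#' Across all supplied methods and widths, which miRNAs are always
#' predicted correctly and which never are.
#'
#' @param predictions data.frame from [predictStrands()], typically all
#'   methods and widths rbind-ed.
#' @return data.frame with columns name, n_predictions, n_correct,
#'   always_correct, never_correct.
#' @export
alwaysNeverCorrect <- function(predictions) {
  p <- predictions[predictions$annotated_arm %in% c("5p", "3p"), ]
  agg <- stats::aggregate(correct ~ name, data = p,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  data.frame(name = agg$name,
             n_predictions = agg$correct[, "n"],
             n_correct = agg$correct[, "k"],
             always_correct = agg$correct[, "k"] == agg$correct[, "n"],
             never_correct = agg$correct[, "k"] == 0)
}
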