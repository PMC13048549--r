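# One front door running the whole analysis: unwinding energies under all
# regimes, nearest-neighbour comparison energies, twin-drive strand
# predictions and their scores.

#' Run the full unwinding and strand-selection analysis
#'
#' For every duplex in the set: cofolds the unconstrained MFE structure,
#' computes unwinding-energy profiles under the requested regimes,
#' computes terminal nearest-neighbour energies from the MFE structure,
#' predicts strand selection with the twin-drive model for every method
#' and width, and scores predictions against the guide-arm annotations.
#'
#' @param set a [MirnaSet-class]; records must have hairpins when
#'   `"hairpin_pinned"` is among the regimes.
#' @param cfg an [EngineConfig-class] (default 20 C).
#' @param regimes unwinding regimes to run (default all three).
#' @param widths window widths (default 1:4).
#' @param params twin-drive constants from [twinDriveParams()].
#' @param nn include the nearest-neighbour comparison method.
#' @return list with `tables` (long energy tables per method),
#'   `predictions` (all methods and widths), `scores`
#'   ([scorePredictions()]), `stratified` ([stratifyByAsymmetry()]),
#'   `tally` ([alwaysNeverCorrect()]) and `group_stats` (guide vs
#'   passenger end statistics per method).
#' @export
runUnwindingAnalysis <- function(set, cfg = engineConfig(),
                                 regimes = .REGIMES, widths = 1:4,
                                 params = twinDriveParams(), nn = TRUE) {
  stopifnot(is(set, "MirnaSet"))
  regimes <- match.arg(regimes, .REGIMES, several.ok = TRUE)
  mfe <- cofoldDuplexes(set@seq5p, set@seq3p, cfg, names = set@name)
  names(mfe) <- set@name
  hpFolds <- NULL
  if ("hairpin_pinned" %in% regimes) {
    hpFolds <- foldHairpins(stats::setNames(set@hairpin, set@name), cfg)
    names(hpFolds) <- set@name
  }
  tables <- list()
  for (r in regimes) {
    prof <- computeUnwindingProfiles(set, r, cfg, widths,
                                     hairpinFolds = hpFolds,
                                     mfeStructures = mfe)
    tables[[r]] <- profilesToTable(prof)
  }
  if (nn) {
    tables[["nearest_neighbor"]] <- nnEnergyTable(mfe, widths)
  }
  predictions <- do.call(rbind, lapply(names(tables), function(m) {
    predictStrands(tables[[m]], set, method = m, params = params)
  }))
  groupStats_ <- lapply(tables, groupStats, set = set)
  list(tables = tables,
       mfe_structures = mfe,
       predictions = predictions,
       scores = scorePredictions(predictions),
       stratified = stratifyByAsymmetry(predictions),
       tally = alwaysNeverCorrect(predictions),
       group_stats = groupStats_)
}
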