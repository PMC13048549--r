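# Temperature sweeps: fold hairpins and duplexes across a set of
# temperatures and classify how predicted MFE structures differ from a
# reference temperature. Difference detection is exact dot-bracket string
# equality after normalization -- reproducible, unlike visual inspection.

#' Fold records across several temperatures
#'
#' One MFE fold per (record, temperature); deterministic for a fixed
#' engine version.
#'
#' @param set a [MirnaSet-class].
#' @param kind fold the "hairpin" sequences or the "duplex" strand pairs.
#' @param temps temperatures in degrees C (default the *C. elegans*
#'   physiological range 15/20/25 plus the conventional default 37).
#' @param cfg base [EngineConfig-class]; its temperature is overridden by
#'   `temps`.
#' @return data.frame with columns name, kind, temp, dotbracket, energy.
#' @export
temperatureSweep <- function(set, kind = c("duplex", "hairpin"),
                             temps = c(15, 20, 25, 37),
                             cfg = engineConfig()) {
  stopifnot(is(set, "MirnaSet"), length(temps) >= 1L)
  kind <- match.arg(kind)
  if (kind == "hairpin" && any(is.na(set@hairpin))) {
    stop("hairpin sweep needs hairpin sequences for all records")
  }
  do.call(rbind, lapply(temps, function(t) {
    cfgT <- engineConfig(temperature = t, paramSet = cfg@paramSet,
                         dangles = cfg@dangles)
    folds <- if (kind == "hairpin") {
      foldHairpins(stats::setNames(set@hairpin, set@name), cfgT)
    } else {
      cofoldDuplexes(set@seq5p, set@seq3p, cfgT, names = set@name)
    }
    data.frame(name = set@name, kind = kind, temp = t,
               dotbracket = vapply(folds, dotBracket, character(1)),
               energy = vapply(folds, freeEnergy, numeric(1)),
               row.names = NULL)
  }))
}

#' Classify structure differences against a reference temperature
#'
#' For each record and each non-reference temperature, compares the MFE
#' structure with the reference-temperature structure and classifies the
#' difference as terminal, central or both (see [classifyDifference()];
#' for hairpins the terminal zone includes the apical loop). Counts sum to
#' the number of non-identical records.
#'
#' @param sweep data.frame from [temperatureSweep()].
#' @param refTemp reference temperature present in the sweep (default 37,
#'   the conventional folding default).
#' @param terminalMargin see [classifyDifference()].
#' @return list with `records` (per-record categories) and `summary`
#'   (per-temperature counts by category plus percentages of total
#'   records).
#' @export
differenceReport <- function(sweep, refTemp = 37, terminalMargin = 4L) {
  if (!refTemp %in% sweep$temp) stop("refTemp absent from sweep")
  ref <- sweep[sweep$temp == refTemp, ]
  othTemps <- setdiff(unique(sweep$temp), refTemp)
  if (!length(othTemps)) {
    return(list(
      records = data.frame(name = character(0), temp = numeric(0),
                           ref_temp = numeric(0), identical = logical(0),
                           category = character(0)),
      summary = data.frame(temp = numeric(0), ref_temp = numeric(0),
                           n = integer(0), identical = integer(0),
                           terminal = integer(0), central = integer(0),
                           both = integer(0), pct_different = numeric(0))))
  }
  recs <- do.call(rbind, lapply(othTemps, function(t) {
    cur <- sweep[sweep$temp == t, ]
    idx <- match(cur$name, ref$name)
    cat <- vapply(seq_len(nrow(cur)), function(i) {
      dbA <- cur$dotbracket[i]
      dbB <- ref$dotbracket[idx[i]]
      if (dbA == dbB) return("identical")
      # the classification needs only pairing topology; a placeholder
      # sequence of matching shape stands in for the real one
      a <- secondaryStructure(gsub("[()x.]", "A", dbA), dbA)
      b <- secondaryStructure(gsub("[()x.]", "A", dbB), dbB)
      classifyDifference(a, b, terminalMargin)
    }, character(1))
    data.frame(name = cur$name, temp = t, ref_temp = refTemp,
               identical = cat == "identical", category = cat,
               row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(othTemps, function(t) {
    cat <- recs$category[recs$temp == t]
    n <- length(cat)
    data.frame(temp = t, ref_temp = refTemp, n = n,
               identical = sum(cat == "identical"),
               terminal = sum(cat == "terminal"),
               central = sum(cat == "central"),
               both = sum(cat == "both"),
               pct_different = 100 * sum(cat != "identical") / n)
  }))
  list(records = recs, summary = summ)
}

#' Compare MFE duplex structures with their hairpin-embedded structures
#'
#' Folds each hairpin, extracts the duplex structure embedded in the
#' hairpin fold, cofolds the free duplex, and reports whether the two
#' structures differ (exact dot-bracket equality) with the
#' terminal/central classification. Differences mark duplexes that the
#' hairpin precursor holds in a sub-optimal (non-MFE) state.
#'
#' @param set a [MirnaSet-class] with hairpins; arm positions are located
#'   automatically when missing.
#' @param cfg an [EngineConfig-class].
#' @param terminalMargin see [classifyDifference()].
#' @return list with `records` (per-record: category, dG of both duplex
#'   structures) and `pct_different`.
#' @export
compareHairpinVsMfeDuplex <- function(set, cfg = engineConfig(),
                                      terminalMargin = 4L) {
  stopifnot(is(set, "MirnaSet"))
  if (any(is.na(set@hairpin))) stop("all records need hairpin sequences")
  if (!all(IRanges::width(set@pos5p) > 0L)) set <- locateMatureInHairpin(set)
  hp <- foldHairpins(stats::setNames(set@hairpin, set@name), cfg)
  names(hp) <- set@name
  mfe <- cofoldDuplexes(set@seq5p, set@seq3p, cfg, names = set@name)
  names(mfe) <- set@name
  cat <- character(length(set))
  for (i in seq_along(cat)) {
    emb <- extractHairpinDuplex(set[i], hp[[i]])
    cat[i] <- classifyDifference(emb, mfe[[i]], terminalMargin)
  }
  recs <- data.frame(name = set@name, category = cat,
                     identical = cat == "identical",
                     dG_mfe = vapply(mfe, freeEnergy, numeric(1)),
                     row.names = NULL)
  list(records = recs,
       pct_different = 100 * mean(cat != "identical"))
}
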