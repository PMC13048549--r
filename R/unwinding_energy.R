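# Unwinding energies: free-energy cost of forcing the terminal 1-4
# nucleotides of each duplex end to be unpaired, under three regimes.
# ddG = dG(partially unwound) - dG(fully wound reference); positive values
# are the energy cost of opening that end.

# remove every pair with a partner inside `win` from a dot-bracket string
.releaseWindow <- function(dotbracket, pairs, win) {
  ch <- strsplit(dotbracket, "")[[1]]
  core <- which(ch != "&")
  touched <- win[!is.na(pairs[win])]
  rel <- unique(c(touched, pairs[touched]))
  ch[core[rel]] <- "."
  ch[core[win]] <- "."
  paste(ch, collapse = "")
}

#' Compute unwinding-energy profiles for a set of miRNA duplexes
#'
#' For each duplex: one fully wound reference energy plus eight partially
#' unwound energies (2 ends x 4 widths), all at the configured
#' temperature.
#'
#' Regimes: under `mfe_pinned` the duplex is held in its MFE structure and
#' the window pairs are released (the partially unwound structure is fixed,
#' so its energy is a direct structure evaluation); under `hairpin_pinned`
#' the reference is the duplex structure embedded in the hairpin MFE fold;
#' under `ends_only` nothing but the window is constrained and the duplex
#' refolds into the constrained MFE, which can capture progressive
#' unwinding or rearrangement after end opening. For `ends_only` the wound
#' reference is the unconstrained MFE duplex, so ends already open in the
#' MFE get ddG = 0.
#'
#' The non-negativity of ddG under `mfe_pinned`/`ends_only` (the wound
#' reference is the global minimum) is asserted on every record, not just
#' in tests.
#'
#' @param set a [MirnaSet-class].
#' @param regime "mfe_pinned", "hairpin_pinned" or "ends_only".
#' @param cfg an [EngineConfig-class].
#' @param widths window widths (default 1:4).
#' @param hairpinFolds optional pre-computed list of hairpin
#'   [SecondaryStructure-class] objects named by record (computed from
#'   `set` when missing and the regime needs them).
#' @param mfeStructures optional pre-computed list of unconstrained MFE
#'   [DuplexStructure-class] objects, to avoid refolding.
#' @return named list of [UnwindingProfile-class] objects.
#' @export
computeUnwindingProfiles <- function(set, regime = .REGIMES,
                                     cfg = engineConfig(), widths = 1:4,
                                     hairpinFolds = NULL,
                                     mfeStructures = NULL) {
  stopifnot(is(set, "MirnaSet"), length(set) >= 1L)
  regime <- match.arg(regime)
  widths <- as.integer(widths)
  nrec <- length(set)

  if (is.null(mfeStructures)) {
    mfeStructures <- cofoldDuplexes(set@seq5p, set@seq3p, cfg,
                                    names = set@name)
  }
  names(mfeStructures) <- set@name

  if (regime == "hairpin_pinned") {
    if (is.null(hairpinFolds)) {
      if (any(is.na(set@hairpin))) {
        stop("hairpin_pinned regime needs hairpin sequences for all records")
      }
      hairpinFolds <- foldHairpins(stats::setNames(set@hairpin, set@name),
                                   cfg)
      names(hairpinFolds) <- set@name
    }
    located <- all(IRanges::width(set@pos5p) > 0L)
    if (!located) set <- locateMatureInHairpin(set)
    refs <- lapply(seq_len(nrec), function(i) {
      extractHairpinDuplex(set[i], hairpinFolds[[set@name[i]]])
    })
    dGWound <- evalStructures(vapply(refs, slot, character(1), "sequence"),
                              vapply(refs, dotBracket, character(1)), cfg)
  } else {
    refs <- mfeStructures
    dGWound <- vapply(refs, freeEnergy, numeric(1))
  }

  grid <- expand.grid(rec = seq_len(nrec), end = .ENDS, n = widths,
                      stringsAsFactors = FALSE)
  if (regime == "ends_only") {
    cons <- lapply(seq_len(nrow(grid)), function(k) {
      unwindEnd(NULL, refs[[grid$rec[k]]], grid$end[k], grid$n[k])
    })
    folds <- cofoldDuplexes(set@seq5p[grid$rec], set@seq3p[grid$rec], cfg,
                            constraints = cons,
                            names = sprintf("%s|%s|%d", set@name[grid$rec],
                                            grid$end, grid$n))
    dGUn <- vapply(folds, freeEnergy, numeric(1))
  } else {
    unwoundDb <- vapply(seq_len(nrow(grid)), function(k) {
      r <- refs[[grid$rec[k]]]
      win <- endWindow(r, grid$end[k], grid$n[k])
      .releaseWindow(dotBracket(r), pairTable(r), win)
    }, character(1))
    seqs <- vapply(refs, slot, character(1), "sequence")[grid$rec]
    dGUn <- evalStructures(seqs, unwoundDb, cfg)
  }

  profiles <- lapply(seq_len(nrec), function(i) {
    m <- matrix(NA_real_, 2L, length(widths),
                dimnames = list(.ENDS, paste0("n", widths)))
    sel <- grid$rec == i
    m[cbind(match(grid$end[sel], .ENDS), match(grid$n[sel], widths))] <-
      dGUn[sel]
    new("UnwindingProfile", name = set@name[i], regime = regime,
        temperature = cfg@temperature, dGWound = dGWound[i],
        dGUnwound = m, ddG = m - dGWound[i])
  })
  names(profiles) <- set@name

  if (regime %in% c("mfe_pinned", "ends_only")) {
    worst <- min(vapply(profiles, function(p) min(ddG(p)), numeric(1)))
    if (worst < -0.005) {
      stop("internal error: negative unwinding energy (", worst,
           ") under regime ", regime)
    }
  }
  profiles
}

#' @rdname computeUnwindingProfiles
#' @export
computeUnwindingProfile <- function(set, regime = .REGIMES,
                                    cfg = engineConfig(), widths = 1:4,
                                    hairpinFolds = NULL) {
  computeUnwindingProfiles(set, regime, cfg, widths, hairpinFolds)[[1]]
}

#' Thermodynamic asymmetry of a profile at one width
#'
#' ddG(5p end) - ddG(3p end); negative values mean the 5p end is easier
#' to unwind.
#'
#' @param profile an [UnwindingProfile-class].
#' @param n window width.
#' @return numeric, kcal/mol.
#' @export
asymmetry <- function(profile, n) {
  stopifnot(is(profile, "UnwindingProfile"))
  col <- match(paste0("n", n), colnames(profile@ddG))
  if (is.na(col)) stop("profile lacks width ", n)
  unname(profile@ddG["5p_end", col] - profile@ddG["3p_end", col])
}

#' Flatten profiles to the long report table
#'
#' One row per (miRNA, end, width): the supplementary-table analogue
#' emitted as TSV by [writeUnwindingTable()].
#'
#' @param profiles list of [UnwindingProfile-class].
#' @return data.frame with columns name, regime, temperature, end, width,
#'   dG_wound, dG_unwound, ddG.
#' @export
profilesToTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    w <- as.integer(sub("^n", "", colnames(p@ddG)))
    data.frame(name = p@name, regime = p@regime,
               temperature = p@temperature,
               end = rep(.ENDS, times = length(w)),
               width = rep(w, each = 2L),
               dG_wound = round(p@dGWound, 2),
               dG_unwound = round(as.vector(p@dGUnwound), 2),
               ddG = round(as.vector(p@ddG), 2),
               row.names = NULL)
  }))
}

#' Write an unwinding-energy table with provenance header
#'
#' @param tbl data.frame from [profilesToTable()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeUnwindingTable <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unwindR %s | engine ViennaRNA %s | params %s | dangles engine-default",
                     as.character(utils::packageVersion("unwindR")),
                     tryCatch(engineVersion(), error = function(e) "unavailable"),
                     "turner2004"), con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Guide-end vs passenger-end summary statistics
#'
#' The guide end of a duplex is the end containing the guide strand's 5'
#' terminus. For each window width, compares the energies of guide ends
#' and passenger ends with a two-tailed equal-variance t-test. Records
#' with unknown guide arm are excluded (count reported via message).
#'
#' @param tbl long table with columns name, end, width and the value
#'   column (from [profilesToTable()] or [nnEnergyTable()]).
#' @param set a [MirnaSet-class] supplying guide-arm annotations.
#' @param valueCol column holding the per-end energy (default "ddG").
#' @return data.frame with one row per width: n, guide mean/sd, passenger
#'   mean/sd and the t-test p-value.
#' @export
groupStats <- function(tbl, set, valueCol = "ddG") {
  stopifnot(is(set, "MirnaSet"))
  arm <- guideArm(set)
  known <- names(arm)[arm %in% c("5p", "3p")]
  dropped <- sum(!tbl$name %in% known)
  if (dropped > 0) {
    message("groupStats: excluding ", dropped,
            " rows with unknown guide arm")
  }
  tbl <- tbl[tbl$name %in% known, ]
  tbl$guideEnd <- ifelse(arm[tbl$name] == "5p", "5p_end", "3p_end")
  tbl$group <- ifelse(tbl$end == tbl$guideEnd, "guide", "passenger")
  do.call(rbind, lapply(sort(unique(tbl$width)), function(w) {
    g <- tbl[[valueCol]][tbl$width == w & tbl$group == "guide"]
    p <- tbl[[valueCol]][tbl$width == w & tbl$group == "passenger"]
    if (length(g) < 2L || length(p) < 2L) {
      stop("need at least two profiles per group")
    }
    tt <- stats::t.test(g, p, var.equal = TRUE)
    data.frame(width = w, n = length(g),
               guide_mean = mean(g), guide_sd = stats::sd(g),
               passenger_mean = mean(p), passenger_sd = stats::sd(p),
               p_value = tt$p.value)
  }))
}
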