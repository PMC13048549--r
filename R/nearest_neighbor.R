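# Terminal nearest-neighbour stack energies: the comparison method. The
# stability of 1-4 terminal nucleotides of a duplex end is the sum of the
# published stack free energies (37 C parameters) of the first 1-4
# base-pair steps counted inward from that end. Unlike unwinding energies,
# this ignores how opening those nucleotides affects the rest of the
# duplex, and the 37 C parameters are kept as-is (a deliberately
# non-physiological comparison condition for *C. elegans*).

#' Load a nearest-neighbour stack table
#'
#' The packaged default is the Turner 2004 helix stack table (Watson-Crick
#' and GU wobble steps, dG at 37 C in kcal/mol), shipped as a TSV with a
#' provenance header. Steps are keyed "XY/WZ": top strand 5'XY3' stacked
#' on bottom strand read 5'WZ3' (so W pairs Y and Z pairs X). The table
#' contains every oriented reading; reading a stack from either strand's
#' 5'->3' direction gives the same value.
#'
#' @param path TSV with columns `step`, `dG37_kcal_mol`; default the
#'   packaged table.
#' @return named numeric vector of stack energies with a `provenance`
#'   attribute (the header comment).
#' @export
nnTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_stacks_turner2004.tsv",
                        package = "unwindR", mustWork = TRUE)
  }
  hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$dG37_kcal_mol, tab$step)
  wc <- c("AA/UU", "AU/AU", "UA/UA", "CU/AG", "CA/UG", "GU/AC", "GA/UC",
          "CG/CG", "GG/CC", "GC/GC")
  miss <- setdiff(wc, names(vals))
  if (length(miss)) {
    stop("nearest-neighbour table lacks Watson-Crick step(s): ",
         paste(miss, collapse = ", "))
  }
  attr(vals, "provenance") <- paste(sub("^#\\s?", "", hdr), collapse = " ")
  vals
}

#' Terminal nearest-neighbour energy of a duplex end
#'
#' Sums the stack values of the first `n` consecutive base-pair steps
#' counted inward from the given end. A stack exists only between two
#' adjacent base pairs, so an unpaired position (overhang, mismatch or
#' bulge) terminates the run: remaining terms contribute 0. In particular
#' an end whose terminal position is unpaired in the structure scores 0 at
#' n = 1.
#'
#' @param duplex a [DuplexStructure-class].
#' @param end "5p_end" or "3p_end".
#' @param n number of terminal nucleotides considered (1-4).
#' @param table stack table from [nnTable()].
#' @return stack energy sum in kcal/mol (0 or negative for canonical
#'   helices; a missing step -- a non-canonical pinned pair -- is an
#'   error naming the step).
#' @export
terminalNNEnergy <- function(duplex, end = c("5p_end", "3p_end"), n,
                             table = nnTable()) {
  end <- match.arg(end)
  stopifnot(is(duplex, "DuplexStructure"), n >= 1L)
  p <- pairTable(duplex)
  ch <- strsplit(.coreSeq(duplex), "")[[1]]
  lens <- .strandLengths(duplex)
  # walk the strand whose 5' terminus sits at this end, inward
  pos <- if (end == "5p_end") seq_len(min(n + 1L, lens[1])) else
    lens[1] + seq_len(min(n + 1L, lens[2]))
  total <- 0
  for (k in seq_len(min(n, length(pos) - 1L))) {
    i <- pos[k]; i2 <- pos[k + 1L]
    j <- p[i]; j2 <- p[i2]
    # both pairs present and properly stacked (partners adjacent)
    if (is.na(j) || is.na(j2) || j2 != j - 1L) break
    step <- paste0(ch[i], ch[i2], "/", ch[j2], ch[j])
    if (!step %in% names(table)) {
      stop("nearest-neighbour lookup error: step ", step,
           " absent from table")
    }
    total <- total + unname(table[step])
  }
  total
}

#' Terminal NN energies for a set of duplexes, long format
#'
#' @param structures named list of [DuplexStructure-class] (e.g. the MFE
#'   structures the duplexes were folded into).
#' @param widths window widths (default 1:4).
#' @param table stack table from [nnTable()].
#' @return data.frame with columns name, end, width, nn_dG (raw stack sum,
#'   negative = stable) and ddG (the same value negated onto the
#'   unwinding-cost scale where positive = stable, so one set of
#'   twin-drive constants serves all energy methods).
#' @export
nnEnergyTable <- function(structures, widths = 1:4, table = nnTable()) {
  stopifnot(length(structures) >= 1L, !is.null(names(structures)))
  grid <- expand.grid(name = names(structures), end = .ENDS,
                      width = as.integer(widths),
                      stringsAsFactors = FALSE)
  grid$nn_dG <- vapply(seq_len(nrow(grid)), function(k) {
    terminalNNEnergy(structures[[grid$name[k]]], grid$end[k],
                     grid$width[k], table)
  }, numeric(1))
  grid$ddG <- -grid$nn_dG
  grid[order(match(grid$name, names(structures)), grid$width, grid$end), ]
}
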