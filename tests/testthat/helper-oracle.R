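# Independent brute-force oracle: enumerate every canonical, non-crossing
# secondary structure of a two-strand sequence (intra-strand hairpin loops
# of at least 3 nt; no minimum across the strand break), optionally
# filtered by forbidden positions, and score each candidate with the
# fixed-structure evaluator. The minimum over the enumeration is an
# engine-DP-independent reference for the constrained cofold MFE.

canPair <- function(a, b) paste0(a, b) %in%
  c("AU", "UA", "GC", "CG", "GU", "UG")

# all pair sets (lists of i<j pairs) for positions of seq (duplex coords),
# L1 = strand break; returns list of integer matrices (2 x npairs)
enumerateStructures <- function(seq5p, seq3p, forbidden = integer(0)) {
  ch <- strsplit(paste0(seq5p, seq3p), "")[[1]]
  L1 <- nchar(seq5p)
  n <- length(ch)
  okPair <- function(i, j) {
    if (i %in% forbidden || j %in% forbidden) return(FALSE)
    if (!canPair(ch[i], ch[j])) return(FALSE)
    # hairpin-loop minimum applies only within one strand
    if (j <= L1 || i > L1) return(j - i > 3L)
    TRUE
  }
  # recursive enumeration over interval [i, j]
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), nrow = 2)))
    out <- list()
    # i unpaired
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s
    # i paired with k
    if (i >= j) return(out)
    for (k in (i + 1L):j) {
      if (!okPair(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- cbind(c(i, k), a, b)
      }
    }
    out
  }
  rec(1L, n)
}

structuresToDotBrackets <- function(structs, L1, n) {
  vapply(structs, function(m) {
    p <- rep(NA_integer_, n)
    if (ncol(m)) {
      p[m[1, ]] <- m[2, ]
      p[m[2, ]] <- m[1, ]
    }
    pairsToDotBracket(p, strandBreak = L1)
  }, character(1))
}

# minimum energy over the full enumeration, via batched evaluation
bruteForceMfe <- function(seq5p, seq3p, cfg, forbidden = integer(0)) {
  structs <- enumerateStructures(seq5p, seq3p, forbidden)
  dbs <- structuresToDotBrackets(structs, nchar(seq5p),
                                 nchar(seq5p) + nchar(seq3p))
  seqs <- rep(paste0(seq5p, "&", seq3p), length(dbs))
  energies <- evalStructures(seqs, dbs, cfg)
  list(energy = min(energies), dotbracket = dbs[which.min(energies)],
       n_structures = length(dbs))
}
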