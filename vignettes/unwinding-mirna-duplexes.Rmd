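---
title: "Quantifying miRNA duplex end stability by in silico unwinding"
author: "unwindR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA duplex end stability by in silico unwinding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwindR)
```

## The biological problem

Dicer cleavage of a pre-miRNA hairpin releases an approximately 22-nt RNA
duplex with 2-nt 3' overhangs. One strand of that duplex -- the guide --
is retained in Argonaute and directs target silencing; the other -- the
passenger -- is degraded. Which strand wins is governed largely by two
properties of the duplex *ends*: the identity of each strand's 5'-terminal
nucleotide (U > A > G > C) and the relative thermodynamic stability of the
two ends, with Argonaute's MID domain favouring the strand whose 5'
terminus sits at the less stable, easier-to-open end.

"End stability" is usually estimated by summing published
nearest-neighbour stack energies for the terminal base pairs. That has two
shortcomings: the published parameters describe 37&nbsp;°C, outside the
physiological range of many organisms (*C. elegans* lives at
15--25&nbsp;°C), and a terminal stack sum ignores how opening those pairs
affects the stability of everything that remains.

unwindR instead measures an **unwinding energy**. For a duplex end $e$ and
window width $n \in \{1,\dots,4\}$:

$$\Delta\Delta G(e, n) \;=\; \Delta G_{\text{unwound}}(e, n) \;-\;
\Delta G_{\text{wound}}$$

where $\Delta G_{\text{wound}}$ is the free energy of the fully wound
reference duplex and $\Delta G_{\text{unwound}}$ that of the same duplex
with the terminal $n$ nucleotides of end $e$ forced to be unpaired --
on *both* strands, because forbidding only one partner of a base pair
would let the other re-pair. Positive $\Delta\Delta G$ is the energetic
price of opening that end; zero means the window was already open; under
the hairpin-derived reference, negative values flag ends that are
energetically *eager* to unwind once the duplex leaves its precursor.

A duplex end is a two-strand object. The window $W(e,n)$ at the 5p end
takes the first $n$ nucleotides of the 5p strand *plus* the last $n$ of
the 3p strand; the 3p end takes the mirror image. Overhang nucleotides
count as window members: they are terminal nucleotides that happen to be
unpaired already, which is exactly what makes $\Delta\Delta G = 0$ for an
already-open end.

## The three folding regimes and the nearest-neighbour comparison

All folding is delegated to the ViennaRNA tools (RNAcofold for two-strand
folds, RNAfold for hairpins, RNAeval for fixed-structure energies), at a
user-chosen temperature (default 20&nbsp;°C, the standard *C. elegans*
culture temperature).

1. **`mfe_pinned`** -- the reference is the duplex MFE structure. The
   partially unwound state keeps every reference pair except those
   touching the window. Because every position is then constrained
   (pairs pinned, the rest forbidden), exactly one structure satisfies
   the constraints and its energy is obtained by direct evaluation.
2. **`hairpin_pinned`** -- the reference is the duplex structure
   *embedded in the hairpin*: the hairpin is folded, and exactly those
   base pairs with both partners inside the two mature arms are kept.
   Roughly a third of duplexes fold differently on their own than inside
   their hairpin, so this regime asks how the precursor's grip changes
   end stabilities.
3. **`ends_only`** -- only the window is constrained (forbidden to pair)
   and the rest of the duplex refolds freely, capturing progressive
   unwinding or rearrangement triggered by end opening. The wound
   reference is the unconstrained MFE, so ends already open in the MFE
   again score zero.
4. **`nearest_neighbor`** -- the comparison method: the sum of Turner
   2004 stack free energies for the first $n$ base-pair steps counted
   inward from the end, truncated at the first unpaired position. The
   37&nbsp;°C parameters are used as published, deliberately without
   temperature correction, because that is the conventional practice the
   unwinding energies are being compared against.

On the packaged cel-let-7 duplex the numbers look like this:

```{r let7, eval = FALSE}
fa <- readRnaFasta(system.file("extdata", "cel-let-7_duplex.fa",
                               package = "unwindR"))
arms <- splitDuplexRecord(fa[[1]])
let7 <- MirnaSet(names(fa), arms["seq5p"], arms["seq3p"], guideArm = "5p")
computeUnwindingProfile(let7, "mfe_pinned", engineConfig(20))
#> UnwindingProfile 'cel-let-7' [mfe_pinned, 20 C]
#>   dG(wound) = -30.12 kcal/mol
#>   ddG (kcal/mol):
#>         n=1  n=2  n=3  n=4
#> 5p_end 0.74 2.88 4.41 8.26
#> 3p_end 3.16 4.54 6.50 7.41
```

The 5p end costs slightly more to unwind fully (8.26 vs 7.41 kcal/mol at
width 4) but is much cheaper to crack open (0.74 vs 3.16 at width 1).

## Constraint generation

The hard-constraint strings are generated, not hand-curated. Pinning a
reference structure transcribes "(" / ")" for pairs and **"x"** (not ".")
for unpaired positions: a "." would let the engine add new pairs, while
the unwinding energy is defined against the fixed reference. Unwinding an
end marks $W(e,n)$ as "x" on both strands and releases both partners of
any pinned pair touching the window. Nested windows give nested
constraint sets, and no emitted constraint ever contains a dangling
half-pin -- both properties are asserted in the test suite. When a
manually curated constraint corpus is available, `diffConstraints()`
compares generated strings against it and reports disagreements rather
than silently overriding either side.

One engine-facing subtlety: pinned references are scored with RNAeval
(the unique satisfying structure needs no search), and only the
`ends_only` regime performs constrained folding, with forbid-only
constraints. This is both cleaner and avoids exercising the engine's
pair-enforcement code path on cut-point-adjacent pairs, where ViennaRNA
2.7.2 is unreliable.

## The twin-drive strand-selection model

Predictions combine the energy drive and the 5'-nucleotide drive:

$$\ln(5p/3p) \;=\; k\,\Delta\Delta G_{5p-3p} \;+\; N_{5p} - N_{3p}$$

with $\Delta\Delta G_{5p-3p} = \Delta\Delta G(\text{5p end}, n) -
\Delta\Delta G(\text{3p end}, n)$ and $N$ indexed by each strand's
5'-terminal nucleotide. A positive log-ratio predicts the 5p arm as
guide, negative the 3p arm; an exact zero is reported as ambiguous and
scored as incorrect, because calling ties correct would inflate accuracy.
The end energies enter the formula blind to the annotation: guide and
passenger labels are used only at scoring time.

Two conventions needed fixing where the sources are silent:

* **Energy scale.** Unwinding energies are positive-when-stable, while
  raw nearest-neighbour stack sums are negative-when-stable. A single
  constants file cannot serve both scales, so terminal stack sums are
  negated onto the unwinding-cost scale before entering the formula.
* **Constants.** The packaged defaults (`twinDriveParams()`) preserve
  the twin-drive model's published sign structure -- $k < 0$ on the
  unwinding-cost scale, so a harder-to-unwind 5p end disfavours the 5p
  strand, and $N_U > N_A > N_G > N_C$ -- with magnitudes
  ($k = -0.5\ \text{mol/kcal}$; $N$ = 1.2/0.8/0.4/0.0) chosen once as
  package defaults. They are *not* a transcription of the original
  fitted values (which were calibrated on murine miRNAs and are not
  reproduced in the packaged file); the provenance header of the
  constants file says exactly this, and any fitted constants can be
  supplied via `twinDriveParams(path = ...)`.

## The synthetic cohort: what it emulates and what it does not

The paper-scale analyses need a catalogue of annotated duplexes.
`makeCohort()` builds one deterministically from a single seed:
strand lengths 19--24 nt, a reverse-complementary core at GC fraction
0.6, 0--3 internal mismatches and 0--1 single-nucleotide bulges placed
in the core interior, 2-nt 3' overhangs, hairpins assembled as
arm + loop (8--14 nt) + arm with 0--5 nt flanks. Each duplex receives a
planted end asymmetry (three terminal A/U pairs at one end, three G/C
pairs at the other), and the guide arm is annotated as the strand whose
5' terminus sits at the easy end -- except for 22.5% of records, whose
annotation is flipped. That exception rate mirrors the observed share of
real miRNAs (about a fifth to a quarter) whose strand choice defies the
5'-nucleotide and end-stability guidelines.

What passing tests on this cohort do show: the whole pipeline --
constraint generation, constrained folding, energy bookkeeping, the
prediction formula, scoring -- behaves correctly, and the thermodynamic
invariants hold on every record. What they do not show: agreement with
the numerical rates reported for the real *C. elegans* miRBase
catalogue. Synthetic cores are more uniformly stable than real miRNA
duplexes, so temperature-driven refolding (observed for 13.2% of real
duplexes between 20 and 37&nbsp;°C) is rarer here, hairpin-vs-MFE
disagreement (31.1% of real duplexes) is rarer, and the planted
asymmetry is cleaner than real asymmetries, which lifts all four
methods' accuracies at width 1 (roughly 79--80% here vs 58--75% on real
data -- in particular the nearest-neighbour method, whose weakness on
real single-nucleotide windows the clean synthetic asymmetry hides).
The acceptance suite therefore asserts the published reference values
and deliberately leaves red whatever the synthetic conditions cannot
reproduce; supplying the real duplex catalogue and annotations through
`readMirnaSet()` is the supported path to a faithful reproduction.

## Numerical choices and degenerate inputs

* Energies are engine values in kcal/mol, printed to 2 decimals; the
  engine version and parameter set are recorded in every table header
  because printed energies are engine-version sensitive.
* Temperature is the only engine setting the standard runs vary
  (15/20/25/37&nbsp;°C); dangling-end treatment stays at the engine
  default and is recorded, not guessed.
* Window widths are hard-limited to 1--4 (`allowWide` unlocks wider
  windows), and a window must leave a foldable core of at least 5 nt on
  the shorter strand.
* Structure comparison is exact dot-bracket equality; the
  terminal/central split uses a configurable `terminalMargin`
  (default 4 nt, the maximum unwinding window) and, for hairpins,
  counts the terminal-loop positions of either structure as terminal.
  The margin is exposed rather than tuned: the reference
  classifications it approximates were made by visual inspection.
* A duplex region with zero inter-arm pairs in the hairpin
  (a degenerate embedding) warns and yields an all-unpaired reference
  rather than erroring, since downstream energies remain well defined.
* A mature arm that cannot be found in its hairpin, or that is found
  more than once, is an error: a silently guessed placement would
  corrupt the hairpin-derived duplex structure.
* Unwinding energies under the MFE-referenced regimes are asserted
  non-negative inside the pipeline itself (a violation indicates an
  engine or bookkeeping fault, not a data property).

## Problem sizes

The test suite folds cohorts of 5--24 synthetic duplexes for unit
properties and one 190-duplex cohort for the end-to-end checks; the
acceptance script runs the same 190-duplex analysis. A full cohort run
(three regimes, both ends, widths 1--4, plus temperature sweeps) is a
few thousand engine evaluations, batched into a handful of engine
processes, and completes in well under a minute on one CPU.

## Known limitations

* Thermodynamic only: no kinetics or unwinding barriers, no
  protein-bound intermediates.
* No pseudoknots and no partition-function ensembles; the MFE structure
  stands in for the structural ensemble.
* isomiR-aware prediction is out of scope, though any isomiR duplex can
  be analysed by supplying its strands directly.
* The packaged twin-drive constants are defaults with the right
  structure, not a fitted calibration; accuracy numbers on real data
  depend on supplying fitted constants.
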