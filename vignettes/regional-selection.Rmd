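---
title: "Detecting regional and branch-specific selection with regsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting regional and branch-specific selection with regsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsel)
```

## The problem

Gene families that span the sex chromosomes — an X-linked gene, its decayed
Y gametolog, and autosomal retrocopies — raise three linked questions: which
candidate homologs are functional genes rather than pseudogenes; whether
different regions of the protein are under different selective pressure;
and when the duplications and retropositions happened. `regsel` implements
that full analysis path on codon data, together with a simulator that
generates data with exactly the statistical structure the analyses assume,
so every stage can be validated end to end without touching any database.

## Homolog QC

A candidate is called a **pseudogene** when any of these fire: no accurate
splice sites, no EST match, longest ATG-initiated/stop-terminated ORF below
150 aa, or — the retrocopy rule — intronless with no promoter signal.
Unknown evidence (an `NA` flag) never condemns a candidate on its own; a
candidate with no firing rule but incomplete evidence is reported
`unresolved` rather than silently promoted to `gene`. Coverage and identity
against the reference CDS come from a semi-global alignment (match +1,
mismatch −1, gap open −4, gap extend −1, end gaps free — a scheme chosen
for "coverage of a reference" semantics; it is configurable and echoed in
outputs), and tree building keeps candidates with coverage ≥ 40%.
Coordinates are 1-based inclusive throughout. ORF search defaults to the
three forward frames because candidates arrive as oriented transcript
hits; all six frames sit behind a flag.

## The codon model and its scaling

The substitution model is the standard reversible 61-state codon process:
single-nucleotide changes only, target-frequency proportional, ×`kappa`
for transitions, ×`omega` for nonsynonymous changes. `codon_rate_matrix()`
by default rescales the generator so its own mean rate at stationarity is
one.

For the mixture machinery (simulation and branch-site fits) the package
deliberately uses a **shared neutral scaling** instead: all site classes
divide by the one factor that makes the `omega = 1` generator unit-rate,
so a branch length is the expected number of substitutions per codon *at
neutrality*, purifying classes evolve slower, and positively selected
classes evolve faster. This matters. If every class is normalized to unit
rate separately, classes differ only in the *composition* of changes
(synonymous vs nonsynonymous), not in rate; in pilot fits under that
convention `omega2` was close to unidentifiable — estimates pinned at the
box bounds and no site ever reached a high posterior. The shared scaling
restores the rate signal that branch-site inference in the field actually
relies on, and keeping simulator and likelihood on the same convention
makes the recovery experiments coherent.

## Branch-site models A and A-null

Four site classes with (background, foreground) omega pairs
(ω0, ω0), (1, 1), (ω0, ω2), (1, ω2), proportions constrained by
p2a/p0 = p2b/p1, ω0 ∈ (0, 1], ω2 ∈ [1, 50]; the null fixes ω2 = 1. The
likelihood is computed by Felsenstein pruning over compressed site
patterns with per-node scaling. Fits hold `kappa` and branch lengths fixed
at their M0 (single-omega) estimates — re-estimating per fit is possible
but slow and changed nothing in piloting at these sizes. The optimizer is
a bounded quasi-Newton (`nlminb`) on logit/log-transformed parameters,
starting from a mostly purifying mixture with a small mildly positive
class; additional random restarts are available via `n_restarts` (default
1; the recovery experiments below use 3, which was enough to stabilize the
fits — more restarts only added cost).

The per-branch test refers 2ΔlnL to the upper tail of χ²(1 df), the
conventional conservative choice for this boundary problem, with
Bonferroni correction over the number of branches scanned. Site
identification uses empirical-Bayes posteriors for the positive classes —
NEB (MLE plug-in) by default, with a coarse-grid BEB mode that integrates
over the mixture parameters; outputs record which estimator produced them
so the two are never conflated. Sites are reported at the 0.8 threshold
and labeled at 0.9.

## Ka/Ks scan and the regional comparison

Pairwise Ka/Ks uses Nei–Gojobori (1986) counting: per-codon fractional
site counts (mutations to stops count as nonsynonymous sites), difference
counts averaged over all minimal mutational pathways that avoid stop
codons (a codon pair whose every pathway crosses a stop is skipped and
counted), and Jukes–Cantor correction, undefined at p ≥ 3/4. The estimator
is a deliberate, recorded choice: the regional finding rides on the
windowing, not on any particular pairwise estimator, so a simple
transparent one is preferable to emulating a specific tool.

Windows are anchored on nucleotide coordinates (default 300 bp window,
50 bp slide); only codons entirely inside a window count, keeping codon
integrity while honoring the nucleotide slide. Windows with fewer than 10
usable codons are flagged. Undefined ratios (Ks = 0 or saturation) are
excluded from statistics and never capped — a cap exists for plotting
only. The two-region comparison assigns windows by midpoint codon
(boundary default 529, i.e. a 529/530 split interpreted on the trimmed
alignment, since such boundaries exceed any single protein's length) and
uses a two-sided Mann–Whitney U test: a rank test matches the
mean-and-median style of comparison and is robust to the ratio's skew. The
change point is the SSE-optimal two-segment mean split; with 300-bp
windows its resolution is half a window (~50 codons), so recovery is
judged on the median over replicate datasets.

## The simulator

`simulate_codon_alignment()` draws the root from the stationary codon
frequencies and applies exact per-branch transition matrices (symmetric
eigendecomposition of the reversible generator — no Gillespie steps), with
the site's class omega on background branches and the foreground omega on
marked branches. One seeded RNG stream drives class assignment, the root,
and every branch draw, so identical configs give byte-identical FASTA.
`simulate_gametolog_trio()` generates the dated quartet
(Y, (retro, (X, cal))) under per-lineage Jukes–Cantor rates, so the
expected corrected distance between lineages separated T MY is
(γi + γj)·T. `inject_pseudogenization()` adds premature stops and
frameshifting indels for the QC fixtures.

What the simulator does *not* emulate: indel processes with realistic gap
lengths, rate variation beyond the four discrete classes, codon usage
heterogeneity along the sequence, or alignment error. Passing recovery
tests therefore demonstrate correctness of the estimators under the
model's own assumptions, not robustness to real-data misalignment or
composition effects.

## Study conditions used in the checks

All sizes are desk scale, chosen to exercise the statistics properly on
one CPU:

* Neutral calibration: two taxa, total divergence 0.5 substitutions/codon,
  κ = 1 (the NG86 estimator assumes no transition bias), 20,000 codons,
  10 replicates. NG86 carries a small downward offset (~0.05) here because
  mutations to stops count as nonsynonymous sites but the process never
  accepts them; the estimates still sit inside [0.9, 1.1].
* Regional scan: 600 codons, ω = 0.1 (codons 1–300) vs 0.8 (301–600),
  divergence 0.4.
* Branch-site null calibration: 100 datasets, 5 taxa × 150 codons,
  ω0 = 0.2 background. The χ²(1) reference is conservative, so the
  empirical type-I rate sits well below nominal.
* Branch-site recovery: a fixed balanced 10-taxon tree, branches 0.2,
  with a deeply diverged foreground stem of 1.0 substitutions/codon (the
  scale of a stem lineage in deep mammalian comparisons); ω2 = 4 on 10% of
  sites, 300 codons, 10 replicates. On a short foreground branch this
  parameter is only weakly identified — estimates collapse to the ω2 = 1
  boundary or the upper box — which is a property of the model, not of the
  optimizer (checked by comparing likelihoods at the truth against the
  fitted points).
* Dating round trip: 50,000 sites, rates 4–6 × 10⁻⁴ /site/MY,
  retroposition at 54 MY, calibration at 30.4 MY.

## Clock dating

Per-lineage rates are γ = K/(2T) from a dated calibration pair, and the
duplication date is T = K_paralog / (2·mean(γ)) with the **arithmetic
mean** of the per-lineage rates — on the worked example bundled with the
package this mean (0.000485 from rates 0.000401 and 0.000569) reproduces
the printed date of 54.1 MY, which a differently rounded "average rate" of
0.000458 would not (it gives 57.3); outputs carry a note when supplied
averages disagree with the mean of the supplied rates. Distances default
to K2P on the full aligned sequence, with JC69 and synonymous-only (Ks)
variants selectable and recorded; which variant produced any external
worked example is generally not recoverable, so the choice is always
echoed in output.

## Degenerate inputs and numerical choices

In-frame stop codons are an error for selection analyses; a permissive
mode keeps them for pseudogene fixtures, and QC masks them before
modeling. Gap or ambiguous codons are skipped pairwise (Ka/Ks) or treated
as missing data (likelihood). LRT statistics microscopically below zero
(optimizer jitter) are clamped to zero with a warning; genuinely negative
values raise an error. Likelihood pruning rescales partials per pattern,
keeping log-likelihoods finite to thousands of codons. The Gblocks-style
cleaning step is a plain gap-fraction column filter with an auditable
mask — it is explicitly *not* an emulation of Gblocks' block heuristics,
and the mask keeps window coordinates mappable back to original columns.
Collapsing a weakly supported branch adds its length to each child edge,
preserving root-to-tip path lengths.

## Limitations

The branch-site machinery fixes branch lengths at M0 estimates; BEB uses a
coarse grid rather than the full construction; the NG86/JC estimator is
not a maximum-likelihood pairwise dN/dS; real-data scale analyses
(dozens of taxa, thousands of codons) work but are slower than compiled
implementations. None of these affect the structure of the inferences the
package is built to demonstrate.
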