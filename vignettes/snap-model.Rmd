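---
title: "Modelling selection during niche adaptation: methods and design"
author: "snapdup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selection during niche adaptation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapdup)
```

## The process being modelled

Bacterial chromosomes duplicate large segments at remarkably high
spontaneous rates (roughly 1e-5 to 1e-2 per cell per generation, depending
on the flanking repeats). Such duplications are unstable — homologous
recombination collapses them back to single copy — unless selection in a
new niche (a poor nutrient, a sub-inhibitory antibiotic) favours the extra
gene dose. While a duplication is held by selection, the genes it carries
that are *not* under selection accumulate inactivating mutations at normal
per-gene rates (1e-6 to 1e-5 per generation). Once a *different* essential
gene has been lost from each of the two copies, segregation would be
lethal: the duplication is locked in place, and the chromosome is left
with a permanently rearranged gene order. `snapdup` models this cascade
and provides a scanner that looks for its genomic signatures — elevated
read depth and half-frequency variants — in sequencing data.

## The four-strain model

Four cell types are followed: wild type (`WT`), duplication carrier
(`DUP`), duplication with one essential gene inactivated (`D1`), and with
a different essential gene inactivated in each copy (`D2`, terminal).
Five transitions connect them (`transitionArrows()`): duplication
formation, segregation, first inactivation, segregation of the
single-inactivated strain (halved by default, because only the segregant
that keeps the intact copy is viable), and the second, reciprocal
inactivation. `D2` has no outgoing arrows. The default per-generation
rates (`defaultRates()`) sit mid-range inside the experimentally anchored
intervals above: 1e-4 (formation), 1e-2 (segregation), 1e-5 (each
inactivation), 5e-3 (`D1` segregation). The exact per-arrow values any
particular organism realizes are unknown; every arrow is configurable.

## Growth: batch cycles under Monod kinetics

Within a growth cycle, strain $i$ grows at the Monod rate
$\psi_i(R) = V_i \, R/(R+k)$, where $V_i$ is its relative fitness
(wild type = 1) and $k$ the half-saturation constant. The resource $R$ is
shared:

$$\frac{dn_i}{dt} = n_i\,\psi_i(R), \qquad
  \frac{dR}{dt} = -e \sum_i n_i\,\psi_i(R),$$

with conversion efficiency $e$ (resource per cell). The system conserves
$\sum_i n_i + R/e$, so a cycle started with resource $r_0$ grows to
capacity $n_0 + r_0/e$.

**Units and calibration.** All population sizes are absolute cell counts,
not per-mL densities: the serial-transfer protocol is defined by absolute
sizes (1e6 founding cells, 1e10 cells at the end of every cycle, 1e8 per
bottleneck) and no culture volume enters the model anywhere. With
$r_0 = 100$ and $k = 1$ (resource units), the default conversion
efficiency is $e = 10^{-8}$, chosen so that the analytic capacity
$r_0/e$ equals the 1e10 end-of-cycle population the protocol is built
around. $e$ remains user-configurable (`growthParams()`).

**Numerics.** The cycle is integrated with an adaptive, stiff-capable
solver (`deSolve::lsodar`), relative tolerance 1e-8 and absolute
tolerance 1e-3 cells (counts span 1 to 1e10). The Monod rate never
reaches zero in finite time, so "grown to full density" is operationalized
as $R < 10^{-6}\,r_0$, located as a root of the solution rather than a
step boundary. Strains entering a cycle at count 0 stay exactly 0 — the
ODE cannot create cells; only the mutation step can. Failure to exhaust
the resource before `maxTime` raises an error instead of silently
truncating the cycle.

## Serial passages and the mutation step

A run starts from 1e6 wild-type cells and repeats: grow to capacity,
count the cycle's generations as $\log_2$ of the total-population
fold-expansion (about 6.64 per 100-fold dilution, so 1000 generations is
roughly 151 passages), apply the mutation step, record, dilute 100-fold
into fresh medium. The continuous bottleneck (every count divided by the
dilution factor, fractional cells allowed) is the default, matching a
deterministic ODE treatment; binomial thinning is available as
`bottleneckMode = "stochastic"`.

The probability that a lineage of parent strain $i$ produces a cell of
strain $j$ during a cycle is $p_{i>j} = \min(1,\; g_i\,\mu_{i>j})$, with
$g_i$ the parent's generations of growth in that cycle. Two ways of
turning this probability into cells are provided:

* **`mutationMode = "percell"` (default).** $p_{i>j}$ is applied to every
  cell of the parent strain: the number of converted cells is drawn
  $\mathrm{Poisson}(n_i\,p_{i>j})$ (the binomial's Poisson limit;
  $p \ll 1$ at the defaults), capped at $n_i$, and moved from $i$ to $j$
  at the end of the cycle. In expectation this reproduces a per-generation
  Markov chain on strain labels, which is what makes the neutral
  duplication balance converge to the classical
  $\mu_{\mathrm{dup}}/(\mu_{\mathrm{dup}}+\mu_{\mathrm{seg}})$
  stationary fraction (the package tests verify this against an
  independent two-state chain iteration). The Poisson draw ignores the
  jackpot skew of mutations arising early in a cycle (Luria–Delbrück);
  at the population sizes modelled here the fluctuation term is
  negligible next to the mean.
* **`mutationMode = "single"`.** The literal Monte Carlo reading: one
  uniform draw per arrow per passage, and a *single* cell of strain $j$
  seeded when $x < p_{i>j}$, joining the culture after the bottleneck so
  its lineage grows one full cycle before first facing dilution
  (`sampleMutationEvents()`, fixed arrow order, reproducible under a
  seed).

The per-cell mode is the default because the one-cell mode cannot supply
mutants at realistic rates for populations of 1e10 cells: with
$p_{\mathrm{WT>DUP}} \approx 6.6\times10^{-4}$ per passage, a duplication
would ever be seeded in fewer than 10% of 1000-generation runs, and the
double-inactivation cascade would essentially never complete — at odds
with both the steady states and the fixation behaviour the model is
meant to exhibit. Interpreting the appearance probability per cell rather
than per population restores the standard mutation-supply scaling while
keeping the published probability formula intact.

Whether the mutation check is performed once per passage or at every
integrator time step is a genuinely open choice; the per-cycle per-cell
reading adopted here has the advantage of being independent of the
solver's step size.

## Fitness presets and outcomes

`scenarioPreset()` encodes six selective conditions. A–C give the
duplicated classes (`DUP`, `D1`, `D2`) equal fitness, a 5% or a 25%
advantage over wild type. D–F keep the 25% duplication advantage and add
a further 2%, 5% or 10% advantage for `D2` (deleting the unnecessary
duplicate genes), composed multiplicatively
($V_{D2} = 1.25\,(1+s)$). The fitness of `D1` is never specified
separately and is set equal to `DUP`; this is an explicit assumption.

Outcomes (`classifyOutcome()`): `fixed_d2` when the `D2` fraction reaches
the fixation threshold (0.99 by default — the exact cutoff is a package
choice and configurable); `segregated` when the duplication classes
return to zero after having existed; `steady_state` when every strain
fraction moves by less than 1e-3 over the last 10% of records;
`incomplete` otherwise.

Under the defaults, preset A settles into a duplication steady state near
1% (the mutation–segregation balance) with `D2` never exceeding 1e-6 of
the population; presets D–F fix the rearranged gene order within 1000
generations, faster the larger the deletion advantage. These behaviours
are asserted quantitatively in `tests/testthat/test-acceptance.R`, which
runs 100 replicates of preset A and 50 each of D–F; replicate seeds are
derived as base seed $+ i$, so any run is reproducible bit for bit.

## The coverage scanner

The scanner formalizes what is usually done by eye on coverage tracks.
Depth is summarized in sliding windows (1 kb window, 100 bp step by
default; the step is a package choice), window means are divided by the
genome-wide *median* of window means — robust so long as duplicated
windows are a minority — and duplications are called as maximal runs of
windows with ratio at least 1.5, merging runs separated by at most 2 kb
and discarding calls shorter than 5 kb. Calls report the mean ratio of
their windows.

**Boundary estimation.** The edges of the outermost qualifying windows
overestimate a duplication by half a window on each side, and requiring
the ratio to clear the threshold adds an asymmetric half-step bias under
noise. Call edges are therefore refined by linear interpolation of the
window-ratio ramp: the reported edge is where the ramp crosses half-way
between the background (ratio 1) and the call's interior ratio. On a
noise-free 2x block this recovers the true edges exactly; at
negative-binomial dispersion 0.1 the package tests require (and achieve)
95% recovery of 8 kb blocks with both edges within one window step.

**Divergent sites.** Inside called duplications, any pileup site with
depth of at least 30 whose strongest non-reference allele lies at a
fraction between 0.3 and 0.7 is reported — the signature of a variant
carried by one copy of a balanced two-copy duplication. Fractions near 1
(fixed differences from the reference) and near 0 (noise) are excluded by
construction. Allele ties break lexicographically for reproducibility.
All thresholds (ratio 1.5, 5 kb, 2 kb gap, depth 30, band 0.3–0.7) were
chosen once to target the regime of interest — 2x duplications of 8 kb
and up carrying ~50% variants — and are exposed as arguments and CLI
flags.

**Effect classification.** Divergent sites can be annotated against a CDS
annotation and reference sequence: indels are frameshift or in-frame by
length modulo 3; substitutions are translated through their codon
honoring strand and phase (missense labels like `R276C`, synonymous,
nonsense); sites outside every CDS are intergenic. A spliced CDS whose
length is not a multiple of 3 is an error, not a silent guess.

## The synthetic generator

Real short-read data enter the scanner only as per-base depth and
per-site allele counts, so the generator emulates exactly those two
signals: depth drawn per base from a negative binomial with mean
`meanDepth` times local copy number (dispersion 0.05 by default —
sequencing depth is overdispersed relative to Poisson; dispersion 0
recovers Poisson), and allele counts drawn binomially at each divergent
site's true fraction. Two known simplifications: bases are independent
(no read-length autocorrelation, so per-base variance is right but
window-mean variance is slightly optimistic), and no mapping artefacts
(GC bias, repeats, edge effects) are emulated. Passing the recovery tests
therefore demonstrates the caller's statistical behaviour on its stated
noise model, not robustness to alignment pathology.

`fig4cFixture()` packages the single fully specified worked case the
scanner targets: a 200 kb contig with one 21 kb duplication at copy 2,
background calibrated to 77.5x so the divergent site inside it has
expected depth 155x, and a 1 bp thymine insertion at true fraction 0.49
inside an annotated CDS. The same seed reproduces the bundle byte for
byte; `writeSyntheticBundle()` emits FASTA, bedGraph, pileup TSV, GFF3
and truth files, which round-trip losslessly through the package readers.

## Problem sizes and determinism

The test suite runs the simulator at full protocol scale (1e10-cell
cycles; replicate counts of 100 for the neutral preset and 50 per
selective preset) and the scanner over 50 independently seeded 120 kb
contigs; the whole suite completes in a few minutes. The acceptance
script reports the divergent-site percentage as the mean over 25
independently seeded fixture replicates: a single binomial draw at depth
155 has a standard deviation of 4 percentage points, so averaging reports
the caller's recovery rather than one noise realization. Every random
quantity in the package flows from an explicit integer seed; there is no
hidden global-RNG dependence between modules (the coverage and pileup
streams of one spec are offset so they are independent but jointly
reproducible).

## Known limitations

* One duplication lineage per strain class; no multi-copy amplification
  beyond two copies, and at most two essential genes per duplication.
* No death or maintenance terms and no chemostat mode; fitness acts only
  through the Monod maximum rate.
* Mutator phenotypes are representable only by scaling the rate
  constants.
* The scanner does not attempt breakpoint refinement from split or paired
  reads, and deliberately ignores mobile-element copy-number gains, which
  mimic duplications in depth but not in mechanism.
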