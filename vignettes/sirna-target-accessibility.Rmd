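---
title: "Target-site structure, accessibility and thermodynamics for siRNA efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-site structure, accessibility and thermodynamics for siRNA efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siRNAtarget)
```

## The question the package addresses

Small interfering RNAs silence genes by guiding RISC to a complementary
mRNA window, yet a large fraction of designed siRNAs silence poorly.  A
long-standing hypothesis is that the *target's* local secondary structure
— whether the 19–21-nt window sits in a stem, a hairpin loop, a bulge — and
the thermodynamics of guide:target binding explain the difference.
`siRNAtarget` implements the full retrospective-analysis machinery for
that question: it annotates every nucleotide of a folded mRNA with its
structural element class, computes per-site accessibility and free-energy
predictors, and runs the statistical battery comparing very-high-efficacy
(VH, coded 1) against low-efficacy (L, coded 0) siRNAs.  A seeded
synthetic-study generator supplies complete desk-scale datasets with the
same statistical structure, so every stage — including the null result the
analysis is designed to be able to detect — is testable end to end.

## Loop decomposition

A nested secondary structure is held as a pair table `p[i] = j` (1-based,
CT convention).  `annotate()` partitions the positions into eight classes:
paired positions are `stem`; each unpaired position belongs to the loop
closed by its nearest enclosing pair, classified by branch count and side
sizes — no interior branch gives `h_loop` (hairpin); one branch with both
sides occupied gives `int_loop`; one branch with a single one-base side
gives `one_bb`; one branch with a longer one-sided gap gives `b_loop`; two
or more branches give `mb_loop`.  Exterior unpaired bases upstream of the
first helix are `loop5`, downstream of the last helix `loop3`.

The exterior 5′/3′ split between two helices is genuinely underdetermined
by the usual definitions, so the package fixes a deterministic rule: an
inter-helix exterior segment is split at its midpoint, the 5′ half
dangling off the preceding helix counted as `loop3`, the 3′ half as
`loop5`, with an odd middle position going to `loop5`; a completely
unpaired molecule is all `loop5`.  This rule degenerates sensibly (tails
behave as expected) but it is an interpretation, and it is deliberately
5′/3′-asymmetric at odd middles — the mirror-symmetry test in the suite
skips exactly those positions.

```{r annotate-demo}
s <- read_dotbracket("GGAAGGAAACCAACC", "((..((...))..))")
annotate(s)
```

## The folding engine and what it stands in for

Real studies fold full transcripts with an external thermodynamic folder
and import its CT / ss-count output; the package reads those formats
directly and they take precedence in the pipeline.  For self-contained,
exhaustively verifiable analyses the package also ships its own engine: a
Nussinov-style dynamic program that maximizes total hydrogen-bond weight
(GC = 3, AU = 2, GU = 1, minimum hairpin span 3) with a deterministic
traceback (pairing preferred over bifurcation, outermost partner first).
Scores are reported negated so "more negative = more stable" matches the
energy convention.  The hydrogen-bond weighting was chosen over a Turner
free-energy model deliberately: it is verifiable against brute-force
enumeration at small n — the test suite proves optimality for every random
sequence up to 12 nt — and it shares the bond-count semantics of the H-b
accessibility index below.  The engine is a desk-scale stand-in, not a
thermodynamic predictor; conclusions about real transcripts should come
from external folder output.

Suboptimal structures are enumerated without duplicates (Wuchty-style
branch and bound) either within a score window of the optimum, or as the
k best structures found by deepening the window from zero.  Exhaustive
enumeration (`window = Inf`) is capped at 40 nt by default because the
structure count grows exponentially; windowed and k-best enumeration work
at any length under a structure budget (`max_structures`, default 5000 per
enumeration step), and a budget-truncated ensemble always still contains
the optimal fold and is flagged `complete = FALSE`.  Ties between equal
scores are broken lexicographically on the pair table, which makes every
ensemble, and hence every downstream number, bit-reproducible.

## Accessibility: ss-count and the H-b index

Across an ensemble of plausible structures, the ss-count of a position is
the number of structures in which it is single-stranded.  The H-b index of
a target site is the average number of hydrogen bonds the site forms
across the ensemble:

$$\mathrm{Hb} = \sum_{i \in \text{site}} \left(1 - \frac{c_i}{N}\right) b_i,
\qquad b_i = \begin{cases} 3 & \text{base } i \in \{G, C\} \\
2 & \text{otherwise,} \end{cases}$$

with \(c_i\) the ss-count and \(N\) the ensemble size.  Low values mean an
accessible, mostly single-stranded site; `classify_accessibility()`
dichotomizes at the conventional cut-point of 25 (strictly below = accessible).
The per-base weights approximate pair bonds without knowing the partner —
ss-count files do not record it — so a G or C pairing through a GU wobble
is counted with 3 bonds instead of 2; this is documented as an
approximation inherent to the index's construction.  The ensemble size
behind the published ss-count files of folding servers is not knowable in
general, so it is an explicit free parameter (`ensemble_k`, default 20)
whenever the internal engine supplies the ensemble, and the pipeline log
records when that happens.

## Thermodynamic features

Four energies are computed per siRNA, with the signs arranged so the three
published group-mean conventions are mutually consistent:

* `dg_duplex` — nearest-neighbour hybridization energy of the guide:target
  duplex: initiation + stack sum + a terminal penalty per AU/UA end.  The
  packaged parameter set is the standard Watson–Crick RNA/RNA table at
  37 °C (Xia et al. 1998, kcal/mol, `source_tag` `xia1998-wc-37C`); any
  file with the same schema is accepted.  Strands must be exact reverse
  complements (wobble pairs are a folding concept, not a duplex-design
  one).
* `dg_break_target` — the cost of opening the binding site:
  `score(optimal fold) − score(fold with the site forced open)`, always
  ≤ 0 (more negative = less accessible) and exactly 0 when the site is
  already unpaired.  Both folds come from the same engine scale; external
  energies are used only when supplied for both folds.  The
  minimum-energy difference (rather than an ensemble average) is used,
  and noted as a choice.
* `dg_oligo_self` — the guide's own optimal fold score (≤ 0; 0 for a
  structure-free guide).
* `dg_overall = dg_duplex − dg_break_target − dg_oligo_self` — net
  binding after paying both opening costs; never more favourable than
  `dg_duplex`.

GC content is binned into the study's main bins (<25 %, the closed
interval 25–55 %, >55 %) and the half-open decade subgroups [25,35),
[35,45), [45,55), [55,65); boundary handling is configurable through
`gc_binning()`.

## The statistical battery

Efficacy is modelled as 0/1 (L/VH).  `logistic_univariable()` and
`logistic_multivariable()` fit maximum-likelihood logistic regressions and
report odds ratios with 95 % Wald intervals from HC1 sandwich standard
errors — the package's reading of "robust CI", with the classical
model-based interval behind `robust = FALSE`.  Non-convergence and
complete separation stop with an error rather than returning silent
estimates.  One subtlety is specific to fixed-length sites: the eight
element counts then sum to the site length and are exactly collinear with
an intercept, so the joint model is fitted without one (an equivalent,
identified parameterization); with mixed 19–21-nt guides, as in real
tables, the ordinary intercept model applies and `analyze_features()`
chooses automatically.

Group comparisons use Student's unpaired equal-variance t test when both
groups pass Shapiro–Wilk at α = 0.05 and the Mann–Whitney U test
otherwise (the rule is overridable); contingency analyses use Fisher's
exact test (2×2) and Pearson's uncorrected chi-square (R×C); the
one-sample GC-proportion test is the exact binomial, two-sided by the
minimum-likelihood rule.  All of these are delegated to the standard R
implementations behind stable package interfaces; the test suite verifies
them against independent combinatorial oracles (full hypergeometric
enumeration, pairwise-win counting, a likelihood grid).

## The synthetic-study generator

`generate_study()` draws mRNAs as i.i.d. sequences (default GC fraction
0.5, lengths uniform on 50–120 nt — tens of nucleotides so the engine's
enumeration stays exact), places one uniform 19-nt target window per mRNA
(guide = exact reverse complement), computes the configured features on
the folded mRNA, and draws efficacy from
\(\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \beta x))\) where x is a
chosen feature.  Draws are kept until both groups reach `n_per_group`
(default 150/150, the fixed retrospective design), bounded at 10⁶ draws.
With β = 0 the generator is an exact null; with β ≠ 0 it induces a known
log-odds effect whose recovery the suite checks.  When β ≠ 0 and no
intercept is given, β₀ is auto-centred at −β times the pilot mean of the
effect feature, so the marginal prevalence is near ½; sampling to fixed
group sizes is case-control sampling, which biases only the intercept,
never the slope, so effect recovery is unaffected.  All randomness flows
through R's seeded Mersenne-Twister stream; the same configuration is
bit-reproducible.

For large simulation studies `features =` restricts computation to the
columns actually used (the computed values are identical to the full
pipeline's); the calibration runs in the test suite and acceptance script
use this with `n_unpaired`.

What the generator does *not* emulate: real transcript length and
composition biases, Turner-model energetics, RNA-binding-protein
occlusion, and inter-site correlation within one transcript.  Passing
tests therefore demonstrate that the pipeline measures what it claims on
data with known structure — not that any biological claim about real
siRNA datasets is reproduced.

## Numerical and design choices

* Coordinates are 1-based, inclusive; T is silently normalized to U;
  any other non-ACGU character (including N) is an error because pairing
  legality, GC% and bond weights all need unambiguous bases.
* Efficacy classes from percent: [90,100] VH, [70,90) H, [50,70) M,
  [0,50) L — deterministic at the published boundary overlaps.
* Multiple exact target hits: the 5′-most wins, with a warning listing
  all hits.  No mismatch tolerance, by design.
* Unpaired runs are truncated at site boundaries (the analysis counts
  bases *in* the site).
* Only the ensemble's optimal structure is annotated for element counts;
  the ensemble feeds the H-b index alone.  This mirrors aligning a guide
  to "the" predicted structure while measuring accessibility across many.
* The element-distribution table counts siRNAs per (element class,
  base-count) cell including the zero row, so one siRNA appears in every
  class column; the regression predictor is the number of targeted bases
  per element by default, with the alternative unit — distinct element
  instances touched — available as `element_instances_in_site()`.
* Logistic convergence: IRLS, tolerance 1e-8, 100 iterations; separation
  detected both by coefficient divergence (|β| > 15) and by perfectly
  split fitted probabilities.
* Problem sizes in the shipped tests: oracle equivalences use 500 random
  sequences of length ≤ 12 with exhaustive enumeration; calibration uses
  1000 seeded replicates of the full 150/150 design; the acceptance
  script re-runs one full study plus 300 + 300 calibration replicates.
  These sizes were chosen so the whole suite verifies every claim at
  desk scale.

## Known limitations

The engine's score is not a free energy; its ΔG°-named features are in
weight units and comparable only within one run.  Pseudoknots are
rejected.  The H-b index inherits the partner-blind bond weights of its
ss-count construction.  Re-analyses of real transcripts should supply
external CT and ss-count files, and even then numerical agreement with any
specific published table depends on the exact folder version and settings,
which are rarely fully specified.
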