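---
title: "Deriving caspase consensus motifs from neo-N-terminal degradomes"
author: "degradomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving caspase consensus motifs from neo-N-terminal degradomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomics)
```

## The problem

Caspases cleave their substrates almost exclusively C-terminal to an
aspartate (P1 = D), and their preference is read mainly at the four
non-prime subsites P4–P1. In a neo-N-terminomics experiment, each peptide
whose preceding residue in the parent protein is aspartate witnesses one
cleavage event (a D↓X site). Given a replicate-structured table of such
events over a proteome, three questions arise:

1. **Which subsite residues are preferred?** For each of the 60
   single-residue motifs (20 residues × subsites P2, P3, P4, with P1
   fixed to D — e.g. `GD`, `KXD`, `IXXD`), is the motif more or less
   frequent among cleavage sites than among all aspartates in the cleaved
   substrates?
2. **Are motifs associated with a functional class?** Do substrates
   carrying a given annotation (here the GO molecular-function term
   *structural constituent of cytoskeleton*, SCoC) get cleaved at a motif
   more often than their overall cleavage load predicts?
3. **Which motif pairs make good consensus candidates?** Among the 1,770
   unordered motif pairs, which combine high specificity for the flagged
   class with high coverage of its cleavage events?

## Subsite enrichment model

For each motif the test contrasts two frequencies as a hypergeometric
draw: `k/n`, the motif's share of cleavage events, against `K/N`, its
share of aspartates in the sequences of cleaved substrates. All four
counts are replicate-weighted — a substrate cleaved in *r* replicates
contributes its sequence counts *r* times, and each event counts once per
replicate in which it was observed — so substrates seen repeatedly
dominate both the foreground and the background coherently.

P-values use the **mid-p** convention, `P(X > k) + 0.5·P(X = k)`,
which assigns half the observed outcome's mass to the tail and removes
much of the conservatism of exact discrete tests. Two-sided values double
the smaller one-sided mid-p, capped at 1. Evaluation is exact
(log-space hypergeometric PMF/CDF); no normal approximation is used
anywhere, because the interesting tails reach below 10⁻⁶.

Multiplicity is handled two ways, as is conventional for this design:
a **two-stage linear step-up FDR** (a first linear step-up pass at level
α/(1+α) estimates the number of true nulls m₀; a second pass sharpens the
adjustment by m₀/m), and a Bonferroni family-wise cutoff α/m for the
strictest claims. Because m₀ ≤ m, the adaptive q-values can undershoot
plain Benjamini–Hochberg values; this is intended.

Three numerical conventions matter and are fixed package-wide:

* Only aspartates at position ≥ 5 (a full P4 window) enter events and
  backgrounds, so all 60 tests share one `N`. C-terminal windows are
  padded with `X`, but only the non-prime half is ever used in
  statistics.
* Residues outside the 20-letter alphabet (X, U, B, Z) at a subsite
  match no motif but still count toward `N`: they are aspartate contexts
  of unknown residue, not missing data.
* "Proteins of the same family with identical P4–P4′ context" have no
  computable family definition, so the collapse rule merges events from
  *different* accessions with identical context windows within a
  replicate (attributed to the lexicographically smallest accession, with
  a merge log). This is a conservative superset of true family
  duplicates and can be disabled.

## The Monte Carlo protein-cleavage null

Annotation association cannot be read off term enrichment alone, because
flagged substrates tend to carry more cleavage sites per protein (the
generator emulates this; the package's Mann–Whitney comparison measures
it), and any single site qualifies a substrate as "cleaved at the
motif". The null model therefore asks: *given* each flagged substrate's
observed per-replicate site count S, and the replicate's overall motif
frequency k/n, how many flagged substrates would be cleaved at the motif
at least once by chance?

Treating the substrate's S sites as a without-replacement draw from the
replicate's n site slots, of which k carry the motif,

Pr(substrate cleaved at motif) = 1 − Π_{i=0}^{S−1} (1 − k/(n−i))
                               = 1 − C(n−k, S)/C(n, S),

with each factor clamped to [0, 1] when S approaches n. The observed
statistic is the **protein-cleavage count**: flagged substrates counted
once per replicate in which they have ≥ 1 matching event (for pairs,
either member counts, at-least-once semantics). Simulation draws one
Bernoulli per (flagged substrate, replicate) and sums; identical
probabilities are grouped into binomial draws, which is distributionally
exact and faster. The simulated distribution yields an empirical
two-sided mid-p (doubling convention, as above) and a fold enrichment,
observed / simulated mean. When the observed count lies beyond the
simulated support the resolution bound 1/n_sims is reported and flagged
as a maximum estimate. Screens attach per-family FDR (each screen —
60 motifs, 1,770 pairs, or a small consensus set — is its own family)
and are reproducible: each target uses a fixed seed offset, so a screen
is deterministic given its seed.

Defaults: `n_sims = 1e5` per target for final analyses; the package's
own tests use 2×10³–2×10⁴ per target for screens and 10⁶ for the exact
Poisson-binomial comparison, sizes chosen so the full suite exercises
every stage at desk scale.

## Candidate pair selection

Each pair is summarised by its fold enrichment and its *coverage* — the
proportion of all observed flagged protein-cleavages it accounts for.
Selection walks the pairs by fold, descending, admitting a pair only if
its coverage strictly exceeds the best so far; the result is exactly the
strict Pareto frontier of (fold, coverage). Two gates precede the walk:

* **Eligibility.** Pairs combining a rare P4 motif (default exclusion
  list `IXXD`, `CXXD`, `GXXD`) with a partner observed in ≤ 1 flagged
  protein-cleavage are excluded: with an expected count near zero, a
  single chance observation produces a spuriously enormous fold. The
  list is configurable and the gate can be disabled.
* **Significance.** Only pairs below the Bonferroni cutoff over the pair
  family (α/1770 ≈ 2.8×10⁻⁵ at α = 0.05) are considered. The gate is
  applied *before* the stepwise walk so that the output equals the
  Pareto frontier of the significant, eligible set — applying it
  afterwards could silently drop a frontier point that a non-significant
  point had shadowed.

Ties in coverage do not extend the candidate list ("strictly higher"
is strict), so among equal-coverage pairs only the highest-fold one
survives.

## The synthetic degradome generator

Every stage is testable without external data through a generator whose
defaults emulate a three-replicate neo-N-terminomics experiment:
800 substrate proteins with i.i.d. UniProt-like residue composition
(aspartate ≈ 5.5%), 1,000 events per replicate sampled without
replacement — matching the without-replacement structure of the null
model — giving roughly 1.2 observed sites per cleaved substrate per
replicate, the density typical of published degradomes (a few hundred
substrates, one to two sites each per replicate). Ten percent of
substrates are flagged as SCoC-like, and flagged substrates get a 3×
per-site weight multiplier, reproducing the heavier per-protein site
counts seen for cytoskeletal substrates. Motif preferences are
controlled by multiplicative subsite weights (e.g. `c(GD = 3)`), with an
optional extra boost applied only in flagged substrates; the manifest
records every planted preference. Evidence rows emit the P1′-onward
peptide fragment with its start coordinate, so tests exercise the
extraction path; the pre-derived event table is also returned as a
direct-site shortcut.

What the generator does **not** emulate: mass-spectral detectability
bias, missed cleavages, protein abundance, shared peptides between
paralogs, and real protein composition (residues are i.i.d.). Passing
calibration and recovery tests therefore show the statistics behave
correctly under the model's own assumptions — not that those
assumptions hold for any particular instrument or tissue.

```{r quick-example}
x <- generate_degradome(synthetic_config(seed = 42, n_proteins = 120,
                                         events_per_replicate = 250,
                                         subsite_weights = c(GD = 3)))
ct <- consensus_table(x$events, x$proteome)
summary(ct)
```

## Design choices where the design was open

* **Two-sided rule.** Whether published subsite p-values doubled the
  smaller tail or summed smaller-probability outcomes is not stated
  in the sources this design follows; doubling is the common mid-p
  convention, behaves correctly for fold ≈ 1 motifs (p near 1), and is
  used for both the hypergeometric and the empirical Monte Carlo tests.
* **One-sided convention fixed by the meta-tests.** `P(X > k) +
  0.5·P(X = k)` reproduces the three analytic overlap values this
  package freezes in its tests (0.025; 0.044; 9.3×10⁻³), which pins the
  convention exactly.
* **Background edge rule.** Excluding aspartates at positions 1–4 from
  both events and backgrounds (rather than counting them with truncated
  windows) keeps one shared background for all 60 tests; at realistic
  protein lengths the difference is a fraction of a percent of `N`.
* **Background K from the definition, not the derivation.** The
  variable-definition table this analysis follows carries an apparent
  typographical duplication in the derivation of `K` (identical to
  `k`); `K` is implemented from its definition — motif occurrences
  before aspartates in cleaved substrate sequences, replicate-weighted
  like `N`.
* **Annotation stage.** Term enrichment takes a user-supplied
  accession→(category, term) table and the substrate set as background;
  upper-tail (enrichment-only) mid-p matches the semantics of standard
  annotation tools, while the consensus table stays two-tailed because
  de-enrichment is informative there. Manual curation (e.g. adding
  homolog-derived terms) is done by editing the table.

## Known limitations

* **Fold instability for rare targets.** Fold enrichment is
  observed/expected; when the expected count is ~2 or less, one or two
  chance observations yield folds of 3–10. In simulation, a genuinely
  boosted motif (fold ~1.3–1.6 after saturation) is therefore routinely
  out-folded by some rare motif's noise spike in a 60-target screen.
  Rank hits by q-value, or gate folds on a minimum observed count (as
  the pair eligibility filter does); raw fold ordering alone is not a
  reliable detector.
* **Saturation.** The protein-cleavage statistic is at-least-once per
  replicate; as per-substrate site counts grow, both observed and
  expected probabilities approach 1 and folds compress toward 1. Strong
  preferences can look modest in dense degradomes.
* **Composition heterogeneity.** The null model uses one motif
  frequency per replicate, but each substrate's candidate sites have
  fixed residue composition, which persists across replicates. This
  mildly inflates the tails of the null screen on heterogeneous
  substrate pools, so screen-level q-values should be read as
  approximate; the package's calibration test measures this effect at
  the default generator scale.
* The aspartate-accessibility assumption — every D in a cleaved
  substrate equally available — ignores topology and solvent
  accessibility; transmembrane substrates are most affected.

## Reproducibility

All randomness flows from explicit integer seeds: the generator is
byte-identical given its seed, each screen target gets a deterministic
seed offset, and pipeline stages write run manifests (hashed inputs,
parameters, package version) sufficient to re-execute a run exactly.
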