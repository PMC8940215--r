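# degradomics

Identification of caspase cleavage-site consensus motifs from
neo-N-terminomics (degradomics) data.

Caspases cleave C-terminal to aspartate (P1 = D), reading specificity
mainly at subsites P4–P2. Given a proteome (FASTA), replicate-structured
peptide evidence, and an annotation map, this package:

* derives **D↓X cleavage events** with their P4–P4′ context windows,
  collapsing family-duplicate sites;
* tests each of the **60 single-residue subsite motifs** (`GD` = G at
  P2, `KXD` = K at P3, `IXXD` = I at P4) with a replicate-weighted,
  two-tailed **mid-p hypergeometric test** — the motif's frequency among
  cleavage sites, k/n, against its frequency among all aspartates in
  cleaved substrates, K/N — under two-stage linear step-up FDR control
  and a Bonferroni family-wise cutoff;
* tests **motif ↔ annotation association** (e.g. the GO term
  *structural constituent of cytoskeleton*) with a Monte Carlo
  protein-cleavage null: each flagged substrate with S observed sites in
  a replicate is cleaved at a motif with probability
  `1 − ∏_{i=0}^{S−1} (1 − k/(n−i)) = 1 − C(n−k,S)/C(n,S)`,
  and the simulated protein-cleavage totals are compared with the
  observed count (empirical mid-p, fold = observed/expected);
* selects **candidate consensus motif pairs** on the strict Pareto
  frontier of specificity (fold enrichment) versus coverage (proportion
  of flagged protein-cleavages), after eligibility and family-wise
  significance gates;
* runs generic **annotation-term enrichment** (upper-tail mid-p,
  per-category FDR) and the per-protein site-count Mann–Whitney
  comparison;
* ships a **synthetic degradome generator** with known ground truth, so
  every stage is calibrated and tested without downloads.

## Worked example

Plant a GD preference (3× at all sites) plus an extra GD boost (4×) in
an annotation-flagged substrate subset, then recover both:

```r
library(degradomics)

x <- generate_degradome(synthetic_config(seed = 42,
        subsite_weights = c(GD = 3), scoc_motif_boost = c(GD = 4)))

ct <- consensus_table(x$events, x$proteome)
summary(ct)
#> Events: 3000  Replicates: 3
#> Enriched motifs (q < 0.05 ): GD
#> De-enriched motifs: LD, ED, TD, KD, MXD, YD, QD
#> Consensus sequence: XXGD

scr <- mc_screen(x$events, x$truth$flagged, c("GD", "RD", "IXXD"),
                 n_sims = 1e4, seed = 1)
scr
#> Monte Carlo screen: 3 target(s), 79 flagged substrate(s)
#> 2 target(s) at q < 0.05
#>
#>   target observed_C expected_mean fold  p_mid  q_fdr
#> 1     GD        159        131.68 1.21 0.0001 0.0002
#> 2     RD         26         36.55 0.71 0.0443 0.0443
#> 3   IXXD         44         42.35 1.04 0.7620 0.5080

sites_per_protein_comparison(x$events, x$truth$flagged)$p
#> [1] 4.88e-66
```

The consensus table finds exactly the planted subsite preference
(`XXGD`); the Monte Carlo screen shows that flagged substrates are
cleaved at GD above what their (deliberately inflated) site counts
predict — 159 flagged protein-cleavages observed against 131.7 expected
(fold 1.21, q = 2×10⁻⁴) — while RD and IXXD behave as chance. Note the
fold compression: protein-cleavages are counted at-least-once per
replicate, so strong per-site preferences yield modest-looking folds in
dense degradomes (see the methods vignette).

Analytic consensus-overlap meta-tests are one call:

```r
consensus_overlap_test(population = 60, consensus_size = 3,
                       drawn = 1, observed_overlap = 1)
#> [1] 0.025
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/degradomics.R simulate --out run --seed 5
Rscript inst/scripts/degradomics.R consensus --fasta run/proteome.fasta \
    --sites run/sites.tsv --out run
Rscript inst/scripts/degradomics.R meta-test 60 3 1 1
```

Every stage writes TSV/JSON artifacts plus a run manifest (hashed
inputs, seed, parameters) sufficient to reproduce the run exactly.

## Documentation

See the methods vignette (`vignettes/degradome-consensus.Rmd`) for the
statistical model, the null-model assumptions, every tunable parameter
with its default and rationale, and known limitations.
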