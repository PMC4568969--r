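---
title: "Co-expression-guided motif enrichment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression-guided motif enrichment: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmotif)
```

## The scientific question

When a gene of interest — the running example in this package is the
mitochondrial deacetylase gene *Sirt3*, induced by dietary restriction (DR)
— is upregulated under some condition but its transcriptional regulator is
unknown, a single promoter rarely carries enough signal to identify the
factor. The pipeline implemented here rests on three assumptions:

1. genes whose expression tracks the seed gene across samples are candidates
   for shared regulation;
2. a shared regulator leaves a footprint: its binding motif is
   statistically enriched in the regulatory sequence of the co-expressed
   genes relative to the rest of the genome;
3. functional binding sites are preferentially conserved across species, so
   conservation-weighting sharpens the footprint.

Each stage is an ordinary, well-understood statistical operation; the value
of the pipeline is the disciplined composition, and the synthetic-data
module exists so the composition can be tested end to end with known truth.

## Stage 1: induction screen and co-expression sets

The seed gene is screened for induction between two conditions with a
classic pooled-variance two-tailed Student t-test, probe by probe (on
multi-probe platforms each probe is tested individually rather than
collapsed first). We use the pooled-variance flavor rather than Welch
because the screened designs are small balanced two-group comparisons where
the classic test is the standard choice. Degenerate zero-variance probes
are given conventional p-values (1 for equal means, 0 with a warning
otherwise) instead of erroring, so screens over thousands of probes never
stop on a flat probe.

Correlation ranking uses Pearson's r between the seed probe and every other
probe **across all samples**. Computing within condition groups and
averaging was a design option; we correlate across all samples because the
induction itself is part of the co-expression signal we want to capture,
and stratifying would remove it.

Probe handling follows the Affymetrix suffix convention: probe-set
identifiers containing `_s_` (shared) or `_x_` (cross-hybridizing) are less
specific and are removed before ranking — *except* when a gene would be
left with no probes at all, in which case its suffixed probes are retained.
The matched substrings are configurable (`filter_probes(patterns = ...)`).
Per gene, correlations of surviving probes are arithmetically averaged.

The top-N gene set consists of the seed gene plus the N−1 most-correlated
eligible genes; the seed counts toward N (so a "25-gene set" has the seed
and 24 correlates). This was genuinely ambiguous — a list of N correlates
plus the seed is equally defensible — and we chose seed-within-N so that
the set size named in outputs equals the number of genes analyzed.
Boundary ties in mean r are broken lexicographically by gene symbol purely
for reproducibility. The "mitochondrial" track restricts eligibility to a
supplied annotation list (a MitoCarta-style inventory); the seed gene is
exempt from the eligibility filter. GO over-representation of a set uses
the upper-tail hypergeometric test against a supplied universe with
Benjamini–Hochberg correction.

## Stage 2: motif models and conservation-weighted scoring

Motifs are JASPAR-style position frequency matrices converted to log-odds
(bits) with a pseudocount distributed proportionally to the background:

$$\mathrm{logodds}_{b,i} = \log_2 \frac{(c_{b,i} + p \cdot \pi_b) / (\sum_b c_{b,i} + p)}{\pi_b}$$

Defaults: pseudocount p = 0.8 (a common JASPAR convention) and uniform
background π = 0.25 per base, both configurable. A uniform-count motif
under uniform background scores identically zero; increasing the
pseudocount can only shrink the maximum score toward background.

Promoter windows are extracted around the TSS with 0-based, half-open
coordinates from BED-like input: 10 kb upstream to 10 kb downstream by
default (a 20 kb window), reverse-complemented for minus-strand genes so
the returned sequence is always 5'→3' relative to the gene. Windows are
clipped at contig ends with a warning.

Scanning scores every offset on both strands; the minus strand is scored
by scanning with the reverse-complemented weight matrix, which is exactly
equivalent to scoring the reverse-complemented L-mer. Offsets overlapping
an N score −∞ and are never reported.

Conservation enters as a per-position weight in [0, 1]: the fraction of
supplied pre-aligned ortholog sequences matching the window base (gaps and
N count as mismatches). We consume pre-aligned ortholog sequences rather
than whole-genome alignments so the pipeline runs from plain FASTA; with
no orthologs the profile is all ones and scoring is unweighted, keeping
the pipeline runnable without any conservation data.

The gene-level statistic is the **best conservation-weighted site**: the
maximum over offsets and strands of (site log-odds × mean weight over the
site span), with 0 when no site scores positive. Published
phylogeny-weighted scanners use richer likelihood models over a species
tree; their internals are not reproducible from the literature we built
against, so we chose the simplest aggregate consistent with downstream AUC
ranking and expose `aggregate = "sum_top_k"` as a sensitivity check. This
is a documented stand-in, not a claim of score-compatibility with those
programs.

## Stage 3: AUC enrichment, permutation null, q-values

Per motif, enrichment of a gene set is the area under the ROC curve for
set members' scores against the rest of the scored universe, computed by
the midrank (Mann–Whitney) formula so ties get half credit:
AUC = P(fg > bg) + ½·P(fg = bg). The null distribution is built from
random gene sets of identical size drawn uniformly without replacement
from the universe — the natural exchangeability null when the only claim
is "these particular genes score higher" — and the p-value uses the
add-one estimator p = (1 + #{null AUC ≥ observed}) / (n_perm + 1), which
never returns 0 and is never below 1/(n_perm+1). n_perm defaults to
1,000 and a seed is mandatory, making every p-value bit-reproducible.
Because foreground and background partition the universe, permutation
AUCs are computed as indexed sums over precomputed universe-wide midranks;
this is an algebraic identity with the definitional formula, not an
approximation (tests verify both routes agree).

Multiple testing is corrected with Benjamini–Hochberg **across the motif
family within each analysis** (each gene set), and tiers are marked at
q < 0.05 and q < 0.01. Whether to pool q-values across analyses was an
open choice; per-analysis correction keeps each heat-map column a
self-contained family of 130-odd tests and matches how the tiers are read.
BH was chosen over π₀-estimating q-value methods for determinism. The
summary table orders motifs by their maximum AUC across however many
analyses were run (the study configuration is 2 tracks × 3 set sizes),
ties broken by motif id, top 10 retained. Cross-analysis overlaps
(which motifs are significant at every set size; optionally, which also
appear in an independent promoter scan) are plain set algebra, reported
per combination.

## Stage 4: promoter dissection and mutant design

Single-promoter work uses exact IUPAC consensus matching (an N in the
sequence never matches), on both strands of the one forward sequence — for
a bidirectional promoter the two gene orientations are a reporting
convention, not separate scans. Tandem pairs are co-oriented,
non-overlapping site pairs with spacer ≤ 50 bp by default; the threshold
is generous because the motivating tandem (two 6-bp ETS cores, 14-bp
spacer, 26-bp span) sits well inside it. Mutant design covers the two
classic reporter manipulations: a fixed-length substitution applied at
every site (the CCGGAA→CCTTAA double transversion changes exactly 2 bases
per site and ablates the consensus; minus-strand sites are edited through
their own strand), and deletion of a tandem pair's full span (26 bp in the
motivating case). Both re-scan the product and report before/after site
counts. For mutation purposes the "site" is the 6-bp core consensus; full
PWM-length sites matter only in scanning. The conservation report for
aligned multi-species promoter sequences computes per-column identity
against a reference and slides a window (default 26 bp) to report the
best-conserved region, leftmost on ties.

## Stage 5: assay reductions

Validation assays reduce with the field-standard formulas. qPCR:
ΔCt = Ct(gene) − Ct(reference); ΔΔCt against the control condition;
fold = 2^(−ΔΔCt). The quantification model (efficiency fixed at 2 versus a
standard curve) is a documented default, not an inference. ChIP: per
precipitation, target percent input / background-gene percent input; mean
± SE (sample SD/√n) across precipitations. All significance tests are
two-tailed pooled-variance Student t.

## The synthetic generator: what it emulates and what it does not

`synthetic_config()` defines the benchmark conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | gene universe (desk-scale stand-in for an array) |
| `n_samples_per_condition` | 10 | control and "DR" group sizes |
| `induction_effect` | 1 log2 unit | seed-gene shift under DR (two-fold) |
| `correlated_block_size` | 24 | genes tracking the seed (seed + block = 25) |
| `target_correlation` | 0.9 | population r of block genes to the seed |
| `noise_sd` | 0.5 | residual log2 intensity SD |
| `dup_probe_fraction` | 0.2 | genes given an `_s_`/`_x_` decoy probe |
| `promoter_length` | 2,000 bp | promoter per gene (configurable to 20 kb) |
| `p_site_fg` / `p_site_bg` | 0.8 / 0.1 | site-planting probability, block∪seed vs rest |
| `n_species` | 4 | ortholog sequences per promoter |
| `substitution_rate` | 0.2 | ortholog divergence outside planted sites |

Block genes are generated as ρ·z + √(1−ρ²)·ε around the standardized
realized seed profile z, so their expected empirical correlation is ρ to
first order (verified by a moment check in the tests). Promoters are
i.i.d. background at the configured GC content with at most one exact
consensus site planted per promoter at a uniform offset and strand —
one-site-max keeps the truth accounting unambiguous. The default planted
motif is a synthetic, sharply peaked 10-column PFM whose consensus
`ACCGGAAGTG` carries the ETS/NRF-2 core CCGGAA; its counts are constructed
(17-vs-1 per column), not taken from a database. Decoy motifs are random
sharp consensus PFMs of the same length. Orthologs are the promoter with
i.i.d. substitutions, at a reduced (default zero) rate inside planted
sites, which makes planted sites the best-conserved regions by
construction.

Generators are seed-deterministic: the expression, promoter, and ortholog
stages use fixed small offsets (+0, +1, +2) from `rng_seed` so each has an
independent, reproducible stream; the benchmark's decoys and enrichment
permutations use +3 and +4.

What the generator does **not** emulate: realistic microarray noise
(GC-content bias, probe affinity effects, heavy tails), correlated
background gene modules, variable-strength or degenerate planted sites,
indels or tree-structured evolution in orthologs, and chance homology
between decoys and background composition. Passing the planted-signal
benchmark therefore demonstrates that the pipeline's statistics are wired
correctly and calibrated under exchangeability — not that the pipeline
will rank the true regulator first on any real dataset, where signal is
weaker and background structure richer.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the default scale
above: a 200-gene universe, 25-gene sets, 2-kb promoters, a 10-motif
family (1 planted + 9 decoys), 1,000 permutations per enrichment test
(200 in the 5,000-test null-calibration grid), 20 replicates for recovery
rates. These sizes were chosen so a full run completes in about a minute
on one core while keeping every statistical check comfortably powered
(the planted-motif AUC sits ≈5 null SDs above 0.5 at this scale).

Numerical conventions collected in one place: 0-based half-open
coordinates everywhere; log base 2; ties in AUC handled by midranks; ties
in rankings broken lexicographically; zero-variance probes excluded from
correlation with a warning; the seed probe having zero variance is an
error; permutation p-values never 0 by the add-one rule; exhaustive
enumeration mode reports the plain proportion (the observed set is one of
the enumerated subsets); N bases never match and never score.

## Known limitations

- The gene-level max-site statistic discards multi-site additivity unless
  `sum_top_k` is requested; weak homotypic clusters can be under-ranked.
- Conservation weighting assumes the supplied orthologs are *aligned* to
  the window; no alignment is performed internally.
- BH within each analysis does not account for correlation between
  similar motifs (ETS-family members share near-identical cores); the
  overlap report surfaces this rather than modeling it.
- The permutation null conditions on the score vector; it does not model
  uncertainty in the scores themselves.
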