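# coexmotif

Co-expression-guided transcription factor motif enrichment.

## What problem this solves

When a gene is induced under some condition (the motivating case: the
mitochondrial deacetylase gene *Sirt3* under dietary restriction) but its
transcriptional regulator is unknown, one promoter alone carries little
statistical signal. `coexmotif` implements the standard rescue: pool
information across the genes most tightly co-expressed with the seed gene,
and ask which binding motifs are enriched in their regulatory sequence.
It is aimed at computational biologists who have (i) a normalized
probe-level expression matrix with condition labels, (ii) promoter
sequence (or a genome plus a TSS table), and (iii) a JASPAR-format motif
library — and who want a calibrated, reproducible enrichment ranking
rather than a one-off script.

The pipeline:

1. **Induction screen** — per-probe two-tailed pooled-variance Student
   *t*-test of the seed gene between conditions.
2. **Co-expression sets** — Pearson correlation of every probe to the seed
   probe across all samples; Affymetrix `_s_`/`_x_` probes filtered (with
   a don't-orphan-the-gene exception); per-gene probe averaging; top-N
   sets (seed included in N), optionally restricted to a mitochondrial
   annotation track; hypergeometric+BH GO over-representation.
3. **Motif scoring** — JASPAR PFMs to log-odds (bits, pseudocount 0.8,
   configurable background); both-strand PWM scanning of ±10 kb TSS
   windows; per-position conservation weights from aligned orthologs; the
   gene score is the best conservation-weighted site.
4. **Enrichment** — per motif, the AUC (midrank Mann–Whitney) of set
   versus rest-of-universe scores; permutation null over random same-size
   gene sets with an add-one p-value, `p = (1 + #{AUC_null ≥ AUC_obs}) / (n_perm + 1)`;
   Benjamini–Hochberg q-values across the motif family within each
   analysis; tiers at q<0.05 / q<0.01; cross-set-size overlap reports.
5. **Promoter dissection** — IUPAC consensus site finding, tandem-pair
   detection, cross-species conservation windows, and reporter mutant
   design (per-site double transversion CCGGAA→CCTTAA; tandem-span
   deletion), with before/after site counts by re-scanning.
6. **Assay reductions** — ΔΔCt relative expression (`fold = 2^(−ΔΔCt)`)
   and background-normalized ChIP percent input with replicate SE and
   *t*-tests.

A seeded synthetic-data module generates all of the above inputs with
known truth (induced seed gene, correlated block, planted motif sites,
diverged orthologs) so the whole pipeline is testable offline.

## Worked example

Simulate the default benchmark conditions (200 genes, 10+10 samples,
2-fold seed induction, a 24-gene correlated block, 2-kb promoters with
planted `ACCGGAAGTG` sites in 80% of block promoters vs 10% elsewhere),
then run every stage:

```r
library(coexmotif)

cfg  <- synthetic_config(rng_seed = 1)
expr <- simulate_expression(cfg)

screen_induction(expr$matrix, "Sirt3", "DR", "control")
#>   probe_id   mean_a   mean_b t_statistic     p_value passes
#> 1 Sirt3_at 9.124422 8.066101    5.055157 8.24069e-05   TRUE

tab <- rank_correlations(filter_probes(expr$matrix), expr$seed_probe)
head(as.data.frame(tab), 3)
#>    gene    mean_r n_probes rank
#> 1 Sirt3 1.0000000        1    1
#> 2  G007 0.9411721        1    2
#> 3  G004 0.9395974        1    3

build_gene_set(tab, "Sirt3", 25)
#> GeneSet 'Sirt3_top25_all' (track=all): 25 genes, seed=Sirt3

bm <- planted_motif_benchmark(cfg)   # score + enrich vs 9 decoy motifs
bm$planted
#>          analysis motif_id       auc     p_value    q_value   tier
#> 1 Sirt3_top25_all SYN_NRF2 0.8354286 0.000999001 0.00999001 q<0.01
```

Reading the numbers: the seed gene is induced about two-fold
(mean 9.12 vs 8.07 log2 units, p = 8.2e-5); the 25-gene set recovers the
planted block (the top correlates all have r ≈ 0.93–0.94 to the seed); and
the planted NRF-2-like motif's score separates set from background with
AUC = 0.84 — a random gene set of size 25 essentially never reaches that,
so the permutation p is at its floor (1/1001) and the BH q across the
10-motif family is 0.01, tier `q<0.01`, ranked first in the summary table.

For real data, replace the simulated pieces with
`read_expression_matrix()`, `read_jaspar()`, `read_fasta()` +
`read_tss_bed()` + `extract_windows()`, `conservation_profile()`,
`score_gene_universe()`, and `run_enrichment_matrix()`.

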