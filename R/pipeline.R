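#' Run the full planted-motif benchmark pipeline once
#'
#' Chains every stage on synthetic data: simulate the expression matrix,
#' filter suffixed probes, rank genes by correlation to the seed probe,
#' build the top-N gene set, simulate promoters with the planted motif's
#' sites enriched in the correlated block, score every gene against the
#' planted motif plus decoys, and run the AUC/permutation/BH enrichment
#' matrix. The planted motif's q-value answers whether the pipeline
#' recovers the signal it was given.
#'
#' @param config A [synthetic_config()]; the configuration's `rng_seed`
#'   drives every stage.
#' @param set_size Gene-set size N (default `correlated_block_size + 1`, so
#'   the set can exactly cover seed + block).
#' @param n_decoys Decoy motifs scored alongside the planted one
#'   (default 9, a 10-motif family).
#' @param n_perm Permutations per enrichment test (default 1000).
#' @param use_conservation Also simulate orthologs and weight scores by
#'   conservation (default FALSE; slower).
#' @return List with `run` (output of [run_enrichment_matrix()]),
#'   `planted` (the planted motif's result row), `planted_top` (logical:
#'   is the planted motif the top row of the summary table), `set`,
#'   `truth`, `set_recall` (fraction of block genes recovered in the set).
#' @export
planted_motif_benchmark <- function(config = synthetic_config(),
                                    set_size = config$correlated_block_size + 1,
                                    n_decoys = 9, n_perm = 1000,
                                    use_conservation = FALSE) {
  expr <- simulate_expression(config)
  filtered <- filter_probes(expr$matrix)
  corr <- rank_correlations(filtered, expr$seed_probe)
  set <- build_gene_set(corr, config$seed_gene, set_size, track = "all")

  fg <- c(config$seed_gene, expr$block_genes)
  prom <- simulate_promoters(expr$truth$gene, fg, config)
  motifs <- c(setNames(list(config$planted_motif),
                       config$planted_motif$motif_id),
              decoy_motifs(n_decoys, length = ncol(config$planted_motif$counts),
                           seed = config$rng_seed + 3L))
  profiles <- NULL
  if (use_conservation) {
    profiles <- lapply(setNames(names(prom$sequences), names(prom$sequences)),
                       function(g) {
      spans <- prom$truth[prom$truth$gene == g, , drop = FALSE]
      orth <- simulate_orthologs(prom$sequences[[g]], config, spans)
      conservation_profile(prom$sequences[[g]], orth)
    })
  }
  scores <- score_gene_universe(prom$sequences, motifs, profiles)
  run <- run_enrichment_matrix(scores, setNames(list(set), set$name),
                               n_perm = n_perm, seed = config$rng_seed + 4L)
  planted_id <- config$planted_motif$motif_id
  planted <- run$results[run$results$motif_id == planted_id, , drop = FALSE]
  list(run = run,
       planted = planted,
       planted_top = rownames(run$auc_matrix)[1] == planted_id,
       set = set,
       truth = expr$truth,
       set_recall = mean(expr$block_genes %in% set$members))
}

#' Null calibration of the permutation enrichment p-value
#'
#' Draws i.i.d. scores for the universe and a random gene set of the given
#' size — the global null, with no planted signal — and records the
#' permutation p-value, repeated over a grid of simulated "motifs" and
#' replicates. Under the null the p-values should be approximately uniform,
#' so the fraction below `alpha` estimates the test's size.
#'
#' @param n_motifs,n_replicates Grid dimensions (defaults 100 x 50).
#' @param universe_size,set_size Universe and set sizes (defaults 200, 25).
#' @param n_perm Permutations per test (default 200).
#' @param seed Base RNG seed.
#' @param alpha Nominal level (default 0.05).
#' @return List with `p_values` (numeric vector, length
#'   `n_motifs * n_replicates`), `fraction_below` (observed size),
#'   `alpha`, and `binomial_se` of the fraction under exact calibration.
#' @export
null_calibration <- function(n_motifs = 100, n_replicates = 50,
                             universe_size = 200, set_size = 25,
                             n_perm = 200, seed = 1, alpha = 0.05) {
  genes <- sprintf("g%03d", seq_len(universe_size))
  total <- n_motifs * n_replicates
  p_values <- numeric(total)
  for (i in seq_len(total)) {
    draw_seed <- seed + 2L * i
    inputs <- local_seed(draw_seed, {
      list(scores = setNames(rnorm(universe_size), genes),
           members = sample(genes, set_size))
    })
    p_values[i] <- enrichment_test(inputs$scores, inputs$members,
                                   n_perm = n_perm,
                                   seed = draw_seed + 1L)$p_value
  }
  frac <- mean(p_values < alpha)
  list(p_values = p_values, fraction_below = frac, alpha = alpha,
       binomial_se = sqrt(alpha * (1 - alpha) / total))
}
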