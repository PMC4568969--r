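#' Default planted motif: a synthetic NRF-2/ETS-like PWM
#'
#' A 10-column position frequency matrix whose consensus, `ACCGGAAGTG`,
#' carries the ETS-family CCGGAA core. The counts are synthetic (built for
#' benchmarking, not taken from any database): 17 of 20 counts on the
#' consensus base per column gives a sharply peaked motif whose exact
#' consensus is rare by chance in kilobase-scale background sequence.
#'
#' @param pseudocount,background Passed to [motif_model()].
#' @return A `MotifModel`.
#' @export
default_planted_motif <- function(pseudocount = 0.8, background = rep(0.25, 4)) {
  consensus_motif("ACCGGAAGTG", motif_id = "SYN_NRF2", name = "NRF2_like_synthetic",
                  pseudocount = pseudocount, background = background)
}

#' Build a sharply peaked motif from a consensus string
#'
#' @param consensus DNA string (ACGT) of length >= 4.
#' @param motif_id,name,pseudocount,background Passed to [motif_model()].
#' @param peak,off Counts assigned to the consensus base and to each other
#'   base per column.
#' @return A `MotifModel`.
#' @export
consensus_motif <- function(consensus, motif_id, name = motif_id,
                            peak = 17, off = 1, pseudocount = 0.8,
                            background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus must be plain ACGT")
  counts <- matrix(off, nrow = 4, ncol = length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- peak
  motif_model(counts, motif_id, name, pseudocount = pseudocount,
              background = background)
}

#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions the generator emulates: a two-group
#' (control vs dietary restriction) expression matrix in which a seed gene
#' is induced and a block of genes tracks it, plus promoter sequences in
#' which the planted motif's sites occur preferentially in the correlated
#' block, plus diverged ortholog sequences for conservation weighting.
#'
#' @param rng_seed Integer seed; every draw in the generators derives from
#'   it (functions use fixed small offsets from it so the expression,
#'   promoter and ortholog stages have independent streams).
#' @param n_genes Size of the gene universe (default 200, a desk-scale
#'   stand-in for a whole array).
#' @param n_samples_per_condition Samples per group (default 10).
#' @param induction_effect Seed-gene shift under "DR" in log2 units
#'   (default 1, i.e. two-fold induction).
#' @param correlated_block_size Number of genes correlated with the seed
#'   (default 24, so seed + block = a 25-gene set).
#' @param target_correlation Population correlation of block genes to the
#'   seed profile (default 0.9).
#' @param noise_sd Residual log2 intensity SD (default 0.5).
#' @param baseline Mean log2 intensity (default 8).
#' @param dup_probe_fraction Fraction of genes given an extra decoy probe
#'   with an `_s_`/`_x_` suffix (default 0.2), exercising probe filtering.
#' @param n_suffix_only_genes Background genes whose only probe carries a
#'   suffix (default 2), exercising the retention rule.
#' @param mito_p_block,mito_p_bg Probability that a block / background gene
#'   is flagged mitochondrial in the truth table (defaults 0.6, 0.2).
#' @param promoter_length Promoter length in bp (default 2000; configurable
#'   up to the full 20 kb window).
#' @param gc_content Background GC fraction (default 0.5).
#' @param planted_motif `MotifModel` whose consensus is planted
#'   (default [default_planted_motif()]).
#' @param p_site_fg,p_site_bg Probability that a foreground (seed + block)
#'   or background gene's promoter receives one planted site (defaults
#'   0.8 and 0.1).
#' @param n_species Ortholog sequences per promoter (default 4).
#' @param substitution_rate Per-base ortholog substitution probability
#'   outside planted sites (default 0.2).
#' @param site_substitution_rate Substitution probability inside planted
#'   site spans (default 0: sites perfectly conserved).
#' @param seed_gene Seed gene symbol (default `"Sirt3"`).
#' @return Object of class `SyntheticConfig` (validated list).
#' @export
synthetic_config <- function(rng_seed = 1,
                             n_genes = 200,
                             n_samples_per_condition = 10,
                             induction_effect = 1,
                             correlated_block_size = 24,
                             target_correlation = 0.9,
                             noise_sd = 0.5,
                             baseline = 8,
                             dup_probe_fraction = 0.2,
                             n_suffix_only_genes = 2,
                             mito_p_block = 0.6,
                             mito_p_bg = 0.2,
                             promoter_length = 2000,
                             gc_content = 0.5,
                             planted_motif = default_planted_motif(),
                             p_site_fg = 0.8,
                             p_site_bg = 0.1,
                             n_species = 4,
                             substitution_rate = 0.2,
                             site_substitution_rate = 0,
                             seed_gene = "Sirt3") {
  cfg <- list(rng_seed = as.integer(rng_seed), n_genes = n_genes,
              n_samples_per_condition = n_samples_per_condition,
              induction_effect = induction_effect,
              correlated_block_size = correlated_block_size,
              target_correlation = target_correlation, noise_sd = noise_sd,
              baseline = baseline, dup_probe_fraction = dup_probe_fraction,
              n_suffix_only_genes = n_suffix_only_genes,
              mito_p_block = mito_p_block, mito_p_bg = mito_p_bg,
              promoter_length = promoter_length, gc_content = gc_content,
              planted_motif = planted_motif, p_site_fg = p_site_fg,
              p_site_bg = p_site_bg, n_species = n_species,
              substitution_rate = substitution_rate,
              site_substitution_rate = site_substitution_rate,
              seed_gene = seed_gene)
  probs <- c(cfg$p_site_fg, cfg$p_site_bg, cfg$gc_content,
             cfg$substitution_rate, cfg$site_substitution_rate,
             cfg$dup_probe_fraction, cfg$mito_p_block, cfg$mito_p_bg)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$target_correlation < 0 || cfg$target_correlation > 1)
    stop("target_correlation must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (!inherits(cfg$planted_motif, "MotifModel"))
    stop("planted_motif must be a MotifModel")
  if (cfg$promoter_length < ncol(cfg$planted_motif$counts))
    stop("promoter_length must be at least the planted motif length")
  if (cfg$correlated_block_size + 1 + cfg$n_suffix_only_genes > cfg$n_genes)
    stop("n_genes too small for the block plus the seed gene")
  structure(cfg, class = "SyntheticConfig")
}

# Gene universe implied by a config: seed gene first, then numbered genes.
synthetic_genes <- function(config) {
  c(config$seed_gene,
    sprintf("G%03d", seq_len(config$n_genes - 1)))
}

#' Simulate a two-condition expression matrix with a correlated block
#'
#' The seed gene's profile is baseline + induction under "DR" + noise.
#' Block genes are built as `rho * z + sqrt(1 - rho^2) * eps` around the
#' standardized realized seed profile `z`, then rescaled to `noise_sd`, so
#' their population correlation to the seed is `rho`. Remaining genes are
#' independent noise. A fraction of genes receive an additional decoy probe
#' with an `_s_` or `_x_` identifier suffix (values independent of the
#' gene's main probe), and a few background genes carry only a suffixed
#' probe, exercising the probe-filtering retention rule.
#'
#' @param config A [synthetic_config()].
#' @return List with `matrix` (an [expression_matrix()]), `truth`
#'   (data.frame `gene`, `role` in seed/block/background, `is_mito`),
#'   `seed_probe` (id of the seed gene's main probe), and
#'   `block_genes`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  local_seed(config$rng_seed, {
    n <- config$n_samples_per_condition
    conditions <- setNames(rep(c("control", "DR"), each = n),
                           c(sprintf("ctrl_%02d", seq_len(n)),
                             sprintf("dr_%02d", seq_len(n))))
    n_samp <- 2 * n
    genes <- synthetic_genes(config)
    block_genes <- genes[1 + seq_len(config$correlated_block_size)]
    bg_genes <- setdiff(genes, c(config$seed_gene, block_genes))
    rho <- config$target_correlation

    seed_vals <- config$baseline +
      config$induction_effect * (conditions == "DR") +
      rnorm(n_samp, sd = config$noise_sd)
    z <- as.numeric(scale(seed_vals))

    gene_profile <- function(gene) {
      if (gene == config$seed_gene) return(seed_vals)
      if (gene %in% block_genes) {
        x <- rho * z + sqrt(1 - rho^2) * rnorm(n_samp)
        return(config$baseline + config$noise_sd * x)
      }
      config$baseline + config$noise_sd * rnorm(n_samp)
    }

    suffix_only <- if (config$n_suffix_only_genes > 0)
      bg_genes[seq_len(config$n_suffix_only_genes)] else character(0)
    dup_pool <- setdiff(genes, suffix_only)
    n_dup <- round(config$dup_probe_fraction * length(dup_pool))
    dup_genes <- if (n_dup > 0) sample(dup_pool, n_dup) else character(0)

    rows <- list(); probe_gene <- character(0)
    add_probe <- function(id, gene, vals) {
      rows[[length(rows) + 1]] <<- vals
      names(rows)[length(rows)] <<- id
      probe_gene[id] <<- gene
    }
    for (g in genes) {
      vals <- gene_profile(g)
      if (g %in% suffix_only) {
        add_probe(paste0(g, "_x_at"), g, vals)
      } else {
        add_probe(paste0(g, "_at"), g, vals)
      }
      if (g %in% dup_genes) {
        suffix <- sample(c("_s_at", "_x_at"), 1)
        add_probe(paste0(g, suffix), g,
                  config$baseline + config$noise_sd * rnorm(n_samp))
      }
    }
    values <- do.call(rbind, rows)
    colnames(values) <- names(conditions)

    is_mito <- setNames(runif(length(genes)) <
                          ifelse(genes %in% c(config$seed_gene, block_genes),
                                 config$mito_p_block, config$mito_p_bg),
                        genes)
    is_mito[config$seed_gene] <- TRUE
    truth <- data.frame(
      gene = genes,
      role = ifelse(genes == config$seed_gene, "seed",
                    ifelse(genes %in% block_genes, "block", "background")),
      is_mito = as.logical(is_mito),
      stringsAsFactors = FALSE)

    list(matrix = expression_matrix(values, conditions, probe_gene),
         truth = truth,
         seed_probe = paste0(config$seed_gene, "_at"),
         block_genes = block_genes)
  })
}

#' Simulate promoter sequences with planted motif sites
#'
#' Background sequence is i.i.d. at the configured GC content. Each
#' foreground gene's promoter receives, with probability `p_site_fg`, one
#' exact copy of the planted motif's consensus at a uniform random offset
#' and strand (`p_site_bg` for other genes). Every planted site is recorded
#' in a truth table.
#'
#' @param genes Character vector: all universe genes.
#' @param fg_genes Foreground genes (typically seed + correlated block).
#' @param config A [synthetic_config()].
#' @return List with `sequences` (named character vector), `truth`
#'   (data.frame `gene`, `offset` (0-based), `strand`), and `consensus`.
#' @export
simulate_promoters <- function(genes, fg_genes, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  consensus <- motif_consensus(config$planted_motif)
  L <- nchar(consensus)
  len <- config$promoter_length
  if (len < L) stop("promoter shorter than the planted motif")
  base_p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
              G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  local_seed(config$rng_seed + 1L, {
    truth <- list()
    sequences <- vapply(genes, function(g) {
      seq_chars <- sample(names(base_p), len, replace = TRUE, prob = base_p)
      p_site <- if (g %in% fg_genes) config$p_site_fg else config$p_site_bg
      if (runif(1) < p_site) {
        offset <- sample.int(len - L + 1, 1) - 1L
        strand <- sample(c("+", "-"), 1)
        site <- if (strand == "+") consensus else revcomp(consensus)
        seq_chars[(offset + 1):(offset + L)] <- strsplit(site, "")[[1]]
        truth[[length(truth) + 1]] <<- data.frame(
          gene = g, offset = offset, strand = strand, stringsAsFactors = FALSE)
      }
      paste0(seq_chars, collapse = "")
    }, character(1))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene = character(0), offset = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    list(sequences = sequences, truth = truth, consensus = consensus)
  })
}

#' Simulate diverged ortholog sequences for a promoter
#'
#' Each species' sequence is the promoter with i.i.d. base substitutions at
#' `substitution_rate`, except inside planted-site spans, which substitute
#' at `site_substitution_rate` (0 by default, making planted sites the
#' best-conserved regions).
#'
#' @param promoter DNA string.
#' @param config A [synthetic_config()].
#' @param site_spans Optional data.frame with `offset` (0-based) rows
#'   marking planted sites of the configured motif's length.
#' @return Named character vector `species_1` .. `species_n`.
#' @export
simulate_orthologs <- function(promoter, config, site_spans = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  chars <- strsplit(toupper(promoter), "")[[1]]
  len <- length(chars)
  rate <- rep(config$substitution_rate, len)
  if (!is.null(site_spans) && nrow(site_spans) > 0) {
    L <- ncol(config$planted_motif$counts)
    for (off in site_spans$offset) rate[(off + 1):(off + L)] <- config$site_substitution_rate
  }
  bases <- c("A", "C", "G", "T")
  local_seed(config$rng_seed + 2L, {
    out <- vapply(seq_len(config$n_species), function(s) {
      hit <- runif(len) < rate
      mutated <- chars
      if (any(hit)) {
        mutated[hit] <- vapply(chars[hit], function(b) {
          sample(setdiff(bases, b), 1)
        }, character(1))
      }
      paste0(mutated, collapse = "")
    }, character(1))
    setNames(out, sprintf("species_%d", seq_len(config$n_species)))
  })
}

#' Generate a set of decoy motifs
#'
#' Sharply peaked PFMs with random ACGT consensus strings, used as the
#' non-planted members of the motif family in benchmarks.
#'
#' @param n Number of decoys.
#' @param length Motif length (default 10).
#' @param seed RNG seed.
#' @return Named list of `MotifModel` objects (`DECOY_01`, ...).
#' @export
decoy_motifs <- function(n, length = 10, seed = 1) {
  local_seed(seed, {
    motifs <- lapply(seq_len(n), function(i) {
      consensus <- paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                          collapse = "")
      consensus_motif(consensus, motif_id = sprintf("DECOY_%02d", i))
    })
    setNames(motifs, vapply(motifs, `[[`, character(1), "motif_id"))
  })
}

#' Write a synthetic benchmark dataset to disk
#'
#' Emits the exact dialects the pipeline readers consume: expression TSV,
#' sample-condition TSV, probe-map TSV, promoter FASTA, planted-site truth
#' BED-like TSV, and the planted motif as a JASPAR PFM file.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- simulate_expression(config)
  fg <- c(config$seed_gene, expr$block_genes)
  prom <- simulate_promoters(expr$truth$gene, fg, config)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    site_truth = file.path(dir, "planted_sites.tsv"),
    motif = file.path(dir, "planted_motif.pfm"),
    mito = file.path(dir, "mito_genes.txt")
  )
  vals <- expr$matrix$values
  write.table(data.frame(probe = rownames(vals), vals, check.names = FALSE),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(expr$matrix$sample_conditions),
                         condition = unname(expr$matrix$sample_conditions)),
              paths$conditions, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(probe = names(expr$matrix$probe_to_gene),
                         gene = unname(expr$matrix$probe_to_gene)),
              paths$probe_map, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write_fasta(prom$sequences, paths$promoters)
  write.table(prom$truth, paths$site_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_jaspar(config$planted_motif, paths$motif)
  writeLines(expr$truth$gene[expr$truth$is_mito], paths$mito)
  invisible(paths)
}
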