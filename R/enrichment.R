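#' Area under the ROC curve for foreground vs background scores
#'
#' The rank-sum (Mann-Whitney) AUC with midrank tie handling:
#' `AUC = P(fg > bg) + 0.5 * P(fg == bg)` for a random foreground /
#' background score pair.
#'
#' @param fg_scores,bg_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(3, 1), c(2, 0))  # 0.75
compute_auc <- function(fg_scores, bg_scores) {
  if (length(fg_scores) == 0 || length(bg_scores) == 0)
    stop("fg_scores and bg_scores must be non-empty")
  n1 <- length(fg_scores)
  n2 <- length(bg_scores)
  r <- rank(c(fg_scores, bg_scores))  # midranks for ties
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Permutation test for gene-set motif enrichment
#'
#' The observed statistic is the AUC of the set members' scores against the
#' rest of the scored universe. The null is built from random gene sets of
#' the same size drawn uniformly without replacement from the universe;
#' `p = (1 + #null AUC >= observed) / (n_perm + 1)` (add-one, so p is never
#' below `1/(n_perm + 1)`). Results are bit-reproducible given
#' `(seed, n_perm)`. With `exhaustive = TRUE` every subset of the set's size
#' is enumerated instead and p is the exact proportion of subset AUCs at or
#' above the observed one (the observed set is among them).
#'
#' @param scores Named numeric vector: one score per universe gene.
#' @param set A `GeneSet` or character vector of member genes; must be a
#'   strict subset of `names(scores)`.
#' @param n_perm Number of random sets (default 1000; ignored when
#'   `exhaustive`).
#' @param seed Integer RNG seed (mandatory for the permutation mode).
#' @param exhaustive Enumerate all subsets instead of sampling (only viable
#'   for small universes).
#' @return List with `auc`, `p_value`, `n_perm`.
#' @export
enrichment_test <- function(scores, set, n_perm = 1000, seed = NULL,
                            exhaustive = FALSE) {
  members <- if (inherits(set, "GeneSet")) set$members else set
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (!all(members %in% names(scores)))
    stop("set members missing from the scored universe: ",
         paste(setdiff(members, names(scores)), collapse = ", "))
  N <- length(scores)
  n1 <- length(members)
  if (n1 >= N) stop("the gene set must be a strict subset of the universe")
  n2 <- N - n1
  # fg and bg partition the universe, so the AUC reduces to a rank sum over
  # the universe-wide midranks; precomputing them makes each permutation a
  # single indexed sum.
  r <- rank(scores)
  auc_of <- function(idx) (sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  obs <- auc_of(match(members, names(scores)))
  if (exhaustive) {
    null_auc <- combn(N, n1, auc_of)
    p <- mean(null_auc >= obs - 1e-12)
    return(list(auc = obs, p_value = p, n_perm = length(null_auc)))
  }
  if (is.null(seed)) stop("seed is required for the permutation null")
  null_auc <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) auc_of(sample.int(N, n1)), numeric(1))
  })
  p <- (1 + sum(null_auc >= obs)) / (n_perm + 1)
  list(auc = obs, p_value = p, n_perm = n_perm)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_qvalues <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# Significance tier label from a q-value.
tier_of <- function(q) ifelse(q < 0.01, "q<0.01", ifelse(q < 0.05, "q<0.05", "none"))

#' Run the full motif-family x gene-set enrichment matrix
#'
#' For every (gene set, motif) pair, runs [enrichment_test()] against the
#' shared universe; q-values are adjusted with Benjamini-Hochberg across the
#' motif family *within each analysis* (gene set), and tiers are marked at
#' q < 0.05 and q < 0.01. The summary heat-map table orders motifs by each
#' motif's maximum AUC across the analyses (ties broken by motif id) and
#' retains the top `top_n`.
#'
#' @param scores Motif x gene numeric matrix (rownames = motif ids,
#'   colnames = universe genes), e.g. from [score_gene_universe()], or a
#'   named list of identically-named score vectors.
#' @param sets Named list of `GeneSet` objects (or member character
#'   vectors); names label the analyses (e.g. `top25_all`).
#' @param n_perm Permutations per test (default 1000).
#' @param seed Base RNG seed; each (analysis, motif) test uses the
#'   deterministic sub-seed `seed + (analysis index - 1) * n_motifs +
#'   motif index - 1`.
#' @param top_n Rows kept in the summary heat-map table (default 10).
#' @return List with `results` (long data.frame: `analysis`, `motif_id`,
#'   `auc`, `p_value`, `q_value`, `tier`), `auc_matrix` (all motifs x
#'   analyses, ordered by max AUC), and `top` (the first `top_n` rows of
#'   `auc_matrix`).
#' @export
run_enrichment_matrix <- function(scores, sets, n_perm = 1000, seed = 1,
                                  top_n = 10) {
  if (is.list(scores) && !is.matrix(scores)) {
    universes <- lapply(scores, names)
    if (!all(vapply(universes, function(u) setequal(u, universes[[1]]), logical(1))))
      stop("inconsistent gene universes across motifs")
    scores <- do.call(rbind, lapply(scores, function(s) s[universes[[1]]]))
  }
  stopifnot(is.matrix(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores matrix needs motif rownames and gene colnames")
  if (is.null(names(sets))) stop("sets must be a named list")
  n_motifs <- nrow(scores)
  res <- do.call(rbind, lapply(seq_along(sets), function(si) {
    per_motif <- lapply(seq_len(n_motifs), function(mi) {
      sub_seed <- seed + (si - 1) * n_motifs + mi - 1
      et <- enrichment_test(scores[mi, ], sets[[si]], n_perm = n_perm,
                            seed = sub_seed)
      data.frame(analysis = names(sets)[si], motif_id = rownames(scores)[mi],
                 auc = et$auc, p_value = et$p_value, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, per_motif)
    block$q_value <- bh_qvalues(block$p_value)
    block$tier <- tier_of(block$q_value)
    block
  }))
  rownames(res) <- NULL
  auc_matrix <- matrix(res$auc, nrow = n_motifs,
                       dimnames = list(rownames(scores), names(sets)))
  max_auc <- apply(auc_matrix, 1, max)
  ord <- order(-max_auc, rownames(auc_matrix))
  auc_matrix <- auc_matrix[ord, , drop = FALSE]
  list(results = res,
       auc_matrix = auc_matrix,
       top = auc_matrix[seq_len(min(top_n, nrow(auc_matrix))), , drop = FALSE])
}

#' Cross-analysis overlap of significantly enriched motifs
#'
#' Summarizes, per motif, the analyses in which it reached significance
#' (tier other than `"none"`), with membership counts for every combination
#' of two or more analyses — the Venn-diagram bookkeeping behind comparing
#' enrichment across set sizes. Optionally intersects with an external list
#' of motifs found in a promoter scan.
#'
#' @param results The long `results` data.frame from
#'   [run_enrichment_matrix()] (needs >= 2 analyses).
#' @param promoter_motifs Optional character vector of motif ids found in a
#'   promoter dissection; adds the intersection of these with the motifs
#'   significant in any analysis.
#' @return Object of class `OverlapSummary`: list with `membership`
#'   (motif x analysis logical matrix), `significant_in` (named list motif
#'   -> analyses), `intersections` (named list combination -> motif ids),
#'   and optionally `promoter_overlap`.
#' @export
overlap_summary <- function(results, promoter_motifs = NULL) {
  analyses <- unique(results$analysis)
  if (length(analyses) < 2) stop("need results from at least 2 analyses")
  motifs <- unique(results$motif_id)
  membership <- matrix(FALSE, nrow = length(motifs), ncol = length(analyses),
                       dimnames = list(motifs, analyses))
  sig <- results[results$tier != "none", , drop = FALSE]
  if (nrow(sig) > 0)
    membership[cbind(sig$motif_id, sig$analysis)] <- TRUE
  significant_in <- lapply(setNames(motifs, motifs),
                           function(m) analyses[membership[m, ]])
  significant_in <- significant_in[lengths(significant_in) > 0]
  intersections <- list()
  for (k in 2:length(analyses)) {
    for (combo in as.data.frame(combn(analyses, k), stringsAsFactors = FALSE)) {
      key <- paste(combo, collapse = " & ")
      hit <- motifs[rowSums(membership[, combo, drop = FALSE]) == length(combo)]
      intersections[[key]] <- hit
    }
  }
  out <- list(membership = membership, significant_in = significant_in,
              intersections = intersections)
  if (!is.null(promoter_motifs)) {
    any_sig <- motifs[rowSums(membership) > 0]
    out$promoter_overlap <- intersect(any_sig, promoter_motifs)
  }
  structure(out, class = "OverlapSummary")
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat("OverlapSummary over", ncol(x$membership), "analyses\n")
  cat("motifs significant anywhere:", sum(rowSums(x$membership) > 0), "\n")
  for (key in names(x$intersections)) {
    cat(sprintf("  %s: %d\n", key, length(x$intersections[[key]])))
  }
  if (!is.null(x$promoter_overlap))
    cat("overlap with promoter scan:",
        paste(x$promoter_overlap, collapse = ", "), "\n")
  invisible(x)
}

#' Write an overlap summary as JSON
#'
#' @param summary An `OverlapSummary`.
#' @param path Output path.
#' @export
write_overlap_json <- function(summary, path) {
  jsonlite::write_json(
    list(significant_in = summary$significant_in,
         intersections = summary$intersections,
         promoter_overlap = summary$promoter_overlap),
    path, auto_unbox = FALSE, pretty = TRUE, null = "null")
}

#' Write the long enrichment results table to TSV
#'
#' @param run Output of [run_enrichment_matrix()] (or its `results` element).
#' @param path Output path.
#' @export
write_enrichment_table <- function(run, path) {
  res <- if (is.data.frame(run)) run else run$results
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
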