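#' Screen a gene for induction between two conditions
#'
#' Runs a classic pooled-variance two-sample Student t-test, two-tailed, on
#' every probe of `gene` separately (multi-probe platforms are screened
#' probe-by-probe rather than collapsed). Used to decide whether the seed
#' gene is induced (e.g. by dietary restriction) before any co-expression
#' analysis is attempted.
#'
#' Degenerate probes with zero pooled variance are handled by convention:
#' equal group means give p = 1, unequal means give p = 0 with a warning.
#'
#' @param matrix An [expression_matrix()].
#' @param gene Gene symbol to screen; must map to at least one probe.
#' @param group_a,group_b Condition labels of the two groups (each needs
#'   at least two samples).
#' @param alpha Significance threshold for the `passes` call (default 0.05).
#' @return A data.frame with one row per probe: `probe_id`, `mean_a`,
#'   `mean_b`, `t_statistic`, `p_value`, `passes`.
#' @export
screen_induction <- function(matrix, gene, group_a, group_b, alpha = 0.05) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  probes <- names(matrix$probe_to_gene)[!is.na(matrix$probe_to_gene) &
                                          matrix$probe_to_gene == gene]
  if (length(probes) == 0) stop("unknown gene (no mapped probes): ", gene)
  idx_a <- which(matrix$sample_conditions == group_a)
  idx_b <- which(matrix$sample_conditions == group_b)
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("each group needs at least 2 samples")
  res <- lapply(probes, function(p) {
    a <- matrix$values[p, idx_a]
    b <- matrix$values[p, idx_b]
    pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    if (pooled_var == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        warning("probe ", p, ": zero pooled variance with unequal means; p = 0")
        tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
      }
    } else {
      fit <- t.test(a, b, var.equal = TRUE)
      tt <- list(statistic = unname(fit$statistic), p.value = fit$p.value)
    }
    data.frame(probe_id = p, mean_a = mean(a), mean_b = mean(b),
               t_statistic = tt$statistic, p_value = tt$p.value,
               passes = tt$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Remove low-specificity probes by identifier suffix
#'
#' Affymetrix `_s_` (shared) and `_x_` (cross-hybridizing) probe sets are
#' less gene-specific than plain `_at` probe sets; they are dropped before
#' correlation ranking, except when doing so would leave a gene with no
#' probes at all, in which case all of that gene's probes are kept.
#' Unmapped probes are retained unchanged.
#'
#' @param matrix An [expression_matrix()].
#' @param patterns Identifier substrings that flag a probe for removal
#'   (fixed strings, matched anywhere in the probe id).
#' @return A filtered [expression_matrix()].
#' @export
filter_probes <- function(matrix, patterns = c("_s_", "_x_")) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  probes <- rownames(matrix$values)
  flagged <- Reduce(`|`, lapply(patterns, function(p) grepl(p, probes, fixed = TRUE)))
  genes <- probe_genes(matrix, probes)
  drop <- flagged & !is.na(genes)
  # retention rule: keep flagged probes of genes that have no unflagged probe
  for (g in unique(genes[drop])) {
    g_probes <- probes[!is.na(genes) & genes == g]
    if (all(flagged[match(g_probes, probes)])) drop[match(g_probes, probes)] <- FALSE
  }
  keep <- probes[!drop]
  expression_matrix(matrix$values[keep, , drop = FALSE],
                    matrix$sample_conditions,
                    matrix$probe_to_gene)
}

#' Rank genes by mean Pearson correlation to a seed probe
#'
#' Computes Pearson's r between the seed probe and every other probe across
#' all samples, averages r over each gene's surviving probes, and ranks
#' genes by descending mean r. Probes with zero variance are excluded with
#' a warning (their correlation is undefined); unmapped probes do not
#' contribute to any gene.
#'
#' @param matrix An [expression_matrix()] (typically after [filter_probes()]).
#' @param seed_probe Probe id of the seed gene's probe.
#' @return A `CorrelationTable` data.frame: `gene`, `mean_r`, `n_probes`,
#'   `rank`, ordered by descending `mean_r` (ties by gene symbol).
#' @export
rank_correlations <- function(matrix, seed_probe) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!seed_probe %in% rownames(matrix$values))
    stop("seed probe not present: ", seed_probe)
  if (ncol(matrix$values) < 3) stop("need at least 3 samples")
  seed_vals <- matrix$values[seed_probe, ]
  if (sd(seed_vals) == 0) stop("seed probe has zero variance")
  vars <- apply(matrix$values, 1, sd)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance probe(s) excluded from correlation")
  }
  ok <- vars > 0
  r <- as.vector(cor(t(matrix$values[ok, , drop = FALSE]), seed_vals))
  names(r) <- rownames(matrix$values)[ok]
  genes <- probe_genes(matrix, names(r))
  mapped <- !is.na(genes)
  mean_r <- tapply(r[mapped], genes[mapped], mean)
  n_probes <- tapply(r[mapped], genes[mapped], length)
  ord <- order(-mean_r, names(mean_r))
  out <- data.frame(gene = names(mean_r)[ord],
                    mean_r = as.numeric(mean_r[ord]),
                    n_probes = as.integer(n_probes[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean_r, ties.method = "min")
  structure(out, class = c("CorrelationTable", "data.frame"))
}

#' Build a top-N co-expression gene set
#'
#' The set contains the seed gene plus the (N - 1) eligible genes with the
#' highest mean correlation to the seed (the seed counts toward N). For the
#' `"mitochondrial"` track, eligibility is membership in `mito_list`
#' (a MitoCarta-style annotation). Boundary ties in mean r are broken by
#' gene symbol so the set is deterministic.
#'
#' @param table A `CorrelationTable` from [rank_correlations()].
#' @param seed_gene Seed gene symbol (always a member).
#' @param N Total set size, seed included.
#' @param track `"all"` or `"mitochondrial"`.
#' @param mito_list Character vector of mitochondrial gene symbols
#'   (required for the mitochondrial track).
#' @param name Optional set name; defaults to `"<seed>_top<N>_<track>"`.
#' @return An object of class `GeneSet`: list with `name`, `seed_gene`,
#'   `members`, `size`, `track`.
#' @export
build_gene_set <- function(table, seed_gene, N, track = c("all", "mitochondrial"),
                           mito_list = NULL, name = NULL) {
  track <- match.arg(track)
  stopifnot(is.data.frame(table), N >= 1)
  if (track == "mitochondrial" && is.null(mito_list))
    stop("mitochondrial track requires mito_list")
  eligible <- table[table$gene != seed_gene, , drop = FALSE]
  if (track == "mitochondrial")
    eligible <- eligible[eligible$gene %in% mito_list, , drop = FALSE]
  if (nrow(eligible) < N - 1)
    stop(sprintf("only %d eligible genes for track '%s'; need %d beyond the seed",
                 nrow(eligible), track, N - 1))
  eligible <- eligible[order(-eligible$mean_r, eligible$gene), , drop = FALSE]
  members <- c(seed_gene, head(eligible$gene, N - 1))
  structure(
    list(name = name %||% sprintf("%s_top%d_%s", seed_gene, N, track),
         seed_gene = seed_gene, members = members,
         size = as.integer(N), track = track),
    class = "GeneSet"
  )
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' (track=%s): %d genes, seed=%s\n",
              x$name, x$track, x$size, x$seed_gene))
  invisible(x)
}

#' Gene ontology over-representation by the hypergeometric test
#'
#' For each term annotating at least one universe gene, computes the
#' upper-tail hypergeometric probability of the observed overlap between the
#' gene set and the term's genes, then adjusts across terms with
#' Benjamini-Hochberg.
#'
#' @param set A `GeneSet` or character vector of member genes (must be a
#'   subset of `universe`).
#' @param annotation Named list gene -> character vector of terms (see
#'   [read_go_annotation()]); genes may have empty term lists.
#' @param universe Character vector: the gene universe.
#' @return data.frame `term`, `overlap`, `term_size`, `p_value`, `q_value`,
#'   ordered by increasing p.
#' @export
go_enrichment <- function(set, annotation, universe) {
  members <- if (inherits(set, "GeneSet")) set$members else set
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  if (!all(members %in% universe)) stop("gene set must be a subset of the universe")
  ann <- annotation[intersect(names(annotation), universe)]
  gene_by_term <- split(rep(names(ann), lengths(ann)), unlist(ann, use.names = FALSE))
  if (length(gene_by_term) == 0)
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  M <- length(universe)
  n <- length(members)
  rows <- lapply(names(gene_by_term), function(term) {
    term_genes <- unique(gene_by_term[[term]])
    K <- length(term_genes)
    k <- length(intersect(term_genes, members))
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_qvalues(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a correlation table to TSV
#'
#' @param table A `CorrelationTable`.
#' @param path Output path.
#' @export
write_correlation_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Write a gene set as a one-symbol-per-line file
#'
#' @param set A `GeneSet`.
#' @param path Output path.
#' @export
write_gene_set <- function(set, path) {
  stopifnot(inherits(set, "GeneSet"))
  writeLines(c(sprintf("# %s seed=%s track=%s", set$name, set$seed_gene, set$track),
               set$members), path)
}
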