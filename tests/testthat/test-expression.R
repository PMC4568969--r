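test_that("screen_induction matches the closed-form Student t and handles degenerate probes", {
  values <- rbind(
    same_at = c(1, 2, 3, 1, 2, 3),
    real_at = c(10.1, 10.3, 9.9, 12.0, 12.4, 11.8),
    const_at = rep(5, 6),
    shift_at = c(2, 2, 2, 7, 7, 7)
  )
  colnames(values) <- paste0("s", 1:6)
  mat <- expression_matrix(
    values,
    setNames(rep(c("a", "b"), each = 3), colnames(values)),
    c(same_at = "SAME", real_at = "REAL", const_at = "CONST", shift_at = "SHIFT")
  )

  # identical group profiles (nonzero variance): t = 0, p = 1
  res <- screen_induction(mat, "SAME", "a", "b")
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$passes)

  # hand-computed two-tailed pooled t probability
  a <- c(10.1, 10.3, 9.9); b <- c(12.0, 12.4, 11.8)
  oracle <- student_t_oracle(a, b)
  res <- screen_induction(mat, "REAL", "a", "b")
  expect_equal(res$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_true(res$passes)

  # zero pooled variance conventions
  expect_equal(screen_induction(mat, "CONST", "a", "b")$p_value, 1)
  expect_warning(res <- screen_induction(mat, "SHIFT", "a", "b"),
                 "zero pooled variance")
  expect_equal(res$p_value, 0)

  expect_error(screen_induction(mat, "NOPE", "a", "b"), "unknown gene")
})

test_that("filter_probes drops suffixed probes but never orphans a gene", {
  mat <- toy_expression_matrix()
  filtered <- filter_probes(mat)
  # G2's only probe is suffixed: retained by the exception rule
  expect_true("g2_s_at" %in% rownames(filtered$values))
  genes_before <- unique(na.omit(mat$probe_to_gene))
  genes_after <- unique(na.omit(filtered$probe_to_gene))
  expect_setequal(genes_before, genes_after)

  # a gene with both plain and suffixed probes loses only the suffixed one
  values <- rbind(`100_at` = 1:4, `101_s_at` = c(2, 1, 4, 3), `200_x_at` = 4:1)
  colnames(values) <- paste0("s", 1:4)
  mat2 <- expression_matrix(values,
                            setNames(rep(c("a", "b"), 2), colnames(values)),
                            c(`100_at` = "G", `101_s_at` = "G", `200_x_at` = "H"))
  f2 <- filter_probes(mat2)
  expect_setequal(rownames(f2$values), c("100_at", "200_x_at"))

  # no suffixed probes: identity
  values3 <- values[1, , drop = FALSE]
  mat3 <- expression_matrix(values3,
                            setNames(rep(c("a", "b"), 2), colnames(values3)),
                            c(`100_at` = "G"))
  expect_identical(filter_probes(mat3)$values, mat3$values)

  # unmapped suffixed probes are retained unchanged
  mat4 <- expression_matrix(values,
                            setNames(rep(c("a", "b"), 2), colnames(values)),
                            c(`100_at` = "G"))
  expect_true("101_s_at" %in% rownames(filter_probes(mat4)$values))
})

test_that("rank_correlations reproduces the Pearson formula and averages per gene", {
  mat <- toy_expression_matrix()
  expect_warning(tab <- rank_correlations(mat, "seed_at"), "zero-variance")
  expect_false("FLAT" %in% tab$gene)  # zero-variance probe excluded
  expect_equal(tab$mean_r[tab$gene == "DUP"], 1)
  expect_equal(tab$mean_r[tab$gene == "ANTI"], -1)
  # SEED and DUP share r = 1 and therefore the top min-rank
  expect_equal(tab$rank[tab$gene == "SEED"], tab$rank[tab$gene == "DUP"])

  # 4-sample toy against the definitional Pearson formula
  values <- rbind(seed_at = c(1, 2, 3, 4), p_at = c(1, 2, 4, 3))
  colnames(values) <- paste0("s", 1:4)
  m <- expression_matrix(values,
                         setNames(rep(c("a", "b"), 2), colnames(values)),
                         c(seed_at = "S", p_at = "P"))
  tab <- rank_correlations(m, "seed_at")
  expect_equal(tab$mean_r[tab$gene == "P"],
               pearson_oracle(c(1, 2, 3, 4), c(1, 2, 4, 3)),
               tolerance = 1e-12)

  expect_error(rank_correlations(mat, "flat_at"), "zero variance")
})

test_that("rank_correlations agrees with a per-probe Pearson oracle on random matrices", {
  for (s in 1:5) {
    set.seed(100 + s)
    values <- matrix(rnorm(50 * 10), nrow = 50,
                     dimnames = list(sprintf("p%02d_at", 1:50), sprintf("s%d", 1:10)))
    genes <- sprintf("GENE%02d", sample(1:20, 50, replace = TRUE))
    mat <- expression_matrix(values,
                             setNames(rep(c("a", "b"), each = 5), colnames(values)),
                             setNames(genes, rownames(values)))
    tab <- rank_correlations(mat, "p01_at")
    r_probe <- vapply(rownames(values),
                      function(p) pearson_oracle(values[p, ], values["p01_at", ]),
                      numeric(1))
    expected <- c(tapply(r_probe, genes, mean))
    expect_equal(setNames(tab$mean_r, tab$gene)[names(expected)],
                 expected, tolerance = 1e-10)
  }
})

test_that("build_gene_set takes the seed plus the top correlates, deterministically", {
  tab <- data.frame(
    gene = c("SEED", LETTERS[1:10]),
    mean_r = c(1, 0.9, 0.8, 0.8, 0.7, 0.5, 0.4, 0.3, 0.2, 0.1, 0.0),
    n_probes = 1L, rank = 1L, stringsAsFactors = FALSE)

  set1 <- build_gene_set(tab, "SEED", 1)
  expect_equal(set1$members, "SEED")

  set4 <- build_gene_set(tab, "SEED", 4)
  # brute-force sort of the r column (seed excluded), top 3
  eligible <- tab[tab$gene != "SEED", ]
  expected <- eligible$gene[order(-eligible$mean_r, eligible$gene)][1:3]
  expect_equal(set4$members, c("SEED", expected))
  expect_equal(set4$members[2:3], c("A", "B"))  # 0.8-tie broken as B < C

  # idempotent/deterministic
  expect_identical(build_gene_set(tab, "SEED", 4)$members, set4$members)

  # mitochondrial track restricts eligibility
  mito <- c("C", "E", "G")
  setm <- build_gene_set(tab, "SEED", 3, track = "mitochondrial", mito_list = mito)
  expect_equal(setm$members, c("SEED", "C", "E"))
  expect_error(build_gene_set(tab, "SEED", 5, track = "mitochondrial",
                              mito_list = mito), "eligible")
  expect_error(build_gene_set(tab, "SEED", 50), "eligible")
})

test_that("the top-N set recovers a correlated block planted in synthetic data", {
  recovered <- vapply(1:20, function(s) {
    cfg <- synthetic_config(rng_seed = 1000 + s)
    expr <- simulate_expression(cfg)
    tab <- rank_correlations(filter_probes(expr$matrix), expr$seed_probe)
    set <- build_gene_set(tab, cfg$seed_gene, cfg$correlated_block_size + 1)
    mean(expr$block_genes %in% set$members)
  }, numeric(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("go_enrichment matches the hypergeometric formula and BH invariants", {
  universe <- sprintf("g%02d", 1:20)
  members <- universe[1:5]
  annotation <- list()
  for (g in universe) annotation[[g]] <- character(0)
  for (g in members) annotation[[g]] <- "hit_term"       # all 5 in the set
  for (g in universe[6:20]) annotation[[g]] <- "other_term"

  res <- go_enrichment(members, annotation, universe)
  # overlap 5 of a 5-gene term in a 5-gene set: p = 1 / C(20, 5)
  expect_equal(res$p_value[res$term == "hit_term"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # term annotating no set member: p = 1
  expect_equal(res$p_value[res$term == "other_term"], 1, tolerance = 1e-12)

  # single tested term: q = p
  ann1 <- setNames(rep(list("only"), 20), universe)
  res1 <- go_enrichment(members, ann1, universe)
  expect_equal(res1$q_value, res1$p_value)

  # random annotations: p in [0,1], q >= p, q monotone in the p-ordering
  set.seed(42)
  ann <- lapply(setNames(universe, universe),
                function(g) sample(paste0("T", 1:6), sample(0:3, 1)))
  res <- go_enrichment(members, ann, universe)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))

  expect_error(go_enrichment(members, annotation, character(0)), "empty universe")
})
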