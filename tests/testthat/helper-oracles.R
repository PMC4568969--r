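# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: naive loops, closed forms, and exhaustive
# enumeration.

# Pearson correlation written out from the definitional formula.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Two-tailed pooled-variance Student t probability from the textbook formula.
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2))
}

# AUC by exhaustive pair counting with half-credit for ties.
auc_pairs_oracle <- function(fg, bg) {
  wins <- 0
  for (f in fg) for (b in bg) wins <- wins + (f > b) + 0.5 * (f == b)
  wins / (length(fg) * length(bg))
}

# Benjamini-Hochberg step-up, written as the explicit recursion over the
# sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q_sorted <- numeric(m)
  q_sorted[m] <- sorted[m]
  if (m > 1) {
    for (i in (m - 1):1) {
      q_sorted[i] <- min(q_sorted[i + 1], sorted[i] * m / i)
    }
  }
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Naive per-offset log-odds scorer: forward strand by direct column sums,
# minus strand by reverse-complementing the L-mer and scoring it forward.
naive_scan_oracle <- function(sequence, motif) {
  lo <- motif$logodds
  L <- ncol(lo)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars) - L + 1
  if (n < 1) return(data.frame(offset = integer(0), strand = character(0),
                               score = numeric(0)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_kmer <- function(kmer) {
    if (any(!kmer %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(seq_len(L), function(j) lo[kmer[j], j], numeric(1)))
  }
  rows <- list()
  for (i in seq_len(n)) {
    kmer <- chars[i:(i + L - 1)]
    rc <- rev(unname(comp[kmer]))
    rows[[length(rows) + 1]] <- data.frame(
      offset = i - 1L, strand = "+", score = score_kmer(kmer),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      offset = i - 1L, strand = "-",
      score = if (anyNA(rc)) -Inf else score_kmer(rc),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Character-level reverse complement, independent of Biostrings.
revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste0(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# A small expression matrix built directly (no generator) for unit tests.
toy_expression_matrix <- function() {
  values <- rbind(
    seed_at    = c(1, 2, 3, 4, 5, 6),
    dup_at     = c(1, 2, 3, 4, 5, 6),
    anti_at    = c(6, 5, 4, 3, 2, 1),
    g1_at      = c(2, 1, 4, 3, 6, 5),
    g2_s_at    = c(5, 5, 5, 1, 1, 2),
    flat_at    = c(3, 3, 3, 3, 3, 3)
  )
  colnames(values) <- paste0("s", 1:6)
  expression_matrix(
    values,
    setNames(rep(c("control", "DR"), each = 3), colnames(values)),
    c(seed_at = "SEED", dup_at = "DUP", anti_at = "ANTI", g1_at = "G1",
      g2_s_at = "G2", flat_at = "FLAT")
  )
}
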