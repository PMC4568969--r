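test_that("read_jaspar parses bracketed and bare dialects and validates input", {
  path <- system.file("extdata", "example_motifs.pfm", package = "coexmotif")
  motifs <- read_jaspar(path)
  expect_named(motifs, c("SYN_NRF2", "SYN_FLAT"))
  expect_equal(ncol(motifs$SYN_NRF2$counts), 10)
  expect_equal(motif_consensus(motifs$SYN_NRF2), "ACCGGAAGTG")
  expect_equal(ncol(motifs$SYN_FLAT$counts), 6)

  # uniform counts under uniform background: log-odds identically zero
  expect_equal(unname(motifs$SYN_FLAT$logodds), matrix(0, 4, 6))

  bad <- tempfile(fileext = ".pfm")
  writeLines(c(">BAD", "1 2 3", "1 2 3 4", "1 2 3 4", "1 2 3 4"), bad)
  expect_error(read_jaspar(bad), "BAD")
  writeLines(c(">NEG x", "1 2 3 -4", "1 2 3 4", "1 2 3 4", "1 2 3 4"), bad)
  expect_error(read_jaspar(bad), "negative")

  # write -> read round trip preserves counts
  out <- tempfile(fileext = ".pfm")
  write_jaspar(motifs, out)
  again <- read_jaspar(out)
  expect_equal(again$SYN_NRF2$counts, motifs$SYN_NRF2$counts)
})

test_that("log-odds follow the pseudocount formula and shrink toward background", {
  counts <- matrix(c(4, 0, 0, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))[, rep(1, 4)]
  m <- motif_model(counts, "TEST", pseudocount = 1)
  # hand formula: log2(((4 + 1*0.25) / (4 + 1)) / 0.25)
  expect_equal(unname(m$logodds["A", 1]), log2((4.25 / 5) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(m$logodds["C", 1]), log2((0.25 / 5) / 0.25),
               tolerance = 1e-12)

  # increasing the pseudocount never increases the maximum score
  set.seed(7)
  for (i in 1:10) {
    counts <- matrix(rpois(4 * 8, 5), nrow = 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    scores <- vapply(c(0.1, 0.8, 2, 10), function(pc)
      motif_max_score(motif_model(counts, "X", pseudocount = pc)), numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("extract_windows does the TSS arithmetic, clips, and honors strand", {
  set.seed(3)
  contig <- random_dna(60000)
  genome <- c(chr1 = contig)
  tss <- data.frame(chrom = "chr1", start = c(50000, 5, 30000),
                    end = c(50001, 6, 30001),
                    gene = c("plus", "edge", "minus"), score = 0,
                    strand = c("+", "+", "-"), stringsAsFactors = FALSE)

  expect_warning(
    wins <- extract_windows(tss, genome, upstream_bp = 10000, downstream_bp = 10000),
    "clipped")
  expect_equal(nchar(wins$plus$sequence), 20000)
  expect_equal(wins$plus$start, 40000)
  expect_equal(wins$plus$end, 60000)
  expect_equal(wins$plus$sequence, substr(contig, 40001, 60000))

  # clipped at the contig start
  expect_equal(wins$edge$start, 0)
  expect_equal(nchar(wins$edge$sequence), 5 + 10000)

  # minus strand equals the reverse complement of the mirrored interval,
  # checked against a naive extractor
  naive <- revcomp_oracle(substr(contig, 30000 - 10000 + 1, 30000 + 10000))
  expect_equal(wins$minus$sequence, naive)

  expect_error(extract_windows(data.frame(chrom = "chrX", start = 10, end = 11,
                                          gene = "g", score = 0, strand = "+"),
                               genome), "unknown contig")
  expect_error(extract_windows(data.frame(chrom = "chr1", start = 70000,
                                          end = 70001, gene = "g", score = 0,
                                          strand = "+"),
                               genome), "outside contig")
})

test_that("scan_sequence matches a naive scorer and respects N and thresholds", {
  motifs <- read_jaspar(system.file("extdata", "example_motifs.pfm",
                                    package = "coexmotif"))
  m <- motifs$SYN_NRF2
  L <- ncol(m$logodds)

  # sequence shorter than the motif: no hits
  expect_equal(nrow(scan_sequence("ACGT", m, threshold = -Inf)), 0)

  # a planted consensus is found at the motif's maximum score
  seq <- paste0("TTTTT", motif_consensus(m), "TTTTT")
  hits <- scan_sequence(seq, m, threshold = motif_max_score(m) - 1e-9)
  expect_equal(hits$offset, 5)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, motif_max_score(m), tolerance = 1e-9)

  # threshold -Inf reports 2*(n-L+1) hits minus N-overlapping offsets
  set.seed(11)
  s <- random_dna(80)
  expect_equal(nrow(scan_sequence(s, m, -Inf)), 2 * (80 - L + 1))
  s_n <- paste0(substr(s, 1, 40), "N", substr(s, 42, 80))
  n_blocked <- sum(vapply(0:(80 - L), function(i) i <= 40 && 40 <= i + L - 1,
                          logical(1)))
  expect_equal(nrow(scan_sequence(s_n, m, -Inf)), 2 * (80 - L + 1 - n_blocked))

  # exact agreement with the naive per-offset oracle
  for (i in 1:3) {
    s <- random_dna(60)
    got <- scan_sequence(s, m, threshold = -Inf)
    want <- naive_scan_oracle(s, m)
    want <- want[is.finite(want$score), ]
    want <- want[order(want$offset, want$strand), ]
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("scan hit sets are strand-symmetric under reverse complement", {
  motifs <- read_jaspar(system.file("extdata", "example_motifs.pfm",
                                    package = "coexmotif"))
  m <- motifs$SYN_NRF2
  L <- ncol(m$logodds)
  set.seed(23)
  for (i in 1:20) {
    s <- random_dna(200)
    fwd <- scan_sequence(s, m, threshold = 3)
    rev <- scan_sequence(revcomp_oracle(s), m, threshold = 3)
    # a + hit at offset o maps to a - hit at 200 - o - L, with equal score
    mapped <- data.frame(
      offset = as.integer(200 - fwd$offset - L),
      strand = as.character(ifelse(fwd$strand == "+", "-", "+")),
      score = fwd$score, stringsAsFactors = FALSE)
    mapped <- mapped[order(mapped$offset, mapped$strand), ]
    expect_equal(rev$offset, mapped$offset)
    expect_equal(rev$strand, mapped$strand)
    expect_equal(rev$score, mapped$score, tolerance = 1e-9)
  }
})

test_that("conservation_profile counts column matches with an all-ones fallback", {
  win <- "ACGTACGT"
  expect_equal(conservation_profile(win)$weights, rep(1, 8))
  expect_equal(conservation_profile(win, rep(win, 3))$weights, rep(1, 8))

  orth <- c("ACGTACGT", "ACGAACGT", "AGGTACGT", "AC-TACGT")
  prof <- conservation_profile(win, orth)
  # column 2: orthologs read C, C, G, C -> 3/4 match
  expect_equal(prof$weights[2], 0.75)
  # column 4: T, A, T, T -> 0.75; column 3: G, G, G, - -> 0.75
  expect_equal(prof$weights[3], 0.75)
  # a column where exactly 2 of 4 match
  orth2 <- c("ACGTACGT", "ACGTACGT", "TCGTACGT", "GCGTACGT")
  expect_equal(conservation_profile(win, orth2)$weights[1], 0.5)

  expect_error(conservation_profile(win, "ACGT"), "length")
})

test_that("gene_motif_score takes the best conservation-weighted site", {
  motifs <- read_jaspar(system.file("extdata", "example_motifs.pfm",
                                    package = "coexmotif"))
  m <- motifs$SYN_NRF2
  L <- ncol(m$logodds)

  expect_equal(gene_motif_score(strrep("N", 100), m), 0)

  seq <- paste0("TTTTT", motif_consensus(m), "TTTTT")
  expect_equal(gene_motif_score(seq, m), motif_max_score(m), tolerance = 1e-9)

  # two consensus sites; down-weight the first to 0.5, keep the second at 1:
  # the best weighted site must be the second (max rule, not sum)
  seq2 <- paste0("TT", motif_consensus(m), "TTTT", motif_consensus(m), "TT")
  w <- rep(1, nchar(seq2))
  w[3:(2 + L)] <- 0.5
  prof <- structure(list(weights = w, n_orthologs = 4),
                    class = "ConservationProfile")
  got <- gene_motif_score(seq2, m, prof)
  # independent check by enumerating all offsets with the naive scorer
  naive <- naive_scan_oracle(seq2, m)
  cs <- c(0, cumsum(w))
  wmean <- function(off) (cs[off + L + 1] - cs[off + 1]) / L
  weighted <- naive$score * vapply(naive$offset, wmean, numeric(1))
  expect_equal(got, max(weighted[is.finite(weighted)]), tolerance = 1e-9)
  expect_equal(got, motif_max_score(m), tolerance = 1e-9)

  # reverse-complement invariance when the profile is reversed too
  set.seed(5)
  s <- random_dna(120)
  w <- runif(120)
  p1 <- structure(list(weights = w, n_orthologs = 1), class = "ConservationProfile")
  p2 <- structure(list(weights = rev(w), n_orthologs = 1), class = "ConservationProfile")
  expect_equal(gene_motif_score(s, m, p1),
               gene_motif_score(revcomp_oracle(s), m, p2), tolerance = 1e-9)
})
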