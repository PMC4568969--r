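#' Construct a motif model from a position frequency matrix
#'
#' Converts base counts to a log-odds position weight matrix (bits). With
#' pseudocount `pc` distributed proportionally to the background, the
#' log-odds for base b at column i is
#' `log2(((counts[b,i] + pc * bg[b]) / (colsum_i + pc)) / bg[b])`.
#'
#' @param counts 4 x L nonnegative numeric matrix of base counts; rows in
#'   A, C, G, T order (rownames, if present, are used to reorder).
#' @param motif_id,name Identifiers for the motif.
#' @param pseudocount Nonnegative pseudocount mass added per column,
#'   split proportionally to the background (default 0.8, a common JASPAR
#'   convention).
#' @param background Base probabilities (A, C, G, T) summing to 1; default
#'   uniform.
#' @return An object of class `MotifModel` with elements `motif_id`, `name`,
#'   `counts`, `pseudocount`, `background`, `logodds` (4 x L, bits).
#' @export
motif_model <- function(counts, motif_id, name = motif_id, pseudocount = 0.8,
                        background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), c("A", "C", "G", "T")))
      stop("counts rownames must be A, C, G, T")
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    rownames(counts) <- c("A", "C", "G", "T")
  }
  if (ncol(counts) < 4) stop("motif ", motif_id, ": length must be >= 4")
  if (any(counts < 0)) stop("motif ", motif_id, ": negative counts")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  colsum <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, colsum + pseudocount, "/")
  logodds <- log2(prob / background)
  dimnames(logodds) <- dimnames(counts)
  structure(
    list(motif_id = motif_id, name = name, counts = counts,
         pseudocount = pseudocount, background = background,
         logodds = logodds),
    class = "MotifModel"
  )
}

#' @export
print.MotifModel <- function(x, ...) {
  cat(sprintf("MotifModel %s (%s): L=%d, consensus %s, max score %.2f bits\n",
              x$motif_id, x$name, ncol(x$counts), motif_consensus(x),
              motif_max_score(x)))
  invisible(x)
}

#' Motif consensus string (per-column argmax base)
#' @param motif A `MotifModel`.
#' @return Character consensus of length L.
#' @export
motif_consensus <- function(motif) {
  paste0(rownames(motif$counts)[apply(motif$counts, 2, which.max)], collapse = "")
}

#' Maximum attainable log-odds score (bits): sum of column maxima
#' @param motif A `MotifModel`.
#' @return Numeric scalar.
#' @export
motif_max_score <- function(motif) sum(apply(motif$logodds, 2, max))

#' Read motifs from a JASPAR PFM text file
#'
#' Accepts the JASPAR flat format: a `>` header line (`>ID name`) followed
#' by four count rows, either bare numbers or the bracketed
#' `A [ 4 19 0 ... ]` style. Rows are normalized to A, C, G, T order.
#'
#' @param path Path to the PFM file.
#' @param pseudocount,background Passed to [motif_model()].
#' @return Named list of `MotifModel` objects (names = motif ids).
#' @export
read_jaspar <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0) stop("no JASPAR records ('>' headers) in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  motifs <- lapply(seq_along(starts), function(i) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    fields <- strsplit(header, "\\s+")[[1]]
    motif_id <- fields[1]
    name <- if (length(fields) > 1) paste(fields[-1], collapse = " ") else motif_id
    body <- lines[(starts[i] + 1):ends[i]]
    if (length(body) != 4)
      stop("motif ", motif_id, ": expected 4 count rows, got ", length(body))
    labels <- toupper(sub("^([ACGTacgt])\\s*\\[?.*$", "\\1", body))
    labelled <- all(labels %in% c("A", "C", "G", "T")) && !anyDuplicated(labels)
    rows <- lapply(body, function(line) {
      nums <- regmatches(line, gregexpr("-?[0-9.]+", line))[[1]]
      as.numeric(nums)
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1)
      stop("motif ", motif_id, ": count rows have unequal lengths (",
           paste(lens, collapse = ", "), ")")
    counts <- do.call(rbind, rows)
    rownames(counts) <- if (labelled) labels else c("A", "C", "G", "T")
    motif_model(counts, motif_id, name, pseudocount = pseudocount,
                background = background)
  })
  setNames(motifs, vapply(motifs, `[[`, character(1), "motif_id"))
}

#' Write motifs to a JASPAR PFM text file
#'
#' @param motifs A `MotifModel` or list of them.
#' @param path Output path.
#' @export
write_jaspar <- function(motifs, path) {
  if (inherits(motifs, "MotifModel")) motifs <- list(motifs)
  lines <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s %s", m$motif_id, m$name),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b, paste(format(m$counts[b, ], trim = TRUE),
                                      collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
}

#' Extract TSS-centered promoter windows from a genome
#'
#' For a plus-strand gene the window is the half-open, 0-based genomic
#' interval `[tss - upstream_bp, tss + downstream_bp)`; for a minus-strand
#' gene it is `[tss - downstream_bp, tss + upstream_bp)` reverse-complemented,
#' so the returned sequence always reads 5' to 3' relative to the gene.
#' Windows running off a contig end are clipped with a warning.
#'
#' @param tss_table data.frame with BED-like columns `chrom`, `start`
#'   (= 0-based TSS), `gene`, `strand` (`+` or `-`); see [read_tss_bed()].
#' @param genome Named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param upstream_bp,downstream_bp Window extents in bp (default 10000
#'   each, i.e. a 20 kbp window).
#' @return Named list of `PromoterWindow` objects (names = genes); each is a
#'   list with `gene`, `contig`, `tss`, `strand`, `upstream_bp`,
#'   `downstream_bp`, `start`, `end`, `sequence`.
#' @export
extract_windows <- function(tss_table, genome, upstream_bp = 10000,
                            downstream_bp = 10000) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  needed <- c("chrom", "start", "gene", "strand")
  if (!all(needed %in% names(tss_table)))
    stop("tss_table needs columns: ", paste(needed, collapse = ", "))
  out <- lapply(seq_len(nrow(tss_table)), function(i) {
    row <- tss_table[i, ]
    contig <- as.character(row$chrom)
    if (!contig %in% names(genome)) stop("unknown contig: ", contig)
    clen <- nchar(genome[[contig]])
    tss <- as.integer(row$start)
    if (tss < 0 || tss >= clen)
      stop("gene ", row$gene, ": TSS ", tss, " outside contig ", contig)
    if (row$strand == "+") {
      start <- tss - upstream_bp; end <- tss + downstream_bp
    } else if (row$strand == "-") {
      start <- tss - downstream_bp; end <- tss + upstream_bp
    } else stop("gene ", row$gene, ": strand must be '+' or '-'")
    cstart <- max(0L, start); cend <- min(clen, end)
    if (cstart != start || cend != end)
      warning("gene ", row$gene, ": window clipped to contig bounds [",
              cstart, ", ", cend, ")")
    seq <- substr(genome[[contig]], cstart + 1, cend)
    if (row$strand == "-") seq <- revcomp(seq)
    structure(
      list(gene = as.character(row$gene), contig = contig, tss = tss,
           strand = as.character(row$strand), upstream_bp = upstream_bp,
           downstream_bp = downstream_bp, start = cstart, end = cend,
           sequence = toupper(seq)),
      class = "PromoterWindow"
    )
  })
  setNames(out, vapply(out, `[[`, character(1), "gene"))
}

#' Read a BED-like TSS table
#'
#' Expects at least six tab-separated columns: chrom, start (the 0-based
#' TSS), end, gene name, score, strand. Extra columns are ignored.
#'
#' @param path Path to the BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`, `score`,
#'   `strand`.
#' @export
read_tss_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 6) stop("BED TSS table needs 6 columns")
  setNames(tab[, 1:6], c("chrom", "start", "end", "gene", "score", "strand"))
}

# Per-offset log-odds scores on both strands. Returns a 2-column matrix
# (fwd, rev) with one row per 0-based offset; offsets overlapping a
# non-ACGT base score -Inf. The reverse strand is scored by scanning with
# the reverse-complemented PWM, which is exact and avoids copying sequence.
score_offsets <- function(sequence, motif) {
  lo <- motif$logodds
  L <- ncol(lo)
  codes <- dna_codes(sequence)
  n <- length(codes) - L + 1
  if (n < 1) return(matrix(numeric(0), nrow = 0, ncol = 2,
                           dimnames = list(NULL, c("fwd", "rev"))))
  lo_rc <- lo[4:1, L:1, drop = FALSE]
  fwd <- numeric(n); rev <- numeric(n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1)]
    fwd <- fwd + lo[, j][cj]
    rev <- rev + lo_rc[, j][cj]
  }
  fwd[is.na(fwd)] <- -Inf
  rev[is.na(rev)] <- -Inf
  cbind(fwd = fwd, rev = rev)
}

#' Scan a sequence for motif hits above a score threshold
#'
#' Scores every offset on both strands with the motif's log-odds matrix and
#' reports those at or above `threshold`. Minus-strand scores are the
#' log-odds of the reverse complement of the L-mer at that offset. Offsets
#' overlapping an N never score (treated as -Inf).
#'
#' @param window A `PromoterWindow` or a plain DNA character string.
#' @param motif A `MotifModel`.
#' @param threshold Score threshold in bits (`-Inf` reports every scorable
#'   offset).
#' @param profile Optional conservation profile (see
#'   [conservation_profile()]); when supplied, each hit's
#'   `conservation_weight` is the mean profile weight over the site span.
#' @return data.frame `offset` (0-based), `strand`, `score`,
#'   `conservation_weight`, ordered by offset then strand.
#' @export
scan_sequence <- function(window, motif, threshold, profile = NULL) {
  sequence <- if (inherits(window, "PromoterWindow")) window$sequence else window
  sc <- score_offsets(sequence, motif)
  L <- ncol(motif$logodds)
  n <- nrow(sc)
  if (n == 0)
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), conservation_weight = numeric(0)))
  w <- site_weights(profile, nchar(sequence), L)
  hits <- data.frame(
    offset = rep(0:(n - 1), 2L),
    strand = rep(c("+", "-"), each = n),
    score = c(sc[, "fwd"], sc[, "rev"]),
    conservation_weight = rep(w, 2L),
    stringsAsFactors = FALSE
  )
  hits <- hits[hits$score >= threshold & is.finite(hits$score), , drop = FALSE]
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Mean conservation weight over each site span [i, i+L) via cumulative sums;
# all ones when no profile is supplied.
site_weights <- function(profile, seq_len, L) {
  n <- seq_len - L + 1
  if (is.null(profile)) return(rep(1, n))
  w <- if (is.list(profile)) profile$weights else profile
  if (length(w) != seq_len)
    stop("conservation profile length (", length(w),
         ") does not match sequence length (", seq_len, ")")
  cs <- c(0, cumsum(w))
  (cs[(1:n) + L] - cs[1:n]) / L
}

#' Per-position conservation profile from aligned ortholog sequences
#'
#' The weight at position i is the fraction of ortholog sequences whose base
#' matches the window base at i; gaps (`-`) and N count as mismatches. With
#' no orthologs the profile is all ones, so downstream scoring degrades
#' gracefully to unweighted scanning.
#'
#' @param window A `PromoterWindow` or DNA character string.
#' @param orthologs Character vector (or `DNAStringSet`) of sequences
#'   aligned to the window (equal length; gap character allowed).
#' @return Object of class `ConservationProfile`: list with `weights`
#'   (numeric in `[0, 1]`, one per window position) and `n_orthologs`.
#' @export
conservation_profile <- function(window, orthologs = character(0)) {
  sequence <- if (inherits(window, "PromoterWindow")) window$sequence else window
  if (inherits(orthologs, "DNAStringSet")) orthologs <- as.character(orthologs)
  len <- nchar(sequence)
  if (length(orthologs) == 0) {
    weights <- rep(1, len)
  } else {
    if (any(nchar(orthologs) != len))
      stop("ortholog sequences must match the window length (", len, ")")
    ref <- strsplit(toupper(sequence), "")[[1]]
    informative <- ref %in% c("A", "C", "G", "T")
    match_count <- numeric(len)
    for (o in orthologs) {
      ob <- strsplit(toupper(o), "")[[1]]
      match_count <- match_count + (ob == ref & informative)
    }
    weights <- match_count / length(orthologs)
  }
  structure(list(weights = weights, n_orthologs = length(orthologs)),
            class = "ConservationProfile")
}

#' Aggregate conservation-weighted motif score for one gene's window
#'
#' The gene-level statistic fed into enrichment: the best single site in the
#' window, where each candidate site's log-odds score is multiplied by the
#' mean conservation weight over its span. Windows with no positive-scoring
#' site score 0 by convention. A sum-of-top-k aggregate is exposed for
#' sensitivity analysis.
#'
#' @param window A `PromoterWindow` or DNA character string.
#' @param motif A `MotifModel`.
#' @param profile Optional [conservation_profile()]; all-ones when omitted.
#' @param aggregate `"max"` (default: best weighted site) or `"sum_top_k"`.
#' @param k Number of sites summed when `aggregate = "sum_top_k"`.
#' @return Numeric scalar score (bits).
#' @export
gene_motif_score <- function(window, motif, profile = NULL,
                             aggregate = c("max", "sum_top_k"), k = 3) {
  aggregate <- match.arg(aggregate)
  sequence <- if (inherits(window, "PromoterWindow")) window$sequence else window
  sc <- score_offsets(sequence, motif)
  if (nrow(sc) == 0) return(0)
  w <- site_weights(profile, nchar(sequence), ncol(motif$logodds))
  weighted <- c(sc[, "fwd"], sc[, "rev"]) * rep(w, 2L)
  weighted[!is.finite(weighted)] <- -Inf   # N-overlapping offsets never score
  pos <- weighted[weighted > 0]
  if (length(pos) == 0) return(0)
  if (aggregate == "max") max(pos) else sum(sort(pos, decreasing = TRUE)[seq_len(min(k, length(pos)))])
}

#' Score a universe of promoter windows against a motif family
#'
#' Convenience wrapper producing the motif x gene score matrix consumed by
#' [run_enrichment_matrix()].
#'
#' @param windows Named list of `PromoterWindow` objects (or named character
#'   vector of sequences), one per gene.
#' @param motifs Named list of `MotifModel` objects.
#' @param profiles Optional named list of conservation profiles keyed by
#'   gene.
#' @param ... Passed to [gene_motif_score()].
#' @return Numeric matrix, motifs in rows, genes in columns.
#' @export
score_gene_universe <- function(windows, motifs, profiles = NULL, ...) {
  if (inherits(motifs, "MotifModel")) motifs <- setNames(list(motifs), motifs$motif_id)
  genes <- names(windows)
  if (is.null(genes)) stop("windows must be named by gene")
  scores <- vapply(genes, function(g) {
    prof <- if (is.null(profiles)) NULL else profiles[[g]]
    vapply(motifs, function(m) gene_motif_score(windows[[g]], m, prof, ...),
           numeric(1))
  }, numeric(length(motifs)))
  if (length(motifs) == 1) scores <- matrix(scores, nrow = 1)
  rownames(scores) <- names(motifs)
  colnames(scores) <- genes
  scores
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
}
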