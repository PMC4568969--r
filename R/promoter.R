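#' Find exact IUPAC consensus matches in a sequence
#'
#' Reports every (overlapping) exact match of an IUPAC consensus pattern on
#' the forward strand and, when `both_strands`, of its reverse complement
#' (reported as a minus-strand site at its forward-strand offset). An N in
#' the sequence never matches any pattern position.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @param pattern IUPAC consensus string (e.g. the ETS/NRF-2 core
#'   `"CCGGAA"`).
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return data.frame `offset` (0-based, forward coordinates), `strand`,
#'   ordered by offset then strand.
#' @export
#' @examples
#' find_consensus_sites("TTCCGGAATT", "CCGGAA")
find_consensus_sites <- function(sequence, pattern, both_strands = TRUE) {
  if (!nzchar(pattern)) stop("empty pattern")
  sequence <- toupper(sequence)
  fwd <- regex_offsets(sequence, iupac_to_regex(pattern))
  out <- data.frame(offset = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- regex_offsets(sequence, iupac_to_regex(revcomp(pattern)))
    out <- rbind(out, data.frame(offset = rev, strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect tandem (co-oriented, closely spaced) site pairs
#'
#' Every ordered pair of non-overlapping sites on the same strand whose
#' spacer (gap between the first site's end and the second site's start) is
#' at most `max_spacer_bp`. The pair's span runs from the first site's start
#' to the second site's end, so two 6-bp sites separated by a 14-bp spacer
#' span 26 bp.
#'
#' @param sites data.frame of sites from [find_consensus_sites()] (columns
#'   `offset`, `strand`), sorted by offset.
#' @param pattern_length Site length in bp.
#' @param max_spacer_bp Maximum spacer (default 50 bp).
#' @return data.frame `first_offset`, `second_offset`, `strand`,
#'   `spacer_bp`, `span_bp`.
#' @export
find_tandem_pairs <- function(sites, pattern_length, max_spacer_bp = 50) {
  out <- data.frame(first_offset = integer(0), second_offset = integer(0),
                    strand = character(0), spacer_bp = integer(0),
                    span_bp = integer(0), stringsAsFactors = FALSE)
  n <- nrow(sites)
  if (n < 2) return(out)
  sites <- sites[order(sites$offset), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sites$strand[i] != sites$strand[j]) next
      spacer <- sites$offset[j] - (sites$offset[i] + pattern_length)
      if (spacer < 0) next                 # overlapping sites excluded
      if (spacer > max_spacer_bp) next
      out <- rbind(out, data.frame(
        first_offset = sites$offset[i], second_offset = sites$offset[j],
        strand = sites$strand[i], spacer_bp = spacer,
        span_bp = 2L * pattern_length + spacer, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Design a substitution mutant over consensus sites
#'
#' Applies the same fixed-length substitution (e.g. the double transversion
#' CCGGAA -> CCTTAA that ablates an NRF-2/ETS site) at every supplied site.
#' Minus-strand sites are edited through the reverse complement, so the
#' substitution always acts on the site as read on its own strand. The
#' per-base edits actually introduced are recorded, and the consensus is
#' re-scanned before and after to count surviving sites.
#'
#' @param sequence Wild-type DNA string.
#' @param sites data.frame of sites (`offset`, `strand`), e.g. from
#'   [find_consensus_sites()]; every site must currently match `from`.
#' @param from,to Equal-length subpatterns; `from` is the site consensus
#'   being replaced (plain ACGT for `to`).
#' @return Object of class `MutantDesign`: list with `kind =
#'   "substitution"`, `sequence` (mutant), `edits` (data.frame `position`
#'   (0-based), `from_base`, `to_base`), `sites_before`, `sites_after`.
#' @export
design_double_transversion <- function(sequence, sites, from = "CCGGAA",
                                       to = "CCTTAA") {
  if (nchar(from) != nchar(to)) stop("from and to must have equal length")
  sequence <- toupper(sequence)
  L <- nchar(from)
  sites_before <- nrow(find_consensus_sites(sequence, from))
  mutant <- sequence
  edits <- list()
  for (i in seq_len(nrow(sites))) {
    off <- sites$offset[i]
    strand <- sites$strand[i]
    current <- substr(mutant, off + 1, off + L)
    site_seq <- if (strand == "-") revcomp(current) else current
    if (!grepl(paste0("^", iupac_to_regex(from), "$"), site_seq, perl = TRUE))
      stop("site at offset ", off, " (", strand,
           ") does not match the from-pattern ", from)
    replacement <- if (strand == "-") revcomp(to) else to
    for (j in seq_len(L)) {
      old_b <- substr(current, j, j)
      new_b <- substr(replacement, j, j)
      if (old_b != new_b)
        edits[[length(edits) + 1]] <- data.frame(
          position = off + j - 1L, from_base = old_b, to_base = new_b,
          stringsAsFactors = FALSE)
    }
    substr(mutant, off + 1, off + L) <- replacement
  }
  edits <- if (length(edits)) do.call(rbind, edits) else
    data.frame(position = integer(0), from_base = character(0),
               to_base = character(0), stringsAsFactors = FALSE)
  structure(
    list(kind = "substitution", sequence = mutant, edits = edits,
         sites_before = sites_before,
         sites_after = nrow(find_consensus_sites(mutant, from))),
    class = "MutantDesign"
  )
}

#' Design a deletion mutant removing a tandem site pair
#'
#' Deletes both sites and the intervening spacer: the half-open span from
#' the first site's start to the second site's end (e.g. 26 bases for two
#' 6-bp sites with a 14-bp spacer).
#'
#' @param sequence Wild-type DNA string.
#' @param pair One row of [find_tandem_pairs()] output (or a list with
#'   `first_offset` and `span_bp`).
#' @param pattern Optional consensus pattern; when given, sites are counted
#'   before and after by re-scanning.
#' @return Object of class `MutantDesign`: list with `kind = "deletion"`,
#'   `sequence` (mutant), `deleted_span` (`start`, `end`, 0-based
#'   half-open), `span_bp`, `sites_before`, `sites_after`.
#' @export
design_deletion <- function(sequence, pair, pattern = NULL) {
  sequence <- toupper(sequence)
  start <- as.integer(pair$first_offset)
  end <- start + as.integer(pair$span_bp)
  if (start < 0 || end > nchar(sequence))
    stop("deletion span [", start, ", ", end, ") outside the sequence")
  mutant <- paste0(substr(sequence, 1, start), substr(sequence, end + 1, nchar(sequence)))
  counts <- c(NA_integer_, NA_integer_)
  if (!is.null(pattern)) {
    counts <- c(nrow(find_consensus_sites(sequence, pattern)),
                nrow(find_consensus_sites(mutant, pattern)))
  }
  structure(
    list(kind = "deletion", sequence = mutant,
         deleted_span = c(start = start, end = end),
         span_bp = end - start,
         sites_before = counts[1], sites_after = counts[2]),
    class = "MutantDesign"
  )
}

#' @export
print.MutantDesign <- function(x, ...) {
  if (x$kind == "substitution") {
    cat(sprintf("MutantDesign (substitution): %d base edit(s), sites %d -> %d\n",
                nrow(x$edits), x$sites_before, x$sites_after))
  } else {
    cat(sprintf("MutantDesign (deletion): %d bp removed [%d, %d), sites %s -> %s\n",
                x$span_bp, x$deleted_span["start"], x$deleted_span["end"],
                x$sites_before, x$sites_after))
  }
  invisible(x)
}

#' Cross-species promoter conservation report
#'
#' Given equal-length aligned promoter sequences (first one the reference by
#' default), computes the per-column identity fraction (share of
#' non-reference sequences matching the reference base; gaps and N count as
#' mismatches) and slides a window of width `window_bp` to find the
#' best-conserved region. Ties go to the leftmost window.
#'
#' @param sequences Named character vector of aligned sequences (>= 2).
#' @param window_bp Window width in bp (default 26, the span of a tandem
#'   site pair).
#' @param reference Name or index of the reference sequence (default 1).
#' @return List with `per_column` (data.frame `position` (0-based),
#'   `identity`), `best_window` (list `start`, `end`, `mean_identity`), and
#'   `window_means` (numeric vector of sliding means).
#' @export
conservation_report <- function(sequences, window_bp = 26, reference = 1) {
  if (length(sequences) < 2)
    stop("need the reference plus at least one other sequence")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) stop("aligned sequences must have equal length")
  len <- lens[[1]]
  if (window_bp > len) stop("window_bp exceeds the alignment length")
  ref_idx <- if (is.character(reference)) match(reference, names(sequences)) else reference
  if (is.na(ref_idx)) stop("reference sequence not found: ", reference)
  identity <- conservation_profile(sequences[[ref_idx]],
                                   unname(sequences[-ref_idx]))$weights
  cs <- c(0, cumsum(identity))
  n_win <- len - window_bp + 1
  window_means <- (cs[(1:n_win) + window_bp] - cs[1:n_win]) / window_bp
  best <- which.max(window_means)          # which.max is leftmost on ties
  list(per_column = data.frame(position = 0:(len - 1), identity = identity),
       best_window = list(start = best - 1L, end = best - 1L + window_bp,
                          mean_identity = window_means[best]),
       window_means = window_means)
}
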