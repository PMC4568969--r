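#' @importFrom stats cor p.adjust phyper pt rnorm runif sd setNames t.test
#' @importFrom utils combn read.delim write.table head
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded helpers never perturb the global stream.
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors; IUPAC ambiguity codes are complemented correctly.
#'
#' @param x Character vector of DNA strings (IUPAC alphabet).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CCGGAA")
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# IUPAC code -> set of concrete bases it matches (N in a *sequence* is never
# matched: the classes below contain A/C/G/T only).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Translate an IUPAC pattern into a PCRE character-class regex.
iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("pattern contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  paste0(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Encode a DNA string as integer codes A=1, C=2, G=3, T=4; anything else
# (N, gaps) becomes NA. Fast path via utf8ToInt.
dna_codes <- function(sequence) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("ACGT")] <- 1:4
  lut[utf8ToInt("acgt")] <- 1:4
  lut[utf8ToInt(sequence)]
}

# 0-based offsets of every (overlapping) match of a regex in a string.
regex_offsets <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
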