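#' Reference-gene relative expression from qPCR Ct values
#'
#' The delta-delta-Ct reduction with amplification efficiency fixed at 2:
#' per sample, `dCt = Ct(gene) - Ct(reference)`; per gene and condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)` and
#' `fold = 2^(-ddCt)`. Significance per gene/condition is a two-tailed
#' pooled-variance Student t-test on the dCt values against the control
#' condition.
#'
#' @param table data.frame with columns `sample`, `condition`, `gene`,
#'   `ct` (cycles, > 0). Every sample must include the reference gene.
#' @param reference_gene Reference gene symbol (e.g. `"B2M"`).
#' @param control_condition Condition label used as the fold-change
#'   baseline.
#' @return data.frame `gene`, `condition`, `fold_change`, `p_value`
#'   (NA for the control condition itself, where fold is 1 by definition).
#' @export
relative_expression <- function(table, reference_gene, control_condition) {
  needed <- c("sample", "condition", "gene", "ct")
  if (!all(needed %in% names(table)))
    stop("table needs columns: ", paste(needed, collapse = ", "))
  if (any(table$ct <= 0)) stop("Ct values must be positive")
  if (!control_condition %in% table$condition)
    stop("control condition not present: ", control_condition)
  ref <- table[table$gene == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0) stop("reference gene not present: ", reference_gene)
  ref_ct <- setNames(ref$ct, ref$sample)
  targets <- table[table$gene != reference_gene, , drop = FALSE]
  if (anyNA(ref_ct[targets$sample]))
    stop("missing reference Ct for sample(s): ",
         paste(unique(targets$sample[is.na(ref_ct[targets$sample])]), collapse = ", "))
  targets$dct <- targets$ct - ref_ct[targets$sample]
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(gt) {
    ctrl_dct <- gt$dct[gt$condition == control_condition]
    if (length(ctrl_dct) == 0)
      stop("gene ", gt$gene[1], ": no control-condition measurements")
    do.call(rbind, lapply(split(gt, gt$condition), function(cc) {
      ddct <- mean(cc$dct) - mean(ctrl_dct)
      is_ctrl <- cc$condition[1] == control_condition
      p <- if (is_ctrl || length(cc$dct) < 2 || length(ctrl_dct) < 2) NA_real_
           else t.test(cc$dct, ctrl_dct, var.equal = TRUE)$p.value
      data.frame(gene = gt$gene[1], condition = cc$condition[1],
                 fold_change = 2^(-ddct), p_value = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Background-normalized ChIP percent input
#'
#' Within each precipitation (and condition), each target gene's percent
#' input is divided by the percent input of a background gene; the
#' normalized values are then averaged across precipitations with a
#' standard error, and each target is tested (two-tailed pooled-variance
#' Student t) between conditions where two are present.
#'
#' @param table data.frame with columns `precipitation`, `condition`,
#'   `gene`, `percent_input` (>= 0).
#' @param background_gene Background locus symbol (e.g. beta-actin); its
#'   percent input must be positive in every precipitation.
#' @param control_condition Optional condition label to test against; when
#'   omitted and exactly two conditions exist, the first (alphabetically)
#'   is used.
#' @return data.frame `gene`, `condition`, `mean_normalized`, `se`,
#'   `n_precipitations`, `p_value` (vs the control condition; NA where not
#'   testable).
#' @export
chip_normalize <- function(table, background_gene, control_condition = NULL) {
  needed <- c("precipitation", "condition", "gene", "percent_input")
  if (!all(needed %in% names(table)))
    stop("table needs columns: ", paste(needed, collapse = ", "))
  if (any(table$percent_input < 0)) stop("percent input must be nonnegative")
  bg <- table[table$gene == background_gene, , drop = FALSE]
  if (nrow(bg) == 0) stop("background gene not present: ", background_gene)
  if (any(bg$percent_input <= 0))
    stop("background percent input must be positive in every precipitation")
  key <- function(d) paste(d$precipitation, d$condition, sep = "\r")
  bg_pi <- setNames(bg$percent_input, key(bg))
  targets <- table[table$gene != background_gene, , drop = FALSE]
  if (anyNA(bg_pi[key(targets)]))
    stop("missing background measurement for some precipitation/condition")
  targets$normalized <- targets$percent_input / bg_pi[key(targets)]
  conditions <- sort(unique(targets$condition))
  if (is.null(control_condition) && length(conditions) == 2)
    control_condition <- conditions[1]
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(gt) {
    do.call(rbind, lapply(split(gt, gt$condition), function(cc) {
      n <- nrow(cc)
      if (n < 2) stop("gene ", gt$gene[1], ", condition ", cc$condition[1],
                      ": need >= 2 precipitations for a standard error")
      p <- NA_real_
      if (!is.null(control_condition) && cc$condition[1] != control_condition) {
        ctrl <- gt$normalized[gt$condition == control_condition]
        if (length(ctrl) >= 2)
          p <- t.test(cc$normalized, ctrl, var.equal = TRUE)$p.value
      }
      data.frame(gene = gt$gene[1], condition = cc$condition[1],
                 mean_normalized = mean(cc$normalized),
                 se = sd(cc$normalized) / sqrt(n),
                 n_precipitations = n, p_value = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
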