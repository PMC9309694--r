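#' Assign animals to A-ED / NC groups by the ICP/MAP ratio
#'
#' Computes the erectile-function readout `ratio = ICP/MAP` per animal and
#' assigns `A-ED` when the ratio is strictly below the threshold and `NC`
#' when strictly above; animals exactly at the threshold are flagged
#' unassigned (`NA` group), since both groups are defined with strict
#' inequalities.
#'
#' @param records `data.frame` with columns `animal`, `ICP`, `MAP` (mmHg).
#' @param threshold grouping threshold on ICP/MAP (default 0.35).
#' @return `records` with `ratio` and `group` columns added (`group` is `NA`
#'   at the exact threshold).
#' @export
assign_groups <- function(records, threshold = 0.35) {
  stopifnot(all(c("animal", "ICP", "MAP") %in% names(records)))
  if (any(records$MAP <= 0)) {
    stop("non-positive MAP for animal(s): ",
         paste(records$animal[records$MAP <= 0], collapse = ", "))
  }
  records$ratio <- records$ICP / records$MAP
  records$group <- ifelse(records$ratio < threshold, "A-ED",
                          ifelse(records$ratio > threshold, "NC", NA))
  records
}

#' qPCR relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale per (gene, sample);
#' `dCt = Ct_gene - Ct_ref` per sample; `ddCt = dCt - mean(dCt over
#' calibrator-group samples)`; fold change `= 2^-ddCt`. Adding a constant to
#' all Ct values of a sample cancels out under the reference normalization.
#'
#' @param plate a `QPCRPlate` ([simulate_qpcr()]) or a long `data.frame`
#'   with columns `gene`, `sample`, `group`, `replicate`, `ct`.
#' @param gene target gene id.
#' @param ref_gene reference gene id (defaults to the plate's, e.g. `Actb`).
#' @param calibrator calibrator group id (defaults to the plate's, e.g. `NC`).
#' @return A list: `per_sample` data.frame (`sample`, `group`, `dct`, `ddct`,
#'   `fold_change`) and `group_means` (mean fold change per group).
#' @export
ddct_fold_change <- function(plate, gene, ref_gene = NULL, calibrator = NULL) {
  if (inherits(plate, "QPCRPlate")) {
    if (is.null(ref_gene)) ref_gene <- plate$ref_gene
    if (is.null(calibrator)) calibrator <- plate$calibrator
    ct <- plate$ct
  } else {
    ct <- plate
    if (is.null(ref_gene) || is.null(calibrator)) {
      stop("ref_gene and calibrator are required for a raw Ct table")
    }
  }
  stopifnot(all(c("gene", "sample", "group", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) stop("Ct values must be finite and positive")
  avg <- stats::aggregate(ct ~ gene + sample + group, data = ct, FUN = mean)
  samples <- unique(avg$sample)
  g_ct <- avg[avg$gene == gene, , drop = FALSE]
  r_ct <- avg[avg$gene == ref_gene, , drop = FALSE]
  no_ref <- setdiff(samples, r_ct$sample)
  if (length(no_ref)) {
    stop("reference gene ", ref_gene, " missing for sample(s): ",
         paste(no_ref, collapse = ", "))
  }
  if (nrow(g_ct) == 0) stop("no Ct values for gene ", gene)
  dct <- g_ct$ct - r_ct$ct[match(g_ct$sample, r_ct$sample)]
  grp <- g_ct$group
  if (!calibrator %in% grp) stop("no samples in calibrator group ", calibrator)
  ddct <- dct - mean(dct[grp == calibrator])
  per_sample <- data.frame(sample = g_ct$sample, group = grp,
                           dct = dct, ddct = ddct,
                           fold_change = 2^(-ddct), stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       group_means = tapply(per_sample$fold_change, per_sample$group, mean))
}

#' Two-group comparison (Welch t or Mann-Whitney)
#'
#' `mode = "t"` runs a two-sided Welch (unequal-variance) t-test;
#' `mode = "mann-whitney"` a two-sided Wilcoxon rank-sum test, exact when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie/continuity correction. `mode = "auto"`
#' picks the t-test iff a Shapiro-Wilk test does not reject normality at
#' alpha = 0.05 in both groups (each group needs n >= 3 for the screen).
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param mode one of `"auto"`, `"t"`, `"mann-whitney"`.
#' @return A list: `statistic`, `p`, `method`.
#' @export
compare_groups <- function(a, b, mode = c("auto", "t", "mann-whitney")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (mode == "auto") {
    if (length(a) < 3 || length(b) < 3) {
      stop("auto mode needs n >= 3 per group for the normality screen")
    }
    normal <- function(v) stats::sd(v) > 0 && stats::shapiro.test(v)$p.value >= 0.05
    mode <- if (normal(a) && normal(b)) "t" else "mann-whitney"
  }
  if (mode == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("both groups are constant")
    res <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(res$statistic), p = res$p.value, method = "welch-t")
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- (length(a) + length(b)) <= 20 && !ties
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    list(statistic = unname(res$statistic), p = res$p.value,
         method = if (exact) "mann-whitney-exact" else "mann-whitney-normal")
  }
}
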