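#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors in the TMM style: the reference is the
#' sample whose 75th percentile of CPM is closest to the mean of those
#' percentiles; each sample's factor is a precision-weighted mean of
#' log2-ratios (M-values) against the reference after trimming the 30% tails
#' of M and the 5% tails of A (log2 average abundance); factors are
#' renormalized to geometric mean 1.
#'
#' @param x an [expression_matrix()] object with >= 2 samples.
#' @return An object of class `NormalizationFactors`: list with `factors`
#'   (named, geometric mean 1), `lib_size` (raw column sums),
#'   `effective_lib_size` (`lib_size * factors`), `method = "TMM"`,
#'   `ref_sample`.
#' @export
normalization_factors <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  counts <- x$counts
  if (ncol(counts) < 2) stop("at least 2 samples required")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  q75 <- apply(sweep(counts, 2, lib / 1e6, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))

  tmm_one <- function(s) {
    if (s == ref) return(1)
    obs <- counts[, s]; rc <- counts[, ref]
    pos <- obs > 0 & rc > 0
    if (!any(pos)) return(1)
    obs <- obs[pos]; rc <- rc[pos]
    m <- log2((obs / lib[s]) / (rc / lib[ref]))
    a <- 0.5 * log2((obs / lib[s]) * (rc / lib[ref]))
    w <- (lib[s] - obs) / (lib[s] * obs) + (lib[ref] - rc) / (lib[ref] * rc)
    n <- length(m)
    keep <- rank(m, ties.method = "first") > floor(n * 0.30) &
      rank(m, ties.method = "first") <= n - floor(n * 0.30) &
      rank(a, ties.method = "first") > floor(n * 0.05) &
      rank(a, ties.method = "first") <= n - floor(n * 0.05)
    if (!any(keep) || sum(w[keep]) == 0) return(1)
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), tmm_one, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(
    list(factors = f, lib_size = lib,
         effective_lib_size = lib * f,
         method = "TMM", ref_sample = colnames(counts)[ref]),
    class = "NormalizationFactors"
  )
}

# Conditional NB exact two-sided p for group sums ya, yb with NB sizes
# ra = n_a/phi, rb = n_b/phi. Given the total t, Y_a is negative
# hypergeometric (beta-binomial with shape ra, rb); the two-sided p doubles
# the smaller tail, counting the observed outcome once, capped at 1.
nb_exact_p <- function(ya, yb, ra, rb) {
  t <- ya + yb
  if (t == 0) return(1)
  a <- 0:t
  lw <- lchoose(a + ra - 1, a) + lchoose(t - a + rb - 1, t - a)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  cw <- cumsum(w)
  lo <- cw[ya + 1]
  hi <- 1 - if (ya == 0) 0 else cw[ya]
  min(1, 2 * min(lo, hi) - w[ya + 1])
}

#' Negative-binomial exact conditional test for two-group counts
#'
#' Per-feature differential expression between A-ED and NC. Counts are
#' scaled to a common (geometric-mean) effective library size; a common NB
#' dispersion is estimated by method of moments pooled across all features
#' (floored at 1e-8); each feature's group sums are modeled as negative
#' binomial and compared by an exact conditional test given their total (the
#' conditional law is negative hypergeometric, free of the mean under the
#' null). Two-sided p doubles the smaller tail (observed outcome counted
#' once), capped at 1. log2 fold changes (A-ED over NC) use normalized group
#' means with a pseudocount of 0.5; FDR is Benjamini-Hochberg within the RNA
#' class.
#'
#' @param x an [expression_matrix()] object.
#' @param factors optional [normalization_factors()]; computed from `x` when
#'   missing.
#' @return A `data.frame` of per-feature results: `feature_id`, `rna_class`,
#'   `mean_NC`, `mean_AED` (normalized group means), `log2FC`, `p`, `fdr`,
#'   `direction` (`up` = higher in A-ED), `dispersion` (common estimate,
#'   attribute also), `tested` (FALSE when a group has a single sample, in
#'   which case p is set to 1).
#' @export
exact_test <- function(x, factors = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(factors)) factors <- normalization_factors(x)
  stopifnot(inherits(factors, "NormalizationFactors"))
  eff <- factors$effective_lib_size[colnames(x$counts)]
  scale_to <- exp(mean(log(eff)))
  norm <- sweep(x$counts, 2, scale_to / eff, "*")
  pseudo <- round(norm)
  grp <- x$groups
  ia <- which(grp == "A-ED"); ib <- which(grp == "NC")
  na <- length(ia); nb <- length(ib)

  # pooled method-of-moments common dispersion on pseudo-counts
  mom <- function(idx) {
    m <- rowMeans(pseudo[, idx, drop = FALSE])
    v <- apply(pseudo[, idx, drop = FALSE], 1, stats::var)
    ok <- m > 0
    c(num = sum(v[ok] - m[ok]), den = sum(m[ok]^2))
  }
  disp <- 1e-8
  if (na >= 2 && nb >= 2) {
    s <- mom(ia) + mom(ib)
    disp <- max(1e-8, s[["num"]] / s[["den"]])
  }

  ya <- round(rowSums(pseudo[, ia, drop = FALSE]))
  yb <- round(rowSums(pseudo[, ib, drop = FALSE]))
  tested <- na >= 2 && nb >= 2
  if (tested) {
    ra <- na / disp; rb <- nb / disp
    p <- vapply(seq_len(nrow(pseudo)),
                function(f) nb_exact_p(ya[f], yb[f], ra, rb), numeric(1))
  } else {
    p <- rep(1, nrow(pseudo))
  }
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  out <- data.frame(
    feature_id = rownames(x$counts),
    rna_class = x$rna_class,
    mean_NC = mean_b,
    mean_AED = mean_a,
    log2FC = log2fc,
    p = p,
    fdr = stats::p.adjust(p, method = "BH"),
    direction = ifelse(log2fc >= 0, "up", "down"),
    tested = tested,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dispersion") <- disp
  out
}

#' Differential-expression filter
#'
#' Keeps features with `|log2FC| > lfc_threshold` and `basis < p_threshold`,
#' both strict inequalities.
#'
#' @param results an [exact_test()] result table.
#' @param lfc_threshold log2 fold-change threshold (default 2, the
#'   miRNA/mRNA selection rule).
#' @param p_threshold significance threshold (default 0.05).
#' @param basis filter on raw `"p"` (default, as the selection criteria
#'   state) or on `"fdr"` (the volcano-plot ordinate).
#' @return The subset of `results` passing the filter.
#' @export
apply_de_filter <- function(results, lfc_threshold = 2, p_threshold = 0.05,
                            basis = c("p", "fdr")) {
  basis <- match.arg(basis)
  keep <- abs(results$log2FC) > lfc_threshold & results[[basis]] < p_threshold
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate lncRNA selection window for qPCR validation
#'
#' Applies the validation inclusion criteria for lncRNAs: mean raw count
#' across all samples strictly between `count_range[1]` and
#' `count_range[2]`, fold change > 2 (`|log2FC| > 1`), and `p <
#' p_threshold` — all strict.
#'
#' @param results an [exact_test()] result table for the lncRNA class.
#' @param x the [expression_matrix()] the results were computed on.
#' @param count_range open interval for the mean raw count (default (1, 120)).
#' @param p_threshold significance threshold (default 0.05).
#' @return The qualifying subset of `results` with a `mean_count` column
#'   (mean raw count over all samples) appended.
#' @export
select_candidate_lncrnas <- function(results, x, count_range = c(1, 120),
                                     p_threshold = 0.05) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  mc <- rowMeans(x$counts)[results$feature_id]
  keep <- mc > count_range[1] & mc < count_range[2] &
    abs(results$log2FC) > 1 & results$p < p_threshold
  out <- results[keep, , drop = FALSE]
  out$mean_count <- unname(mc[keep])
  rownames(out) <- NULL
  out
}
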