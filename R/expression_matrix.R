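#' Expression matrix for one RNA class
#'
#' A light container (in the spirit of edgeR's `DGEList`) holding integer
#' counts for one RNA class over named samples with a two-group design
#' (`"A-ED"` vs `"NC"`), plus optional feature lengths for FPKM.
#'
#' @param counts integer matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @param groups character or factor of length `ncol(counts)` with values in
#'   `{"A-ED", "NC"}`.
#' @param rna_class one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @param lengths optional numeric vector of feature lengths in bp, named or
#'   in row order, required by [fpkm()].
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts`, `groups` (factor with levels `NC`, `A-ED`), `rna_class`,
#'   `lengths`.
#' @export
expression_matrix <- function(counts, groups, rna_class = c("lncRNA", "miRNA", "mRNA"),
                              lengths = NULL) {
  rna_class <- match.arg(rna_class)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  dup_f <- unique(rownames(counts)[duplicated(rownames(counts))])
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_f)) stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  if (length(dup_s)) stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (max(counts) <= .Machine$integer.max) storage.mode(counts) <- "integer"
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  bad <- setdiff(unique(groups), c("A-ED", "NC"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (length(unique(groups)) < 2) stop("both groups (A-ED and NC) must be represented")
  if (!is.null(lengths)) {
    if (!is.null(names(lengths))) {
      missing <- setdiff(rownames(counts), names(lengths))
      if (length(missing)) stop("lengths missing for features: ", paste(missing, collapse = ", "))
      lengths <- lengths[rownames(counts)]
    } else if (length(lengths) != nrow(counts)) {
      stop("lengths must be named or match the number of features")
    }
    if (any(lengths <= 0)) stop("feature lengths must be positive")
    names(lengths) <- rownames(counts)
  }
  structure(
    list(
      counts = counts,
      groups = factor(groups, levels = c("NC", "A-ED")),
      rna_class = rna_class,
      lengths = lengths
    ),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d %s features x %d samples (%d A-ED, %d NC)\n",
    nrow(x$counts), x$rna_class, ncol(x$counts),
    sum(x$groups == "A-ED"), sum(x$groups == "NC")
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Subset an ExpressionMatrix by feature ids
#'
#' @param x an [expression_matrix()] object.
#' @param features character vector of feature ids to keep.
#' @return An `ExpressionMatrix` restricted to `features`.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(features, rownames(x$counts))
  if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
  x$counts <- x$counts[features, , drop = FALSE]
  if (!is.null(x$lengths)) x$lengths <- x$lengths[features]
  x
}

#' Counts per million
#'
#' Library-size-normalized expression, optionally using effective library
#' sizes from [normalization_factors()].
#'
#' @param x an [expression_matrix()] object.
#' @param factors optional `NormalizationFactors` from [normalization_factors()];
#'   when supplied, effective library sizes (raw size x scaling factor) are used.
#' @param log if `TRUE`, return `log2(CPM + 1)`.
#' @return Numeric matrix of the same shape as `x$counts`.
#' @export
cpm <- function(x, factors = NULL, log = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lib <- colSums(x$counts)
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "NormalizationFactors"))
    lib <- factors$effective_lib_size[colnames(x$counts)]
  }
  out <- sweep(x$counts, 2, lib / 1e6, "/")
  if (log) log2(out + 1) else out
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM_gs = counts_gs * 1e9 / (length_g * total_mapped_s)` where
#' `total_mapped_s` is the column sum of counts.
#'
#' @param x an [expression_matrix()] object with feature `lengths` set.
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$lengths)) {
    stop("feature lengths required for FPKM; none present for: ",
         paste(utils::head(rownames(x$counts), 3), collapse = ", "), ", ...")
  }
  lib <- colSums(x$counts)
  if (any(lib == 0)) stop("all-zero sample(s): ",
                          paste(colnames(x$counts)[lib == 0], collapse = ", "))
  sweep(x$counts / x$lengths, 2, lib / 1e9, "/")
}
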