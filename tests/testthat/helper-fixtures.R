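# Shared fixtures built in code.

small_matrix <- function(counts, groups = c("A-ED", "A-ED", "A-ED", "NC", "NC", "NC"),
                         rna_class = "mRNA", lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("f%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  expression_matrix(counts, groups, rna_class, lengths = lengths)
}

# Exhaustive-draw oracle for the hypergeometric upper tail: enumerate every
# size-n subset of a universe with K marked items and count overlaps >= x.
hyper_tail_by_enumeration <- function(x, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the marked ones
  sum(hits >= x) / ncol(draws)
}

# Rank/moment re-computation of the correlations, independent of stats::cor.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
midrank <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  r
}
naive_spearman <- function(x, y) naive_pearson(midrank(x), midrank(y))

pair_f1 <- function(result, truth) {
  truth_keys <- paste(truth$planted_pairs$lncrna, truth$planted_pairs$mrna)
  got <- paste(result$pairs$lncrna[result$pairs$retained],
               result$pairs$mrna[result$pairs$retained])
  tp <- sum(got %in% truth_keys)
  if (length(got) == 0 || length(truth_keys) == 0) return(0)
  prec <- tp / length(got); rec <- tp / length(truth_keys)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
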