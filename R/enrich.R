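#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact test per gene set: with a universe of `U` genes,
#' `m` of them in the set and a query of `q` genes of which `k` hit the set,
#' the p-value is the hypergeometric upper tail `P[X >= k]` — the same tail
#' implementation as the ceRNA [sponge_test()]. BH FDR is computed across
#' sets; results are sorted by ascending p with set id as the tie-break, and
#' the top `top` rows are returned (the conventional report shows the top 20
#' per collection).
#'
#' @param query character vector of gene ids (must lie within `universe`).
#' @param collection a `GeneSetCollection` ([read_gmt()] /
#'   [simulate_gene_sets()]); sets are intersected with the universe.
#' @param universe character vector of gene ids (e.g. all mRNAs in the
#'   expression matrix).
#' @param top number of top results to return (default 20; `Inf` for all).
#' @return A `data.frame`: `set_id`, `description`, `k`, `m`, `q`, `U`, `p`,
#'   `fdr`, `hits` (semicolon-separated ids).
#' @export
enrich <- function(query, collection, universe, top = 20) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) stop("empty query")
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  U <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    hits <- intersect(query, members)
    m <- length(members)
    k <- length(hits)
    p <- if (m == 0) 1 else hyper_upper_tail(k, K = m, n = q, N = U)
    data.frame(set_id = id,
               description = unname(collection$descriptions[id]),
               k = k, m = m, q = q, U = U, p = p,
               hits = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  out <- out[c("set_id", "description", "k", "m", "q", "U", "p", "fdr", "hits")]
  rownames(out) <- NULL
  utils::head(out, top)
}
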