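#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `x` marked items when `n` items are drawn
#' without replacement from a universe of `N` items of which `K` are marked:
#' \deqn{P[X \ge x] = \sum_{i=x}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' This single tail implementation backs both the ceRNA shared-sponge test
#' ([sponge_test()]) and gene-set over-representation ([enrich()]).
#'
#' The sum is evaluated on the log scale with [lchoose()] for numerical
#' stability at large `N`.
#'
#' @param x integer, observed overlap (number of marked items drawn).
#' @param K integer, number of marked items in the universe.
#' @param n integer, number of items drawn.
#' @param N integer, universe size.
#' @return `P[X >= x]`, a probability in `[0, 1]`.
#' @examples
#' hyper_upper_tail(3, K = 4, n = 5, N = 10)  # 66/252
#' @export
hyper_upper_tail <- function(x, K, n, N) {
  stopifnot(length(x) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(x, K, n, N) < 0) || any(c(x, K, n, N) != round(c(x, K, n, N)))) {
    stop("x, K, n, N must be non-negative integers")
  }
  if (K > N || n > N) {
    stop("inconsistent counts: K and n must not exceed the universe size N")
  }
  if (x > min(K, n)) {
    stop("inconsistent counts: x exceeds min(K, n)")
  }
  if (x <= max(0, K + n - N)) {
    return(1)  # overlap of at least x is forced
  }
  i <- x:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(lt)))
}
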