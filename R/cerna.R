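#' Correlation records for expression screening
#'
#' `spearman_cor` is the Pearson correlation of mid-ranks (average ranks for
#' ties); `pearson_cor` is the sample moment correlation. Constant input
#' makes the correlation undefined: the record is flagged (`defined = FALSE`,
#' value `NA`) and such pairs are treated as failing any screen rather than
#' erroring a run.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list of class `CorrelationRecord`: `kind` (`"SCC"`/`"PCC"`),
#'   `value`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) cor_record(x, y, "SCC")

#' @rdname spearman_cor
#' @export
pearson_cor <- function(x, y) cor_record(x, y, "PCC")

cor_record <- function(x, y, kind) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("correlation requires at least 3 samples")
  defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  value <- if (!defined) NA_real_ else if (kind == "SCC") {
    stats::cor(x, y, method = "spearman")
  } else {
    stats::cor(x, y, method = "pearson")
  }
  structure(list(kind = kind, value = value, n = length(x), defined = defined),
            class = "CorrelationRecord")
}

# Expression values used for screening: log2(CPM + 1). Library sizes must
# come from the full matrix (via `factors` computed before DE subsetting);
# column sums of a DE-only subset would absorb the group signal the screen
# is looking for.
screen_values <- function(x, factors = NULL) cpm(x, factors = factors, log = TRUE)

#' Screen miRNA-target pairs for negative co-expression
#'
#' Keeps a predicted (miRNA, target) pair iff it appears in the target table
#' with both features present in the supplied (differentially expressed)
#' matrices and its Spearman correlation across all samples of both groups
#' is strictly negative. Pairs with undefined (constant) correlation fail
#' the screen.
#'
#' @param expr_mir miRNA [expression_matrix()], typically already restricted
#'   to differentially expressed features.
#' @param expr_target lncRNA or mRNA [expression_matrix()], likewise
#'   restricted.
#' @param targets a target table (`mirna`, `target`, `target_class`).
#' @param scc_max strict upper bound on the Spearman correlation (default 0).
#' @param factors_mir,factors_target optional [normalization_factors()]
#'   computed on the full (pre-subset) matrices; their effective library
#'   sizes are used for the CPM values the correlations are taken over.
#' @return A `data.frame` of retained pairs: `mirna`, `target`,
#'   `target_class`, `scc`, `n`.
#' @export
screen_mirna_pairs <- function(expr_mir, expr_target, targets, scc_max = 0,
                               factors_mir = NULL, factors_target = NULL) {
  stopifnot(inherits(expr_mir, "ExpressionMatrix"),
            inherits(expr_target, "ExpressionMatrix"))
  if (!identical(colnames(expr_mir$counts), colnames(expr_target$counts))) {
    stop("expression matrices must share the same samples in the same order")
  }
  tab <- targets[targets$target_class == expr_target$rna_class &
                   targets$mirna %in% rownames(expr_mir$counts) &
                   targets$target %in% rownames(expr_target$counts), , drop = FALSE]
  if (nrow(tab) == 0) {
    return(data.frame(mirna = character(), target = character(),
                      target_class = character(), scc = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  vm <- screen_values(expr_mir, factors_mir)
  vt <- screen_values(expr_target, factors_target)
  scc <- vapply(seq_len(nrow(tab)), function(i) {
    r <- spearman_cor(vm[tab$mirna[i], ], vt[tab$target[i], ])
    if (r$defined) r$value else NA_real_
  }, numeric(1))
  keep <- !is.na(scc) & scc < scc_max
  out <- data.frame(mirna = tab$mirna[keep], target = tab$target[keep],
                    target_class = tab$target_class[keep], scc = scc[keep],
                    n = rep.int(ncol(vm), sum(keep)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Screen lncRNA-mRNA pairs for positive co-expression with shared sponges
#'
#' Candidate pairs are lncRNA-mRNA combinations that share at least one
#' miRNA surviving [screen_mirna_pairs()] for both partners; a pair is kept
#' iff its Pearson correlation across all samples is strictly greater than
#' `pcc_min`. Pairs with undefined correlation fail the screen.
#'
#' @param expr_lnc,expr_mrna [expression_matrix()] objects restricted to
#'   differentially expressed features.
#' @param mir_pairs the output of [screen_mirna_pairs()] for both classes
#'   (row-bound), i.e. the anti-correlated predicted target pairs.
#' @param pcc_min strict lower bound on the Pearson correlation (default 0.5).
#' @param factors_lnc,factors_mrna optional [normalization_factors()] from
#'   the full matrices (see [screen_mirna_pairs()]).
#' @return A `data.frame`: `lncrna`, `mrna`, `pcc`, `shared_mirnas`
#'   (semicolon-separated), `x` (number shared).
#' @export
screen_lnc_mrna_pairs <- function(expr_lnc, expr_mrna, mir_pairs, pcc_min = 0.5,
                                  factors_lnc = NULL, factors_mrna = NULL) {
  stopifnot(inherits(expr_lnc, "ExpressionMatrix"),
            inherits(expr_mrna, "ExpressionMatrix"))
  if (!identical(colnames(expr_lnc$counts), colnames(expr_mrna$counts))) {
    stop("expression matrices must share the same samples in the same order")
  }
  empty <- data.frame(lncrna = character(), mrna = character(), pcc = numeric(),
                      shared_mirnas = character(), x = integer(),
                      stringsAsFactors = FALSE)
  lp <- mir_pairs[mir_pairs$target_class == "lncRNA", , drop = FALSE]
  mp <- mir_pairs[mir_pairs$target_class == "mRNA", , drop = FALSE]
  if (nrow(lp) == 0 || nrow(mp) == 0) return(empty)
  shared_mir <- intersect(lp$mirna, mp$mirna)
  if (length(shared_mir) == 0) return(empty)
  cand <- unique(do.call(rbind, lapply(shared_mir, function(m) {
    expand.grid(lncrna = unique(lp$target[lp$mirna == m]),
                mrna = unique(mp$target[mp$mirna == m]),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })))
  mir_by_lnc <- split(lp$mirna, lp$target)
  mir_by_mrna <- split(mp$mirna, mp$target)
  vl <- screen_values(expr_lnc, factors_lnc)
  vm <- screen_values(expr_mrna, factors_mrna)
  shared <- lapply(seq_len(nrow(cand)), function(i) {
    sort(intersect(mir_by_lnc[[cand$lncrna[i]]], mir_by_mrna[[cand$mrna[i]]]))
  })
  pcc <- vapply(seq_len(nrow(cand)), function(i) {
    r <- pearson_cor(vl[cand$lncrna[i], ], vm[cand$mrna[i], ])
    if (r$defined) r$value else NA_real_
  }, numeric(1))
  keep <- !is.na(pcc) & pcc > pcc_min & lengths(shared) >= 1
  out <- data.frame(
    lncrna = cand$lncrna[keep], mrna = cand$mrna[keep], pcc = pcc[keep],
    shared_mirnas = vapply(shared[keep], paste, "", collapse = ";"),
    x = lengths(shared)[keep], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Hypergeometric shared-sponge test
#'
#' Tests whether a lncRNA and an mRNA share significantly many sponge
#' miRNAs: with `N` miRNAs in the universe, `K` targeting the lncRNA, `n`
#' targeting the mRNA and `x` shared, the p-value is the hypergeometric
#' upper tail `P[X >= x]` (over-representation; see [hyper_upper_tail()]).
#' A pair is retained when `p < alpha` (strict), conventionally 0.05 on the
#' raw p.
#'
#' @param x observed number of shared sponge miRNAs.
#' @param K,n numbers of universe miRNAs targeting the lncRNA and the mRNA.
#' @param N universe size (by default in the pipeline: all differentially
#'   expressed miRNAs appearing in the target table).
#' @return The upper-tail probability `P[X >= x]`.
#' @export
sponge_test <- function(x, K, n, N) hyper_upper_tail(x, K, n, N)

#' Apply the sponge test to screened lncRNA-mRNA pairs
#'
#' Counts `K` and `n` over the post-screen target pairs (targets must be
#' anti-correlated to count as sponges) and computes `p_sponge` for every
#' pair against the given miRNA universe.
#'
#' @param pairs output of [screen_lnc_mrna_pairs()].
#' @param mir_pairs output of [screen_mirna_pairs()] (both classes row-bound).
#' @param universe character vector of miRNA ids defining `N`.
#' @param alpha retention threshold on the raw `p_sponge` (default 0.05).
#' @param adjust if `TRUE`, additionally compute BH-adjusted p and retain on
#'   it instead of the raw p.
#' @return `pairs` with columns `K`, `n_mrna_mirnas`, `N`, `p_sponge`
#'   (and `p_sponge_adj` if requested) and `retained`.
#' @export
sponge_test_pairs <- function(pairs, mir_pairs, universe, alpha = 0.05,
                              adjust = FALSE) {
  if (nrow(pairs) == 0) {
    pairs$K <- integer(); pairs$n_mrna_mirnas <- integer(); pairs$N <- integer()
    pairs$p_sponge <- numeric(); pairs$retained <- logical()
    return(pairs)
  }
  lp <- mir_pairs[mir_pairs$target_class == "lncRNA" &
                    mir_pairs$mirna %in% universe, , drop = FALSE]
  mp <- mir_pairs[mir_pairs$target_class == "mRNA" &
                    mir_pairs$mirna %in% universe, , drop = FALSE]
  k_lnc <- table(factor(unique(lp[c("mirna", "target")])$target))
  n_mrna <- table(factor(unique(mp[c("mirna", "target")])$target))
  N <- length(universe)
  pairs$K <- as.integer(k_lnc[pairs$lncrna])
  pairs$n_mrna_mirnas <- as.integer(n_mrna[pairs$mrna])
  pairs$N <- N
  pairs$p_sponge <- vapply(seq_len(nrow(pairs)), function(i) {
    sponge_test(pairs$x[i], pairs$K[i], pairs$n_mrna_mirnas[i], N)
  }, numeric(1))
  if (adjust) {
    pairs$p_sponge_adj <- stats::p.adjust(pairs$p_sponge, method = "BH")
    pairs$retained <- pairs$p_sponge_adj < alpha
  } else {
    pairs$retained <- pairs$p_sponge < alpha
  }
  pairs
}

#' Build a tripartite ceRNA network from explicit edge lists
#'
#' Low-level constructor shared by [assemble_network()] and worked examples:
#' takes lncRNA-miRNA and miRNA-mRNA edges plus per-node regulation
#' directions and returns a typed tripartite graph. Within-class and
#' lncRNA-mRNA edges are impossible by construction; miRNA nodes not lying
#' on at least one complete lncRNA-miRNA-mRNA path are pruned.
#'
#' @param lnc_mir `data.frame` with columns `lncrna`, `mirna` (optional
#'   further columns become edge attributes).
#' @param mir_mrna `data.frame` with columns `mirna`, `mrna` (ditto).
#' @param directions named character vector (`up`/`down`) covering every node.
#' @param pairs optional lncRNA-mRNA pair table kept as provenance.
#' @return An object of class `CeRNANetwork`: list with `graph` (igraph,
#'   node attributes `class` and `direction`, edge attribute `kind`) and
#'   `pairs`.
#' @export
cerna_network_from_edges <- function(lnc_mir, mir_mrna, directions, pairs = NULL) {
  stopifnot(all(c("lncrna", "mirna") %in% names(lnc_mir)),
            all(c("mirna", "mrna") %in% names(mir_mrna)))
  lnc_mir <- lnc_mir[!duplicated(lnc_mir[c("lncrna", "mirna")]), , drop = FALSE]
  mir_mrna <- mir_mrna[!duplicated(mir_mrna[c("mirna", "mrna")]), , drop = FALSE]
  # prune miRNAs without a complete path
  on_path <- intersect(lnc_mir$mirna, mir_mrna$mirna)
  lnc_mir <- lnc_mir[lnc_mir$mirna %in% on_path, , drop = FALSE]
  mir_mrna <- mir_mrna[mir_mrna$mirna %in% on_path, , drop = FALSE]
  nodes <- data.frame(
    name = c(unique(lnc_mir$lncrna), unique(on_path), unique(mir_mrna$mrna)),
    class = rep(c("lncRNA", "miRNA", "mRNA"),
                c(length(unique(lnc_mir$lncrna)), length(unique(on_path)),
                  length(unique(mir_mrna$mrna)))),
    stringsAsFactors = FALSE
  )
  missing <- setdiff(nodes$name, names(directions))
  if (length(missing)) {
    stop("regulation direction missing for node(s): ",
         paste(missing, collapse = ", "))
  }
  nodes$direction <- unname(directions[nodes$name])
  e1 <- data.frame(from = lnc_mir$lncrna, to = lnc_mir$mirna, kind = "sponge",
                   stringsAsFactors = FALSE)
  extra1 <- setdiff(names(lnc_mir), c("lncrna", "mirna"))
  for (col in extra1) e1[[col]] <- lnc_mir[[col]]
  e2 <- data.frame(from = mir_mrna$mirna, to = mir_mrna$mrna, kind = "represses",
                   stringsAsFactors = FALSE)
  for (col in extra1) e2[[col]] <- NA
  extra2 <- setdiff(names(mir_mrna), c("mirna", "mrna"))
  for (col in setdiff(extra2, names(e2))) {
    e1[[col]] <- NA
    e2[[col]] <- mir_mrna[[col]]
  }
  for (col in intersect(extra2, extra1)) e2[[col]] <- mir_mrna[[col]]
  edges <- rbind(e1, e2[names(e1)])
  # deterministic order regardless of input ordering
  nodes <- nodes[order(nodes$class, nodes$name), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(graph = g, pairs = pairs), class = "CeRNANetwork")
}

#' Assemble the ceRNA network from retained pairs
#'
#' Combines all retained lncRNA-mRNA pairs and their shared screened miRNAs
#' into a tripartite lncRNA-miRNA-mRNA graph. Edges carry the Spearman
#' correlation of the miRNA screen; nodes carry `class` and the
#' differential-expression `direction`. miRNA nodes not on a complete path
#' are pruned. The result is invariant to the input pair order.
#'
#' @param pairs a [sponge_test_pairs()] table (only rows with `retained`
#'   are used, unless the column is absent in which case all rows are used).
#' @param mir_pairs the [screen_mirna_pairs()] output, supplying SCC edge
#'   metadata.
#' @param directions named character vector of `up`/`down` per node id
#'   (e.g. from [exact_test()] `direction` columns).
#' @return A `CeRNANetwork` (see [cerna_network_from_edges()]).
#' @export
assemble_network <- function(pairs, mir_pairs, directions) {
  if ("retained" %in% names(pairs)) pairs <- pairs[pairs$retained, , drop = FALSE]
  if (nrow(pairs) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g, pairs = pairs), class = "CeRNANetwork"))
  }
  scc_key <- paste(mir_pairs$mirna, mir_pairs$target, sep = "\r")
  scc <- stats::setNames(mir_pairs$scc, scc_key)
  lm <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ms <- strsplit(pairs$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    data.frame(lncrna = pairs$lncrna[i], mirna = ms,
               scc = unname(scc[paste(ms, pairs$lncrna[i], sep = "\r")]),
               stringsAsFactors = FALSE)
  }))
  mm <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ms <- strsplit(pairs$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    data.frame(mirna = ms, mrna = pairs$mrna[i],
               scc = unname(scc[paste(ms, pairs$mrna[i], sep = "\r")]),
               stringsAsFactors = FALSE)
  }))
  cerna_network_from_edges(lm, mm, directions, pairs = pairs)
}

#' Per-axis mRNA counts of a lncRNA in a ceRNA network
#'
#' For each miRNA adjacent to `lncrna`, reports how many mRNAs it connects
#' to (`n_mrna`), how many of those are reachable through no other miRNA
#' adjacent to the lncRNA (`n_exclusive`), and the shared ones.
#'
#' @param network a `CeRNANetwork`.
#' @param lncrna a lncRNA node id.
#' @return A list: `axes` data.frame (`mirna`, `n_mrna`, `n_exclusive`) and
#'   `mrnas`, a named list of the mRNA ids per axis.
#' @export
axis_summary <- function(network, lncrna) {
  stopifnot(inherits(network, "CeRNANetwork"))
  g <- network$graph
  if (!lncrna %in% igraph::V(g)$name) stop("no such node: ", lncrna)
  cls <- stats::setNames(igraph::V(g)$class, igraph::V(g)$name)
  nb <- igraph::neighbors(g, lncrna)$name
  mirs <- nb[cls[nb] == "miRNA"]
  mrnas <- lapply(mirs, function(m) {
    x <- igraph::neighbors(g, m)$name
    sort(x[cls[x] == "mRNA"])
  })
  names(mrnas) <- mirs
  n_excl <- vapply(seq_along(mirs), function(i) {
    others <- unique(unlist(mrnas[-i]))
    sum(!mrnas[[i]] %in% others)
  }, integer(1))
  list(
    axes = data.frame(mirna = mirs, n_mrna = lengths(mrnas),
                      n_exclusive = n_excl, stringsAsFactors = FALSE),
    mrnas = mrnas
  )
}

#' Run the full ceRNA inference pipeline
#'
#' Normalization, per-class differential expression, DE filtering, the
#' three-rule screening (SCC < 0 on predicted miRNA targets, PCC > 0.5 on
#' lncRNA-mRNA pairs with a shared screened miRNA, hypergeometric sponge
#' test at `sponge_alpha`), and network assembly.
#'
#' @param lnc,mir,mrna [expression_matrix()] objects for the three classes,
#'   sharing samples.
#' @param targets a merged target table (`mirna`, `target`, `target_class`).
#' @param lfc_lnc,lfc_mir,lfc_mrna strict `|log2FC|` thresholds per class
#'   (defaults: 1 for lncRNAs — fold change > 2 — and 2 for miRNAs/mRNAs).
#' @param p_threshold strict raw-p DE threshold (default 0.05).
#' @param scc_max,pcc_min,sponge_alpha screening thresholds.
#' @param universe miRNA universe for the sponge test: `"de_table"` (default;
#'   all DE miRNAs appearing in the target table restricted to DE features),
#'   `"de_screened"` (only miRNAs surviving the SCC screen) or `"all_de"`
#'   (all DE miRNAs).
#' @param adjust_sponge apply BH to `p_sponge` before retention.
#' @return A list: `de` (per-class [exact_test()] tables), `de_features`
#'   (per-class kept ids), `mir_pairs`, `pairs` (with sponge test columns),
#'   `network`.
#' @export
run_cerna_pipeline <- function(lnc, mir, mrna, targets,
                               lfc_lnc = 1, lfc_mir = 2, lfc_mrna = 2,
                               p_threshold = 0.05,
                               scc_max = 0, pcc_min = 0.5, sponge_alpha = 0.05,
                               universe = c("de_table", "de_screened", "all_de"),
                               adjust_sponge = FALSE) {
  universe <- match.arg(universe)
  nf <- list(
    lncRNA = normalization_factors(lnc),
    miRNA = normalization_factors(mir),
    mRNA = normalization_factors(mrna)
  )
  de <- list(
    lncRNA = exact_test(lnc, nf$lncRNA),
    miRNA = exact_test(mir, nf$miRNA),
    mRNA = exact_test(mrna, nf$mRNA)
  )
  keep <- list(
    lncRNA = apply_de_filter(de$lncRNA, lfc_lnc, p_threshold)$feature_id,
    miRNA = apply_de_filter(de$miRNA, lfc_mir, p_threshold)$feature_id,
    mRNA = apply_de_filter(de$mRNA, lfc_mrna, p_threshold)$feature_id
  )
  empty_net <- structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                              pairs = NULL), class = "CeRNANetwork")
  if (any(lengths(keep) == 0)) {
    return(list(de = de, de_features = keep,
                mir_pairs = NULL, pairs = NULL, network = empty_net))
  }
  lnc_de <- subset_features(lnc, keep$lncRNA)
  mir_de <- subset_features(mir, keep$miRNA)
  mrna_de <- subset_features(mrna, keep$mRNA)
  tab_de <- targets[targets$mirna %in% keep$miRNA &
                      targets$target %in% c(keep$lncRNA, keep$mRNA), , drop = FALSE]
  mir_pairs <- rbind(
    screen_mirna_pairs(mir_de, lnc_de, tab_de, scc_max, nf$miRNA, nf$lncRNA),
    screen_mirna_pairs(mir_de, mrna_de, tab_de, scc_max, nf$miRNA, nf$mRNA)
  )
  pairs <- screen_lnc_mrna_pairs(lnc_de, mrna_de, mir_pairs, pcc_min,
                                 nf$lncRNA, nf$mRNA)
  uni <- switch(universe,
    de_table = intersect(keep$miRNA, unique(tab_de$mirna)),
    de_screened = unique(mir_pairs$mirna),
    all_de = keep$miRNA
  )
  pairs <- sponge_test_pairs(pairs, mir_pairs, uni, alpha = sponge_alpha,
                             adjust = adjust_sponge)
  directions <- c(
    stats::setNames(de$lncRNA$direction, de$lncRNA$feature_id),
    stats::setNames(de$miRNA$direction, de$miRNA$feature_id),
    stats::setNames(de$mRNA$direction, de$mRNA$feature_id)
  )
  network <- assemble_network(pairs, mir_pairs, directions)
  list(de = de, de_features = keep, mir_pairs = mir_pairs, pairs = pairs,
       network = network)
}
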