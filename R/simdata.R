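#' Configuration for the synthetic ceRNA experiment generator
#'
#' Defines a two-group (A-ED vs NC) rat corpus-cavernosum-like RNA-seq
#' experiment with planted ceRNA triplets: an up-regulated lncRNA and an
#' up-regulated mRNA that share predicted sponge miRNAs, each sponge miRNA
#' down-regulated so that across samples it is anti-correlated with both
#' partners while the lncRNA and mRNA positively co-vary. All `simulate_*`
#' generators are deterministic given `seed`; each draws from its own stream
#' (`seed + fixed offset`, documented in the function) so fixtures are
#' individually reproducible.
#'
#' Counts are negative binomial with the variance function
#' `var = mu + dispersion * mu^2`.
#'
#' @param seed integer RNG seed governing every sub-generator.
#' @param n_per_group samples per group (>= 3; correlations are undefined below 3).
#' @param n_lnc,n_mir,n_mrna feature counts per RNA class.
#' @param n_planted_triplets number of planted ceRNA triplets; each uses one
#'   lncRNA, one mRNA and `sponges_per_triplet` miRNAs.
#' @param sponges_per_triplet shared sponge miRNAs per planted pair (>= 1).
#' @param lnc_fc,mrna_fc,mir_fc true fold changes (> 0) for planted features;
#'   the miRNA moves in the opposite direction (its A-ED mean is divided by
#'   `mir_fc`).
#' @param dispersion NB dispersion phi (> 0).
#' @param baseline_mean_log_range length-2 numeric; per-feature baseline means
#'   are drawn log-uniformly from `exp(range)`.
#' @param target_density probability in `[0, 1]` that a miRNA targets a
#'   non-planted (miRNA, feature) combination in the predicted target table.
#' @param lib_size_range length-2 positive numeric; per-sample library-size
#'   multipliers are drawn log-uniformly from this range.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 10L,
                       n_lnc = 220L, n_mir = 360L, n_mrna = 1520L,
                       n_planted_triplets = 20L,
                       sponges_per_triplet = 3L,
                       lnc_fc = 6, mrna_fc = 6, mir_fc = 6,
                       dispersion = 0.1,
                       baseline_mean_log_range = c(log(5), log(500)),
                       target_density = 0.05,
                       lib_size_range = c(0.5, 2)) {
  cfg <- list(
    seed = as.integer(seed), n_per_group = as.integer(n_per_group),
    n_lnc = as.integer(n_lnc), n_mir = as.integer(n_mir), n_mrna = as.integer(n_mrna),
    n_planted_triplets = as.integer(n_planted_triplets),
    sponges_per_triplet = as.integer(sponges_per_triplet),
    lnc_fc = lnc_fc, mrna_fc = mrna_fc, mir_fc = mir_fc,
    dispersion = dispersion,
    baseline_mean_log_range = as.numeric(baseline_mean_log_range),
    target_density = target_density,
    lib_size_range = as.numeric(lib_size_range)
  )
  cfg_fail <- function(field, why) stop("invalid config field '", field, "': ", why)
  if (cfg$n_per_group < 3) cfg_fail("n_per_group", "must be >= 3")
  for (f in c("n_lnc", "n_mir", "n_mrna")) {
    if (cfg[[f]] < 1) cfg_fail(f, "must be >= 1")
  }
  if (cfg$n_planted_triplets < 0) cfg_fail("n_planted_triplets", "must be >= 0")
  if (cfg$sponges_per_triplet < 1) cfg_fail("sponges_per_triplet", "must be >= 1")
  for (f in c("lnc_fc", "mrna_fc", "mir_fc")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) cfg_fail(f, "fold changes must be > 0")
  }
  if (cfg$dispersion <= 0) cfg_fail("dispersion", "must be > 0")
  if (length(cfg$baseline_mean_log_range) != 2 ||
      diff(cfg$baseline_mean_log_range) < 0) {
    cfg_fail("baseline_mean_log_range", "must be an increasing pair")
  }
  if (cfg$target_density < 0 || cfg$target_density > 1) {
    cfg_fail("target_density", "must be in [0, 1]")
  }
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0) {
    cfg_fail("lib_size_range", "must be an increasing pair of positive reals")
  }
  if (cfg$n_planted_triplets > min(cfg$n_lnc, cfg$n_mrna) ||
      cfg$n_planted_triplets * cfg$sponges_per_triplet > cfg$n_mir) {
    cfg_fail("n_planted_triplets",
             "exceeds available features (lncRNA/mRNA count or miRNA count / sponges_per_triplet)")
  }
  structure(cfg, class = "SimulationConfig")
}

feature_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

# Ground truth bookkeeping shared by the generators.
truth_network <- function(config) {
  lnc <- feature_ids("lnc", config$n_lnc)
  mir <- feature_ids("mir", config$n_mir)
  mrna <- feature_ids("mrna", config$n_mrna)
  k <- config$n_planted_triplets
  spt <- config$sponges_per_triplet
  dir_lnc <- stats::setNames(rep("null", config$n_lnc), lnc)
  dir_mir <- stats::setNames(rep("null", config$n_mir), mir)
  dir_mrna <- stats::setNames(rep("null", config$n_mrna), mrna)
  pairs <- data.frame(lncrna = character(), mrna = character(),
                      stringsAsFactors = FALSE)
  sponges <- list()
  if (k > 0) {
    pairs <- data.frame(lncrna = lnc[seq_len(k)], mrna = mrna[seq_len(k)],
                        stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      ms <- mir[((i - 1) * spt + 1):(i * spt)]
      sponges[[paste(pairs$lncrna[i], pairs$mrna[i], sep = "|")]] <- ms
      dir_mir[ms] <- "down"
    }
    dir_lnc[pairs$lncrna] <- "up"
    dir_mrna[pairs$mrna] <- "up"
  }
  structure(
    list(planted_pairs = pairs, planted_sponges = sponges,
         direction = list(lncRNA = dir_lnc, miRNA = dir_mir, mRNA = dir_mrna)),
    class = "TruthNetwork"
  )
}

#' Simulate two-group count matrices with planted ceRNA triplets
#'
#' Draws negative-binomial counts for the three RNA classes under the design
#' described in [sim_config()]: `mu_gs = baseline_g * fc_g^[s in A-ED] *
#' libsize_s`, `var = mu + phi mu^2`. Planted lncRNAs/mRNAs are up-regulated
#' in A-ED by their fold changes; their sponge miRNAs are down-regulated by
#' `1/mir_fc`; all other features have fold change 1. Uses RNG stream
#' `seed + 0`.
#'
#' @param config a [sim_config()] object.
#' @return A list with `ExpressionMatrix` elements `lncRNA`, `miRNA`, `mRNA`,
#'   the `TruthNetwork` in `truth`, and the per-sample library-size
#'   multipliers in `lib_sizes`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  truth <- truth_network(config)
  set.seed(config$seed)
  n <- config$n_per_group
  samples <- c(sprintf("AED_%02d", seq_len(n)), sprintf("NC_%02d", seq_len(n)))
  groups <- rep(c("A-ED", "NC"), each = n)
  lib <- exp(stats::runif(2 * n, log(config$lib_size_range[1]),
                          log(config$lib_size_range[2])))
  names(lib) <- samples

  one_class <- function(class, ids, fc_planted, len_range) {
    nf <- length(ids)
    base <- exp(stats::runif(nf, config$baseline_mean_log_range[1],
                             config$baseline_mean_log_range[2]))
    fc <- rep(1, nf)
    names(fc) <- ids
    dirs <- truth$direction[[class]]
    fc[dirs == "up"] <- fc_planted
    fc[dirs == "down"] <- 1 / fc_planted
    mu <- outer(base, lib) * outer(fc, ifelse(groups == "A-ED", 1, 0), "^")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                     nrow = nf, dimnames = list(ids, samples))
    lens <- round(stats::runif(nf, len_range[1], len_range[2]))
    names(lens) <- ids
    expression_matrix(counts, groups, class, lengths = lens)
  }

  out <- list(
    lncRNA = one_class("lncRNA", names(truth$direction$lncRNA), config$lnc_fc, c(200, 3000)),
    miRNA = one_class("miRNA", names(truth$direction$miRNA), config$mir_fc, c(20, 24)),
    mRNA = one_class("mRNA", names(truth$direction$mRNA), config$mrna_fc, c(500, 5000)),
    truth = truth,
    lib_sizes = lib
  )
  out
}

#' Simulate a merged miRNA target-prediction table
#'
#' Emulates the union of several target-prediction tools: every planted
#' sponge relation (miRNA to its lncRNA and mRNA partners) is present, and
#' each non-planted (miRNA, feature) combination is included independently
#' with probability `target_density`. Each pair carries 1-3 pseudo-tool
#' votes. Uses RNG stream `seed + 1`.
#'
#' @param config a [sim_config()] object.
#' @param truth the `TruthNetwork` from [simulate_counts()] under the same config.
#' @return A `data.frame` with columns `mirna`, `target`, `target_class`
#'   (`lncRNA`/`mRNA`) and `tools` (semicolon-separated vote sources).
#' @export
simulate_target_table <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "TruthNetwork"))
  set.seed(config$seed + 1L)
  mir <- names(truth$direction$miRNA)
  tg <- rbind(
    data.frame(target = names(truth$direction$lncRNA), target_class = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(target = names(truth$direction$mRNA), target_class = "mRNA",
               stringsAsFactors = FALSE)
  )
  # planted relations
  planted <- NULL
  if (nrow(truth$planted_pairs) > 0) {
    planted <- do.call(rbind, lapply(seq_len(nrow(truth$planted_pairs)), function(i) {
      key <- paste(truth$planted_pairs$lncrna[i], truth$planted_pairs$mrna[i], sep = "|")
      ms <- truth$planted_sponges[[key]]
      rbind(
        data.frame(mirna = ms, target = truth$planted_pairs$lncrna[i],
                   target_class = "lncRNA", stringsAsFactors = FALSE),
        data.frame(mirna = ms, target = truth$planted_pairs$mrna[i],
                   target_class = "mRNA", stringsAsFactors = FALSE)
      )
    }))
  }
  # background relations
  grid <- expand.grid(mirna = mir, idx = seq_len(nrow(tg)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < config$target_density
  bg <- data.frame(mirna = grid$mirna[keep],
                   target = tg$target[grid$idx[keep]],
                   target_class = tg$target_class[grid$idx[keep]],
                   stringsAsFactors = FALSE)
  tab <- rbind(planted, bg)
  tab <- tab[!duplicated(tab[c("mirna", "target")]), , drop = FALSE]
  tools <- c("targetscan", "mircode", "mirdb")
  nv <- sample(1:3, nrow(tab), replace = TRUE)
  tab$tools <- vapply(nv, function(k) paste(sort(sample(tools, k)), collapse = ";"), "")
  tab <- tab[order(tab$mirna, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Simulate a gene-set collection with known enriched sets
#'
#' Builds GMT-style sets over the mRNA universe; `n_enriched` sets are loaded
#' with planted (truly up-regulated) mRNAs at proportion `enriched_fraction`,
#' the rest are uniform background draws. Uses RNG stream `seed + 2`.
#'
#' @param config a [sim_config()] object.
#' @param truth the matching `TruthNetwork`.
#' @param n_sets,set_size_range,n_enriched,enriched_fraction collection shape.
#' @return A list of class `GeneSetCollection` with elements `sets` (named
#'   list of id vectors), `descriptions` (named character) and
#'   `truth_enriched` (ids of the loaded sets; empty when nothing is planted).
#' @export
simulate_gene_sets <- function(config, truth, n_sets = 30,
                               set_size_range = c(10, 50),
                               n_enriched = 3, enriched_fraction = 0.6) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "TruthNetwork"))
  set.seed(config$seed + 2L)
  universe <- names(truth$direction$mRNA)
  planted <- truth$planted_pairs$mrna
  if (length(planted) == 0) n_enriched <- 0
  ids <- sprintf("SET_%03d", seq_len(n_sets))
  sets <- vector("list", n_sets)
  names(sets) <- ids
  for (i in seq_len(n_sets)) {
    size <- sample(set_size_range[1]:set_size_range[2], 1)
    if (i <= n_enriched) {
      n_hit <- min(length(planted), max(1, round(enriched_fraction * size)))
      members <- c(sample(planted, n_hit),
                   sample(setdiff(universe, planted), size - n_hit))
    } else {
      members <- sample(universe, size)
    }
    sets[[i]] <- sort(unique(members))
  }
  structure(
    list(sets = sets,
         descriptions = stats::setNames(
           ifelse(seq_len(n_sets) <= n_enriched,
                  "synthetic enriched set", "synthetic background set"), ids),
         truth_enriched = ids[seq_len(n_enriched)]),
    class = "GeneSetCollection"
  )
}

#' Simulate per-animal ICP/MAP phenotype records
#'
#' Draws MAP (mmHg) and ICP/MAP ratios for `n_below` animals below and
#' `n_above` animals above the grouping threshold, in shuffled order.
#' Uses RNG stream `seed + 3`.
#'
#' @param config a [sim_config()] object.
#' @param n_below,n_above animals with ratio below / above the threshold
#'   (defaults mirror a 7 vs 15 geriatric-rat cohort).
#' @param threshold ICP/MAP grouping threshold (default 0.35).
#' @return A `data.frame` (animal, MAP, ICP, true_group) where `true_group`
#'   is the generator's label (`A-ED` below, `NC` above the threshold).
#' @export
simulate_phenotype <- function(config, n_below = 7, n_above = 15, threshold = 0.35) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  n <- n_below + n_above
  ratio <- c(stats::runif(n_below, 0.10, threshold - 0.05),
             stats::runif(n_above, threshold + 0.05, 0.70))
  truth <- rep(c("A-ED", "NC"), c(n_below, n_above))
  ord <- sample.int(n)
  map <- stats::rnorm(n, 110, 8)
  data.frame(
    animal = sprintf("rat_%02d", seq_len(n)),
    MAP = map,
    ICP = ratio[ord] * map,
    true_group = truth[ord],
    stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR plate with a known fold change
#'
#' Generates Ct values for a target gene and a reference gene (beta-actin)
#' in two groups with technical replicates. Per-sample offsets are added to
#' both genes (they cancel under reference normalization); measurement noise
#' is Gaussian on the Ct scale. The true `2^-ddCt` fold change of A-ED over
#' NC is `true_fc`. Uses RNG stream `seed + 4`.
#'
#' @param config a [sim_config()] object.
#' @param gene,ref_gene target and reference gene ids.
#' @param true_fc true A-ED/NC expression fold change of `gene`.
#' @param noise_sd Ct measurement noise SD (0 gives exact closed-form values).
#' @param n_per_group biological samples per group.
#' @param n_replicates technical replicates per (gene, sample).
#' @return A list of class `QPCRPlate`: `ct` long `data.frame`
#'   (gene, sample, group, replicate, ct), `ref_gene`, `calibrator`
#'   (`"NC"`), and `truth` (`true_fc`, `true_ddct = -log2(true_fc)`).
#' @export
simulate_qpcr <- function(config, gene = "ENSRNOT00000029245", ref_gene = "Actb",
                          true_fc = 2, noise_sd = 0.15,
                          n_per_group = 7, n_replicates = 3) {
  stopifnot(inherits(config, "SimulationConfig"), true_fc > 0, noise_sd >= 0)
  set.seed(config$seed + 4L)
  samples <- c(sprintf("AED_%02d", seq_len(n_per_group)),
               sprintf("NC_%02d", seq_len(n_per_group)))
  groups <- rep(c("A-ED", "NC"), each = n_per_group)
  sample_eff <- stats::rnorm(length(samples), 0, 0.3)
  dct0 <- 8  # calibrator-group delta-Ct of the target
  rows <- expand.grid(gene = c(gene, ref_gene), s = seq_along(samples),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_ct <- ifelse(rows$gene == ref_gene, 17,
                    17 + dct0 - log2(true_fc) * (groups[rows$s] == "A-ED"))
  ct <- base_ct + sample_eff[rows$s] +
    if (noise_sd > 0) stats::rnorm(nrow(rows), 0, noise_sd) else 0
  structure(
    list(
      ct = data.frame(gene = rows$gene, sample = samples[rows$s],
                      group = groups[rows$s], replicate = rows$replicate,
                      ct = ct, stringsAsFactors = FALSE),
      ref_gene = ref_gene,
      calibrator = "NC",
      truth = list(true_fc = true_fc, true_ddct = -log2(true_fc))
    ),
    class = "QPCRPlate"
  )
}

#' Simulate raw reads with planted QC failures
#'
#' Emits a FASTQ-ready read set with controlled fractions of reads that fail
#' each of the three quality rules checked by [filter_reads()]:
#' adapter-containing reads, reads with more than 10% unknown bases (N), and
#' reads with more than 50% low-quality (Q <= 20) bases. Planted failing
#' reads violate exactly one rule, so per-rule failure counts are exact
#' ground truth under first-failing-rule attribution. Clean reads are
#' resampled if they happen to contain the adapter. Uses RNG stream
#' `seed + 5`.
#'
#' @param config a [sim_config()] object.
#' @param n_reads total reads.
#' @param read_length read length (bp).
#' @param frac_adapter,frac_high_n,frac_low_quality planted failure fractions.
#' @param adapter adapter sequence planted into failing reads.
#' @return A list: `reads` (a `Biostrings::QualityScaledDNAStringSet`),
#'   `adapter`, and `truth` with `n_adapter`, `n_high_n`, `n_low_quality`,
#'   `n_kept`.
#' @export
simulate_reads <- function(config, n_reads = 1000, read_length = 100,
                           frac_adapter = 0.10, frac_high_n = 0.05,
                           frac_low_quality = 0.05,
                           adapter = "AGATCGGAAGAGC") {
  stopifnot(inherits(config, "SimulationConfig"),
            frac_adapter + frac_high_n + frac_low_quality <= 1,
            nchar(adapter) > 0, read_length > nchar(adapter))
  set.seed(config$seed + 5L)
  n_ad <- as.integer(round(frac_adapter * n_reads))
  n_hn <- as.integer(round(frac_high_n * n_reads))
  n_lq <- as.integer(round(frac_low_quality * n_reads))
  n_ok <- as.integer(n_reads) - n_ad - n_hn - n_lq

  rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")
  seq_without_adapter <- function(len) {
    repeat {
      s <- rand_seq(len)
      if (!grepl(adapter, s, fixed = TRUE)) return(s)
    }
  }
  qual_str <- function(q) rawToChar(as.raw(q + 33L))
  flat_q <- function(len, q) qual_str(rep(q, len))

  seqs <- character(n_reads)
  quals <- character(n_reads)
  kind <- rep(c("adapter", "high_n", "low_q", "clean"), c(n_ad, n_hn, n_lq, n_ok))
  n_bases <- ceiling(0.15 * read_length)          # > 10% N
  lq_bases <- ceiling(0.60 * read_length)         # > 50% bases at Q <= 20
  for (i in seq_len(n_reads)) {
    switch(kind[i],
      adapter = {
        pos <- sample.int(read_length - nchar(adapter) + 1, 1)
        s <- seq_without_adapter(read_length)
        substr(s, pos, pos + nchar(adapter) - 1) <- adapter
        seqs[i] <- s
        quals[i] <- flat_q(read_length, 37L)
      },
      high_n = {
        s <- strsplit(seq_without_adapter(read_length), "")[[1]]
        s[sample.int(read_length, n_bases)] <- "N"
        seqs[i] <- paste(s, collapse = "")
        quals[i] <- flat_q(read_length, 37L)
      },
      low_q = {
        seqs[i] <- seq_without_adapter(read_length)
        q <- rep(37L, read_length)
        q[sample.int(read_length, lq_bases)] <- 10L
        quals[i] <- qual_str(q)
      },
      clean = {
        seqs[i] <- seq_without_adapter(read_length)
        quals[i] <- qual_str(sample(30:40, read_length, replace = TRUE))
      }
    )
  }
  ord <- sample.int(n_reads)
  ids <- sprintf("read_%05d", seq_len(n_reads))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs[ord], ids)),
    Biostrings::PhredQuality(quals[ord])
  )
  list(
    reads = reads,
    adapter = adapter,
    truth = list(n_adapter = n_ad, n_high_n = n_hn, n_low_quality = n_lq,
                 n_kept = n_ok)
  )
}
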