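make_reads <- function(seqs, quals) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, sprintf("r%d", seq_along(seqs)))),
    Biostrings::PhredQuality(quals)
  )
}
q_of <- function(q, len) rawToChar(as.raw(rep(q + 33L, len)))

test_that("read filter applies the three rules with strict boundaries", {
  adapter <- "AGATCGGAAGAGC"
  base <- paste(rep("ACGT", 25), collapse = "")   # 100 bp, no adapter
  with_adapter <- paste0(adapter, substr(base, 1, 100 - nchar(adapter)))
  n10 <- paste0(strrep("N", 10), substr(base, 1, 90))   # exactly 10% N -> kept
  n11 <- paste0(strrep("N", 11), substr(base, 1, 89))   # more than 10% -> dropped
  q_half <- paste0(q_of(20, 50), q_of(30, 50))          # exactly 50% Q<=20 -> kept
  q_51 <- paste0(q_of(20, 51), q_of(30, 49))            # more than 50% -> dropped
  reads <- make_reads(
    c(base, with_adapter, n10, n11, base, base),
    c(q_of(30, 100), q_of(30, 100), q_of(30, 100), q_of(30, 100), q_half, q_51)
  )
  out <- filter_reads(reads, adapter)
  expect_equal(out$report$n_adapter, 1)
  expect_equal(out$report$n_high_n, 1)
  expect_equal(out$report$n_low_quality, 1)
  expect_equal(names(out$kept), c("r1", "r3", "r5"))  # order preserved
  again <- filter_reads(out$kept, adapter)
  expect_equal(length(again$kept), length(out$kept))  # idempotent
})

test_that("filter counts on the generated FASTQ fixture match generator truth", {
  cfg <- sim_config(seed = 9)
  rs <- simulate_reads(cfg, n_reads = 300)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs$reads, fq)
  out <- filter_reads(read_fastq(fq), rs$adapter)
  expect_equal(out$report$n_adapter, rs$truth$n_adapter)
  expect_equal(out$report$n_high_n, rs$truth$n_high_n)
  expect_equal(out$report$n_low_quality, rs$truth$n_low_quality)
  expect_equal(out$report$n_kept, rs$truth$n_kept)
})

test_that("count matrices survive the TSV round trip bit-exactly", {
  cfg <- sim_config(seed = 1, n_lnc = 15, n_mir = 9, n_mrna = 20,
                    n_planted_triplets = 3)
  x <- simulate_counts(cfg)$lncRNA
  cp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_counts(x, cp, sp)
  y <- read_counts(cp, sp, rna_class = "lncRNA")
  expect_identical(y$counts, x$counts)
  expect_identical(as.character(y$groups), as.character(x$groups))
  expect_equal(y$lengths, x$lengths)
})

test_that("readers reject malformed input instead of coercing", {
  cp <- tempfile(); sp <- tempfile()
  writeLines(c("feature_id\ts1\ts2", "f1\t3\t4", "f1\t5\t6"), cp)
  writeLines(c("sample\tgroup", "s1\tA-ED", "s2\tNC"), sp)
  expect_error(read_counts(cp, sp), "duplicate")
  writeLines(c("feature_id\ts1\ts2", "f1\t3\t4"), cp)
  writeLines(c("sample\tgroup", "s1\tA-ED", "s2\tcontrol"), sp)
  expect_error(read_counts(cp, sp), "group")
  bad_fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad_fq)  # quality length mismatch
  expect_error(read_fastq(bad_fq), "FASTQ")
})

test_that("target tables from several tools merge with vote union", {
  p1 <- tempfile(); p2 <- tempfile()
  writeLines(c("mirna\ttarget\ttarget_class",
               "mir1\tgeneA\tmRNA", "mir1\tlncA\tlncRNA"), p1)
  writeLines(c("mirna\ttarget\ttarget_class",
               "mir1\tgeneA\tmRNA", "mir2\tgeneB\tmRNA"), p2)
  tab <- read_target_table(c(p1, p2), tools = c("targetscan", "mirdb"))
  expect_equal(nrow(tab), 3)
  shared <- tab[tab$mirna == "mir1" & tab$target == "geneA", ]
  expect_equal(shared$tools, "mirdb;targetscan")
  expect_equal(shared$n_tools, 2L)
  out <- tempfile()
  write_target_table(tab, out)
  expect_equal(read_target_table(out)[c("mirna", "target", "target_class", "tools")],
               tab[c("mirna", "target", "target_class", "tools")])
})

test_that("gene-set collections survive the GMT round trip", {
  cfg <- sim_config(seed = 2, n_lnc = 5, n_mir = 6, n_mrna = 100,
                    n_planted_triplets = 2)
  sim <- simulate_counts(cfg)
  gs <- simulate_gene_sets(cfg, sim$truth, n_sets = 8)
  path <- tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path)
  expect_identical(back$sets, gs$sets)
  expect_identical(unname(back$descriptions), unname(gs$descriptions))
})

test_that("networks survive SIF and GraphML export", {
  net <- aed_example_network()
  sif <- tempfile(fileext = ".sif")
  write_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), igraph::gsize(net$graph))
  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  g2 <- read_network_graphml(gml)
  expect_true(igraph::is_isomorphic_to(g2, net$graph))
  expect_setequal(igraph::V(g2)$name, igraph::V(net$graph)$name)
  ord <- match(igraph::V(net$graph)$name, igraph::V(g2)$name)
  expect_identical(igraph::V(g2)$class[ord], igraph::V(net$graph)$class)
  expect_identical(igraph::V(g2)$direction[ord], igraph::V(net$graph)$direction)
})
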