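#' Quality-filter raw reads
#'
#' Applies the study's three raw-read criteria in order; a read is kept iff
#' (1) it contains no adapter as an exact substring, (2) no more than 10% of
#' its bases are unknown (N), and (3) no more than 50% of its bases are low
#' quality (Phred Q <= 20). Boundary values (exactly 10% N, exactly 50%
#' low-quality) are kept: the criteria read "more than" strictly. Failures
#' are attributed to the first failing rule in the listed order. The filter
#' is order-preserving and idempotent.
#'
#' @param reads a `Biostrings::QualityScaledDNAStringSet` (e.g. from
#'   [read_fastq()] or [simulate_reads()]).
#' @param adapters character vector of adapter sequences (non-empty strings).
#' @return A list: `kept` (the surviving reads, original order) and `report`,
#'   a list with `n_input`, `n_adapter`, `n_high_n`, `n_low_quality`,
#'   `n_kept`.
#' @export
filter_reads <- function(reads, adapters) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  adapters <- as.character(adapters)
  if (length(adapters) == 0 || any(!nzchar(adapters))) {
    stop("adapters must be one or more non-empty nucleotide strings")
  }
  w <- Biostrings::width(reads)
  if (any(w == 0)) stop("empty read sequence(s) at index: ",
                        paste(which(w == 0), collapse = ", "))
  has_adapter <- rep(FALSE, length(reads))
  for (a in adapters) {
    has_adapter <- has_adapter | Biostrings::vcountPattern(a, reads, fixed = TRUE) > 0
  }
  n_frac <- as.vector(Biostrings::letterFrequency(reads, "N")) / w
  q <- as(Biostrings::quality(reads), "IntegerList")
  lowq_frac <- vapply(q, function(v) mean(v <= 20), numeric(1))

  fail_adapter <- has_adapter
  fail_n <- !fail_adapter & n_frac > 0.10
  fail_q <- !fail_adapter & !fail_n & lowq_frac > 0.50
  keep <- !(fail_adapter | fail_n | fail_q)
  list(
    kept = reads[keep],
    report = list(
      n_input = length(reads),
      n_adapter = sum(fail_adapter),
      n_high_n = sum(fail_n),
      n_low_quality = sum(fail_q),
      n_kept = sum(keep)
    )
  )
}

#' Read / write FASTQ
#'
#' Thin wrappers over Biostrings' quality-scaled FASTQ IO (4-line records,
#' Phred+33).
#'
#' @param path file path.
#' @return `read_fastq` returns a `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # structural validation first: the Biostrings reader silently pads
  # mismatched quality strings instead of rejecting them
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ in ", path, ": line count not a multiple of 4")
  }
  idx <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[idx], "@") | !startsWith(lines[idx + 2], "+") |
                 nchar(lines[idx + 1]) != nchar(lines[idx + 3]) |
                 nchar(lines[idx + 1]) == 0)
  if (length(bad)) {
    stop("malformed FASTQ record(s) in ", path, " at index: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
      # the reader warns about dropping its own internal metadata columns
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) stop("malformed FASTQ in ", path, ": ", conditionMessage(e))
  )
}

#' @param reads a `QualityScaledDNAStringSet`.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Read / write count matrices with a sample sheet
#'
#' Counts travel as TSV with a `feature_id` first column and one column per
#' sample; the sample sheet is a TSV with columns `sample` and `group`
#' (values `A-ED` / `NC`). `write_counts` also writes the sample sheet and,
#' when lengths are present, a `length` column after `feature_id`.
#' Write-then-read reproduces the object exactly.
#'
#' @param counts_path,samples_path TSV paths.
#' @param rna_class RNA class of the matrix.
#' @return `read_counts` returns an [expression_matrix()].
#' @export
read_counts <- function(counts_path, samples_path,
                        rna_class = c("lncRNA", "miRNA", "mRNA")) {
  rna_class <- match.arg(rna_class)
  for (p in c(counts_path, samples_path)) {
    if (!file.exists(p)) stop("no such file: ", p)
  }
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id") stop("counts TSV must start with a feature_id column")
  lengths <- NULL
  if (identical(names(tab)[2], "length")) {
    lengths <- stats::setNames(tab$length, tab$feature_id)
    tab$length <- NULL
  }
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$feature_id
  if (!is.numeric(counts)) stop("non-numeric count entries in ", counts_path)
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(sheet))) {
    stop("sample sheet must have columns 'sample' and 'group'")
  }
  missing <- setdiff(colnames(counts), sheet$sample)
  if (length(missing)) stop("samples absent from sheet: ", paste(missing, collapse = ", "))
  groups <- sheet$group[match(colnames(counts), sheet$sample)]
  expression_matrix(counts, groups, rna_class, lengths = lengths)
}

#' @param x an [expression_matrix()] object.
#' @rdname read_counts
#' @export
write_counts <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(x$counts), stringsAsFactors = FALSE)
  if (!is.null(x$lengths)) df$length <- unname(x$lengths)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(x$counts), group = as.character(x$groups)),
    samples_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(counts_path)
}

#' Read and merge miRNA target-prediction tables
#'
#' Each input TSV has columns `mirna`, `target`, `target_class` and either a
#' `tools` column (semicolon-separated vote sources) or a per-file `tool`
#' name supplied via `tools`. Rows sharing (mirna, target) across files are
#' merged with the union of their votes.
#'
#' @param paths one or more TSV paths.
#' @param tools optional character vector, one tool name per path, used when
#'   a file lacks a `tools` column.
#' @return A merged target table `data.frame` with columns `mirna`, `target`,
#'   `target_class`, `tools`, `n_tools`; no duplicate (mirna, target) rows.
#' @export
read_target_table <- function(paths, tools = NULL) {
  stopifnot(length(paths) >= 1)
  if (!is.null(tools)) stopifnot(length(tools) == length(paths))
  parts <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p)) stop("no such file: ", p)
    tab <- utils::read.delim(p, stringsAsFactors = FALSE)
    need <- c("mirna", "target", "target_class")
    if (!all(need %in% names(tab))) {
      stop("target table ", p, " must have columns: ", paste(need, collapse = ", "))
    }
    bad <- setdiff(unique(tab$target_class), c("lncRNA", "mRNA"))
    if (length(bad)) stop("unknown target_class in ", p, ": ", paste(bad, collapse = ", "))
    if (!"tools" %in% names(tab)) {
      if (is.null(tools)) stop("file ", p, " has no 'tools' column and no tool name given")
      tab$tools <- tools[i]
    }
    tab[c("mirna", "target", "target_class", "tools")]
  })
  merge_target_tables(do.call(rbind, parts))
}

# Union tool votes for duplicated (mirna, target) rows.
merge_target_tables <- function(tab) {
  key <- paste(tab$mirna, tab$target, sep = "\r")
  votes <- tapply(tab$tools, key, function(v) {
    paste(sort(unique(unlist(strsplit(v, ";", fixed = TRUE)))), collapse = ";")
  })
  first <- tab[!duplicated(key), , drop = FALSE]
  k1 <- paste(first$mirna, first$target, sep = "\r")
  cls <- tapply(tab$target_class, key, function(v) unique(v))
  if (any(lengths(cls) > 1)) {
    stop("conflicting target_class for pair(s): ",
         paste(utils::head(names(cls)[lengths(cls) > 1]), collapse = ", "))
  }
  out <- data.frame(
    mirna = first$mirna, target = first$target,
    target_class = first$target_class,
    tools = unname(votes[k1]),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$tools))) stop("empty tool votes")
  out$n_tools <- lengths(strsplit(out$tools, ";", fixed = TRUE))
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @param tab a target table `data.frame` (`mirna`, `target`, `target_class`,
#'   `tools`).
#' @param path output TSV path.
#' @rdname read_target_table
#' @export
write_target_table <- function(tab, path) {
  need <- c("mirna", "target", "target_class", "tools")
  stopifnot(all(need %in% names(tab)))
  utils::write.table(tab[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is one set per line: set id, TAB, description, TAB, member genes.
#' Reading goes through `fgsea::gmtPathways`; descriptions are re-read from
#' the raw lines since GMT carries them in column 2.
#'
#' @param path a GMT file path.
#' @return `read_gmt` returns a `GeneSetCollection` (see
#'   [simulate_gene_sets()]).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sets <- fgsea::gmtPathways(path)
  if (any(duplicated(names(sets)))) {
    stop("duplicate set ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  if (any(lengths(sets) == 0)) stop("empty gene set(s) in ", path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- stats::setNames(vapply(fields, `[`, "", 2), vapply(fields, `[`, "", 1))
  structure(
    list(sets = sets, descriptions = desc[names(sets)], truth_enriched = NULL),
    class = "GeneSetCollection"
  )
}

#' @param collection a `GeneSetCollection`.
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export / import a ceRNA network
#'
#' `write_network` serializes a [assemble_network()] result as Cytoscape SIF
#' (`lncRNA sponge miRNA` / `miRNA represses mRNA` lines), GraphML (with node
#' attributes `class` and `direction` and edge attributes), or a pair of
#' node/edge attribute TSVs (`<path>.nodes.tsv`, `<path>.edges.tsv`).
#' `read_network_graphml` reads a GraphML export back into an igraph object
#' with identical attributes.
#'
#' @param network a `CeRNANetwork` from [assemble_network()].
#' @param path output path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `write_network` returns `path` invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(network, "CeRNANetwork"))
  format <- match.arg(format)
  g <- network$graph
  el <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  if (format == "sif") {
    cls <- stats::setNames(nodes$class, nodes$name)
    rel <- ifelse(cls[el$from] == "lncRNA" | cls[el$to] == "lncRNA",
                  "sponge", "represses")
    # orient lncRNA->miRNA and miRNA->mRNA for readability
    a <- ifelse(cls[el$from] == "miRNA" & cls[el$to] == "lncRNA", el$to, el$from)
    b <- ifelse(cls[el$from] == "miRNA" & cls[el$to] == "lncRNA", el$from, el$to)
    writeLines(paste(a, rel, b, sep = "\t"), path)
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(el, paste0(path, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}
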