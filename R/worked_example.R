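#' Published rat A-ED ceRNA network axes
#'
#' The regulatory network reported for geriatric rat corpus cavernosum: the
#' up-regulated lncRNA ENSRNOT00000029245 connected to mRNAs through two
#' up-regulated miRNA axes (miR484x and rno-miR-653-5p). The study enumerates
#' 23 mRNAs exclusive to the miR484x axis and 14 exclusive to the
#' rno-miR-653-5p axis, and reports Il6r as regulated through both axes; the
#' edge lists here therefore carry Il6r on both. All nodes are up-regulated.
#'
#' @return A list: `lncrna`, `axes` (named list of mRNA ids per miRNA axis;
#'   Il6r appears in both), and `directions` (named `up` vector over all
#'   nodes).
#' @export
aed_example_axes <- function() {
  lnc <- "ENSRNOT00000029245"
  mir484x <- c(
    "Tspan18", "Mtss1", "Szrd1", "Pik3cg", "NEWGENE_619861", "Fgf1", "Btrc",
    "B2m", "Ggta1", "kdm4a", "Fxyd7", "Naf1", "Vps9d1", "Ppm1l", "Bcl2l1",
    "RGD1560281", "Scamp1", "Sele", "Nrcam", "Hsp90b1", "Cmpk1", "Fam20b",
    "Hiatl3"
  )
  mir653 <- c(
    "Sorcs3", "LOC100910882", "Morf4l2", "Ptprd", "Hmgcs1", "Lox", "Gpm6a",
    "Trim32", "Tnfrsf11b", "Phf14", "Ncapg2", "Cyyr1", "Reep3", "Nus1"
  )
  axes <- list(
    "miR484x" = c(mir484x, "Il6r"),
    "rno-miR-653-5p" = c(mir653, "Il6r")
  )
  nodes <- c(lnc, names(axes), unique(unlist(axes)))
  list(lncrna = lnc, axes = axes,
       directions = stats::setNames(rep("up", length(nodes)), nodes))
}

#' Build the published A-ED worked-example network
#'
#' Assembles [aed_example_axes()] into a `CeRNANetwork` via
#' [cerna_network_from_edges()].
#'
#' @return A `CeRNANetwork`.
#' @export
aed_example_network <- function() {
  ax <- aed_example_axes()
  lnc_mir <- data.frame(lncrna = ax$lncrna, mirna = names(ax$axes),
                        stringsAsFactors = FALSE)
  mir_mrna <- do.call(rbind, lapply(names(ax$axes), function(m) {
    data.frame(mirna = m, mrna = ax$axes[[m]], stringsAsFactors = FALSE)
  }))
  cerna_network_from_edges(lnc_mir, mir_mrna, ax$directions)
}
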