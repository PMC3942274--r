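#' Analysis thresholds
#'
#' One object holding every numeric decision rule used across the pipeline,
#' so that a report can echo the exact thresholds it was produced under.
#'
#' Defaults encode the study rules this package operationalises:
#' a heteroplasmic SNP needs the minor allele in *more than* 10% of reads at a
#' position covered at least 10x; homologous regions between consensus genomes
#' are retained at >= 95% identity; ORFs are reported at >= 300 bp; an ORF is
#' species-unique when homologous coverage by every other genome is <= 95% of
#' its length; contigs are joined only on an overlap of *more than* 100 bp with
#' < 1% dissimilarity.
#'
#' @param min_depth Minimum read depth for a position to be analysable (>= 10x).
#' @param min_minor_frac Minor-allele read fraction that must be *strictly
#'   exceeded* for a heteroplasmic SNP call (0.10).
#' @param block_min_count Minimum HSNPs to form an HSNP block.
#' @param block_max_gap Maximum bp gap between consecutive HSNPs in a block.
#' @param homology_min_identity Identity cutoff for retained homologous
#'   regions (inclusive at the boundary).
#' @param orf_min_len Minimum ORF length in bp, stop codon included.
#' @param orf_unique_max_cov Maximum homologous coverage (fraction of query
#'   length) for an ORF still classified unique.
#' @param join_min_overlap Contig-join overlap that must be strictly exceeded.
#' @param join_max_dissim Contig-join dissimilarity that must not be reached.
#' @return A list of class `AnalysisThresholds`.
#' @export
analysis_thresholds <- function(min_depth = 10L,
                                min_minor_frac = 0.10,
                                block_min_count = 3L,
                                block_max_gap = 150L,
                                homology_min_identity = 0.95,
                                orf_min_len = 300L,
                                orf_unique_max_cov = 0.95,
                                join_min_overlap = 100L,
                                join_max_dissim = 0.01) {
  th <- list(
    min_depth = as.integer(min_depth),
    min_minor_frac = min_minor_frac,
    block_min_count = as.integer(block_min_count),
    block_max_gap = as.integer(block_max_gap),
    homology_min_identity = homology_min_identity,
    orf_min_len = as.integer(orf_min_len),
    orf_unique_max_cov = orf_unique_max_cov,
    join_min_overlap = as.integer(join_min_overlap),
    join_max_dissim = join_max_dissim
  )
  props <- c("min_minor_frac", "homology_min_identity", "orf_unique_max_cov",
             "join_max_dissim")
  for (p in props) {
    if (!(th[[p]] > 0 && th[[p]] < 1)) stop(p, " must lie in (0, 1)")
  }
  counts <- c("min_depth", "block_min_count", "block_max_gap", "orf_min_len",
              "join_min_overlap")
  for (p in counts) {
    if (th[[p]] < 1L) stop(p, " must be >= 1")
  }
  structure(th, class = c("AnalysisThresholds", "list"))
}
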