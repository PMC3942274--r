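#' Call heteroplasmic SNPs (HSNPs) from a pileup
#'
#' A position is called heteroplasmic when its depth is at least
#' `min_depth` (default 10x) and a single minor allele is observed in *more
#' than* `min_minor_frac` (default 10%) of the reads. The rule is per-allele:
#' the minor allele is the single most frequent non-major base, and two rare
#' bases that only jointly exceed the threshold do not trigger a call.
#' Deletions and insertions never trigger a call, and deleted reads at a
#' position count toward depth but not toward any allele. Ties between equal
#' counts are broken alphabetically (A < C < G < T).
#'
#' @param pileup A `Pileup` from [build_pileup()].
#' @param thresholds An [analysis_thresholds()].
#' @param mask Optional [coverage_mask()]; positions inside its excluded
#'   intervals are skipped entirely.
#' @return data.frame of class `HSNP` with columns pos (0-based),
#'   major_allele, minor_allele, minor_count, depth, minor_frac.
#' @export
call_hsnps <- function(pileup, thresholds = analysis_thresholds(),
                       mask = NULL) {
  empty <- structure(
    data.frame(pos = integer(), major_allele = character(),
               minor_allele = character(), minor_count = integer(),
               depth = integer(), minor_frac = numeric(),
               stringsAsFactors = FALSE),
    class = c("HSNP", "data.frame"))
  if (nrow(pileup) == 0L) return(empty)
  p <- as.data.frame(pileup)
  if (!is.null(mask) && nrow(mask$excluded_intervals) > 0L) {
    iv <- mask$excluded_intervals
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = p$pos + 1L, width = 1L),
      IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    )
    p <- p[!hit, , drop = FALSE]
  }
  if (nrow(p) == 0L) return(empty)
  cm <- as.matrix(p[, c("A", "C", "G", "T")])
  maj_i <- max.col(cm, ties.method = "first")
  maj_count <- cm[cbind(seq_len(nrow(cm)), maj_i)]
  cm2 <- cm
  cm2[cbind(seq_len(nrow(cm)), maj_i)] <- -1L
  min_i <- max.col(cm2, ties.method = "first")
  min_count <- cm2[cbind(seq_len(nrow(cm2)), min_i)]
  call <- p$depth >= thresholds$min_depth &
    min_count > 0L &
    min_count / p$depth > thresholds$min_minor_frac
  out <- data.frame(
    pos = p$pos[call],
    major_allele = BASES[maj_i[call]],
    minor_allele = BASES[min_i[call]],
    minor_count = as.integer(min_count[call]),
    depth = p$depth[call],
    minor_frac = min_count[call] / p$depth[call],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("HSNP", "data.frame"))
}

#' Cluster HSNPs into high-density HSNP blocks
#'
#' Greedy left-to-right chaining: consecutive HSNPs at most `block_max_gap` bp
#' apart join one chain; chains with at least `block_min_count` members become
#' HSNP blocks, all other HSNPs are reported as singletons. Every input HSNP
#' appears in exactly one of the two outputs.
#'
#' @param hsnps An `HSNP` data.frame sorted by position.
#' @param thresholds An [analysis_thresholds()].
#' @return List with `blocks` (data.frame: block_id, start, end, n — start/end
#'   are the positions of the first and last member), `members` (list of HSNP
#'   data.frames, one per block) and `singletons` (HSNP data.frame).
#' @export
cluster_hsnp_blocks <- function(hsnps, thresholds = analysis_thresholds()) {
  if (nrow(hsnps) > 1L && is.unsorted(hsnps$pos, strictly = TRUE)) {
    stop("hsnps must be sorted by position with no duplicates")
  }
  if (nrow(hsnps) == 0L) {
    return(list(
      blocks = data.frame(block_id = integer(), start = integer(),
                          end = integer(), n = integer()),
      members = list(),
      singletons = hsnps
    ))
  }
  chain <- cumsum(c(0L, diff(hsnps$pos) > thresholds$block_max_gap)) + 1L
  sizes <- table(chain)
  is_block <- sizes[as.character(chain)] >= thresholds$block_min_count
  block_chains <- unique(chain[is_block])
  members <- lapply(block_chains, function(ch) {
    m <- hsnps[chain == ch, , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  blocks <- data.frame(
    block_id = seq_along(block_chains),
    start = vapply(members, function(m) m$pos[1L], 0L),
    end = vapply(members, function(m) m$pos[nrow(m)], 0L),
    n = vapply(members, nrow, 0L)
  )
  singletons <- hsnps[!is_block, , drop = FALSE]
  rownames(singletons) <- NULL
  list(blocks = blocks, members = members, singletons = singletons)
}

#' Summarise HSNP calls and their block structure
#'
#' @param hsnps All called HSNPs.
#' @param clusters Result of [cluster_hsnp_blocks()].
#' @param genome_length Genome length in bp.
#' @return List: n_total, n_in_blocks, n_singletons, n_blocks, bp_per_hsnp
#'   (genome_length / n_total rounded to integer; NA when no HSNP was called).
#' @export
hsnp_summary <- function(hsnps, clusters, genome_length) {
  n_in_blocks <- sum(clusters$blocks$n)
  n_single <- nrow(clusters$singletons)
  n_total <- nrow(hsnps)
  if (n_total != n_in_blocks + n_single) {
    stop("blocks + singletons do not partition the HSNP set")
  }
  list(
    n_total = n_total,
    n_in_blocks = n_in_blocks,
    n_singletons = n_single,
    n_blocks = nrow(clusters$blocks),
    bp_per_hsnp = if (n_total > 0L) as.integer(round(genome_length / n_total))
                  else NA_integer_
  )
}

#' Write HSNPs as VCF 4.2 (1-based; ALT is the minor allele)
#' @param hsnps An `HSNP` data.frame.
#' @param genome The reference [circular_genome()].
#' @param path Output path.
#' @export
write_hsnps_vcf <- function(hsnps, genome, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$id, genome$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele read fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(hsnps) > 0L) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
            genome$id, hsnps$pos + 1L, hsnps$major_allele,
            hsnps$minor_allele, hsnps$depth, hsnps$minor_frac)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write HSNPs as TSV (0-based positions)
#' @param hsnps An `HSNP` data.frame.
#' @param path Output path.
#' @export
write_hsnps_tsv <- function(hsnps, path) {
  utils::write.table(as.data.frame(hsnps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write HSNP blocks as BED with member counts
#' @param clusters Result of [cluster_hsnp_blocks()].
#' @param genome_id Sequence name.
#' @param path Output path.
#' @export
write_blocks_bed <- function(clusters, genome_id, path) {
  b <- clusters$blocks
  lines <- if (nrow(b) > 0L) {
    # BED half-open: end member position is inclusive, hence end + 1
    sprintf("%s\t%d\t%d\tblock%d\t%d", genome_id, b$start, b$end + 1L,
            b$block_id, b$n)
  } else character()
  writeLines(lines, path)
  invisible(path)
}
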