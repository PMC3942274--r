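#' Read a SAM file into an alignment record table
#'
#' Converts SAM to BAM via Rsamtools and extracts the fields the pileup
#' builder needs.
#'
#' @param path Path to a SAM file with a valid header.
#' @return data.frame with columns qname, flag, rname, pos (1-based), cigar,
#'   seq.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "seq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
  )
  data.frame(
    qname = S4Vectors::mcols(ga)$qname,
    flag = S4Vectors::mcols(ga)$flag,
    rname = as.character(GenomicAlignments::seqnames(ga)),
    pos = GenomicAlignments::start(ga),
    cigar = GenomicAlignments::cigar(ga),
    seq = as.character(S4Vectors::mcols(ga)$seq),
    stringsAsFactors = FALSE
  )
}

#' Build per-position base-count columns from aligned reads
#'
#' Walks each record's CIGAR: M/=/X bases are tallied into per-base counts,
#' D ops increment the deletion count of the spanned positions, I ops
#' increment the insertion count of the position preceding the insertion.
#' Soft clips and N skips are ignored. Depth counts reads whose CIGAR consumes
#' the reference at a position (M/=/X/D), so `A + C + G + T + del == depth`
#' everywhere (ambiguous read bases are kept in depth but excluded from the
#' base counts). Records whose CIGAR query length disagrees with their
#' sequence length are rejected and counted.
#'
#' @param alignments Either a path to a SAM file or a data.frame of records
#'   (as produced by [read_sam()] or `simulate_reads()$sam`).
#' @param reference The [circular_genome()] the records are aligned to.
#' @return A data.frame of class `Pileup` with columns pos (0-based), depth,
#'   A, C, G, T, del, ins, restricted to covered positions; attribute
#'   `n_rejected` carries the rejected-record count, attribute `genome_length`
#'   the reference length.
#' @export
build_pileup <- function(alignments, reference) {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  L <- reference$length
  empty <- data.frame(pos = integer(), depth = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      del = integer(), ins = integer())
  if (nrow(alignments) == 0L) {
    return(structure(empty, class = c("Pileup", "data.frame"),
                     n_rejected = 0L, genome_length = L))
  }
  al <- alignments[alignments$rname == reference$id, , drop = FALSE]
  ops <- GenomicAlignments::explodeCigarOps(al$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(al$cigar)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(al$cigar)
  ok <- qlen == nchar(al$seq)
  n_rejected <- sum(!ok)
  al <- al[ok, , drop = FALSE]; ops <- ops[ok]; lens <- lens[ok]
  if (nrow(al) == 0L) {
    return(structure(empty, class = c("Pileup", "data.frame"),
                     n_rejected = n_rejected, genome_length = L))
  }

  n_ops <- lengths(ops)
  simple <- n_ops == 1L & vapply(ops, `[[`, "", 1L) == "M"
  m_ref <- list(al$pos[simple])
  m_q <- list(rep(1L, sum(simple)))
  m_len <- list(unlist(lens[simple], use.names = FALSE))
  m_rec <- list(which(simple))
  d_ref <- list(); d_len <- list(); i_ref <- list()
  for (r in which(!simple)) {
    ref_off <- al$pos[r]          # 1-based next reference position
    q_off <- 1L                   # 1-based next query position
    op <- ops[[r]]; ln <- lens[[r]]
    for (j in seq_along(op)) {
      o <- op[j]; w <- ln[j]
      if (o %in% c("M", "=", "X")) {
        m_ref <- c(m_ref, ref_off); m_q <- c(m_q, q_off); m_len <- c(m_len, w)
        m_rec <- c(m_rec, r)
        ref_off <- ref_off + w; q_off <- q_off + w
      } else if (o == "D" || o == "N") {
        if (o == "D") { d_ref <- c(d_ref, ref_off); d_len <- c(d_len, w) }
        ref_off <- ref_off + w
      } else if (o == "I") {
        i_ref <- c(i_ref, ref_off - 1L)
        q_off <- q_off + w
      } else if (o == "S") {
        q_off <- q_off + w
      } # H/P consume nothing relevant
    }
  }
  m_ref <- unlist(m_ref); m_q <- unlist(m_q); m_len <- unlist(m_len)
  m_rec <- unlist(m_rec)
  d_ref <- unlist(d_ref); d_len <- unlist(d_len); i_ref <- unlist(i_ref)

  # expand match blocks into positions and bases
  pos1 <- sequence(m_len, from = m_ref)                    # 1-based ref pos
  bases <- strsplit(paste(substring(al$seq[m_rec], m_q, m_q + m_len - 1L),
                          collapse = ""), "")[[1]]
  stopifnot(length(pos1) == length(bases))
  depth <- tabulate(pos1, nbins = L)
  bi <- match(bases, BASES)
  keep <- !is.na(bi)
  counts <- matrix(0L, nrow = 4L, ncol = L)
  if (any(keep)) {
    tab <- tabulate((pos1[keep] - 1L) * 4L + bi[keep], nbins = 4L * L)
    counts[] <- tab
  }
  del <- integer(L); ins <- integer(L)
  if (length(d_ref) > 0L) {
    dpos <- sequence(d_len, from = d_ref)
    del <- tabulate(dpos, nbins = L)
    depth <- depth + del
  }
  if (length(i_ref) > 0L) {
    ins <- tabulate(i_ref[i_ref >= 1L], nbins = L)
  }
  covered <- which(depth > 0L)
  out <- data.frame(
    pos = covered - 1L, depth = depth[covered],
    A = counts[1L, covered], C = counts[2L, covered],
    G = counts[3L, covered], T = counts[4L, covered],
    del = del[covered], ins = ins[covered]
  )
  structure(out, class = c("Pileup", "data.frame"),
            n_rejected = n_rejected, genome_length = L)
}

#' Coverage mask: genome space excluded from analysis
#'
#' Positions covered below `min_depth` (including positions with no reads at
#' all) are excluded from SNP analysis, mirroring the rule that only regions
#' with at least 10x coverage are searched.
#'
#' @param pileup A `Pileup` from [build_pileup()].
#' @param genome_length Genome length in bp (defaults to the pileup's
#'   reference length).
#' @param min_depth Minimum passing depth; "at least 10x" means depth >= 10
#'   passes.
#' @return List of class `CoverageMask`: `excluded_intervals` (data.frame of
#'   0-based half-open start/end), `excluded_bp`, `excluded_fraction` (rounded
#'   to 4 decimals), `min_depth`, `genome_length`.
#' @export
coverage_mask <- function(pileup, genome_length = attr(pileup, "genome_length"),
                          min_depth = 10L) {
  stopifnot(min_depth >= 1L)
  depth <- integer(genome_length)
  if (nrow(pileup) > 0L) depth[pileup$pos + 1L] <- pileup$depth
  excl <- depth < min_depth
  r <- rle(excl)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  bp <- sum(iv$end - iv$start)
  structure(list(
    excluded_intervals = iv,
    excluded_bp = bp,
    excluded_fraction = round(bp / genome_length, 4),
    min_depth = as.integer(min_depth),
    genome_length = genome_length
  ), class = c("CoverageMask", "list"))
}

#' Write a pileup as TSV (pos, depth, A, C, G, T, del, ins)
#' @param pileup A `Pileup`.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a coverage mask as BED (0-based half-open excluded intervals)
#' @param mask A `CoverageMask`.
#' @param genome_id Sequence name for the BED chrom column.
#' @param path Output path.
#' @export
write_mask_bed <- function(mask, genome_id, path) {
  iv <- mask$excluded_intervals
  lines <- if (nrow(iv) > 0L) {
    sprintf("%s\t%d\t%d\tlow_coverage", genome_id, iv$start, iv$end)
  } else character()
  writeLines(lines, path)
  invisible(path)
}
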