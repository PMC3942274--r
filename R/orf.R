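#' Scan open reading frames on both strands of a circular genome
#'
#' An ORF is an ATG-to-stop span (stop codon included) of at least
#' `orf_min_len` bp (default 300) under the standard genetic code. Both
#' strands and all three frames are scanned; ORFs may wrap the origin once
#' (never longer than the genome). Per stop codon and frame only the longest
#' qualifying ORF is reported (nested later ATGs are suppressed), matching the
#' default behaviour of standard ORF finders. Identifiers are assigned
#' deterministically: records are sorted by (start, strand) and named
#' `orf0`, `orf1`, ... .
#'
#' @param genome A [circular_genome()].
#' @param thresholds An [analysis_thresholds()].
#' @return data.frame of class `OrfRecord`: orf_id, start (0-based, forward
#'   strand), end (half-open; exceeds the genome length when the ORF wraps the
#'   origin), strand, length, seq, protein (translation without the terminal
#'   stop).
#' @export
scan_orfs <- function(genome, thresholds = analysis_thresholds()) {
  L <- genome$length
  min_len <- thresholds$orf_min_len
  recs <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") genome$sequence else
      reverse_complement(genome$sequence)
    doubled <- paste0(S, S)
    find_all <- function(pat) {
      m <- gregexpr(pat, doubled, fixed = TRUE)[[1]]
      if (m[1] == -1L) integer() else as.integer(m) - 1L
    }
    atg <- find_all("ATG")
    atg <- atg[atg < L]
    stops <- sort(c(find_all("TAA"), find_all("TAG"), find_all("TGA")))
    if (length(atg) == 0L) next
    p_all <- integer(); len_all <- integer()
    for (f in 0:2) {
      p <- atg[atg %% 3L == f]
      if (length(p) == 0L) next
      sf <- stops[stops %% 3L == f]
      idx <- findInterval(p, sf) + 1L
      q <- sf[idx]
      ok <- !is.na(q)
      p <- p[ok]; q <- q[ok]
      len <- q + 3L - p
      ok <- len >= min_len & len <= L
      p_all <- c(p_all, p[ok]); len_all <- c(len_all, len[ok])
    }
    if (length(p_all) == 0L) next
    # longest ORF per circular stop codon (stop position taken modulo L so a
    # wrap-reached stop merges with its linear-frame twin)
    grp <- (p_all + len_all - 3L) %% L
    keep <- as.integer(
      tapply(seq_along(p_all), grp, function(ii) ii[which.max(len_all[ii])]))
    for (i in keep) {
      start_local <- p_all[i]
      start_fwd <- if (strand == "+") start_local else
        (L - start_local - len_all[i]) %% L
      seq <- substr(doubled, start_local + 1L, start_local + len_all[i])
      recs[[length(recs) + 1L]] <- list(
        start = start_fwd, end = start_fwd + len_all[i], strand = strand,
        length = len_all[i], seq = seq
      )
    }
  }
  if (length(recs) == 0L) {
    return(structure(
      data.frame(orf_id = character(), start = integer(), end = integer(),
                 strand = character(), length = integer(), seq = character(),
                 protein = character(), stringsAsFactors = FALSE),
      class = c("OrfRecord", "data.frame")))
  }
  out <- as.data.frame(data.table::rbindlist(recs))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "strand", "length")]), , drop = FALSE]
  out$orf_id <- sprintf("orf%d", seq_len(nrow(out)) - 1L)
  out$protein <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(out$seq, 1L, nchar(out$seq) - 3L)),
    genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE))
  rownames(out) <- NULL
  out <- out[, c("orf_id", "start", "end", "strand", "length", "seq",
                 "protein")]
  structure(out, class = c("OrfRecord", "data.frame"))
}

#' Total ORF content of a genome
#'
#' Summed ORF lengths (overlapping ORFs each count their full length) and the
#' percentage of the genome they represent, rounded to one decimal.
#'
#' @param orfs An `OrfRecord` data.frame, or a single numeric total bp.
#' @param genome_length Genome length in bp.
#' @return List: total_bp, percent.
#' @export
orf_genome_fraction <- function(orfs, genome_length) {
  total <- if (is.numeric(orfs) && length(orfs) == 1L) orfs
           else sum(orfs$length)
  list(total_bp = total, percent = round(100 * total / genome_length, 1))
}

#' Classify species-unique ORFs by homologous coverage
#'
#' An ORF is unique to its genome when, against *every* other genome, the
#' merged homologous alignments (95%-identity regions, minimum 50 bp) cover at
#' most `orf_unique_max_cov` (default 95%) of the ORF length: an ORF covered
#' to 96% elsewhere is not unique.
#'
#' @param query_orfs `OrfRecord` data.frame from [scan_orfs()] (must carry the
#'   `seq` column).
#' @param other_genomes List of [circular_genome()] objects to compare
#'   against.
#' @param thresholds An [analysis_thresholds()].
#' @param min_aln_len Minimum homologous-alignment length for ORF-scale
#'   comparison.
#' @return data.frame of class `OrfComparison`: orf_id, best_coverage (the
#'   maximum coverage over subjects), unique, plus one coverage column per
#'   subject genome.
#' @export
classify_unique <- function(query_orfs, other_genomes,
                            thresholds = analysis_thresholds(),
                            min_aln_len = 50L) {
  stopifnot(length(other_genomes) >= 1L)
  n <- nrow(query_orfs)
  cov <- matrix(0, nrow = n, ncol = length(other_genomes))
  subj_ids <- vapply(other_genomes, `[[`, "", "id")
  colnames(cov) <- subj_ids
  for (i in seq_len(n)) {
    orf_g <- circular_genome(query_orfs$orf_id[i], query_orfs$seq[i])
    for (j in seq_along(other_genomes)) {
      alns <- find_homologous_regions(
        orf_g, other_genomes[[j]], thresholds,
        min_len = min_aln_len, circular_subject = TRUE)
      if (length(alns) == 0L) next
      iv <- IRanges::reduce(IRanges::IRanges(
        start = vapply(alns, `[[`, 0, "a_start") + 1L,
        end = vapply(alns, `[[`, 0, "a_end")))
      cov[i, j] <- sum(IRanges::width(iv)) / query_orfs$length[i]
    }
  }
  best <- if (n > 0L) apply(cov, 1L, max) else numeric()
  out <- data.frame(
    orf_id = query_orfs$orf_id,
    best_coverage = best,
    unique = best <= thresholds$orf_unique_max_cov,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(cov))
  structure(out, class = c("OrfComparison", "data.frame"))
}

# Best local alignment of query_sub against gene (both strands); recursion on
# the flanks finds multiple fragments of the same donor gene without masking.
collect_local_segments <- function(query, q_from, q_to, gene_id, gene_seq,
                                   min_segment, min_identity) {
  if (q_to - q_from < min_segment) return(list())
  sub <- substr(query, q_from + 1L, q_to)
  best <- NULL
  for (strand in c("+", "-")) {
    gseq <- if (strand == "+") gene_seq else reverse_complement(gene_seq)
    pa <- Biostrings::pairwiseAlignment(
      sub, gseq, type = "local",
      substitutionMatrix = nuc_submat(), gapOpening = 5, gapExtension = 2)
    if (Biostrings::score(pa) <= 0) next
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- Biostrings::nmatch(pa) / cols
    qs <- q_from + Biostrings::start(Biostrings::pattern(pa)) - 1L
    qe <- q_from + Biostrings::end(Biostrings::pattern(pa))
    gs <- Biostrings::start(Biostrings::subject(pa)) - 1L
    ge <- Biostrings::end(Biostrings::subject(pa))
    if (strand == "-") {
      tmp <- gs
      gs <- nchar(gene_seq) - ge
      ge <- nchar(gene_seq) - tmp
    }
    cand <- list(source_gene = gene_id, q_start = qs, q_end = qe,
                 g_start = gs, g_end = ge, strand = strand,
                 identity = ident, score = Biostrings::score(pa))
    if ((qe - qs) >= min_segment && ident >= min_identity &&
        (is.null(best) || cand$score > best$score)) best <- cand
  }
  if (is.null(best)) return(list())
  c(
    collect_local_segments(query, q_from, best$q_start, gene_id, gene_seq,
                           min_segment, min_identity),
    list(best),
    collect_local_segments(query, best$q_end, q_to, gene_id, gene_seq,
                           min_segment, min_identity)
  )
}

#' Decompose a chimeric ORF into donor-gene fragments
#'
#' Novel mitochondrial ORFs associated with cytoplasmic male sterility are
#' often chimeras stitched from fragments of functional genes. This collects
#' local alignments of the ORF against a gene database (both strands, with
#' recursive flank re-search so several fragments of one donor are found) and
#' tiles them greedily by descending score into non-overlapping query
#' segments; overlapping lower-scoring segments are trimmed to the uncovered
#' part and kept only if still at least `min_segment` bp. Ties break toward
#' the longer segment, then lexicographic gene id.
#'
#' @param orf One row of an `OrfRecord` data.frame (or any list with `seq`),
#'   or a plain character sequence.
#' @param gene_db Named character vector or list mapping gene_id to sequence.
#' @param min_segment Minimum reported fragment length (bp).
#' @param min_identity Minimum fragment identity.
#' @return List of class `ChimeraDecomposition`: `segments` (data.frame:
#'   source_gene, q_start, q_end, g_start, g_end, strand, identity; 0-based
#'   half-open, sorted by q_start) and `unassigned` (data.frame of uncovered
#'   query intervals).
#' @export
decompose_chimera <- function(orf, gene_db, min_segment = 30L,
                              min_identity = 0.90) {
  query <- if (is.character(orf) && length(orf) == 1L) orf else orf$seq
  stopifnot(length(gene_db) >= 1L)
  qlen <- nchar(query)
  cand <- list()
  for (g in names(gene_db)) {
    cand <- c(cand, collect_local_segments(
      query, 0L, qlen, g, as.character(gene_db[[g]]),
      min_segment, min_identity))
  }
  empty_seg <- data.frame(
    source_gene = character(), q_start = integer(), q_end = integer(),
    g_start = integer(), g_end = integer(), strand = character(),
    identity = numeric(), stringsAsFactors = FALSE)
  if (length(cand) == 0L) {
    return(structure(list(
      segments = empty_seg,
      unassigned = data.frame(start = 0L, end = qlen)
    ), class = "ChimeraDecomposition"))
  }
  score <- vapply(cand, `[[`, 0, "score")
  seg_len <- vapply(cand, function(x) x$q_end - x$q_start, 0)
  gid <- vapply(cand, `[[`, "", "source_gene")
  ord <- order(-score, -seg_len, gid)
  covered <- logical(qlen)
  chosen <- list()
  for (i in ord) {
    sg <- cand[[i]]
    idx <- (sg$q_start + 1L):sg$q_end
    free <- !covered[idx]
    if (sum(free) < min_segment) next
    # trim to the leading/trailing uncovered run (greedy tiling)
    r <- range(which(free))
    if (any(covered[idx[r[1]:r[2]]])) next   # would straddle a chosen segment
    trim_lo <- r[1] - 1L; trim_hi <- length(idx) - r[2]
    sg$q_start <- sg$q_start + trim_lo; sg$q_end <- sg$q_end - trim_hi
    if (sg$strand == "+") {
      sg$g_start <- sg$g_start + trim_lo; sg$g_end <- sg$g_end - trim_hi
    } else {
      sg$g_start <- sg$g_start + trim_hi; sg$g_end <- sg$g_end - trim_lo
    }
    covered[(sg$q_start + 1L):sg$q_end] <- TRUE
    chosen[[length(chosen) + 1L]] <- sg
  }
  if (length(chosen) == 0L) {
    return(structure(list(
      segments = empty_seg,
      unassigned = data.frame(start = 0L, end = qlen)
    ), class = "ChimeraDecomposition"))
  }
  segs <- as.data.frame(data.table::rbindlist(
    lapply(chosen, function(x) x[setdiff(names(x), "score")])))
  segs <- segs[order(segs$q_start), , drop = FALSE]
  rownames(segs) <- NULL
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  unass <- data.frame(start = starts[!r$values], end = ends[!r$values])
  structure(list(segments = segs, unassigned = unass),
            class = "ChimeraDecomposition")
}

#' Write ORFs as GFF3 and protein FASTA
#' @param orfs An `OrfRecord` data.frame.
#' @param genome The [circular_genome()] scanned.
#' @param prefix Output prefix (writes `<prefix>.gff3`, `<prefix>_protein.fa`).
#' @export
write_orfs <- function(orfs, genome, prefix) {
  if (nrow(orfs) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = orfs$start + 1L,
                                end = pmin(orfs$end, genome$length)),
      strand = orfs$strand
    )
    gr$type <- "open_reading_frame"
    gr$ID <- orfs$orf_id
    gr$wraps_origin <- orfs$end > genome$length
    rtracklayer::export.gff3(gr, paste0(prefix, ".gff3"))
    aa <- Biostrings::AAStringSet(orfs$protein)
    names(aa) <- orfs$orf_id
    Biostrings::writeXStringSet(aa, paste0(prefix, "_protein.fa"))
  } else {
    writeLines("##gff-version 3", paste0(prefix, ".gff3"))
    file.create(paste0(prefix, "_protein.fa"))
  }
  invisible(prefix)
}
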