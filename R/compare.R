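#' Find homologous regions between two circular genomes
#'
#' Seed-and-extend local homology search standing in for a BLAST comparison of
#' consensus genomes: exact k-mer anchors (default k = 15) are collected on
#' both strands against the doubled subject sequence (so regions crossing the
#' subject's origin are found), merged into diagonal runs, chained across
#' small gaps, and stitched into gapped alignments; inter-anchor gaps are
#' aligned with Needleman-Wunsch (Biostrings). Alignments shorter than
#' `min_len` or below the identity cutoff (default 95%, inclusive at the
#' boundary) are discarded, and alignments contained in a longer one on the
#' same query interval are deduplicated.
#'
#' @param a,b [circular_genome()] objects (query and subject).
#' @param thresholds An [analysis_thresholds()] (identity cutoff).
#' @param min_len Minimum alignment length in columns (default 200 bp;
#'   use ~50 bp when the query is a single ORF).
#' @param k Anchor k-mer size.
#' @param circular_subject Double the subject to catch origin-crossing
#'   homology (default TRUE; set FALSE for linear sequences such as ORFs or
#'   contigs).
#' @return List of class `LocalAlignmentList`; each element has fields
#'   a_start, a_end (0-based half-open on the query), b_start, b_end (0-based
#'   half-open on the forward strand of the subject; end may exceed the
#'   subject length when the region wraps its origin), strand, length
#'   (alignment columns), matches, identity, a_aln, b_aln (gapped alignment
#'   rows; b_aln is written in query orientation).
#' @export
find_homologous_regions <- function(a, b, thresholds = analysis_thresholds(),
                                    min_len = 200L, k = 15L,
                                    circular_subject = TRUE) {
  stopifnot(a$length >= k, b$length >= k)
  out <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") b$sequence else reverse_complement(b$sequence)
    subj_full <- if (circular_subject) paste0(subj, subj) else subj
    chains <- anchor_chains(a$sequence, subj_full, k)
    for (ch in chains) {
      al <- stitch_chain(a$sequence, subj_full, ch, k)
      if (is.null(al)) next
      if (al$length < min_len) next
      if (al$identity < thresholds$homology_min_identity) next
      al$strand <- strand
      # subject coordinates on the forward strand of b
      if (strand == "+") {
        al$b_start <- al$s_start %% b$length
        al$b_end <- al$b_start + (al$s_end - al$s_start)
      } else {
        ns <- nchar(subj_full)
        fwd_start <- ns - al$s_end
        al$b_start <- fwd_start %% b$length
        al$b_end <- al$b_start + (al$s_end - al$s_start)
      }
      al$s_start <- NULL; al$s_end <- NULL
      out[[length(out) + 1L]] <- al
    }
  }
  out <- dedupe_alignments(out, b$length)
  structure(out, class = "LocalAlignmentList")
}

# K-mer anchors -> diagonal runs -> chains. Returns a list of chains, each a
# matrix with columns q_start, q_end, s_start, s_end (0-based half-open exact
# diagonal segments, possibly containing mismatches between anchors on the
# same diagonal).
anchor_chains <- function(query, subject, k,
                          run_gap = 50L, chain_gap = 300L, diag_band = 50L) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(list())
  dtq <- data.table::data.table(
    kmer = substring(query, 1:(nq - k + 1L), k:nq), q = 0:(nq - k))
  dts <- data.table::data.table(
    kmer = substring(subject, 1:(ns - k + 1L), k:ns), s = 0:(ns - k))
  anc <- dtq[dts, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(anc) == 0L) return(list())
  anc[, diag := s - q]
  data.table::setorder(anc, diag, q)
  new_run <- c(TRUE, diff(anc$diag) != 0L | diff(anc$q) > run_gap)
  anc[, run := cumsum(new_run)]
  runs <- anc[, .(q_start = min(q), q_end = max(q) + k,
                  s_start = min(s), s_end = max(s) + k,
                  diag = diag[1L]), by = run]
  data.table::setorder(runs, q_start, s_start)
  used <- rep(FALSE, nrow(runs))
  chains <- list()
  for (i in seq_len(nrow(runs))) {
    if (used[i]) next
    idx <- i; used[i] <- TRUE
    cur <- i
    repeat {
      cand <- which(!used &
                      runs$q_start >= runs$q_end[cur] - 2L * diag_band &
                      runs$q_start - runs$q_end[cur] <= chain_gap &
                      abs(runs$diag - runs$diag[cur]) <= diag_band &
                      runs$s_start >= runs$s_end[cur] - 2L * diag_band)
      if (length(cand) == 0L) break
      nxt <- cand[which.min(runs$q_start[cand])]
      idx <- c(idx, nxt); used[nxt] <- TRUE
      cur <- nxt
    }
    chains[[length(chains) + 1L]] <-
      as.matrix(runs[idx, c("q_start", "q_end", "s_start", "s_end")])
  }
  chains
}

# Stitch a chain of diagonal runs into one gapped alignment with aligned rows.
stitch_chain <- function(query, subject, chain, k) {
  a_parts <- character(); b_parts <- character()
  prev_qe <- NA_integer_; prev_se <- NA_integer_
  q_start <- NA_integer_; s_start <- NA_integer_
  for (i in seq_len(nrow(chain))) {
    qs <- chain[i, "q_start"]; qe <- chain[i, "q_end"]
    ss <- chain[i, "s_start"]; se <- chain[i, "s_end"]
    if (!is.na(prev_qe)) {
      # trim overlap with the previous run (runs are diagonal: trim both rows)
      if (qs < prev_qe) { d <- prev_qe - qs; qs <- qs + d; ss <- ss + d }
      if (ss < prev_se) { d <- prev_se - ss; qs <- qs + d; ss <- ss + d }
      if (qs >= qe || ss >= se) next
      qgap <- substr(query, prev_qe + 1L, qs)
      sgap <- substr(subject, prev_se + 1L, ss)
      if (nchar(qgap) > 0L || nchar(sgap) > 0L) {
        if (nchar(qgap) == nchar(sgap)) {
          a_parts <- c(a_parts, qgap); b_parts <- c(b_parts, sgap)
        } else if (nchar(qgap) == 0L) {
          a_parts <- c(a_parts, strrep("-", nchar(sgap)))
          b_parts <- c(b_parts, sgap)
        } else if (nchar(sgap) == 0L) {
          a_parts <- c(a_parts, qgap)
          b_parts <- c(b_parts, strrep("-", nchar(qgap)))
        } else {
          pa <- Biostrings::pairwiseAlignment(
            qgap, sgap, type = "global",
            substitutionMatrix = nuc_submat(), gapOpening = 5, gapExtension = 2)
          a_parts <- c(a_parts, as.character(Biostrings::alignedPattern(pa)))
          b_parts <- c(b_parts, as.character(Biostrings::alignedSubject(pa)))
        }
      }
    } else {
      q_start <- qs; s_start <- ss
    }
    a_parts <- c(a_parts, substr(query, qs + 1L, qe))
    b_parts <- c(b_parts, substr(subject, ss + 1L, se))
    prev_qe <- qe; prev_se <- se
  }
  if (is.na(prev_qe)) return(NULL)
  a_aln <- paste(a_parts, collapse = "")
  b_aln <- paste(b_parts, collapse = "")
  stopifnot(nchar(a_aln) == nchar(b_aln))
  av <- strsplit(a_aln, "")[[1]]; bv <- strsplit(b_aln, "")[[1]]
  matches <- sum(av == bv & av != "-")
  cols <- length(av)
  list(
    a_start = unname(q_start), a_end = unname(prev_qe),
    s_start = unname(s_start), s_end = unname(prev_se),
    length = cols, matches = matches, identity = matches / cols,
    a_aln = a_aln, b_aln = b_aln
  )
}

nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
}

# Drop alignments whose query interval is contained in a longer alignment on
# the same strand, and alignments duplicated by subject doubling.
dedupe_alignments <- function(alns, b_len) {
  if (length(alns) <= 1L) return(alns)
  key <- vapply(alns, function(x)
    sprintf("%d:%d:%s:%d", x$a_start, x$a_end, x$strand,
            x$b_start %% b_len), "")
  alns <- alns[!duplicated(key)]
  n <- length(alns)
  if (n <= 1L) return(alns)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[i]) next
      if (alns[[j]]$length > alns[[i]]$length &&
          alns[[j]]$a_start <= alns[[i]]$a_start &&
          alns[[j]]$a_end >= alns[[i]]$a_end &&
          alns[[j]]$strand == alns[[i]]$strand) {
        drop[i] <- TRUE
      }
    }
  }
  alns[!drop]
}

#' Tabulate local alignments (BLAST outfmt-6-like)
#' @param alns A `LocalAlignmentList`.
#' @return data.frame: qstart, qend, sstart, send (0-based half-open),
#'   strand, identity, length.
#' @export
alignments_table <- function(alns) {
  if (length(alns) == 0L) {
    return(data.frame(qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), strand = character(),
                      identity = numeric(), length = integer()))
  }
  data.frame(
    qstart = vapply(alns, `[[`, 0, "a_start"),
    qend = vapply(alns, `[[`, 0, "a_end"),
    sstart = vapply(alns, `[[`, 0, "b_start"),
    send = vapply(alns, `[[`, 0, "b_end"),
    strand = vapply(alns, `[[`, "", "strand"),
    identity = vapply(alns, `[[`, 0, "identity"),
    length = vapply(alns, `[[`, 0, "length")
  )
}

#' Call substitution SNPs between two consensus genomes
#'
#' Every mismatch column of the retained homologous alignments yields one SNP;
#' gap columns (insertions/deletions) are never reported. Alleles are reported
#' on the forward strand of each genome; positions covered by several
#' alignments are deduplicated on (a_pos, b_pos).
#'
#' @param alns A `LocalAlignmentList` from [find_homologous_regions()].
#' @param b_len Subject genome length (for wrapping coordinates); taken from
#'   the alignments' `b_end` when omitted.
#' @return data.frame of class `ConsensusSNP`: a_pos, b_pos (0-based forward
#'   strand), a_base, b_base.
#' @export
call_consensus_snps <- function(alns, b_len = NULL) {
  recs <- list()
  for (al in alns) {
    av <- strsplit(al$a_aln, "")[[1]]
    bv <- strsplit(al$b_aln, "")[[1]]
    a_off <- cumsum(av != "-")            # query bases consumed incl. column
    b_off <- cumsum(bv != "-")
    mm <- which(av != "-" & bv != "-" & av != bv)
    if (length(mm) == 0L) next
    a_pos <- al$a_start + a_off[mm] - 1L
    if (al$strand == "+") {
      b_pos <- al$b_start + b_off[mm] - 1L
      b_base <- bv[mm]
    } else {
      # b_aln is the reverse complement of the forward subject
      b_pos <- al$b_end - b_off[mm]
      b_base <- chartr("ACGT", "TGCA", bv[mm])
    }
    if (!is.null(b_len)) b_pos <- b_pos %% b_len
    recs[[length(recs) + 1L]] <- data.frame(
      a_pos = a_pos, b_pos = b_pos, a_base = av[mm], b_base = b_base,
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) {
    return(structure(data.frame(a_pos = integer(), b_pos = integer(),
                                a_base = character(), b_base = character(),
                                stringsAsFactors = FALSE),
                     class = c("ConsensusSNP", "data.frame")))
  }
  out <- do.call(rbind, recs)
  out <- out[!duplicated(out[, c("a_pos", "b_pos")]), , drop = FALSE]
  out <- out[order(out$a_pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ConsensusSNP", "data.frame"))
}

#' Annotate the coding consequence of a substitution within a gene
#'
#' Positions are 1-based relative to the start codon (the A of ATG is
#' position 1), the convention used for reporting variants like A/C^170.
#' The affected codon index is `ceiling(nt_pos / 3)`; reference and mutated
#' codons are translated with the standard genetic code and the change is
#' labelled `"<ref_aa>/<alt_aa>^<codon_index>"`, or `"No change"` when
#' synonymous. Multi-nucleotide substitutions (e.g. a di-nucleotide change
#' within one codon, TG/CA^134-135 giving V/A^45) are supported: `alt`
#' replaces `nchar(alt)` bases starting at `nt_pos`.
#'
#' @param gene_sequence In-frame coding sequence from ATG (gene strand).
#' @param nt_pos 1-based position of the first substituted base.
#' @param alt Replacement base(s) on the gene strand.
#' @param gene_id Identifier used in the output.
#' @return List of class `CodingChange`: gene_id, nt_pos, ref_nt, alt_nt,
#'   codon_index, ref_aa, alt_aa, label.
#' @export
annotate_coding_change <- function(gene_sequence, nt_pos, alt,
                                   gene_id = "gene") {
  len <- nchar(alt)
  if (nt_pos < 1L || nt_pos + len - 1L > nchar(gene_sequence)) {
    stop("nt_pos (plus the substitution length) lies beyond the gene")
  }
  ref_nt <- substr(gene_sequence, nt_pos, nt_pos + len - 1L)
  if (ref_nt == alt) stop("alt equals the reference base(s)")
  mutated <- gene_sequence
  substr(mutated, nt_pos, nt_pos + len - 1L) <- alt
  ci1 <- ceiling(nt_pos / 3)
  ci2 <- ceiling((nt_pos + len - 1L) / 3)
  codon_span <- function(s) substr(s, 3L * (ci1 - 1L) + 1L, 3L * ci2)
  ref_aa <- translate_nt(codon_span(gene_sequence))
  alt_aa <- translate_nt(codon_span(mutated))
  label <- if (ref_aa == alt_aa) "No change" else
    sprintf("%s/%s^%d", ref_aa, alt_aa, ci1)
  structure(list(
    gene_id = gene_id, nt_pos = as.integer(nt_pos), ref_nt = ref_nt,
    alt_nt = alt, codon_index = as.integer(ci1), ref_aa = ref_aa,
    alt_aa = alt_aa, label = label
  ), class = "CodingChange")
}

#' Position of a genome coordinate relative to a gene's start codon
#'
#' @param pos 0-based genome position.
#' @param gene One row of an annotation data.frame (start, end, strand).
#' @return 1-based position relative to the start codon on the gene strand.
#' @export
gene_relative_position <- function(pos, gene) {
  if (pos < gene$start || pos >= gene$end) stop("position outside the gene")
  if (gene$strand == "+") pos - gene$start + 1L else gene$end - pos
}

#' Locate the premature stop created by a frameshifting deletion
#'
#' Removes `del_start..del_end` (1-based, inclusive, gene coordinates relative
#' to the start codon) from an in-frame coding sequence, translates the result
#' and reports the first stop codon — the mechanism by which a small deletion
#' (e.g. a 4-nt loss) truncates a protein. Positions of the stop are reported
#' both in the mutated sequence and mapped back to reference (undeleted)
#' coordinates.
#'
#' @param gene_sequence In-frame coding sequence from ATG.
#' @param del_start,del_end 1-based inclusive deletion bounds.
#' @return List: stop_codon, stop_pos_mutated, stop_pos_reference (1-based
#'   first base of the stop), stop_codon_index, protein (translation up to and
#'   including the stop). `NULL` stop fields when no stop is reached.
#' @export
premature_stop_after_deletion <- function(gene_sequence, del_start, del_end) {
  stopifnot(del_start >= 1L, del_end >= del_start,
            del_end <= nchar(gene_sequence))
  mutated <- paste0(substr(gene_sequence, 1L, del_start - 1L),
                    substr(gene_sequence, del_end + 1L,
                           nchar(gene_sequence)))
  usable <- nchar(mutated) - nchar(mutated) %% 3L
  aa <- translate_nt(substr(mutated, 1L, usable))
  stop_i <- regexpr("*", aa, fixed = TRUE)
  if (stop_i < 0L) {
    return(list(stop_codon = NULL, stop_pos_mutated = NULL,
                stop_pos_reference = NULL, stop_codon_index = NULL,
                protein = aa))
  }
  pos_mut <- 3L * (as.integer(stop_i) - 1L) + 1L
  del_len <- del_end - del_start + 1L
  pos_ref <- if (pos_mut >= del_start) pos_mut + del_len else pos_mut
  list(
    stop_codon = substr(mutated, pos_mut, pos_mut + 2L),
    stop_pos_mutated = pos_mut,
    stop_pos_reference = pos_ref,
    stop_codon_index = as.integer(stop_i),
    protein = substr(aa, 1L, as.integer(stop_i))
  )
}

#' Join two contigs on a suffix/prefix overlap
#'
#' Implements the assembly join rule: contigs are merged only when the best
#' suffix(a)/prefix(b) overlap alignment is *longer than* `join_min_overlap`
#' (strictly more than 100 bp by default) and its dissimilarity — mismatch
#' plus gap columns over all overlap columns — is below `join_max_dissim`
#' (1%). A refusal is a value naming the failed rule, not an error.
#'
#' @param a,b Contig sequences (character) or [circular_genome()] objects.
#' @param thresholds An [analysis_thresholds()].
#' @return List of class `ContigJoin`: `joined` (logical); when joined,
#'   `sequence`, `overlap` (columns), `dissimilarity`; when refused, `reason`.
#' @export
merge_contigs <- function(a, b, thresholds = analysis_thresholds()) {
  if (inherits(a, "CircularGenome")) a <- a$sequence
  if (inherits(b, "CircularGenome")) b <- b$sequence
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix = nuc_submat(), gapOpening = 5, gapExtension = 2)
  p_rng <- c(Biostrings::start(Biostrings::pattern(pa)),
             Biostrings::end(Biostrings::pattern(pa)))
  s_rng <- c(Biostrings::start(Biostrings::subject(pa)),
             Biostrings::end(Biostrings::subject(pa)))
  refuse <- function(reason) {
    structure(list(joined = FALSE, reason = reason), class = "ContigJoin")
  }
  if (Biostrings::score(pa) <= 0 || p_rng[2] < p_rng[1]) {
    return(refuse("no suffix/prefix overlap found"))
  }
  if (p_rng[2] != nchar(a) || s_rng[1] != 1L) {
    return(refuse("best overlap is not suffix(a)/prefix(b)"))
  }
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  matches <- Biostrings::nmatch(pa)
  dissim <- (cols - matches) / cols
  if (cols <= thresholds$join_min_overlap) {
    return(refuse(sprintf(
      "overlap of %d bp is not greater than %d bp", cols,
      thresholds$join_min_overlap)))
  }
  if (dissim >= thresholds$join_max_dissim) {
    return(refuse(sprintf(
      "overlap dissimilarity %.4f is not below %.4f", dissim,
      thresholds$join_max_dissim)))
  }
  structure(list(
    joined = TRUE,
    sequence = paste0(a, substr(b, s_rng[2] + 1L, nchar(b))),
    overlap = cols,
    dissimilarity = dissim
  ), class = "ContigJoin")
}

#' Estimate the false-positive rate of the consensus SNP search
#'
#' Compares region pairs believed identical (conserved gene space) and reports
#' substitution calls per compared bp.
#'
#' @param conserved_pairs List of 2-element character vectors (or lists)
#'   `c(a_region, b_region)`.
#' @param thresholds An [analysis_thresholds()].
#' @return List: rate (SNPs per bp), n_snps, compared_bp.
#' @export
estimate_fp_rate <- function(conserved_pairs,
                             thresholds = analysis_thresholds()) {
  if (length(conserved_pairs) == 0L) stop("no region pairs to compare")
  n_snps <- 0L; compared <- 0L
  for (pr in conserved_pairs) {
    a <- pr[[1]]; b <- pr[[2]]
    if (identical(a, b)) {
      compared <- compared + nchar(a)
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = nuc_submat(), gapOpening = 5, gapExtension = 2)
    av <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    bv <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    both <- av != "-" & bv != "-"
    n_snps <- n_snps + sum(both & av != bv)
    compared <- compared + sum(both)
  }
  if (compared == 0L) stop("zero compared bp")
  list(rate = n_snps / compared, n_snps = n_snps, compared_bp = compared)
}

#' Write consensus SNPs as TSV
#' @param snps A `ConsensusSNP` data.frame.
#' @param path Output path.
#' @export
write_consensus_snps_tsv <- function(snps, path) {
  utils::write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
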