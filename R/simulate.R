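#' @importFrom stats rbinom rnorm runif setNames
NULL

BASES <- c("A", "C", "G", "T")

# Evaluate expr under a fixed seed without leaking RNG state to the caller.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# A random in-frame coding sequence: ATG, n_codons - 2 non-stop codons, stop.
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_codons <- len %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- as.character(Biostrings::mkAllStrings(BASES, 3))
  sense <- setdiff(all_codons, stops)
  mid <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(mid, collapse = ""), sample(stops, 1L))
}

#' Generate a synthetic master mitochondrial genome with gene annotations
#'
#' Builds a random circular genome that emulates the layout of a plant
#' mitochondrial master circle: protein-coding genes (ATG start, in-frame stop,
#' no internal stop) scattered on both strands, plus large repeated sequences
#' placed verbatim at two loci each (the repeats that mediate mitochondrial
#' recombination). Everything is reproducible from `seed`.
#'
#' @param length Genome length in bp.
#' @param n_genes Number of protein-coding genes to plant.
#' @param gene_len_range Length range (bp) for genes; lengths are rounded down
#'   to a codon multiple.
#' @param n_repeats Number of distinct repeat families; each is placed at two
#'   loci.
#' @param repeat_len Repeat length in bp.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with elements `genome` ([circular_genome()]) and `annotations`
#'   (data.frame from [gene_annotations()]), plus `repeats` (data.frame of
#'   planted repeat loci).
#' @export
generate_master <- function(length, n_genes = 30L,
                            gene_len_range = c(300L, 1500L),
                            n_repeats = 2L, repeat_len = 1000L,
                            seed = 1L) {
  stopifnot(length > 0, n_genes >= 0, n_repeats >= 0)
  with_seed(seed, {
    gene_lens <- if (n_genes > 0L) {
      ls <- sample(seq(gene_len_range[1], gene_len_range[2]), n_genes,
                   replace = TRUE)
      pmax(9L, (ls %/% 3L) * 3L)
    } else integer()
    block_lens <- c(gene_lens, rep(repeat_len, 2L * n_repeats))
    if (sum(block_lens) > length) {
      stop(sprintf(
        "infeasible packing: %d bp of genes+repeats exceed genome length %d bp",
        sum(block_lens), length))
    }
    n_blocks <- length(block_lens)
    if (n_blocks == 0L) {
      g <- circular_genome(sprintf("master_seed%d", seed), random_dna(length))
      return(list(
        genome = g,
        annotations = gene_annotations(character(), integer(), integer(),
                                       character(), character(), length),
        repeats = data.frame(repeat_id = character(), start = integer(),
                             end = integer())
      ))
    }
    # block contents
    gene_seqs <- if (n_genes > 0L) vapply(gene_lens, random_cds, "") else character()
    gene_strands <- if (n_genes > 0L) sample(c("+", "-"), n_genes, TRUE) else character()
    rep_seqs <- if (n_repeats > 0L) vapply(rep(repeat_len, n_repeats),
                                           random_dna, "") else character()
    block_seqs <- c(
      ifelse(gene_strands == "-", vapply(gene_seqs, reverse_complement, ""),
             gene_seqs),
      rep(rep_seqs, each = 2L)
    )
    block_kind <- c(rep("gene", n_genes), rep("repeat", 2L * n_repeats))
    block_name <- c(
      if (n_genes > 0L) sprintf("gene%02d", seq_len(n_genes)) else character(),
      if (n_repeats > 0L) rep(sprintf("rep%02d", seq_len(n_repeats)), each = 2L)
      else character()
    )
    # shuffle block order, distribute the slack as random inter-block gaps
    ord <- sample(n_blocks)
    slack <- length - sum(block_lens)
    gaps <- as.vector(stats::rmultinom(1L, slack, rep(1, n_blocks)))
    seq_parts <- character(2L * n_blocks)
    starts <- integer(n_blocks)
    pos <- 0L
    for (i in seq_len(n_blocks)) {
      b <- ord[i]
      seq_parts[2L * i - 1L] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      starts[b] <- pos
      seq_parts[2L * i] <- block_seqs[b]
      pos <- pos + nchar(block_seqs[b])
    }
    sequence <- paste(seq_parts, collapse = "")
    stopifnot(nchar(sequence) == length)
    g <- circular_genome(sprintf("master_seed%d", seed), sequence)
    gi <- which(block_kind == "gene")
    ann <- gene_annotations(
      gene_id = block_name[gi],
      start = starts[gi],
      end = starts[gi] + block_lens[gi],
      strand = gene_strands,
      category = rep("protein", n_genes),
      genome_length = length
    )
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    ri <- which(block_kind == "repeat")
    reps <- data.frame(
      repeat_id = block_name[ri],
      start = starts[ri],
      end = starts[ri] + block_lens[ri],
      stringsAsFactors = FALSE
    )
    list(genome = g, annotations = ann, repeats = reps)
  })
}

# Validate and normalise edit intervals: 0-based half-open, non-wrapping,
# pairwise disjoint across reversals and deletions.
check_edit_intervals <- function(reversals, deletions, L) {
  to_mat <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(integer(), ncol = 2))
    m <- do.call(rbind, lapply(x, function(iv) as.integer(iv[1:2])))
    m
  }
  rv <- to_mat(reversals); dl <- to_mat(deletions)
  all_iv <- rbind(rv, dl)
  if (nrow(all_iv) > 0L) {
    if (any(all_iv[, 1] < 0L | all_iv[, 2] > L | all_iv[, 1] >= all_iv[, 2])) {
      stop("edit intervals must satisfy 0 <= start < end <= genome length")
    }
    o <- order(all_iv[, 1])
    s <- all_iv[o, 1]; e <- all_iv[o, 2]
    if (nrow(all_iv) > 1L && any(s[-1] < e[-length(e)])) {
      stop("edit intervals must be pairwise non-overlapping")
    }
  }
  list(reversals = rv, deletions = dl)
}

# Segment map between a mitotype and its master: rows in mitotype order,
# columns m_start, m_end (master, 0-based half-open), mt_start, mt_end,
# strand (+1 forward, -1 reversed-in-place).
mitotype_segment_map <- function(reversals, deletions, L) {
  ed <- check_edit_intervals(asplit_rows(reversals), asplit_rows(deletions), L)
  rv <- ed$reversals; dl <- ed$deletions
  bounds <- sort(unique(c(0L, L, rv[, 1], rv[, 2], dl[, 1], dl[, 2])))
  segs <- cbind(m_start = bounds[-length(bounds)], m_end = bounds[-1])
  keep <- logical(nrow(segs)); strand <- integer(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]
    in_del <- nrow(dl) > 0L && any(dl[, 1] <= s & s < dl[, 2])
    in_rev <- nrow(rv) > 0L && any(rv[, 1] <= s & s < rv[, 2])
    keep[i] <- !in_del
    strand[i] <- if (in_rev) -1L else 1L
  }
  segs <- segs[keep, , drop = FALSE]; strand <- strand[keep]
  w <- segs[, 2] - segs[, 1]
  mt_end <- cumsum(w)
  cbind(m_start = segs[, 1], m_end = segs[, 2],
        mt_start = mt_end - w, mt_end = mt_end, strand = strand)
}

asplit_rows <- function(m) {
  if (is.null(m) || length(m) == 0L) return(list())
  if (is.matrix(m)) lapply(seq_len(nrow(m)), function(i) m[i, ]) else m
}

#' Derive a mitotype from a master genome
#'
#' Applies substitutions, segment reversals (in-place reverse complement) and
#' deletions to the master circle and records the complete edit list as truth.
#' Substitution positions are drawn outside reversal/deletion intervals, so a
#' substitution's master coordinate is also its alignment coordinate against
#' the master — this keeps the simulated heteroplasmy truth table exact.
#'
#' @param master List from [generate_master()], or a [circular_genome()] (then
#'   pass `annotations` separately).
#' @param n_subst Number of substitutions to plant (never recreating the
#'   reference base).
#' @param reversals,deletions Lists of `c(start, end)` 0-based half-open
#'   master intervals; all edit intervals must be pairwise disjoint and must
#'   not wrap the origin.
#' @param fraction Stoichiometric fraction of this mitotype in the chondriome.
#' @param seed Integer seed for substitution placement.
#' @param annotations Optional annotation data.frame (taken from `master` when
#'   it comes from [generate_master()]).
#' @param id Identifier; default derives from the master id.
#' @return Object of class `Mitotype`: list with `genome`, `fraction`,
#'   `truth_edits` (substitutions/reversals/deletions), `segment_map`,
#'   `annotations` (lifted; genes overlapping an edit boundary or inside a
#'   deletion are dropped, genes inside a reversal flip strand), `master_id`.
#' @export
derive_mitotype <- function(master, n_subst = 0L, reversals = list(),
                            deletions = list(), fraction = 1, seed = 1L,
                            annotations = NULL, id = NULL) {
  if (!inherits(master, "CircularGenome")) {
    annotations <- if (is.null(annotations)) master$annotations else annotations
    master <- master$genome
  }
  stopifnot(fraction >= 0, fraction <= 1)
  L <- master$length
  ed <- check_edit_intervals(reversals, deletions, L)
  rv <- ed$reversals; dl <- ed$deletions
  in_any <- function(p, m) {
    if (nrow(m) == 0L) return(rep(FALSE, length(p)))
    out <- rep(FALSE, length(p))
    for (i in seq_len(nrow(m))) out <- out | (p >= m[i, 1] & p < m[i, 2])
    out
  }
  subs <- with_seed(seed, {
    cand <- 0:(L - 1L)
    cand <- cand[!in_any(cand, rbind(rv, dl))]
    if (n_subst > length(cand)) stop("not enough editable positions for n_subst")
    pos <- if (n_subst > 0L) sort(sample(cand, n_subst)) else integer()
    ref <- if (n_subst > 0L) substring(master$sequence, pos + 1L, pos + 1L)
           else character()
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "",
                  USE.NAMES = FALSE)
    data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  })
  seq_vec <- strsplit(master$sequence, "")[[1]]
  if (nrow(subs) > 0L) seq_vec[subs$pos + 1L] <- subs$alt
  for (i in seq_len(nrow(rv))) {
    idx <- (rv[i, 1] + 1L):rv[i, 2]
    seq_vec[idx] <- rev(chartr("ACGT", "TGCA", seq_vec[idx]))
  }
  del_mask <- in_any(seq_along(seq_vec) - 1L, dl)
  mt_seq <- paste(seq_vec[!del_mask], collapse = "")
  segmap <- mitotype_segment_map(rv, dl, L)
  mt_id <- if (is.null(id)) sprintf("%s_mt_seed%d", master$id, seed) else id
  lifted <- lift_annotations(annotations, segmap)
  structure(list(
    genome = circular_genome(mt_id, mt_seq),
    fraction = fraction,
    truth_edits = list(substitutions = subs, reversals = rv, deletions = dl),
    segment_map = segmap,
    annotations = lifted,
    master_id = master$id
  ), class = "Mitotype")
}

# Lift master annotations through the segment map. Genes fully inside one
# segment lift cleanly (reversed segments flip strand); genes crossing a
# segment boundary are dropped.
lift_annotations <- function(ann, segmap) {
  if (is.null(ann) || nrow(ann) == 0L) return(ann)
  keep <- logical(nrow(ann))
  new_start <- integer(nrow(ann)); new_end <- integer(nrow(ann))
  new_strand <- ann$strand
  for (i in seq_len(nrow(ann))) {
    s <- ann$start[i]; e <- ann$end[i]
    j <- which(segmap[, "m_start"] <= s & e <= segmap[, "m_end"])
    if (length(j) != 1L) next
    keep[i] <- TRUE
    if (segmap[j, "strand"] == 1L) {
      new_start[i] <- segmap[j, "mt_start"] + (s - segmap[j, "m_start"])
      new_end[i] <- new_start[i] + (e - s)
    } else {
      new_end[i] <- segmap[j, "mt_start"] + (segmap[j, "m_end"] - s)
      new_start[i] <- new_end[i] - (e - s)
      new_strand[i] <- if (ann$strand[i] == "+") "-" else "+"
    }
  }
  out <- ann[keep, , drop = FALSE]
  out$start <- new_start[keep]; out$end <- new_end[keep]
  out$strand <- new_strand[keep]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replay a mitotype's truth edits on the master sequence
#'
#' Independent reconstruction used by the truth invariants: substitutions
#' first, then in-place reversals, then deletions.
#'
#' @param master A [circular_genome()].
#' @param truth_edits The `truth_edits` element of a `Mitotype`.
#' @return Character scalar: the reconstructed mitotype sequence.
#' @export
replay_edits <- function(master, truth_edits) {
  seq_vec <- strsplit(master$sequence, "")[[1]]
  subs <- truth_edits$substitutions
  if (!is.null(subs) && nrow(subs) > 0L) seq_vec[subs$pos + 1L] <- subs$alt
  rv <- truth_edits$reversals
  for (i in seq_len(NROW(rv))) {
    idx <- (rv[i, 1] + 1L):rv[i, 2]
    seq_vec[idx] <- rev(chartr("ACGT", "TGCA", seq_vec[idx]))
  }
  dl <- truth_edits$deletions
  drop <- rep(FALSE, length(seq_vec))
  for (i in seq_len(NROW(dl))) drop[(dl[i, 1] + 1L):dl[i, 2]] <- TRUE
  paste(seq_vec[!drop], collapse = "")
}

#' Read-simulation configuration
#'
#' Emulates 454 GS FLX single-end shotgun sequencing: read lengths follow a
#' truncated normal (mean 449 bp, bounds 100-1000 bp, matching the platform's
#' read-length range), substitution errors are uniform over the three
#' alternative bases, and homopolymer-indel errors are off by default (the
#' downstream caller ignores indels; a non-zero `indel_error` exists only to
#' stress the pileup builder).
#'
#' @param mean_depth Target fold-coverage of the master genome.
#' @param read_len_mean,read_len_sd Read length distribution (bp).
#' @param subst_error Per-base substitution error probability.
#' @param indel_error Per-base probability of a 1-bp insertion or deletion.
#' @param seed Integer seed.
#' @return List of class `ReadSimConfig`.
#' @export
read_sim_config <- function(mean_depth, read_len_mean = 449,
                            read_len_sd = 100, subst_error = 0.01,
                            indel_error = 0, seed = 1L) {
  stopifnot(mean_depth > 0, read_len_mean > 0, read_len_sd >= 0,
            subst_error >= 0, subst_error <= 1,
            indel_error >= 0, indel_error <= 1)
  structure(list(mean_depth = mean_depth, read_len_mean = read_len_mean,
                 read_len_sd = read_len_sd, subst_error = subst_error,
                 indel_error = indel_error, seed = as.integer(seed)),
            class = c("ReadSimConfig", "list"))
}

#' Simulate single-end reads from a mitotype mixture
#'
#' Each read is drawn from a mitotype with probability equal to its
#' stoichiometric fraction, sampled uniformly around that mitotype's circle,
#' given a truncated-normal length, and sequenced with uniform substitution
#' errors. Truth alignments against the master coordinate system are emitted as
#' SAM records: reads wrapping the origin (and reads crossing a reversal
#' boundary) are split into records sharing the read name; reads spanning a
#' mitotype deletion carry a D CIGAR op.
#'
#' @param mitotypes List of `Mitotype` objects (fractions must sum to 1).
#' @param master The master [circular_genome()] (SAM reference).
#' @param cfg A [read_sim_config()].
#' @return Object of class `ReadSet`: list with `reads` (data.frame: qname,
#'   mitotype, mt_start, length, n_errors, seq), `sam` (data.frame of truth
#'   alignment records), `errors` (data.frame: qname, read_pos, true_base,
#'   read_base), `hsnp_truth` (data.frame: pos, ref, alt, true_minor_frac),
#'   `master_id`, `cfg`.
#' @export
simulate_reads <- function(mitotypes, master, cfg) {
  if (inherits(mitotypes, "Mitotype")) mitotypes <- list(mitotypes)
  fr <- vapply(mitotypes, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("mitotype fractions must sum to 1 (got %.6f)", sum(fr)))
  }
  L <- master$length
  n_reads <- max(1L, as.integer(round(cfg$mean_depth * L / cfg$read_len_mean)))
  with_seed(cfg$seed, {
    mt_idx <- sample.int(length(mitotypes), n_reads, replace = TRUE, prob = fr)
    lens <- round(rnorm(n_reads, cfg$read_len_mean, cfg$read_len_sd))
    bad <- which(lens < 100 | lens > 1000)
    while (length(bad) > 0L) {
      lens[bad] <- round(rnorm(length(bad), cfg$read_len_mean, cfg$read_len_sd))
      bad <- bad[lens[bad] < 100 | lens[bad] > 1000]
    }
    mt_lens <- vapply(mitotypes, function(m) m$genome$length, 0L)
    lens <- as.integer(pmin(lens, mt_lens[mt_idx]))
    starts <- as.integer(floor(runif(n_reads) * mt_lens[mt_idx]))
    qnames <- sprintf("read%06d", seq_len(n_reads))

    seqs <- character(n_reads)
    n_err <- integer(n_reads)
    err_list <- vector("list", n_reads)
    sam_list <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      m <- mitotypes[[mt_idx[i]]]
      raw <- circ_substr(m$genome, starts[i], lens[i])
      ne <- rbinom(1L, lens[i], cfg$subst_error)
      ep <- if (ne > 0L) sort(sample.int(lens[i], ne)) else integer()
      rv <- strsplit(raw, "")[[1]]
      if (ne > 0L) {
        tb <- rv[ep]
        nb <- vapply(tb, function(b) sample(setdiff(BASES, b), 1L), "",
                     USE.NAMES = FALSE)
        rv[ep] <- nb
        err_list[[i]] <- data.frame(qname = qnames[i], read_pos = ep - 1L,
                                    true_base = tb, read_base = nb,
                                    stringsAsFactors = FALSE)
      }
      read_seq <- paste(rv, collapse = "")
      if (cfg$indel_error > 0) {
        read_seq <- apply_indel_errors(read_seq, cfg$indel_error)
      }
      seqs[i] <- read_seq
      n_err[i] <- ne
      sam_list[[i]] <- read_sam_records(
        qname = qnames[i], read_seq = read_seq, mt_start = starts[i],
        mt_len = nchar(read_seq), segmap = m$segment_map, rname = master$id
      )
    }
    sam <- as.data.frame(data.table::rbindlist(
      unlist(sam_list, recursive = FALSE)))
    errors <- if (any(n_err > 0L)) {
      as.data.frame(data.table::rbindlist(
        err_list[!vapply(err_list, is.null, TRUE)]))
    } else {
      data.frame(qname = character(), read_pos = integer(),
                 true_base = character(), read_base = character())
    }
    structure(list(
      reads = data.frame(qname = qnames, mitotype = mt_idx,
                         mt_start = starts, length = lens, n_errors = n_err,
                         seq = seqs, stringsAsFactors = FALSE),
      sam = sam,
      errors = errors,
      hsnp_truth = hsnp_truth_table(mitotypes, master),
      master_id = master$id,
      cfg = cfg
    ), class = "ReadSet")
  })
}

# 454-style 1-bp homopolymer indels, for stress-testing the pileup builder
# only (truth SAM CIGARs do not model them; callers enabling indel_error get a
# read set whose alignments are approximate by design).
apply_indel_errors <- function(read_seq, rate) {
  v <- strsplit(read_seq, "")[[1]]
  n <- length(v)
  hits <- which(runif(n) < rate)
  if (length(hits) == 0L) return(read_seq)
  for (p in rev(hits)) {
    if (runif(1) < 0.5) v <- append(v, v[p], after = p) else v <- v[-p]
  }
  paste(v, collapse = "")
}

# Map one read (mitotype interval [mt_start, mt_start+mt_len) mod Lmt) through
# the segment map into SAM records against the master.
read_sam_records <- function(qname, read_seq, mt_start, mt_len, segmap, rname) {
  Lmt <- segmap[nrow(segmap), "mt_end"]
  iv <- if (mt_start + mt_len <= Lmt) {
    cbind(mt_start, mt_start + mt_len)
  } else {
    rbind(c(mt_start, Lmt), c(0L, mt_start + mt_len - Lmt))
  }
  pieces <- list()   # each: ref_start, ref_end, strand, read_from, read_to
  read_off <- 0L
  for (r in seq_len(nrow(iv))) {
    s <- iv[r, 1]; e <- iv[r, 2]
    hit <- which(segmap[, "mt_end"] > s & segmap[, "mt_start"] < e)
    for (j in hit) {
      ps <- max(s, segmap[j, "mt_start"]); pe <- min(e, segmap[j, "mt_end"])
      if (segmap[j, "strand"] == 1L) {
        rs <- segmap[j, "m_start"] + (ps - segmap[j, "mt_start"])
        re <- rs + (pe - ps)
      } else {
        re <- segmap[j, "m_end"] - (ps - segmap[j, "mt_start"])
        rs <- re - (pe - ps)
      }
      pieces[[length(pieces) + 1L]] <- c(
        ref_start = unname(rs), ref_end = unname(re),
        strand = unname(segmap[j, "strand"]),
        read_from = unname(read_off + (ps - s)),
        read_to = unname(read_off + (pe - s))
      )
    }
    read_off <- read_off + (e - s)
  }
  pm <- do.call(rbind, pieces)
  # merge consecutive forward pieces separated only by a master deletion
  merged <- list(); cur <- NULL
  for (i in seq_len(nrow(pm))) {
    p <- as.list(pm[i, ])
    if (!is.null(cur) && cur$strand == 1L && p$strand == 1L &&
        p$read_from == cur$read_to && p$ref_start > cur$ref_end) {
      cur$gaps <- rbind(cur$gaps, c(cur$ref_end, p$ref_start))
      cur$ref_end <- p$ref_end
      cur$read_to <- p$read_to
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- p; cur$gaps <- NULL
    }
  }
  merged[[length(merged) + 1L]] <- cur
  recs <- lapply(seq_along(merged), function(k) {
    p <- merged[[k]]
    piece_seq <- substr(read_seq, p[["read_from"]] + 1L, p[["read_to"]])
    gaps <- p$gaps
    if (p[["strand"]] == 1L) {
      flag <- if (k == 1L) 0L else 2048L
      if (is.null(gaps)) {
        cigar <- sprintf("%dM", nchar(piece_seq))
      } else {
        bnds <- sort(unique(c(p[["ref_start"]], as.vector(gaps), p[["ref_end"]])))
        ops <- character()
        for (b in seq_len(length(bnds) - 1L)) {
          w <- bnds[b + 1L] - bnds[b]
          is_gap <- any(gaps[, 1] == bnds[b])
          ops <- c(ops, sprintf("%d%s", w, if (is_gap) "D" else "M"))
        }
        cigar <- paste(ops, collapse = "")
      }
      list(qname = qname, flag = flag, rname = rname,
           pos = as.integer(p[["ref_start"]]) + 1L, cigar = cigar,
           seq = piece_seq)
    } else {
      flag <- if (k == 1L) 16L else (16L + 2048L)
      list(qname = qname, flag = flag, rname = rname,
           pos = as.integer(p[["ref_start"]]) + 1L,
           cigar = sprintf("%dM", nchar(piece_seq)),
           seq = revcomp_chr(piece_seq))
    }
  })
  recs
}

# chartr-based reverse complement for hot loops (no Biostrings object churn)
revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Pooled truth table of heteroplasmic positions implied by the mitotype
# substitution edits (alignment coordinates == master coordinates by
# construction; see derive_mitotype).
hsnp_truth_table <- function(mitotypes, master) {
  fr <- vapply(mitotypes, `[[`, 0, "fraction")
  recs <- list()
  for (k in seq_along(mitotypes)) {
    subs <- mitotypes[[k]]$truth_edits$substitutions
    if (!is.null(subs) && nrow(subs) > 0L) {
      recs[[length(recs) + 1L]] <- cbind(subs, fraction = fr[k])
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      true_minor_frac = numeric()))
  }
  all <- do.call(rbind, recs)
  out <- lapply(split(all, all$pos), function(d) {
    allele_fr <- c(setNames(1 - sum(d$fraction), d$ref[1]),
                   tapply(d$fraction, d$alt, sum))
    allele_fr <- sort(allele_fr, decreasing = TRUE)
    minor <- if (length(allele_fr) > 1L) allele_fr[2] else 0
    data.frame(pos = d$pos[1], ref = d$ref[1],
               alt = names(allele_fr)[2],
               true_minor_frac = unname(minor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$true_minor_frac > 0, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write simulated reads as FASTQ (constant quality "I")
#' @param rs A `ReadSet`.
#' @param path Output path.
#' @export
write_fastq <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", rs$reads$qname, "\n", rs$reads$seq, "\n+\n",
                    strrep("I", nchar(rs$reads$seq))), con)
  invisible(path)
}

#' Write truth alignments as SAM
#' @param rs A `ReadSet`.
#' @param master The master [circular_genome()] the records refer to.
#' @param path Output path.
#' @export
write_sam <- function(rs, master, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", master$id, master$length))
  s <- rs$sam
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  s$qname, s$flag, s$rname, s$pos, s$cigar, s$seq,
                  strrep("I", nchar(s$seq)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulation truth tables as TSV
#'
#' Writes `<prefix>_reads.tsv`, `<prefix>_errors.tsv`, `<prefix>_hsnp_truth.tsv`
#' and `<prefix>_mitotypes.tsv` (fractions and edit counts).
#' @param rs A `ReadSet`.
#' @param mitotypes The mitotype list the reads were drawn from.
#' @param prefix Output path prefix.
#' @export
write_truth_tables <- function(rs, mitotypes, prefix) {
  wt <- function(d, suffix) {
    utils::write.table(d, paste0(prefix, suffix), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(rs$reads[, c("qname", "mitotype", "mt_start", "length", "n_errors")],
     "_reads.tsv")
  wt(rs$errors, "_errors.tsv")
  wt(rs$hsnp_truth, "_hsnp_truth.tsv")
  mt <- data.frame(
    mitotype = seq_along(mitotypes),
    id = vapply(mitotypes, function(m) m$genome$id, ""),
    fraction = vapply(mitotypes, `[[`, 0, "fraction"),
    n_subst = vapply(mitotypes, function(m)
      nrow(m$truth_edits$substitutions), 0L),
    n_reversals = vapply(mitotypes, function(m)
      NROW(m$truth_edits$reversals), 0L),
    n_deletions = vapply(mitotypes, function(m)
      NROW(m$truth_edits$deletions), 0L)
  )
  wt(mt, "_mitotypes.tsv")
  invisible(prefix)
}
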