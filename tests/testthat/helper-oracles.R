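# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately use naive enumeration / seqinr rather than the package
# code paths they check.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Codon-table oracle via seqinr (independent of Biostrings::translate).
oracle_translate <- function(nt) {
  paste(seqinr::translate(seqinr::s2c(tolower(nt))), collapse = "")
}

# Brute-force six-frame circular ORF enumeration: every ATG, walk codons to
# the first stop, keep spans >= min_len (stop included), longest per circular
# stop and strand. Returns a sorted data.frame(start, end, strand, length)
# in forward-genome coordinates (end may exceed L for origin-wrapping ORFs).
oracle_orfs <- function(sequence, min_len = 300L) {
  L <- nchar(sequence)
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  recs <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") sequence else revcomp(sequence)
    dbl <- paste0(S, S)
    for (p in 0:(L - 1L)) {
      if (substr(dbl, p + 1L, p + 3L) != "ATG") next
      q <- p + 3L
      stop_at <- NA_integer_
      while (q + 3L <= p + L) {
        cod <- substr(dbl, q + 1L, q + 3L)
        if (cod %in% c("TAA", "TAG", "TGA")) { stop_at <- q; break }
        q <- q + 3L
      }
      if (is.na(stop_at)) next
      len <- stop_at + 3L - p
      if (len < min_len) next
      recs[[length(recs) + 1L]] <-
        data.frame(p_local = p, stop_mod = stop_at %% L, strand = strand,
                   length = len, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer()))
  }
  d <- do.call(rbind, recs)
  keep <- do.call(rbind, lapply(
    split(d, paste(d$strand, d$stop_mod)),
    function(g) g[which.max(g$length), ]))
  start_fwd <- ifelse(keep$strand == "+", keep$p_local,
                      (L - keep$p_local - keep$length) %% L)
  out <- data.frame(start = as.integer(start_fwd),
                    end = as.integer(start_fwd + keep$length),
                    strand = keep$strand, length = keep$length)
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Exhaustive adjacency-set comparison for signed circular permutations:
# naive nested-loop membership test, no canonical encodings shared with the
# implementation's vectorised pmin() trick.
oracle_breakpoints <- function(a_genes, a_signs, b_genes, b_signs) {
  n <- length(a_genes)
  adj <- function(genes, signs) {
    lapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      list(g1 = genes[i], s1 = signs[i], g2 = genes[j], s2 = signs[j])
    })
  }
  same_adj <- function(x, y) {
    (x$g1 == y$g1 && x$s1 == y$s1 && x$g2 == y$g2 && x$s2 == y$s2) ||
      (x$g1 == y$g2 && x$s1 == -y$s2 && x$g2 == y$g1 && x$s2 == -y$s1)
  }
  A <- adj(a_genes, a_signs); B <- adj(b_genes, b_signs)
  sum(vapply(A, function(x) !any(vapply(B, same_adj, TRUE, x = x)), TRUE))
}

# All signed circular permutations of n symbols: element 1 fixed at the first
# position (rotation representative), with free sign; returns a list of
# list(genes, signs).
all_signed_circular_perms <- function(n) {
  syms <- letters[seq_len(n)]
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  tails <- perms_of(syms[-1L])
  signsets <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- list()
  for (tl in tails) {
    genes <- c(syms[1L], tl)
    for (r in seq_len(nrow(signsets))) {
      out[[length(out) + 1L]] <- list(genes = genes,
                                      signs = unname(signsets[r, ]))
    }
  }
  out
}

# Synthetic stand-in for the nad9 coding sequence (the real supplementary
# alignment is not redistributable here). It embeds only the printed variant
# anatomy: codon 40 AAT (N), 41 TCT (S), 42 AAA (K); codon 45 GTG (V) with
# TGTG occupying nt 134-137; an in-frame TAG at reference nt 158-160 that is
# exposed (codon 52 of the shifted frame) when nt 134-137 are deleted; and no
# earlier stop in the shifted frame between the deletion and nt 158.
synthetic_nad9 <- function() {
  codons <- character(60)
  set.seed(42)
  sense <- setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  codons[] <- sample(sense, 60, replace = TRUE)
  codons[1] <- "ATG"
  codons[40] <- "AAT"   # N; A->C at nt 118 gives CAT = H
  codons[41] <- "TCT"   # S; C->A at nt 122 gives TAT = Y
  codons[42] <- "AAA"   # K; A->T at nt 125 gives ATA = I
  codons[45] <- "GTG"   # V; TG->CA at nt 134-135 gives GCA = A
  codons[46] <- "TGC"   # C; completes the TGTG run at nt 134-137
  codons[60] <- "TAA"
  seqv <- strsplit(paste(codons, collapse = ""), "")[[1]]
  # after deleting nt 134-137 the shifted frame reads ref nt 133,138,139 |
  # 140,141,142 | ... ; make every shifted codon before nt 158 a sense codon
  # (setting its first base to C can never create a stop in either frame),
  # then plant TAG at reference nt 158-160 (shifted codon 52).
  for (st in seq(140L, 155L, by = 3L)) {
    if (paste(seqv[st:(st + 2L)], collapse = "") %in%
        c("TAA", "TAG", "TGA")) {
      seqv[st] <- "C"
    }
  }
  seqv[158:160] <- c("T", "A", "G")
  # the frameshift must not hit a stop before 158: fix the straddling codon
  stopifnot(!(paste(seqv[c(133L, 138L, 139L)], collapse = "") %in%
                c("TAA", "TAG", "TGA")))
  paste(seqv, collapse = "")
}

# Small trio of related genomes used by the comparison/report tests.
make_test_trio <- function(length = 15000L, seed = 11L) {
  m <- generate_master(length, n_genes = 12L, gene_len_range = c(300L, 600L),
                       n_repeats = 0L, repeat_len = 0L, seed = seed)
  child <- derive_mitotype(m, n_subst = 10L,
                           reversals = list(c(2000L, 3500L)),
                           fraction = 1, seed = seed + 1L, id = "child")
  parent_b <- derive_mitotype(m, n_subst = 40L,
                              reversals = list(c(4500L, 8000L),
                                               c(9000L, 12000L)),
                              deletions = list(c(13000L, 13400L)),
                              fraction = 1, seed = seed + 2L, id = "parentB")
  list(master = m, child = child, parent_b = parent_b)
}
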