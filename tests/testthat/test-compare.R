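test_that("self-comparison yields one full-length alignment at identity 1", {
  g <- circular_genome("s", random_seq(5000, seed = 31))
  alns <- find_homologous_regions(g, g)
  expect_equal(length(alns), 1L)
  expect_equal(alns[[1]]$a_start, 0)
  expect_equal(alns[[1]]$a_end, 5000)
  expect_equal(alns[[1]]$identity, 1)
  expect_equal(alns[[1]]$strand, "+")
})

test_that("a reversed segment aligns on the minus strand, flanks on plus", {
  g <- circular_genome("a", random_seq(6000, seed = 32))
  v <- strsplit(g$sequence, "")[[1]]
  seg <- 2501:3500
  v[seg] <- rev(chartr("ACGT", "TGCA", v[seg]))
  b <- circular_genome("b", paste(v, collapse = ""))
  alns <- find_homologous_regions(g, b)
  tab <- alignments_table(alns)
  plus <- tab[tab$strand == "+", ]
  minus <- tab[tab$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  # the reversed kilobase found in reverse orientation at its locus
  expect_lt(abs(minus$qstart - 2500), 20)
  expect_lt(abs(minus$qend - 3500), 20)
  expect_lt(abs(minus$sstart - 2500), 20)
  # both flanks found forward
  expect_true(any(plus$qstart <= 10 & plus$qend >= 2400))
  expect_true(any(plus$qstart <= 3600 & plus$qend >= 5900))
})

test_that("heavily mutated sequence falls below the identity cutoff", {
  g <- circular_genome("a", random_seq(4000, seed = 33))
  set.seed(34)
  v <- strsplit(g$sequence, "")[[1]]
  hit <- sample(4000, 400)
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  b <- circular_genome("b", paste(v, collapse = ""))
  alns <- find_homologous_regions(g, b)
  covered <- sum(vapply(alns, function(x) x$a_end - x$a_start, 0))
  expect_lt(covered, 2000)  # 90% identity genome-wide: homology collapses
})

test_that("consensus SNP calling reports planted substitutions and skips indels", {
  g <- circular_genome("a", random_seq(5000, seed = 35))
  v <- strsplit(g$sequence, "")[[1]]
  planted <- c(500L, 1200L, 2000L, 2500L, 3000L, 4000L, 4499L)  # 0-based
  for (p in planted) {
    v[p + 1] <- setdiff(c("A", "C", "G", "T"), v[p + 1])[1]
  }
  b <- circular_genome("b", paste(v, collapse = ""))
  snps <- call_consensus_snps(find_homologous_regions(g, b), b_len = b$length)
  expect_equal(sort(snps$a_pos), planted)
  expect_true(all(snps$a_base != snps$b_base))
  # identical sequences: no SNPs
  expect_equal(nrow(call_consensus_snps(find_homologous_regions(g, g))), 0L)
  # a 3-bp deletion plus 2 substitutions: only the substitutions are reported
  v2 <- strsplit(g$sequence, "")[[1]]
  v2[1001] <- setdiff(c("A", "C", "G", "T"), v2[1001])[1]
  v2[3501] <- setdiff(c("A", "C", "G", "T"), v2[3501])[1]
  v2 <- v2[-(2200:2202)]
  d <- circular_genome("d", paste(v2, collapse = ""))
  snps2 <- call_consensus_snps(find_homologous_regions(g, d), b_len = d$length)
  expect_setequal(snps2$a_pos, c(1000L, 3500L))
})

test_that("consensus SNP counts are symmetric with swapped alleles", {
  g <- circular_genome("a", random_seq(4000, seed = 36))
  set.seed(37)
  v <- strsplit(g$sequence, "")[[1]]
  hit <- sample(4000, 25)
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  b <- circular_genome("b", paste(v, collapse = ""))
  ab <- call_consensus_snps(find_homologous_regions(g, b), b_len = b$length)
  ba <- call_consensus_snps(find_homologous_regions(b, g), b_len = g$length)
  expect_equal(nrow(ab), nrow(ba))
  m <- merge(ab, ba, by.x = c("a_pos", "b_pos"), by.y = c("b_pos", "a_pos"))
  expect_equal(nrow(m), nrow(ab))
  expect_true(all(m$a_base.x == m$b_base.y & m$b_base.x == m$a_base.y))
})

test_that("stitched identity agrees with full dynamic programming on short sequences", {
  set.seed(38)
  for (rep in 1:4) {
    a <- circular_genome("a", random_seq(1500))
    v <- strsplit(a$sequence, "")[[1]]
    hit <- sample(1500, 30)
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    b <- circular_genome("b", paste(v, collapse = ""))
    alns <- find_homologous_regions(a, b)
    expect_equal(length(alns), 1L)
    pa <- Biostrings::pairwiseAlignment(
      a$sequence, b$sequence, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    dp_identity <- Biostrings::nmatch(pa) /
      nchar(as.character(Biostrings::alignedPattern(pa)))
    expect_lt(abs(alns[[1]]$identity - dp_identity), 0.005)
  }
})

test_that("coding changes are annotated in start-codon-relative notation", {
  # hand example: gene ATG GAA TAA, SNP A->C at nt 5 turns E into A
  cc <- annotate_coding_change("ATGGAATAA", 5, "C")
  expect_equal(cc$codon_index, 2L)
  expect_equal(cc$label, "E/A^2")
  # synonymous third-position change
  cc2 <- annotate_coding_change("ATGGAATAA", 6, "G")
  expect_equal(cc2$label, "No change")
  # positions beyond the gene are rejected
  expect_error(annotate_coding_change("ATGGAATAA", 10, "A"), "beyond")
  # agreement with a six-frame translation oracle on random genes
  set.seed(40)
  m <- generate_master(9000, 6, c(300, 600), 0, 0, seed = 41)
  for (rep in 1:250) {
    gi <- sample(nrow(m$annotations), 1)
    gene <- m$annotations[gi, ]
    gseq <- substr(m$genome$sequence, gene$start + 1, gene$end)
    if (gene$strand == "-") {
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq)))
    }
    nt_pos <- sample(nchar(gseq), 1)
    ref <- substr(gseq, nt_pos, nt_pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cc <- annotate_coding_change(gseq, nt_pos, alt)
    expect_equal(cc$codon_index, ceiling(nt_pos / 3))
    mut <- gseq
    substr(mut, nt_pos, nt_pos) <- alt
    ci <- cc$codon_index
    exp_ref <- oracle_translate(substr(gseq, 3 * ci - 2, 3 * ci))
    exp_alt <- oracle_translate(substr(mut, 3 * ci - 2, 3 * ci))
    if (exp_ref == exp_alt) {
      expect_equal(cc$label, "No change")
    } else {
      expect_equal(cc$label, sprintf("%s/%s^%d", exp_ref, exp_alt, ci))
    }
  }
})

test_that("gene-relative positions respect strand", {
  gene_p <- data.frame(start = 100L, end = 130L, strand = "+")
  gene_m <- data.frame(start = 100L, end = 130L, strand = "-")
  expect_equal(gene_relative_position(100L, gene_p), 1L)
  expect_equal(gene_relative_position(129L, gene_p), 30L)
  expect_equal(gene_relative_position(129L, gene_m), 1L)
  expect_equal(gene_relative_position(100L, gene_m), 30L)
  expect_error(gene_relative_position(130L, gene_p), "outside")
})

test_that("a frameshifting deletion exposes the first downstream stop", {
  # build a 120-codon gene with a known out-of-frame TGA
  set.seed(42)
  nad <- synthetic_nad9()
  res <- premature_stop_after_deletion(nad, 134, 137)
  expect_equal(res$stop_codon, "TAG")
  expect_equal(res$stop_pos_reference, 158)
  expect_equal(res$stop_pos_mutated, 154L)
  # without a reachable stop the result says so instead of inventing one
  clean <- strrep("GGC", 40)
  res2 <- premature_stop_after_deletion(paste0("ATG", clean), 10, 10)
  expect_null(res2$stop_codon)
})

test_that("contig joining enforces the >100 bp / <1% dissimilarity rule", {
  th <- analysis_thresholds()
  whole <- random_seq(9000, seed = 43)
  a <- substr(whole, 1, 5000)
  # exact 150 bp overlap: |merged| = 5000 + 4000 - 150
  b150 <- substr(whole, 4851, 8850)
  j <- merge_contigs(a, b150, th)
  expect_true(j$joined)
  expect_equal(nchar(j$sequence), 8850L)
  expect_equal(j$overlap, 150L)
  expect_identical(j$sequence, substr(whole, 1, 8850))
  # exact 100 bp overlap: strictly "greater than 100 bp" -> refusal
  b100 <- substr(whole, 4901, 8900)
  j100 <- merge_contigs(a, b100, th)
  expect_false(j100$joined)
  expect_match(j100$reason, "not greater than 100")
  # 150 bp overlap with 2 mismatches (1.33% > 1%) -> refusal
  v <- strsplit(b150, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  v[80] <- setdiff(c("A", "C", "G", "T"), v[80])[1]
  jmm <- merge_contigs(a, paste(v, collapse = ""), th)
  expect_false(jmm$joined)
  expect_match(jmm$reason, "dissimilarity")
  # unrelated contigs: refusal, not an error
  expect_false(merge_contigs(random_seq(800, seed = 1),
                             random_seq(800, seed = 2), th)$joined)
})

test_that("false-positive rate over conserved gene space is counted per bp", {
  genes <- lapply(c(5000, 6000, 6046), random_seq)
  pairs <- lapply(genes, function(g) list(g, g))
  r0 <- estimate_fp_rate(pairs)
  expect_equal(r0$rate, 0)
  expect_equal(r0$compared_bp, 17046L)
  # one planted mismatch in 10,000 bp
  g <- random_seq(10000, seed = 44)
  v <- strsplit(g, "")[[1]]
  v[777] <- setdiff(c("A", "C", "G", "T"), v[777])[1]
  r1 <- estimate_fp_rate(list(list(g, paste(v, collapse = ""))))
  expect_equal(r1$n_snps, 1L)
  expect_equal(r1$rate, 1e-4)
  expect_error(estimate_fp_rate(list()), "no region pairs")
})
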