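test_that("master generation is deterministic and respects its contract", {
  m1 <- generate_master(50000, 30, c(300, 1500), 2, 1000, seed = 7)
  m2 <- generate_master(50000, 30, c(300, 1500), 2, 1000, seed = 7)
  expect_identical(m1, m2)
  expect_equal(m1$genome$length, 50000L)
  expect_equal(nrow(m1$annotations), 30L)
  # non-overlapping genes
  a <- m1$annotations[order(m1$annotations$start), ]
  expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  # repeats placed verbatim at two loci
  reps <- m1$repeats
  for (rid in unique(reps$repeat_id)) {
    loci <- reps[reps$repeat_id == rid, ]
    expect_gte(nrow(loci), 2L)
    seqs <- substring(m1$genome$sequence, loci$start + 1, loci$end)
    expect_true(all(seqs == seqs[1]))
  }
})

test_that("generated protein genes translate cleanly (codon-table oracle)", {
  m <- generate_master(20000, 12, c(300, 900), 0, 0, seed = 3)
  for (i in seq_len(nrow(m$annotations))) {
    g <- m$annotations[i, ]
    nt <- substr(m$genome$sequence, g$start + 1, g$end)
    if (g$strand == "-") {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    aa <- oracle_translate(nt)
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("degenerate and infeasible master requests are handled", {
  m0 <- generate_master(2000, 0, c(300, 600), 0, 0, seed = 1)
  expect_equal(nrow(m0$annotations), 0L)
  expect_equal(m0$genome$length, 2000L)
  expect_error(generate_master(1000, 10, c(300, 600), 0, 0, seed = 1),
               "infeasible packing")
})

test_that("mitotype derivation records exact, replayable truth", {
  m <- generate_master(10000, 6, c(300, 600), 0, 0, seed = 2)
  # identity case
  mt0 <- derive_mitotype(m, n_subst = 0, fraction = 1, seed = 5)
  expect_identical(mt0$genome$sequence, m$genome$sequence)
  # exact Hamming distance for pure substitutions
  mt <- derive_mitotype(m, n_subst = 150, fraction = 0.5, seed = 5)
  ham <- sum(strsplit(mt$genome$sequence, "")[[1]] !=
               strsplit(m$genome$sequence, "")[[1]])
  expect_equal(ham, 150L)
  expect_true(all(mt$truth_edits$substitutions$ref !=
                    mt$truth_edits$substitutions$alt))
  # replay reproduces the mitotype byte for byte
  mt2 <- derive_mitotype(m, n_subst = 40, reversals = list(c(2000, 3000)),
                         deletions = list(c(5000, 5500)), fraction = 1,
                         seed = 6)
  expect_identical(replay_edits(m$genome, mt2$truth_edits),
                   mt2$genome$sequence)
  expect_equal(mt2$genome$length, 10000L - 500L)
  # overlapping edits rejected
  expect_error(
    derive_mitotype(m, reversals = list(c(100, 500)),
                    deletions = list(c(400, 600)), seed = 1),
    "non-overlapping")
})

test_that("a reversal lifts contained genes with flipped strand and order", {
  m <- generate_master(12000, 8, c(300, 450), 0, 0, seed = 9)
  ann <- m$annotations
  # pick a window containing >= 2 whole genes
  win <- c(ann$start[2] - 10L, ann$end[4] + 10L)
  inside <- ann$start >= win[1] & ann$end <= win[2]
  mt <- derive_mitotype(m, n_subst = 0, reversals = list(win), fraction = 1,
                        seed = 1)
  lifted <- mt$annotations
  # brute-force coordinate-lifting oracle for genes inside the reversal
  for (i in which(inside)) {
    g <- ann[i, ]
    exp_start <- win[1] + (win[2] - g$end)
    exp_end <- exp_start + (g$end - g$start)
    j <- which(lifted$gene_id == g$gene_id)
    expect_equal(lifted$start[j], exp_start)
    expect_equal(lifted$end[j], exp_end)
    expect_false(lifted$strand[j] == g$strand)
    # lifted sequence is the reverse complement of the original locus
    expect_identical(
      substr(mt$genome$sequence, exp_start + 1, exp_end),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(m$genome$sequence, g$start + 1, g$end)))))
  }
  # gene order within the window is reversed
  ord_master <- ann$gene_id[inside][order(ann$start[inside])]
  in_lift <- lifted$gene_id %in% ord_master
  ord_lift <- lifted$gene_id[in_lift][order(lifted$start[in_lift])]
  expect_identical(ord_lift, rev(ord_master))
})

test_that("read simulation honours lengths, fractions and error bookkeeping", {
  m <- generate_master(20000, 5, c(300, 600), 0, 0, seed = 4)
  mt1 <- derive_mitotype(m, 0, fraction = 0.8, seed = 1, id = "mt1")
  mt2 <- derive_mitotype(m, 100, fraction = 0.2, seed = 2, id = "mt2")
  cfg <- read_sim_config(mean_depth = 60, subst_error = 0.01, seed = 33)
  rs <- simulate_reads(list(mt1, mt2), m$genome, cfg)
  n <- nrow(rs$reads)
  expect_gt(n, 1000)
  # mean read length within 2% of 449
  expect_lt(abs(mean(rs$reads$length) - 449) / 449, 0.02)
  # total bases within 5% of depth * length at depth >= 50
  expect_lt(abs(sum(rs$reads$length) - 60 * 20000) / (60 * 20000), 0.05)
  # multinomial consistency of mitotype sampling (within 3 SE)
  share <- mean(rs$reads$mitotype == 2L)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(share - 0.2), 3 * se)
  # removing recorded errors recovers an exact substring of the source
  errs <- split(rs$errors, rs$errors$qname)
  some <- names(errs)[seq_len(min(25, length(errs)))]
  for (qn in some) {
    i <- match(qn, rs$reads$qname)
    v <- strsplit(rs$reads$seq[i], "")[[1]]
    e <- errs[[qn]]
    v[e$read_pos + 1L] <- e$true_base
    src <- list(mt1, mt2)[[rs$reads$mitotype[i]]]
    expect_identical(paste(v, collapse = ""),
                     circ_substr(src$genome, rs$reads$mt_start[i],
                                 rs$reads$length[i]))
  }
  # fractions must sum to one
  bad <- derive_mitotype(m, 0, fraction = 0.5, seed = 1)
  expect_error(simulate_reads(list(bad), m$genome, cfg), "sum to 1")
})

test_that("error-free reads from the master are exact substrings and give a clean pileup", {
  m <- generate_master(8000, 4, c(300, 450), 0, 0, seed = 8)
  mt <- derive_mitotype(m, 0, fraction = 1, seed = 1)
  rs <- simulate_reads(list(mt), m$genome,
                       read_sim_config(15, subst_error = 0, seed = 3))
  dbl <- paste0(m$genome$sequence, m$genome$sequence)
  expect_true(all(vapply(rs$reads$seq, grepl, TRUE, x = dbl, fixed = TRUE)))
})

test_that("pooled pileup minor fraction matches the mixture (binomial oracle)", {
  m <- generate_master(5000, 0, c(300, 450), 0, 0, seed = 12)
  mt1 <- derive_mitotype(m, 0, fraction = 0.8, seed = 1, id = "a")
  mt2 <- derive_mitotype(m, 25, fraction = 0.2, seed = 2, id = "b")
  rs <- simulate_reads(list(mt1, mt2), m$genome,
                       read_sim_config(100, subst_error = 0, seed = 9))
  pile <- build_pileup(rs$sam, m$genome)
  truth <- rs$hsnp_truth
  hit <- merge(as.data.frame(pile), truth, by = "pos")
  cm <- as.matrix(hit[, c("A", "C", "G", "T")])
  minor <- cm[cbind(seq_len(nrow(hit)), match(hit$alt, c("A", "C", "G", "T")))]
  frac <- minor / hit$depth
  se <- sqrt(0.2 * 0.8 / hit$depth)
  expect_true(all(abs(frac - 0.2) <= 3 * se))
})

test_that("reads crossing structural edits carry correct truth CIGARs", {
  m <- generate_master(6000, 0, c(300, 450), 0, 0, seed = 21)
  mt <- derive_mitotype(m, 0, reversals = list(c(2000, 3000)),
                        deletions = list(c(4000, 4200)), fraction = 1,
                        seed = 1)
  rs <- simulate_reads(list(mt), m$genome,
                       read_sim_config(25, subst_error = 0, seed = 5))
  # deletion-spanning records exist and their D width matches the deletion
  has_d <- grepl("D", rs$sam$cigar)
  expect_true(any(has_d))
  expect_true(all(grepl("200D", rs$sam$cigar[has_d])))
  # reversal reads map on the minus strand
  expect_true(any(bitwAnd(rs$sam$flag, 16L) > 0L))
  # a clean pileup: no non-reference bases anywhere covered
  pile <- build_pileup(rs$sam, m$genome)
  ref <- strsplit(m$genome$sequence, "")[[1]]
  ref_count <- as.matrix(pile[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(pile)), match(ref[pile$pos + 1], c("A", "C", "G", "T")))]
  expect_equal(sum(pile$depth - pile$del - ref_count), 0L)
  # the deleted master interval collects deletion evidence, not base calls
  delcols <- pile[pile$pos >= 4000 & pile$pos < 4200, ]
  expect_true(all(delcols$del == delcols$depth))
})

test_that("simulated output files are deterministic given the seed", {
  sc <- simulation_scenario(genome_length = 5000, n_genes = 3, n_repeats = 0,
                            repeat_len = 0, fractions = c(0.8, 0.2),
                            n_subst = 20, mean_depth = 10)
  d1 <- tempfile(); d2 <- tempfile()
  run_simulate(run_config(output_dir = d1, seed = 5, scenario = sc))
  run_simulate(run_config(output_dir = d2, seed = 5, scenario = sc))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
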