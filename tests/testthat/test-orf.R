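# A genome with no ATG anywhere (both strands): alternating C/G only would
# still allow CAT on the minus strand, so build from codons lacking ATG/CAT.
test_that("a sequence with no start codon yields no ORFs", {
  g <- circular_genome("noatg", strrep("CCGG", 300))
  expect_equal(nrow(scan_orfs(g)), 0L)
})

test_that("planted ORFs are found at exact coordinates; shorter spans are not", {
  # stop-rich background so no accidental long ORFs, with planted ATG..stop
  # spans; surround each with in-frame stops so the planted ATG is the first
  set.seed(60)
  stops <- c("TAA", "TAG", "TGA")
  bg <- function(n_codons) paste(sample(stops, n_codons, TRUE), collapse = "")
  planted <- list()
  parts <- character()
  pos <- 0L
  lens <- c(300L, 399L, 600L, 900L, 303L)
  for (len in lens) {
    pad <- bg(40)
    parts <- c(parts, pad)
    pos <- pos + nchar(pad)
    cds <- chondriomics:::random_cds(len)
    planted[[length(planted) + 1L]] <- c(start = pos, end = pos + len)
    parts <- c(parts, cds)
    pos <- pos + len
  }
  parts <- c(parts, bg(40))
  g <- circular_genome("planted", paste(parts, collapse = ""))
  orfs <- scan_orfs(g)
  plus <- orfs[orfs$strand == "+", ]
  for (pl in planted) {
    expect_true(any(plus$start == pl["start"] & plus$end == pl["end"]))
  }
  # a 297 bp span (ATG + 97 codons + stop) is below the 300 bp floor
  short <- paste0(bg(20), chondriomics:::random_cds(297), bg(20))
  g2 <- circular_genome("short", short)
  expect_false(any(scan_orfs(g2)$length == 297L))
  # at exactly 300 bp it is reported
  exact <- paste0(bg(20), chondriomics:::random_cds(300), bg(20))
  g3 <- circular_genome("exact", exact)
  expect_true(any(scan_orfs(g3)$length == 300L))
})

test_that("scan_orfs matches the brute-force six-frame oracle on random circles", {
  set.seed(61)
  for (rep in 1:6) {
    g <- circular_genome("r", random_seq(5000))
    got <- scan_orfs(g, analysis_thresholds())
    want <- oracle_orfs(g$sequence, 300L)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$length, want$length)
  }
})

test_that("every reported ORF translates cleanly with a terminal stop", {
  g <- circular_genome("t", random_seq(20000, seed = 62))
  orfs <- scan_orfs(g)
  expect_gt(nrow(orfs), 0L)
  expect_true(all(orfs$length %% 3 == 0))
  expect_true(all(substr(orfs$seq, 1, 3) == "ATG"))
  expect_true(all(substr(orfs$seq, nchar(orfs$seq) - 2, nchar(orfs$seq)) %in%
                    c("TAA", "TAG", "TGA")))
  expect_false(any(grepl("*", orfs$protein, fixed = TRUE)))
  # ids are deterministic and start from 0
  expect_equal(orfs$orf_id[1], "orf0")
  expect_identical(scan_orfs(g)$orf_id, orfs$orf_id)
})

test_that("origin-wrapping ORFs are reported once with wrapped coordinates", {
  stops <- strrep("TAATAGTGA", 30)
  cds <- chondriomics:::random_cds(600)
  # place the CDS so it straddles the origin: last 200 bases first
  tail_len <- 200L
  seqv <- paste0(substr(cds, 600L - tail_len + 1L, 600), stops,
                 substr(cds, 1, 600 - tail_len))
  g <- circular_genome("wrap", seqv)
  orfs <- scan_orfs(g)
  wrapped <- orfs[orfs$end > g$length, ]
  expect_equal(nrow(wrapped), 1L)
  expect_equal(wrapped$length, 600L)
  expect_equal(wrapped$start, g$length - (600L - tail_len))
  expect_equal(wrapped$seq, cds)
})

test_that("ORF genome fractions reproduce the published arithmetic", {
  expect_equal(orf_genome_fraction(81978, 451678)$percent, 18.1)
  expect_equal(orf_genome_fraction(78651, 399005)$percent, 19.7)
  expect_equal(orf_genome_fraction(90237, 431959)$percent, 20.9)
  empty <- scan_orfs(circular_genome("e", strrep("CCGG", 100)))
  expect_equal(orf_genome_fraction(empty, 400)$percent, 0)
})

test_that("uniqueness classification applies the 95%-coverage rule strictly", {
  set.seed(63)
  # ORF present verbatim in the subject: coverage 1, not unique
  orf_seq <- chondriomics:::random_cds(450)
  host <- circular_genome("host", paste0(random_seq(3000), orf_seq,
                                         random_seq(3000)))
  orfs <- data.frame(orf_id = "orf0", start = 0L, end = 450L, strand = "+",
                     length = 450L, seq = orf_seq, protein = "",
                     stringsAsFactors = FALSE)
  cmp <- classify_unique(orfs, list(host))
  expect_equal(cmp$best_coverage, 1)
  expect_false(cmp$unique)
  # novel random ORF: coverage ~0, unique
  novel <- data.frame(orf_id = "orf1", start = 0L, end = 450L, strand = "+",
                      length = 450L, seq = chondriomics:::random_cds(450),
                      protein = "", stringsAsFactors = FALSE)
  cmp2 <- classify_unique(novel, list(host))
  expect_lt(cmp2$best_coverage, 0.2)
  expect_true(cmp2$unique)
  # force a mismatch right after a planted prefix so the alignment cannot
  # extend by a chance base match
  flank_after <- function(seq, upto) {
    nxt <- substr(seq, upto + 1, upto + 1)
    paste0(setdiff(c("A", "C", "G", "T"), nxt)[1], random_seq(1999))
  }
  # exactly 96% covered: strictly more than 95%, so NOT unique
  part <- circular_genome("part", paste0(random_seq(2000),
                                         substr(orf_seq, 1, 432),
                                         flank_after(orf_seq, 432)))
  cmp3 <- classify_unique(orfs, list(part))
  expect_equal(cmp3$best_coverage, 0.96)
  expect_false(cmp3$unique)
  # at exactly 95% coverage the ORF is still counted unique ("95% or less")
  orf420 <- chondriomics:::random_cds(420)
  orfs420 <- data.frame(orf_id = "orf2", start = 0L, end = 420L, strand = "+",
                        length = 420L, seq = orf420, protein = "",
                        stringsAsFactors = FALSE)
  part95 <- circular_genome("p95", paste0(random_seq(2000),
                                          substr(orf420, 1, 399),
                                          flank_after(orf420, 399)))
  cmp4 <- classify_unique(orfs420, list(part95))
  expect_equal(cmp4$best_coverage, 0.95)
  expect_true(cmp4$unique)
  # uniqueness requires low coverage against EVERY other genome
  cmp5 <- classify_unique(orfs, list(part, circular_genome("bg", random_seq(4000))))
  expect_false(cmp5$unique)
})

test_that("chimeric ORFs decompose into their donor fragments", {
  set.seed(64)
  genes <- list(rps2 = random_seq(600), cox1 = random_seq(900),
                nad4 = random_seq(700), rps19 = random_seq(400),
                bystander = random_seq(500))
  frag <- list(c("rps2", 101, 200), c("cox1", 301, 400), c("nad4", 201, 296),
               c("rps19", 51, 150))
  chim <- paste(vapply(frag, function(f)
    substr(genes[[f[1]]], as.integer(f[2]), as.integer(f[3])), ""),
    collapse = "")
  dc <- decompose_chimera(chim, genes)
  segs <- dc$segments
  expect_equal(nrow(segs), 4L)
  expect_equal(segs$source_gene, c("rps2", "cox1", "nad4", "rps19"))
  # boundaries within +-5 bp of the construction
  exp_q <- c(0L, 100L, 200L, 296L)
  expect_true(all(abs(segs$q_start - exp_q) <= 5))
  expect_true(all(abs(segs$q_end - c(100L, 200L, 296L, 396L)) <= 5))
  expect_equal(nrow(dc$unassigned), 0L)
  # an ORF copied from one gene's interior: a single full-cover segment
  one <- decompose_chimera(substr(genes$cox1, 201, 500), genes["cox1"])
  expect_equal(nrow(one$segments), 1L)
  expect_equal(one$segments$q_start, 0L)
  expect_equal(one$segments$q_end, 300L)
  expect_equal(one$segments$g_start, 200L)
  # random query vs unrelated database: nothing assigned
  none <- decompose_chimera(random_seq(400), genes)
  expect_equal(nrow(none$segments), 0L)
  expect_equal(none$unassigned$end, 400L)
})

test_that("extending a subject with the query sequence only raises coverage", {
  set.seed(65)
  orf_seq <- chondriomics:::random_cds(360)
  orfs <- data.frame(orf_id = "o", start = 0L, end = 360L, strand = "+",
                     length = 360L, seq = orf_seq, protein = "",
                     stringsAsFactors = FALSE)
  base <- random_seq(3000)
  cov1 <- classify_unique(orfs, list(circular_genome("s1", base)))$best_coverage
  cov2 <- classify_unique(orfs, list(circular_genome(
    "s2", paste0(base, orf_seq))))$best_coverage
  expect_gte(cov2, cov1)
  expect_equal(cov2, 1)
})
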