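#' Simulation scenario for a synthetic chondriome
#'
#' Defaults describe the study-like desk-scale condition: a 50 kb circular
#' master, 30 genes, two 1 kb repeat families, a chondriome of two mitotypes
#' at 0.8/0.2 stoichiometry differing by 200 substitutions, 100x of 449 bp
#' single-end reads at 1% substitution error.
#'
#' @param genome_length,n_genes,gene_len_range,n_repeats,repeat_len Master
#'   genome layout (see [generate_master()]).
#' @param fractions Stoichiometric fractions of the mitotypes (must sum to 1);
#'   the first mitotype is the unedited master.
#' @param n_subst Distinguishing substitutions per derived mitotype.
#' @param reversals,deletions Lists (one per derived mitotype) of edit
#'   interval lists.
#' @param mean_depth,read_len_mean,read_len_sd,subst_error Read simulation
#'   (see [read_sim_config()]).
#' @return List of class `SimulationScenario`.
#' @export
simulation_scenario <- function(genome_length = 50000L, n_genes = 30L,
                                gene_len_range = c(300L, 1500L),
                                n_repeats = 2L, repeat_len = 1000L,
                                fractions = c(0.8, 0.2), n_subst = 200L,
                                reversals = NULL, deletions = NULL,
                                mean_depth = 100, read_len_mean = 449,
                                read_len_sd = 100, subst_error = 0.01) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("scenario field 'fractions' must sum to 1 (got %.6f)",
                 sum(fractions)))
  }
  if (length(fractions) < 1L) stop("scenario field 'fractions' is empty")
  n_derived <- length(fractions) - 1L
  norm_edits <- function(x, name) {
    if (is.null(x)) return(rep(list(list()), n_derived))
    if (length(x) != n_derived) {
      stop(sprintf("scenario field '%s' needs one entry per derived mitotype",
                   name))
    }
    x
  }
  structure(list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    gene_len_range = as.integer(gene_len_range),
    n_repeats = as.integer(n_repeats), repeat_len = as.integer(repeat_len),
    fractions = fractions, n_subst = as.integer(n_subst),
    reversals = norm_edits(reversals, "reversals"),
    deletions = norm_edits(deletions, "deletions"),
    mean_depth = mean_depth, read_len_mean = read_len_mean,
    read_len_sd = read_len_sd, subst_error = subst_error
  ), class = c("SimulationScenario", "list"))
}

#' Run configuration
#'
#' Bundles inputs (either a simulation scenario or paths to FASTA/GFF3/SAM
#' files), analysis thresholds, seed and output directory. Every threshold is
#' echoed into the analysis report for provenance, and a config survives a
#' JSON round-trip losslessly ([write_run_config()] / [read_run_config()]).
#'
#' @param output_dir Directory for outputs (created if needed).
#' @param seed Integer seed funnelling all randomness.
#' @param thresholds An [analysis_thresholds()].
#' @param scenario A [simulation_scenario()] (for `run_simulate`).
#' @param inputs For [run_analyze()]: list with `genomes` (named list of
#'   [circular_genome()] or a FASTA path), optional `annotations` (named list
#'   of annotation data.frames or GFF3 paths) and optional `sam` (named list
#'   of SAM paths or record data.frames, one per genome with reads).
#' @return List of class `RunConfig`.
#' @export
run_config <- function(output_dir = tempfile("chondriomics_"), seed = 1L,
                       thresholds = analysis_thresholds(),
                       scenario = simulation_scenario(), inputs = NULL) {
  structure(list(
    output_dir = output_dir, seed = as.integer(seed),
    thresholds = thresholds, scenario = scenario, inputs = inputs
  ), class = c("RunConfig", "list"))
}

#' @rdname run_config
#' @param config A `RunConfig`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- list(output_dir = config$output_dir, seed = config$seed,
            thresholds = unclass(config$thresholds),
            scenario = unclass(config$scenario))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- x$scenario
  run_config(
    output_dir = x$output_dir, seed = x$seed,
    thresholds = do.call(analysis_thresholds, as.list(x$thresholds)),
    scenario = do.call(simulation_scenario, c(
      sc[setdiff(names(sc), c("reversals", "deletions"))],
      list(reversals = if (length(sc$reversals)) sc$reversals,
           deletions = if (length(sc$deletions)) sc$deletions)))
  )
}

#' Simulate a chondriome dataset to disk
#'
#' Generates the master genome, derived mitotypes, reads and truth tables of
#' the configured scenario and writes FASTA, GFF3, FASTQ, SAM and TSV truth
#' files into the output directory. Byte-identical across runs with the same
#' config.
#'
#' @param config A [run_config()].
#' @return (Invisibly) list with the in-memory `master`, `mitotypes`,
#'   `read_set` and the output paths.
#' @export
run_simulate <- function(config) {
  sc <- config$scenario
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  master <- generate_master(sc$genome_length, sc$n_genes, sc$gene_len_range,
                            sc$n_repeats, sc$repeat_len, seed = config$seed)
  mitotypes <- list(derive_mitotype(master, n_subst = 0L,
                                    fraction = sc$fractions[1],
                                    seed = config$seed,
                                    id = paste0(master$genome$id, "_mt1")))
  for (k in seq_len(length(sc$fractions) - 1L)) {
    mitotypes[[k + 1L]] <- derive_mitotype(
      master, n_subst = sc$n_subst,
      reversals = sc$reversals[[k]], deletions = sc$deletions[[k]],
      fraction = sc$fractions[k + 1L], seed = config$seed + k,
      id = sprintf("%s_mt%d", master$genome$id, k + 1L))
  }
  cfg <- read_sim_config(sc$mean_depth, sc$read_len_mean, sc$read_len_sd,
                         sc$subst_error, seed = config$seed)
  message(sprintf("[simulate] %d bp master, %d mitotypes, target %.0fx",
                  sc$genome_length, length(mitotypes), sc$mean_depth))
  rs <- simulate_reads(mitotypes, master$genome, cfg)
  p <- function(f) file.path(config$output_dir, f)
  write_genomes_fasta(c(list(master$genome),
                        lapply(mitotypes, `[[`, "genome")), p("genomes.fa"))
  write_annotations_gff3(master$annotations, master$genome, p("master.gff3"))
  write_fastq(rs, p("reads.fastq"))
  write_sam(rs, master$genome, p("reads.sam"))
  write_truth_tables(rs, mitotypes, p("truth"))
  invisible(list(master = master, mitotypes = mitotypes, read_set = rs,
                 paths = list(
                   fasta = p("genomes.fa"), gff3 = p("master.gff3"),
                   fastq = p("reads.fastq"), sam = p("reads.sam"),
                   truth_prefix = p("truth"))))
}

resolve_genomes <- function(inputs) {
  g <- inputs$genomes
  if (is.character(g) && length(g) == 1L) g <- read_genomes_fasta(g)
  if (inherits(g, "CircularGenome")) g <- list(g)
  names(g) <- vapply(g, `[[`, "", "id")
  g
}

#' Analyse a set of chondriome genomes and emit a consolidated report
#'
#' Runs every stage on the configured inputs: per-genome pileup, coverage
#' mask and HSNP calling/blocking (for genomes with reads), pairwise
#' consensus-genome homology and SNP calls, pairwise gene-order rearrangement
#' reports, per-genome ORF scans with uniqueness classification. Writes the
#' per-stage TSV/VCF/BED/GFF3 files plus a consolidated `report.json` whose
#' numbers all come from those files' contents, with thresholds and seed
#' echoed for provenance.
#'
#' @param config A [run_config()] with `inputs` set.
#' @return (Invisibly) the report list.
#' @export
run_analyze <- function(config) {
  if (is.null(config$inputs)) stop("config$inputs is required for analysis")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- resolve_genomes(config$inputs)
  if (length(genomes) == 0L) stop("no input genomes")
  th <- config$thresholds
  p <- function(f) file.path(config$output_dir, f)
  report <- list(thresholds = unclass(th), seed = config$seed,
                 genomes = lapply(genomes, function(g)
                   list(id = g$id, length = g$length)))

  anns <- config$inputs$annotations
  if (!is.null(anns)) {
    anns <- lapply(seq_along(anns), function(i) {
      a <- anns[[i]]
      if (is.character(a)) read_annotations_gff3(a, genomes[[i]]$length) else a
    })
    names(anns) <- names(genomes)[seq_along(anns)]
  }

  # --- heteroplasmy per genome with reads -------------------------------
  sams <- config$inputs$sam
  hsnp_report <- list()
  for (gid in names(sams)) {
    t0 <- Sys.time()
    g <- genomes[[gid]]
    pile <- build_pileup(sams[[gid]], g)
    mask <- coverage_mask(pile, g$length, th$min_depth)
    hs <- call_hsnps(pile, th, mask)
    cl <- cluster_hsnp_blocks(hs, th)
    sm <- hsnp_summary(hs, cl, g$length)
    write_pileup_tsv(pile, p(sprintf("%s_pileup.tsv", gid)))
    write_mask_bed(mask, gid, p(sprintf("%s_mask.bed", gid)))
    write_hsnps_vcf(hs, g, p(sprintf("%s_hsnps.vcf", gid)))
    write_hsnps_tsv(hs, p(sprintf("%s_hsnps.tsv", gid)))
    write_blocks_bed(cl, gid, p(sprintf("%s_hsnp_blocks.bed", gid)))
    hsnp_report[[gid]] <- c(sm, list(
      excluded_bp = mask$excluded_bp,
      excluded_fraction = mask$excluded_fraction))
    message(sprintf("[hsnp] %s: %d calls, %d blocks (%.1fs)", gid, sm$n_total,
                    sm$n_blocks, as.numeric(Sys.time() - t0, units = "secs")))
  }
  report$hsnp <- hsnp_report

  # --- pairwise consensus comparison ------------------------------------
  pair_report <- list()
  ids <- names(genomes)
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      t0 <- Sys.time()
      a <- genomes[[ids[i]]]; b <- genomes[[ids[j]]]
      alns <- find_homologous_regions(a, b, th)
      snps <- call_consensus_snps(alns, b_len = b$length)
      key <- sprintf("%s_vs_%s", ids[i], ids[j])
      utils::write.table(alignments_table(alns),
                         p(sprintf("%s_alignments.tsv", key)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_consensus_snps_tsv(snps, p(sprintf("%s_snps.tsv", key)))
      coding <- annotate_pair_snps(snps, a, anns[[ids[i]]])
      if (!is.null(coding)) {
        utils::write.table(coding, p(sprintf("%s_coding.tsv", key)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      pair_report[[key]] <- list(
        n_alignments = length(alns),
        homologous_bp = sum(vapply(alns, `[[`, 0, "length")),
        n_snps = nrow(snps),
        n_coding_changes = if (is.null(coding)) 0L else
          sum(coding$label != "No change"))
      message(sprintf("[compare] %s: %d alignments, %d SNPs (%.1fs)", key,
                      length(alns), nrow(snps),
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  report$pairwise <- pair_report

  # --- synteny ----------------------------------------------------------
  if (!is.null(anns) && length(anns) >= 2L) {
    syn_report <- list()
    orders <- lapply(names(anns), function(gid)
      gene_order_from_annotations(anns[[gid]], gid))
    names(orders) <- names(anns)
    for (i in seq_len(length(orders) - 1L)) for (j in (i + 1L):length(orders)) {
      key <- sprintf("%s_vs_%s", names(orders)[i], names(orders)[j])
      shared <- intersect(orders[[i]]$genes, orders[[j]]$genes)
      if (length(shared) < 2L) next
      rep_ij <- rearrangement_report(orders[[i]], orders[[j]],
                                     anns[[i]], anns[[j]])
      write_synteny_tsv(rep_ij, p(paste0(key, "_synteny")))
      syn_report[[key]] <- list(
        common_genes = rep_ij$common_genes,
        n_blocks = nrow(rep_ij$blocks),
        n_pairs = nrow(rep_ij$conserved_pairs),
        breakpoints = rep_ij$breakpoints,
        events_estimate = rep_ij$events_estimate)
    }
    report$synteny <- syn_report
  }

  # --- ORFs -------------------------------------------------------------
  orf_report <- list()
  orfs_by_genome <- lapply(genomes, scan_orfs, thresholds = th)
  for (gid in ids) {
    orfs <- orfs_by_genome[[gid]]
    fr <- orf_genome_fraction(orfs, genomes[[gid]]$length)
    write_orfs(orfs, genomes[[gid]], p(sprintf("%s_orfs", gid)))
    entry <- list(n_orfs = nrow(orfs), total_bp = fr$total_bp,
                  percent = fr$percent)
    if (length(ids) >= 2L && nrow(orfs) > 0L) {
      others <- genomes[setdiff(ids, gid)]
      cmp <- classify_unique(orfs, unname(others), th)
      utils::write.table(as.data.frame(cmp),
                         p(sprintf("%s_orf_uniqueness.tsv", gid)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      entry$n_unique <- sum(cmp$unique)
    }
    orf_report[[gid]] <- entry
  }
  report$orf <- orf_report

  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  message(sprintf("[report] written to %s", p("report.json")))
  invisible(report)
}

# Coding-change annotation for consensus SNPs falling inside annotated genes
# of the query genome (positions reported 1-based relative to start codon).
annotate_pair_snps <- function(snps, genome, ann) {
  if (is.null(ann) || nrow(snps) == 0L) return(NULL)
  genes <- ann[ann$category == "protein" & ann$end <= genome$length, ,
               drop = FALSE]
  if (nrow(genes) == 0L) return(NULL)
  rows <- list()
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, ]
    inside <- snps$a_pos >= gene$start & snps$a_pos < gene$end
    if (!any(inside)) next
    gseq <- substr(genome$sequence, gene$start + 1L, gene$end)
    if (gene$strand == "-") gseq <- reverse_complement(gseq)
    for (si in which(inside)) {
      nt_pos <- gene_relative_position(snps$a_pos[si], gene)
      alt <- snps$b_base[si]
      if (gene$strand == "-") alt <- chartr("ACGT", "TGCA", alt)
      cc <- tryCatch(annotate_coding_change(gseq, nt_pos, alt, gene$gene_id),
                     error = function(e) NULL)
      if (is.null(cc)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cc$gene_id, a_pos = snps$a_pos[si], nt_pos = cc$nt_pos,
        ref_nt = cc$ref_nt, alt_nt = cc$alt_nt,
        codon_index = cc$codon_index, label = cc$label,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
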