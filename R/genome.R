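#' Circular genome container
#'
#' A minimal container for a circular nucleotide sequence. Plant mitochondrial
#' ("master circle") genomes are conventionally represented as a circle with an
#' arbitrary origin; all position arithmetic in this package is modulo the
#' genome length, with 0-based half-open coordinates internally and 1-based
#' coordinates only in human-facing report formats (VCF, GFF3).
#'
#' @param id Single character identifier.
#' @param sequence Nucleotide string over the alphabet \{A, C, G, T\}.
#' @return An object of class `CircularGenome`: a list with elements `id`,
#'   `sequence` and `length`.
#' @examples
#' g <- circular_genome("toy", "ATGAAATAA")
#' g$length
#' @export
circular_genome <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("genome sequence must be non-empty")
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence must use only A, C, G, T")
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence)),
    class = "CircularGenome"
  )
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("CircularGenome '%s': %d bp (circular)\n", x$id, x$length))
  invisible(x)
}

#' Extract a (possibly origin-wrapping) substring of a circular genome
#'
#' @param genome A [circular_genome()].
#' @param start 0-based start position (taken modulo genome length).
#' @param len Number of bases to extract; must not exceed the genome length.
#' @return Character scalar of length `len`.
#' @export
circ_substr <- function(genome, start, len) {
  L <- genome$length
  stopifnot(len >= 0L, len <= L)
  if (len == 0L) return("")
  start <- ((start %% L) + L) %% L
  end <- start + len
  if (end <= L) {
    substr(genome$sequence, start + 1L, end)
  } else {
    paste0(
      substr(genome$sequence, start + 1L, L),
      substr(genome$sequence, 1L, end - L)
    )
  }
}

#' Gene annotation table constructor
#'
#' Annotations are held as a plain data.frame with 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive). `end` may exceed the
#' genome length to denote a feature wrapping the origin.
#'
#' @param gene_id Character vector of unique identifiers.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param category One of `"protein"`, `"tRNA"`, `"rRNA"`, `"pseudo"`, `"orf"`.
#' @param genome_length Genome length in bp, used for validation.
#' @return data.frame with columns gene_id, start, end, strand, category.
#' @export
gene_annotations <- function(gene_id, start, end, strand, category,
                             genome_length) {
  n <- length(gene_id)
  stopifnot(
    length(start) == n, length(end) == n,
    length(strand) == n, length(category) == n
  )
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique per genome")
  stopifnot(all(strand %in% c("+", "-")))
  stopifnot(all(category %in% c("protein", "tRNA", "rRNA", "pseudo", "orf")))
  start <- as.integer(start); end <- as.integer(end)
  if (n > 0L) {
    stopifnot(all(start >= 0L), all(start < genome_length), all(end > start))
    if (any(category == "protein" & (end - start) < 3L)) {
      stop("protein genes must span at least one codon")
    }
  }
  data.frame(
    gene_id = as.character(gene_id), start = start, end = end,
    strand = as.character(strand), category = as.character(category),
    stringsAsFactors = FALSE
  )
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate an in-frame nucleotide sequence (standard code)
#'
#' @param nt Character scalar, length divisible by 3, in frame from its first
#'   base. Stops are rendered `*`.
#' @return Amino-acid string.
#' @export
translate_nt <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::GENETIC_CODE,
    no.init.codon = TRUE,
    if.fuzzy.codon = "X"
  ))
}

#' Write genomes to FASTA
#' @param genomes List of [circular_genome()] objects.
#' @param path Output file path.
#' @export
write_genomes_fasta <- function(genomes, path) {
  if (inherits(genomes, "CircularGenome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read genomes from FASTA as CircularGenome objects
#' @param path FASTA file path.
#' @return Named list of [circular_genome()] objects.
#' @export
read_genomes_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    circular_genome(sub("\\s.*$", "", names(seqs)[i]), as.character(seqs[[i]]))
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write gene annotations to GFF3
#' @param ann Annotation data.frame from [gene_annotations()].
#' @param genome A [circular_genome()] (provides seqid and length).
#' @param path Output path.
#' @export
write_annotations_gff3 <- function(ann, genome, path) {
  if (nrow(ann) == 0L) {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", genome$id, genome$length)),
               path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  gr$category <- ann$category
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read gene annotations from GFF3
#' @param path GFF3 file path.
#' @param genome_length Genome length for validation.
#' @return Annotation data.frame (0-based half-open).
#' @export
read_annotations_gff3 <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(gene_annotations(character(), integer(), integer(), character(),
                            character(), genome_length))
  }
  cat_col <- if ("category" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$category)
  } else {
    rep("protein", length(gr))
  }
  gene_annotations(
    gene_id = as.character(gr$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = cat_col,
    genome_length = genome_length
  )
}
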