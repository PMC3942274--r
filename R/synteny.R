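#' Signed circular gene order
#'
#' @param genes Character vector of gene symbols in circular order.
#' @param signs Integer vector of +1/-1 (gene strand), or a character vector
#'   of "+"/"-".
#' @param genome_id Identifier.
#' @return List of class `GeneOrder` with `genome_id`, `genes`, `signs`.
#'   Cyclic rotations of the same order compare equal (see
#'   [gene_orders_equal()]).
#' @export
gene_order <- function(genes, signs = rep(1L, length(genes)),
                       genome_id = "genome") {
  if (is.character(signs)) signs <- ifelse(signs == "-", -1L, 1L)
  signs <- as.integer(signs)
  stopifnot(length(genes) == length(signs), all(signs %in% c(-1L, 1L)))
  if (anyDuplicated(genes)) stop("gene symbols must be unique within an order")
  structure(list(genome_id = genome_id, genes = as.character(genes),
                 signs = signs), class = "GeneOrder")
}

#' Gene order from an annotation table
#'
#' Orders genes by start coordinate around the circle; strand gives the sign.
#' Genes sharing a symbol (multi-copy genes such as rRNA repeats) are
#' disambiguated deterministically by coordinate order with suffixes `-1`,
#' `-2`, ...
#'
#' @param annotations data.frame with gene_id, start, strand columns.
#' @param genome_id Identifier for the order.
#' @return A [gene_order()].
#' @export
gene_order_from_annotations <- function(annotations, genome_id = "genome") {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(gene_order(character(), integer(), genome_id))
  }
  ann <- annotations[order(annotations$start), , drop = FALSE]
  ids <- ann$gene_id
  dup <- ids[duplicated(ids)]
  for (g in unique(dup)) {
    w <- which(ids == g)
    ids[w] <- sprintf("%s-%d", g, seq_along(w))
  }
  gene_order(ids, ann$strand, genome_id)
}

#' Test two gene orders for cyclic equality
#'
#' Equal when one is a rotation of the other with identical signs.
#' @param a,b [gene_order()] objects.
#' @return Logical.
#' @export
gene_orders_equal <- function(a, b) {
  n <- length(a$genes)
  if (n != length(b$genes)) return(FALSE)
  if (n == 0L) return(TRUE)
  starts <- which(b$genes == a$genes[1L])
  for (s in starts) {
    idx <- ((s - 1L + 0:(n - 1L)) %% n) + 1L
    if (identical(b$genes[idx], a$genes) &&
        identical(b$signs[idx], a$signs)) return(TRUE)
  }
  FALSE
}

# Restrict an order to a gene set, preserving cyclic order.
induce_order <- function(ord, shared) {
  keep <- ord$genes %in% shared
  gene_order(ord$genes[keep], ord$signs[keep], ord$genome_id)
}

# Canonical encoding of the signed adjacency between consecutive elements
# (cyclic): (a,sa)->(b,sb) is the same adjacency as (b,-sb)->(a,-sa).
adjacency_set <- function(ord) {
  n <- length(ord$genes)
  if (n < 2L) return(character())
  nxt <- c(2:n, 1L)
  enc1 <- sprintf("%s%s|%s%s",
                  ifelse(ord$signs == 1L, "+", "-"), ord$genes,
                  ifelse(ord$signs[nxt] == 1L, "+", "-"), ord$genes[nxt])
  enc2 <- sprintf("%s%s|%s%s",
                  ifelse(ord$signs[nxt] == 1L, "-", "+"), ord$genes[nxt],
                  ifelse(ord$signs == 1L, "-", "+"), ord$genes)
  unique(pmin(enc1, enc2))
}

# Logical vector over the adjacencies of `a` (position i = adjacency between
# element i and i+1, cyclic): is the adjacency present in b?
conserved_adjacency_flags <- function(a, b) {
  n <- length(a$genes)
  if (n < 2L) return(logical())
  nxt <- c(2:n, 1L)
  enc1 <- sprintf("%s%s|%s%s",
                  ifelse(a$signs == 1L, "+", "-"), a$genes,
                  ifelse(a$signs[nxt] == 1L, "+", "-"), a$genes[nxt])
  enc2 <- sprintf("%s%s|%s%s",
                  ifelse(a$signs[nxt] == 1L, "-", "+"), a$genes[nxt],
                  ifelse(a$signs == 1L, "-", "+"), a$genes)
  pmin(enc1, enc2) %in% adjacency_set(b)
}

#' Count breakpoints between two signed circular gene orders
#'
#' The breakpoint distance: the number of gene adjacencies (signed, cyclic)
#' present in one order's induced subpermutation of the shared genes but
#' absent from the other's. Genes private to one genome are dropped before
#' counting. The count is symmetric in its arguments and serves as the
#' operational estimate of the number of recombination/rearrangement events
#' separating two genome structures.
#'
#' @param a,b [gene_order()] objects.
#' @return Integer breakpoint count.
#' @export
breakpoint_count <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  if (length(shared) < 2L) stop("need at least 2 shared genes")
  ai <- induce_order(a, shared)
  bi <- induce_order(b, shared)
  sum(!conserved_adjacency_flags(ai, bi))
}

#' Maximal synteny blocks between two gene orders
#'
#' Maximal runs of shared genes whose internal adjacencies are conserved
#' (orientation-consistently, so a whole block may be inverted in the other
#' genome). Blocks partition the conserved adjacencies; single conserved
#' adjacencies form 2-gene blocks.
#'
#' @param a,b [gene_order()] objects.
#' @param a_annotations,b_annotations Optional annotation data.frames used to
#'   attach bp spans to the blocks (columns a_start/a_end, b_start/b_end).
#' @return data.frame: block_id, n_genes, genes (comma-joined signed symbols
#'   in `a` order), orientation ("same"/"inverted"), and span columns when
#'   annotations are supplied.
#' @export
synteny_blocks <- function(a, b, a_annotations = NULL, b_annotations = NULL) {
  shared <- intersect(a$genes, b$genes)
  empty <- data.frame(block_id = integer(), n_genes = integer(),
                      genes = character(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (length(shared) < 2L) return(empty)
  ai <- induce_order(a, shared)
  bi <- induce_order(b, shared)
  n <- length(ai$genes)
  cons <- conserved_adjacency_flags(ai, bi)
  if (!any(cons)) return(empty)
  runs <- list()
  if (all(cons)) {
    runs[[1L]] <- seq_len(n)                 # identical circular orders
  } else {
    # breakpoints cut the circle; blocks are the arcs between them
    bp <- which(!cons)                        # adjacency i = (i, i+1)
    for (j in seq_along(bp)) {
      from <- bp[j] %% n + 1L
      to <- bp[if (j == length(bp)) 1L else j + 1L]
      len <- ((to - from) %% n) + 1L
      idx <- ((from - 1L + 0:(len - 1L)) %% n) + 1L
      if (len >= 2L) runs[[length(runs) + 1L]] <- idx
    }
  }
  if (length(runs) == 0L) return(empty)
  sgn <- function(s) ifelse(s == 1L, "+", "-")
  rows <- lapply(seq_along(runs), function(k) {
    idx <- runs[[k]]
    g1 <- ai$genes[idx[1L]]
    s1 <- ai$signs[idx[1L]]
    s_in_b <- bi$signs[match(g1, bi$genes)]
    data.frame(
      block_id = k, n_genes = length(idx),
      genes = paste0(sgn(ai$signs[idx]), ai$genes[idx], collapse = ","),
      orientation = if (s_in_b == s1) "same" else "inverted",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  span_cols <- function(ann, prefix) {
    if (is.null(ann)) return(NULL)
    ids <- ann$gene_id
    dup <- ids[duplicated(ids)]
    for (g in unique(dup)) {
      w <- which(ids == g)
      ids[w] <- sprintf("%s-%d", g, seq_along(w))
    }
    t(vapply(runs, function(idx) {
      m <- match(ai$genes[idx], ids)
      m <- m[!is.na(m)]
      if (length(m) == 0L) return(c(NA_integer_, NA_integer_))
      c(min(ann$start[m]), max(ann$end[m]))
    }, integer(2)))
  }
  sa <- span_cols(a_annotations, "a")
  if (!is.null(sa)) { out$a_start <- sa[, 1L]; out$a_end <- sa[, 2L] }
  sb <- span_cols(b_annotations, "b")
  if (!is.null(sb)) { out$b_start <- sb[, 1L]; out$b_end <- sb[, 2L] }
  out
}

#' Conserved gene pairs: isolated conserved adjacencies
#'
#' Adjacent, orientation-consistent gene pairs shared by both cyclic orders
#' that are not part of any larger (3+ gene) synteny block.
#'
#' @param a,b [gene_order()] objects.
#' @return data.frame with columns gene1, gene2.
#' @export
conserved_pairs <- function(a, b) {
  blocks <- synteny_blocks(a, b)
  two <- blocks[blocks$n_genes == 2L, , drop = FALSE]
  if (nrow(two) == 0L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(two$genes, ",", fixed = TRUE)
  data.frame(
    gene1 = sub("^[+-]", "", vapply(parts, `[[`, "", 1L)),
    gene2 = sub("^[+-]", "", vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Full rearrangement report between two genomes' gene orders
#'
#' @param a,b [gene_order()] objects.
#' @param a_annotations,b_annotations Optional annotation tables for bp spans.
#' @return List of class `RearrangementReport`: common_genes, conserved_pairs,
#'   blocks, breakpoints, events_estimate (operationalised as the breakpoint
#'   count).
#' @export
rearrangement_report <- function(a, b, a_annotations = NULL,
                                 b_annotations = NULL) {
  shared <- intersect(a$genes, b$genes)
  bp <- breakpoint_count(a, b)
  structure(list(
    common_genes = length(shared),
    conserved_pairs = conserved_pairs(a, b),
    blocks = synteny_blocks(a, b, a_annotations, b_annotations),
    breakpoints = bp,
    events_estimate = bp
  ), class = "RearrangementReport")
}

#' Genome fraction covered by synteny blocks
#'
#' @param blocks Either a blocks data.frame with `a_start`/`a_end` span
#'   columns, or a single numeric total bp (when the block total is already
#'   known, e.g. from a published figure).
#' @param genome_length Genome length in bp.
#' @return List: total_bp, fraction, percent (100 x fraction),
#'   percent_integer (rounded to integer, the headline figure).
#' @export
block_genome_fraction <- function(blocks, genome_length) {
  if (is.numeric(blocks) && length(blocks) == 1L) {
    total <- blocks
  } else {
    if (nrow(blocks) == 0L) {
      total <- 0L
    } else {
      if (!all(c("a_start", "a_end") %in% names(blocks))) {
        stop("blocks need a_start/a_end spans (supply annotations)")
      }
      iv <- blocks[!is.na(blocks$a_start), , drop = FALSE]
      iv <- iv[order(iv$a_start), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv$a_start[-1L] < iv$a_end[-nrow(iv)])) {
        stop("block spans overlap")
      }
      if (any(iv$a_end > genome_length)) stop("block spans exceed the genome")
      total <- sum(iv$a_end - iv$a_start)
    }
  }
  fraction <- total / genome_length
  list(total_bp = total, fraction = fraction, percent = 100 * fraction,
       percent_integer = as.integer(round(100 * fraction)))
}

#' Write synteny blocks and conserved pairs as TSV
#' @param report A `RearrangementReport`.
#' @param prefix Output path prefix (writes `<prefix>_blocks.tsv` and
#'   `<prefix>_pairs.tsv`).
#' @export
write_synteny_tsv <- function(report, prefix) {
  utils::write.table(report$blocks, paste0(prefix, "_blocks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$conserved_pairs, paste0(prefix, "_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
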