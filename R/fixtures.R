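#' Generate a random in-frame coding sequence
#'
#' The gene starts with a start codon, ends with a stop codon, and draws
#' every internal codon uniformly from the non-excluded codon set, so it
#' contains no internal stop or start codon and every internal codon is a
#' valid mutation source.
#'
#' @param n_codons Total codon count including start and stop (>= 3).
#' @param table A [codon_table()].
#' @return A single DNA string of length `3 * n_codons`.
#' @export
generate_cds <- function(n_codons, table = codon_table()) {
  if (n_codons < 3L) stop("a CDS needs at least 3 codons", call. = FALSE)
  start <- sample(table$start_codons, 1L)
  stop_ <- sample(table$stop_codons, 1L)
  internal <- sample(table$allowed, n_codons - 2L, replace = TRUE)
  paste(c(start, internal, stop_), collapse = "")
}

#' Generate a set of donor genes
#'
#' Codon counts are drawn from the multiples of `codon_step` (default 20)
#' inside `codon_range`. With the default step every gene length is a
#' multiple of 60 bases, so the base
#' budget at any mutation level that is a multiple of 5 percent is an
#' integer multiple of 3 -- meaning every generated gene admits an exact
#' mutation plan under any category ratio, including three-base-only
#' mixes, at all standard benchmark levels.
#'
#' @param n Number of genes.
#' @param codon_range Length-2 integer range of codon counts per gene.
#' @param codon_step Step between admissible codon counts.
#' @param table A [codon_table()].
#' @param prefix Id prefix.
#' @return Named character vector of CDS sequences.
#' @export
generate_gene_set <- function(n, codon_range = c(100L, 300L),
                              codon_step = 20L, table = codon_table(),
                              prefix = "gene") {
  lo <- as.integer(ceiling(codon_range[1] / codon_step) * codon_step)
  if (lo > codon_range[2]) {
    stop("codon_range contains no multiple of codon_step", call. = FALSE)
  }
  ncod <- sample(seq(lo, codon_range[2], by = codon_step), n, replace = TRUE)
  seqs <- vapply(ncod, generate_cds, character(1), table = table)
  setNames(seqs, sprintf("%s%03d", prefix, seq_len(n)))
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at the requested GC content.
#'
#' @param length Genome length in bases.
#' @param gc GC fraction in (0, 1).
#' @return A DNA string.
#' @export
generate_genome <- function(length, gc = 0.5) {
  stopifnot(length > 0, gc > 0, gc < 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Generate non-overlapping gene features over a genome
#'
#' Places `n_features` non-overlapping intervals separated by at least
#' `min_gap` bases, leaving intergenic gaps, and returns them as a GFF3-style
#' feature table.
#'
#' @param seq_id Sequence id the features live on.
#' @param seq_length Sequence length.
#' @param n_features Number of features.
#' @param feature_length Length of each feature.
#' @param min_gap Minimum intergenic gap between consecutive features.
#' @return Data frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `type` (`"gene"`), `strand`.
#' @export
generate_features <- function(seq_id, seq_length, n_features,
                              feature_length = 900L, min_gap = 200L) {
  if (n_features == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      strand = character(0)))
  }
  slack <- seq_length - n_features * feature_length -
    (n_features + 1L) * min_gap
  if (slack < 0) {
    stop("cannot pack ", n_features, " features of ", feature_length,
         " bp with ", min_gap, " bp gaps into ", seq_length, " bp",
         call. = FALSE)
  }
  # distribute the slack over the n_features + 1 gaps
  cuts <- sort(sample.int(slack + 1L, n_features, replace = TRUE) - 1L)
  starts <- integer(n_features)
  pos <- 0L
  prev_cut <- 0L
  for (i in seq_len(n_features)) {
    pos <- pos + min_gap + (cuts[i] - prev_cut)
    starts[i] <- pos + 1L
    pos <- pos + feature_length
    prev_cut <- cuts[i]
  }
  data.frame(seq_id = seq_id, start = starts,
             end = starts + feature_length - 1L,
             type = "gene",
             strand = sample(c("+", "-"), n_features, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Write a feature table as GFF3
#'
#' @param features Data frame from [generate_features()].
#' @param path Output path.
#' @param source Source column value.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path, source = "hgtbench") {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=feat%04d",
                     features$seq_id, source, features$type,
                     features$start, features$end, features$strand,
                     seq_len(nrow(features)))
    writeLines(lines, con)
  }
  close(con)
  invisible(path)
}

#' Generate a synthetic donor/recipient community
#'
#' Emulates the benchmark layout (donor genes transferred into a set of
#' recipient genomes) at a configurable, reduced scale: donor genes with
#' realistic CDS structure, recipient genomes of i.i.d. sequence with
#' annotated gene features (leaving intergenic gaps), and a uniform
#' abundance profile.
#'
#' @param n_genes Number of donor genes.
#' @param n_recipients Number of recipient genomes.
#' @param recipient_length Length of each recipient genome.
#' @param gene_codon_range Codon-count range for donor genes.
#' @param gc GC content of recipients.
#' @param n_features Annotated features per recipient; the default scales
#'   with genome length (one 900 bp feature per 5 kb).
#' @param table A [codon_table()].
#' @return List with `genes` (named character), `recipients` (named list of
#'   single-sequence named character vectors), `features` (named list of
#'   feature data frames), `abundance` (named numeric, all 1).
#' @export
generate_community <- function(n_genes = 20L, n_recipients = 3L,
                               recipient_length = 200000L,
                               gene_codon_range = c(100L, 300L),
                               gc = 0.5, n_features = NULL,
                               table = codon_table()) {
  if (is.null(n_features)) {
    n_features <- max(1L, as.integer(recipient_length %/% 5000L))
  }
  genes <- generate_gene_set(n_genes, gene_codon_range, table = table)
  recipients <- list()
  features <- list()
  for (i in seq_len(n_recipients)) {
    rid <- sprintf("recipient%02d", i)
    sid <- paste0(rid, "_chr")
    recipients[[rid]] <- setNames(generate_genome(recipient_length, gc), sid)
    features[[rid]] <- generate_features(sid, recipient_length, n_features)
  }
  list(genes = genes, recipients = recipients, features = features,
       abundance = setNames(rep(1, n_recipients), names(recipients)))
}

#' Build perfectly assembled contigs around planted insertions
#'
#' For benchmarking the recovery evaluator without an assembler: each
#' insertion yields one contig consisting of its cassette plus `context`
#' recipient bases on each side, sliced from the original (pre-insertion)
#' recipient sequence and clipped at sequence ends. Taking the context from
#' the original sequence guarantees pure recipient-derived flanks even when
#' two insertions happen to fall close together.
#'
#' @param recipients Named list of original recipient genomes, each a named
#'   character vector of sequences.
#' @param cassettes Named character vector of inserted cassettes (gene id ->
#'   flanked sequence), as returned by [plant_transfers()].
#' @param events Insertion event data frame (original coordinates).
#' @param context Recipient bases to keep on each side of the cassette.
#' @return Named character vector of contigs (`contig_<gene_id>`).
#' @export
perfect_contigs <- function(recipients, cassettes, events, context = 1500L) {
  stopifnot(context >= 0)
  out <- character(nrow(events))
  nms <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    seq <- recipients[[ev$recipient_id]][[ev$seq_id]]
    bp <- ev$break_position
    lo <- max(1L, bp - context + 1L)
    hi <- min(nchar(seq), bp + context)
    out[i] <- paste0(substr(seq, lo, bp), cassettes[[ev$gene_id]],
                     substr(seq, bp + 1L, hi))
    nms[i] <- paste0("contig_", ev$gene_id)
  }
  setNames(out, nms)
}
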