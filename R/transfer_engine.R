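#' Add a flanking sequence to both ends of a gene
#'
#' Transferred genes can carry a fixed context string on both ends, for
#' example a transposon insertion sequence, before being planted into a
#' recipient genome.
#'
#' @param gene_seq Gene sequence.
#' @param flank Flanking sequence over \{A,C,G,T\}; may be `""`.
#' @return `flank + gene + flank`.
#' @examples
#' add_flanks("AAA", "GT") # "GTAAAGT"
#' @export
add_flanks <- function(gene_seq, flank = "") {
  check_dna(gene_seq, "gene", allow_empty = FALSE)
  if (nchar(flank) > 0) check_dna(flank, "flank")
  paste0(flank, gene_seq, flank)
}

#' Assign donor genes to recipient genomes
#'
#' @param gene_ids Character vector of gene ids.
#' @param recipient_ids Character vector of recipient genome ids.
#' @param mode `"uniform"` (each gene assigned to a recipient uniformly at
#'   random) or `"even"` (genes split as evenly as possible, random order).
#' @param fixed Optional named character vector `gene_id -> recipient_id`
#'   overriding randomisation.
#' @return Named character vector mapping every gene id to a recipient id.
#' @export
assign_genes <- function(gene_ids, recipient_ids, mode = c("even", "uniform"),
                         fixed = NULL) {
  mode <- match.arg(mode)
  if (length(recipient_ids) == 0L) {
    stop("at least one recipient genome is required", call. = FALSE)
  }
  if (!is.null(fixed)) {
    if (!all(gene_ids %in% names(fixed))) {
      stop("fixed assignment misses some genes", call. = FALSE)
    }
    return(fixed[gene_ids])
  }
  n <- length(gene_ids)
  if (mode == "uniform") {
    rec <- sample(recipient_ids, n, replace = TRUE)
  } else {
    rec <- rep(recipient_ids, length.out = n)
    rec <- sample(rec)
  }
  setNames(rec, gene_ids)
}

#' Intergenic regions of a genome from GFF3 annotation
#'
#' The intergenic space is the complement of the union of annotated feature
#' intervals, per sequence.
#'
#' @param gff Path to a GFF3 file or a `GRanges` of features.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param feature_types Feature types to mask (default `"gene"`).
#' @param min_length Drop intergenic regions shorter than this (default 0).
#' @return Data frame with columns `seq_id`, `start`, `end` (1-based,
#'   inclusive), sorted and non-overlapping within each sequence.
#' @export
intergenic_regions <- function(gff, seq_lengths, feature_types = "gene",
                               min_length = 0L) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3") else gff
  if (length(gr) > 0 && "type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) %in% feature_types]
  }
  rows <- list()
  for (sid in names(seq_lengths)) {
    len <- seq_lengths[[sid]]
    feats <- gr[as.character(GenomicRanges::seqnames(gr)) == sid]
    covered <- IRanges::reduce(IRanges::ranges(feats))
    gaps <- IRanges::gaps(covered, start = 1L, end = len)
    if (length(gaps)) {
      rows[[sid]] <- data.frame(seq_id = sid,
                                start = IRanges::start(gaps),
                                end = IRanges::end(gaps),
                                stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(seq_id = character(0), start = integer(0), end = integer(0))
  }
  out <- out[(out$end - out$start + 1L) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select insertion breakpoints in a recipient genome
#'
#' In `uniform` mode, Q distinct positions are drawn uniformly from the
#' concatenated coordinate space `[1, P]` (P = total genome length), so
#' longer replicons receive proportionally more insertions, and mapped back
#' to per-sequence coordinates. In `intergenic` mode, Q distinct intergenic
#' regions are drawn uniformly and each is cut at its midpoint. Breakpoints
#' are 1-based "insert after this base" positions in original coordinates.
#'
#' @param seqs Named character vector: the recipient's sequences.
#' @param Q Number of breakpoints.
#' @param mode `"uniform"` or `"intergenic"`.
#' @param regions Data frame from [intergenic_regions()] (intergenic mode).
#' @return Data frame with columns `seq_id`, `break_position`.
#' @export
select_breakpoints <- function(seqs, Q, mode = c("uniform", "intergenic"),
                               regions = NULL) {
  mode <- match.arg(mode)
  stopifnot(Q >= 0)
  if (Q == 0L) {
    return(data.frame(seq_id = character(0), break_position = integer(0)))
  }
  if (mode == "uniform") {
    lens <- nchar(seqs)
    P <- sum(lens)
    if (Q > P) stop("Q exceeds total genome length", call. = FALSE)
    pos <- sort(sample.int(P, Q)) # distinct cut points
    cum <- cumsum(lens)
    idx <- findInterval(pos - 1L, cum) + 1L
    off <- pos - c(0L, cum)[idx]
    out <- data.frame(seq_id = names(seqs)[idx], break_position = off,
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(regions) || nrow(regions) == 0L) {
      stop("intergenic mode requires a non-empty region table", call. = FALSE)
    }
    if (Q > nrow(regions)) {
      stop("Q exceeds the number of intergenic regions", call. = FALSE)
    }
    pick <- sample.int(nrow(regions), Q)
    reg <- regions[pick, , drop = FALSE]
    # midpoint cut: region [start, end] 1-based inclusive; insert after the
    # base at floor((start - 1 + end) / 2), which always lies inside the region
    mid <- floor((reg$start - 1L + reg$end) / 2)
    out <- data.frame(seq_id = reg$seq_id, break_position = as.integer(mid),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(paste(out$seq_id, out$break_position))) {
    stop("duplicate breakpoints selected", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Insert gene cassettes into a recipient genome
#'
#' Each sequence is rebuilt as prefix + cassette + suffix. Insertions are
#' applied right-to-left so that all recorded break positions stay in the
#' coordinates of the ORIGINAL sequence; this makes exact excision (and thus
#' a byte-exact round-trip) possible from the report alone.
#'
#' @param seqs Named character vector: the recipient's sequences.
#' @param placements Data frame with columns `seq_id`, `break_position`,
#'   `cassette`, `gene_id` (and optionally `flank_length`).
#' @param recipient_id Recipient genome id recorded in the events.
#' @return List with `seqs` (modified sequences) and `events` (data frame:
#'   `recipient_id`, `seq_id`, `break_position`, `gene_id`, `flank_length`,
#'   `cassette_length`).
#' @export
insert_genes <- function(seqs, placements, recipient_id = "recipient") {
  empty <- data.frame(recipient_id = character(0), seq_id = character(0),
                      break_position = integer(0), gene_id = character(0),
                      flank_length = integer(0), cassette_length = integer(0))
  if (is.null(placements) || nrow(placements) == 0L) {
    return(list(seqs = seqs, events = empty))
  }
  if (anyDuplicated(paste(placements$seq_id, placements$break_position))) {
    stop("conflicting placements: duplicate break position on one sequence",
         call. = FALSE)
  }
  if (!all(placements$seq_id %in% names(seqs))) {
    stop("placement references unknown sequence id", call. = FALSE)
  }
  fl <- if ("flank_length" %in% names(placements)) {
    placements$flank_length
  } else rep(NA_integer_, nrow(placements))
  out <- seqs
  for (sid in unique(placements$seq_id)) {
    p <- placements[placements$seq_id == sid, , drop = FALSE]
    if (any(p$break_position < 0L | p$break_position > nchar(seqs[[sid]]))) {
      stop("break position outside sequence ", sid, call. = FALSE)
    }
    p <- p[order(-p$break_position), , drop = FALSE] # right-to-left
    s <- out[[sid]]
    for (i in seq_len(nrow(p))) {
      bp <- p$break_position[i]
      s <- paste0(substr(s, 1L, bp), p$cassette[i],
                  substr(s, bp + 1L, nchar(s)))
    }
    out[[sid]] <- s
  }
  events <- data.frame(
    recipient_id = recipient_id,
    seq_id = placements$seq_id,
    break_position = as.integer(placements$break_position),
    gene_id = placements$gene_id,
    flank_length = as.integer(fl),
    cassette_length = nchar(placements$cassette),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$seq_id, events$break_position), , drop = FALSE]
  rownames(events) <- NULL
  list(seqs = out, events = events)
}

#' Excise inserted cassettes, restoring the original genome
#'
#' Inverse of [insert_genes()]: removes each cassette at its recorded
#' original-coordinate break position. Events are processed in ascending
#' position order: once every cassette at a lower position has been
#' removed, the next cassette sits exactly at its original break position.
#'
#' @param seqs Modified sequences (named character vector).
#' @param events Insertion event data frame for this recipient.
#' @return Named character vector of restored sequences.
#' @export
excise_insertions <- function(seqs, events) {
  out <- seqs
  for (sid in unique(events$seq_id)) {
    ev <- events[events$seq_id == sid, , drop = FALSE]
    ev <- ev[order(ev$break_position), , drop = FALSE]
    s <- out[[sid]]
    for (i in seq_len(nrow(ev))) {
      bp <- ev$break_position[i]
      cl <- ev$cassette_length[i]
      s <- paste0(substr(s, 1L, bp), substr(s, bp + cl + 1L, nchar(s)))
    }
    out[[sid]] <- s
  }
  out
}

#' Write an insertion report
#'
#' @param events Insertion event data frame (possibly several recipients).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_insertion_report <- function(events, path) {
  cols <- c("recipient_id", "seq_id", "break_position", "gene_id",
            "flank_length", "cassette_length")
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(recipient_id = character(0), seq_id = character(0),
                         break_position = integer(0), gene_id = character(0),
                         flank_length = integer(0), cassette_length = integer(0))
  }
  events <- events[order(events$recipient_id, events$seq_id,
                         events$break_position), cols, drop = FALSE]
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an insertion report
#'
#' @param path TSV path written by [write_insertion_report()].
#' @return Data frame of insertion events.
#' @export
read_insertion_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Plant a set of transferred genes into a community of recipients
#'
#' High-level driver: flanks the (mutated) genes, assigns them to
#' recipients, selects breakpoints per recipient (uniform or intergenic),
#' inserts the cassettes and collects the combined insertion report.
#'
#' @param genes Named character vector of (mutated) gene sequences.
#' @param recipients Named list of recipient genomes; each element a named
#'   character vector of that genome's sequences.
#' @param flank Flanking sequence added to both ends of every gene.
#' @param mode `"uniform"` or `"intergenic"`.
#' @param regions Named list of intergenic-region data frames per recipient
#'   (intergenic mode only).
#' @param assignment Optional fixed `gene_id -> recipient_id` map.
#' @return List with `genomes` (modified recipients), `events` (combined
#'   insertion report data frame) and `cassettes` (named character vector of
#'   the flanked sequences actually inserted).
#' @export
plant_transfers <- function(genes, recipients, flank = "",
                            mode = c("uniform", "intergenic"),
                            regions = NULL, assignment = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(genes) > 0, length(recipients) > 0)
  cassettes <- vapply(genes, add_flanks, character(1), flank = flank)
  names(cassettes) <- names(genes)
  assign_map <- if (is.null(assignment)) {
    assign_genes(names(genes), names(recipients))
  } else assignment

  all_events <- list()
  out_genomes <- recipients
  for (rid in names(recipients)) {
    gids <- names(assign_map)[assign_map == rid]
    if (length(gids) == 0L) next
    bp <- select_breakpoints(recipients[[rid]], length(gids), mode,
                             regions = regions[[rid]])
    # random pairing of genes with cut points
    gids <- if (length(gids) > 1L) sample(gids) else gids
    placements <- data.frame(
      seq_id = bp$seq_id, break_position = bp$break_position,
      cassette = unname(cassettes[gids]), gene_id = gids,
      flank_length = nchar(flank), stringsAsFactors = FALSE
    )
    res <- insert_genes(recipients[[rid]], placements, recipient_id = rid)
    out_genomes[[rid]] <- res$seqs
    all_events[[rid]] <- res$events
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  list(genomes = out_genomes, events = events, cassettes = cassettes)
}
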