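#' Read a 12-column tabular alignment hit file
#'
#' The standard tabular format produced by local aligners (blastn
#' `-outfmt 6` and compatible tools): query, subject, percent identity,
#' alignment length, mismatches, gap opens, q.start, q.end, s.start, s.end,
#' e-value, bit score. No header line is expected.
#'
#' @param path Path to the tabular file.
#' @return Data frame with the canonical column names.
#' @export
read_hit_table <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), 12), cols))
    out$query_id <- character(0); out$subject_id <- character(0)
    return(out)
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns", call. = FALSE)
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Generate exact-match hits between queries and contigs
#'
#' A drop-in replacement for an external aligner on error-free synthetic
#' data: each exact occurrence of a query (or its reverse complement) in a
#' contig is reported as a 100%-identity, full-length hit in the standard
#' 12-column layout. Minus-strand occurrences have `s_start > s_end`.
#'
#' @param queries Named character vector of query sequences.
#' @param contigs Named character vector of contig sequences.
#' @return Hit data frame as from [read_hit_table()].
#' @export
exact_hits <- function(queries, contigs) {
  subj <- Biostrings::DNAStringSet(unname(contigs))
  names(subj) <- names(contigs)
  rows <- list()
  for (qi in seq_along(queries)) {
    qlen <- nchar(queries[[qi]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
      m <- Biostrings::vmatchPattern(pat, subj)
      for (ci in seq_along(m)) {
        hits <- m[[ci]]
        if (length(hits) == 0L) next
        for (h in seq_along(hits)) {
          st <- IRanges::start(hits)[h]
          en <- IRanges::end(hits)[h]
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = names(queries)[qi], subject_id = names(contigs)[ci],
            percent_identity = 100, alignment_length = qlen,
            mismatches = 0L, gap_opens = 0L,
            q_start = 1L, q_end = qlen,
            s_start = if (strand == "+") st else en,
            s_end = if (strand == "+") en else st,
            e_value = 0, bit_score = 2 * qlen,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(read_hit_table(tempfile_empty()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

tempfile_empty <- function() {
  f <- tempfile()
  file.create(f)
  f
}

#' Filter alignment hits by identity and query coverage
#'
#' @param hits Hit data frame ([read_hit_table()] layout).
#' @param query_lengths Named numeric vector: full length of every query.
#' @param min_identity Identity cutoff in percent (default 99).
#' @param min_coverage Query coverage cutoff in percent (default 99).
#' @return The qualifying subset of `hits`.
#' @export
filter_hits <- function(hits, query_lengths, min_identity = 99,
                        min_coverage = 99) {
  if (nrow(hits) == 0L) return(hits)
  unknown <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(unknown)) {
    stop("no length known for query: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  qlen <- query_lengths[hits$query_id]
  cov <- 100 * (hits$q_end - hits$q_start + 1) / qlen
  hits[hits$percent_identity >= min_identity & cov >= min_coverage, ,
       drop = FALSE]
}

#' Does a flanking sequence match a recipient genome?
#'
#' Default matcher for error-free synthetic data: the flank matches if a
#' contiguous window covering at least `min_fraction` of it occurs exactly
#' (on either strand) in any recipient sequence. Window starts are scanned
#' from both ends so that a short foreign margin on either side (for
#' example an inserted flanking cassette string) does not mask an otherwise
#' recipient-derived flank.
#'
#' @param flank_seq Non-empty flanking sequence from a contig.
#' @param recipient Named character vector of the recipient's sequences.
#' @param min_fraction Minimum matching fraction of the flank (default
#'   0.95).
#' @return Logical.
#' @export
match_flank_exact <- function(flank_seq, recipient, min_fraction = 0.95) {
  n <- nchar(flank_seq)
  if (n == 0L) return(FALSE)
  w <- as.integer(ceiling(min_fraction * n))
  subj <- Biostrings::DNAStringSet(unname(recipient))
  offs <- 0:(n - w)
  for (o in offs) {
    win <- substr(flank_seq, o + 1L, o + w)
    for (pat in c(win, revcomp(win))) {
      if (sum(Biostrings::vcountPattern(pat, subj)) > 0) return(TRUE)
    }
  }
  FALSE
}

best_hit <- function(hits) {
  # highest bit score; ties by longer alignment, then lexicographic contig id
  o <- order(-hits$bit_score, -hits$alignment_length, hits$subject_id)
  hits[o[1], , drop = FALSE]
}

#' Assess recovery of planted transfers from assembled contigs
#'
#' A planted transfer counts as recovered when a filtered contig hit for it
#' exists and at least one of the contig's two regions flanking the match
#' is longer than `min_flank` bases AND matches the recipient genome the
#' transfer was planted into. Flank lengths are the contig bases outside
#' the matched interval on each side.
#'
#' @param insertions Insertion event data frame (from
#'   [write_insertion_report()] / [read_insertion_report()]).
#' @param hits Filtered hit data frame (queries = transferred cassettes,
#'   subjects = contigs); apply [filter_hits()] first.
#' @param contigs Named character vector of contig sequences.
#' @param recipients Named list of recipient genomes (original, without the
#'   insertions), each a named character vector of sequences.
#' @param min_flank Flank-length threshold in bases; strictly greater than
#'   this qualifies (default 1000, i.e. > 1 kb).
#' @param flank_rule Function `(flank_seq, recipient) -> logical`; default
#'   [match_flank_exact()].
#' @return Data frame with one row per planted gene: `gene_id`,
#'   `recipient_id`, `recovered`, `contig_id`, `left_flank_len`,
#'   `right_flank_len`, `left_matches`, `right_matches`.
#' @export
assess_recovery <- function(insertions, hits, contigs, recipients,
                            min_flank = 1000L,
                            flank_rule = match_flank_exact) {
  res <- vector("list", nrow(insertions))
  for (i in seq_len(nrow(insertions))) {
    gid <- insertions$gene_id[i]
    rid <- insertions$recipient_id[i]
    h <- hits[hits$query_id == gid, , drop = FALSE]
    row <- data.frame(gene_id = gid, recipient_id = rid, recovered = FALSE,
                      contig_id = NA_character_, left_flank_len = NA_integer_,
                      right_flank_len = NA_integer_, left_matches = NA,
                      right_matches = NA, stringsAsFactors = FALSE)
    if (nrow(h) > 0L) {
      h <- best_hit(h)
      cid <- h$subject_id
      if (!cid %in% names(contigs)) {
        stop("hit references unknown contig ", cid, call. = FALSE)
      }
      cseq <- contigs[[cid]]
      s_lo <- min(h$s_start, h$s_end)
      s_hi <- max(h$s_start, h$s_end)
      left_len <- s_lo - 1L
      right_len <- nchar(cseq) - s_hi
      rec_genome <- recipients[[rid]]
      left_ok <- FALSE
      right_ok <- FALSE
      if (left_len > min_flank) {
        left_ok <- flank_rule(substr(cseq, 1L, left_len), rec_genome)
      }
      if (right_len > min_flank) {
        right_ok <- flank_rule(substr(cseq, s_hi + 1L, nchar(cseq)),
                               rec_genome)
      }
      row$contig_id <- cid
      row$left_flank_len <- as.integer(left_len)
      row$right_flank_len <- as.integer(right_len)
      row$left_matches <- left_ok
      row$right_matches <- right_ok
      row$recovered <- (left_len > min_flank && left_ok) ||
        (right_len > min_flank && right_ok)
    }
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise recovery records
#'
#' @param records Data frame from [assess_recovery()].
#' @return Data frame with one row per recipient plus an `overall` row:
#'   `recipient_id`, `recovered`, `total`.
#' @export
summarize_recovery <- function(records) {
  per <- aggregate(recovered ~ recipient_id, data = records, FUN = sum)
  tot <- aggregate(recovered ~ recipient_id, data = records, FUN = length)
  out <- data.frame(recipient_id = per$recipient_id,
                    recovered = as.integer(per$recovered),
                    total = as.integer(tot$recovered),
                    stringsAsFactors = FALSE)
  out <- out[order(out$recipient_id), , drop = FALSE]
  rbind(out, data.frame(recipient_id = "overall",
                        recovered = sum(out$recovered),
                        total = sum(out$total)))
}
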