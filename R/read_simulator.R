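#' Expected mean sequencing depth of a community
#'
#' Depth (fold coverage) is total sequenced bases over total community
#' length: `n_pairs * 2 * read_length / sum(lengths)` in the
#' uniform-abundance case.
#'
#' @param lengths Numeric vector of member genome lengths in bases.
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in bases.
#' @return Expected fold coverage.
#' @examples
#' expected_depth(1e6, 5000, 100) # 1x
#' @export
expected_depth <- function(lengths, n_pairs, read_length) {
  total <- sum(lengths)
  if (total <= 0) stop("total community length must be positive", call. = FALSE)
  n_pairs * 2 * read_length / total
}

#' Simulate error-free paired-end reads from a genome community
#'
#' Fragments of exactly `insert_size` bases (optionally jittered) are drawn
#' from community members. A member is chosen per pair with probability
#' proportional to `abundance x total member length`, so equal abundances
#' yield even sequencing depth across genomes; within a member, sequences
#' are chosen proportional to their number of valid fragment start
#' positions, the start is uniform and the fragment strand is uniform.
#' R1 is the fragment's 5' prefix and R2 the reverse complement of its 3'
#' suffix (FR orientation); with `insert_size == read_length` the two mates
#' fully overlap. Reads are exact substrings: no error model is applied.
#' Fragments never wrap around sequence ends; circular replicons are
#' treated as linear.
#'
#' @param genomes Named list: per member, a named character vector of its
#'   sequences.
#' @param abundance Named numeric vector of relative abundance weights per
#'   member (need not sum to 1). Members missing from it get weight 0.
#' @param n_pairs Number of pairs to simulate.
#' @param read_length Read length (bases).
#' @param insert_size Total fragment length (>= read_length).
#' @param insert_sd Standard deviation of optional normal jitter on the
#'   fragment length (default 0: fixed-length fragments).
#' @param pair_prefix Prefix for pair ids.
#' @return Data frame with columns `pair_id`, `r1`, `r2`, `member`,
#'   `seq_id`, `start` (1-based fragment start on the forward strand),
#'   `strand` (`"+"`/`"-"`), `fragment_length`.
#' @export
simulate_reads <- function(genomes, abundance, n_pairs, read_length = 100L,
                           insert_size = 250L, insert_sd = 0,
                           pair_prefix = "pair") {
  stopifnot(insert_size >= read_length, n_pairs >= 0)
  members <- names(genomes)
  w <- abundance[members]
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("no member has positive abundance", call. = FALSE)
  glen <- vapply(genomes, function(g) sum(nchar(g)), numeric(1))
  prob <- w * glen
  feasible <- vapply(genomes, function(g) any(nchar(g) >= insert_size),
                     logical(1))
  if (any(prob > 0 & !feasible)) {
    stop("insert size exceeds the longest sequence of a sampled member",
         call. = FALSE)
  }
  if (n_pairs == 0L) {
    return(data.frame(pair_id = character(0), r1 = character(0),
                      r2 = character(0), member = character(0),
                      seq_id = character(0), start = integer(0),
                      strand = character(0), fragment_length = integer(0)))
  }

  midx <- sample.int(length(members), n_pairs, replace = TRUE,
                     prob = prob / sum(prob))
  flen <- if (insert_sd > 0) {
    pmax(read_length, as.integer(round(stats::rnorm(n_pairs, insert_size,
                                                    insert_sd))))
  } else rep(as.integer(insert_size), n_pairs)

  seq_id <- character(n_pairs)
  start <- integer(n_pairs)
  frag <- character(n_pairs)
  for (m in unique(midx)) {
    rows_m <- which(midx == m)
    seqs <- genomes[[m]]
    for (fl in unique(flen[rows_m])) {
      rows <- rows_m[flen[rows_m] == fl]
      nv <- pmax(nchar(seqs) - fl + 1L, 0L) # valid start positions per seq
      if (sum(nv) == 0L) {
        stop("no sequence long enough for a fragment in member ",
             members[m], call. = FALSE)
      }
      si <- if (length(seqs) == 1L) rep(1L, length(rows)) else {
        sample.int(length(seqs), length(rows), replace = TRUE,
                   prob = nv / sum(nv))
      }
      st <- pmin(1L + as.integer(floor(stats::runif(length(rows)) * nv[si])),
                 nv[si])
      seq_id[rows] <- names(seqs)[si]
      start[rows] <- st
      frag[rows] <- substring(seqs[si], st, st + fl - 1L)
    }
  }
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  neg <- strand == "-"
  if (any(neg)) frag[neg] <- revcomp(frag[neg])
  r1 <- substr(frag, 1L, read_length)
  r2 <- revcomp(substring(frag, flen - read_length + 1L, flen))
  data.frame(
    pair_id = sprintf("%s_%07d", pair_prefix, seq_len(n_pairs)),
    r1 = r1, r2 = r2,
    member = members[midx], seq_id = seq_id, start = start,
    strand = strand, fragment_length = flen,
    stringsAsFactors = FALSE
  )
}

#' Write read pairs as two FASTQ files
#'
#' Standard 4-line records; mate ids are suffixed `/1` and `/2`; qualities
#' are the maximal constant `"I"` (Q40), reflecting error-free reads.
#'
#' @param pairs Data frame from [simulate_reads()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @param append Append to existing files (for chunked simulation).
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(pairs, r1_path, r2_path, append = FALSE) {
  fastq_block <- function(ids, seqs, mate) {
    if (length(ids) == 0L) return(character(0))
    qual <- strrep("I", nchar(seqs))
    as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", qual))
  }
  con1 <- file(r1_path, if (append) "a" else "w")
  writeLines(fastq_block(pairs$pair_id, pairs$r1, 1L), con1)
  close(con1)
  con2 <- file(r2_path, if (append) "a" else "w")
  writeLines(fastq_block(pairs$pair_id, pairs$r2, 2L), con2)
  close(con2)
  invisible(c(r1_path, r2_path))
}

#' Simulate reads in fixed-size chunks, streaming to FASTQ
#'
#' Keeps memory bounded for large simulations: at most `chunk_size` pairs
#' are held in memory at any time.
#'
#' @inheritParams simulate_reads
#' @param r1_path,r2_path Output FASTQ paths.
#' @param provenance_path Optional TSV recording each pair's origin.
#' @param chunk_size Pairs per chunk (default 100000).
#' @return Invisibly, the number of pairs written.
#' @export
simulate_reads_to_fastq <- function(genomes, abundance, n_pairs,
                                    read_length = 100L, insert_size = 250L,
                                    insert_sd = 0, r1_path, r2_path,
                                    provenance_path = NULL,
                                    chunk_size = 100000L) {
  written <- 0L
  first <- TRUE
  while (written < n_pairs) {
    k <- as.integer(min(chunk_size, n_pairs - written))
    chunk <- simulate_reads(genomes, abundance, k, read_length, insert_size,
                            insert_sd,
                            pair_prefix = sprintf("pair%03d",
                                                  written %/% chunk_size))
    write_fastq(chunk, r1_path, r2_path, append = !first)
    if (!is.null(provenance_path)) {
      prov <- chunk[, c("pair_id", "member", "seq_id", "start", "strand")]
      suppressWarnings(write.table(
        prov, provenance_path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = first, append = !first))
    }
    written <- written + k
    first <- FALSE
  }
  invisible(written)
}

#' Genome sizes of the twenty-genome benchmark community
#'
#' The ten Alphaproteobacteria donor genomes and ten Betaproteobacteria
#' recipient genomes used in the published benchmark, with their sizes in
#' Mbp (75.83 Mbp total). Useful as input to [expected_depth()]: ten
#' million 2 x 100 bp pairs over this community give a mean depth of 26.4x.
#'
#' @return Data frame with columns `class`, `strain`, `genome_size_mbp`.
#' @export
benchmark_community <- function() {
  read.delim(system.file("extdata", "benchmark_community.tsv",
                         package = "hgtbench"),
             stringsAsFactors = FALSE)
}

#' Realized per-member depth of a simulated read set
#'
#' @param pairs Data frame from [simulate_reads()].
#' @param genomes The community the pairs were simulated from.
#' @param read_length Read length used.
#' @return Data frame with columns `member`, `n_pairs`, `length`, `depth`.
#' @export
realized_depth <- function(pairs, genomes, read_length) {
  glen <- vapply(genomes, function(g) sum(nchar(g)), numeric(1))
  cnt <- table(factor(pairs$member, levels = names(genomes)))
  data.frame(
    member = names(genomes),
    n_pairs = as.integer(cnt),
    length = as.numeric(glen),
    depth = as.integer(cnt) * 2 * read_length / as.numeric(glen),
    stringsAsFactors = FALSE
  )
}
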