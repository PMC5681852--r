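#' Run the full simulation benchmark end-to-end
#'
#' Drives every stage against a synthetic community: generate fixtures,
#' mutate donor genes, plant them into recipients, simulate error-free
#' paired-end reads, build perfectly assembled contigs, and score recovery.
#' Each stage draws from its own RNG stream derived from the master seed
#' (see [derive_seed()]), so the stages are independently reproducible.
#'
#' @param seed Master seed.
#' @param level Mutation level in percent.
#' @param ratio Length-4 category ratio.
#' @param flank Flanking sequence added to transfers.
#' @param n_genes,n_recipients,recipient_length Community scale.
#' @param n_pairs,read_length,insert_size Read-simulation parameters.
#' @param context Recipient context per side in the perfect contigs.
#' @param mode Breakpoint mode, `"uniform"` or `"intergenic"`.
#' @return List with `community`, `mutated`, `planted`, `reads`, `contigs`,
#'   `records`, `summary`.
#' @export
run_benchmark <- function(seed = 1L, level = 10, ratio = c(1, 0, 1, 1),
                          flank = "TAGATGAGTGATTAGTTAGTTA",
                          n_genes = 20L, n_recipients = 3L,
                          recipient_length = 200000L,
                          n_pairs = 20000L, read_length = 100L,
                          insert_size = 250L, context = 1500L,
                          mode = c("uniform", "intergenic")) {
  mode <- match.arg(mode)
  table <- codon_table()

  community <- with_seed(derive_seed(seed, "fixtures"),
                         generate_community(n_genes, n_recipients,
                                            recipient_length, table = table))
  mutated <- with_seed(derive_seed(seed, "mutate"),
                       mutate_genes(community$genes, level, ratio, table))
  regions <- if (mode == "intergenic") {
    lapply(names(community$recipients), function(rid) {
      seqlen <- setNames(nchar(community$recipients[[rid]]),
                         names(community$recipients[[rid]]))
      feats <- community$features[[rid]]
      gaps_from_features(feats, seqlen)
    })
  } else NULL
  if (!is.null(regions)) names(regions) <- names(community$recipients)
  planted <- with_seed(derive_seed(seed, "insert"),
                       plant_transfers(mutated$seqs, community$recipients,
                                       flank = flank, mode = mode,
                                       regions = regions))
  reads <- with_seed(derive_seed(seed, "reads"),
                     simulate_reads(planted$genomes, community$abundance,
                                    n_pairs, read_length, insert_size))
  contigs <- perfect_contigs(community$recipients, planted$cassettes,
                             planted$events, context)
  hits <- exact_hits(planted$cassettes[planted$events$gene_id], contigs)
  hits <- filter_hits(hits, setNames(nchar(planted$cassettes),
                                     names(planted$cassettes)))
  records <- assess_recovery(planted$events, hits, contigs,
                             community$recipients)
  list(community = community, mutated = mutated, planted = planted,
       reads = reads, contigs = contigs, records = records,
       summary = summarize_recovery(records))
}

#' Intergenic gaps from a feature table
#'
#' Complement of the feature intervals within each sequence, without going
#' through GFF3 on disk. See [intergenic_regions()] for the file-based
#' variant.
#'
#' @param features Data frame with `seq_id`, `start`, `end`.
#' @param seq_lengths Named vector of sequence lengths.
#' @param min_length Drop gaps shorter than this.
#' @return Data frame with `seq_id`, `start`, `end`.
#' @export
gaps_from_features <- function(features, seq_lengths, min_length = 0L) {
  rows <- list()
  for (sid in names(seq_lengths)) {
    len <- seq_lengths[[sid]]
    f <- features[features$seq_id == sid, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = len)
    if (length(gaps)) {
      rows[[sid]] <- data.frame(seq_id = sid, start = IRanges::start(gaps),
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
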