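# Independent oracles used across tests; deliberately implemented through
# different code paths than the package internals they check.

# positional Hamming distance of two equal-length strings
hamming_str <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force census of the codon mutation space, classified with
# Biostrings::translate rather than the package's lookup table
oracle_census <- function(excluded = c("ATG", "GTG", "TTG",
                                       "TAA", "TAG", "TGA")) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAStringSet(codons),
                          no.init.codon = TRUE)))
  names(aa) <- codons
  allowed <- setdiff(codons, excluded)
  counts <- matrix(0L, nrow = 3, ncol = 2,
                   dimnames = list(1:3, c("silent", "non_silent")))
  for (a in allowed) {
    av <- strsplit(a, "")[[1]]
    for (b in allowed) {
      if (a == b) next
      d <- sum(av != strsplit(b, "")[[1]])
      s <- if (aa[[a]] == aa[[b]]) "silent" else "non_silent"
      counts[d, s] <- counts[d, s] + 1L
    }
  }
  counts
}

# small community used by several tests
make_test_community <- function(seed, n_genes = 6L, n_recipients = 2L,
                                recipient_length = 50000L) {
  withr::with_seed(seed,
    generate_community(n_genes = n_genes, n_recipients = n_recipients,
                       recipient_length = recipient_length,
                       gene_codon_range = c(60L, 120L), n_features = 10L))
}
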