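#' @importFrom methods is
#' @importFrom stats setNames aggregate rnorm
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

check_dna <- function(x, what = "sequence", allow_empty = TRUE) {
  if (length(x) != 1L || is.na(x)) {
    stop(what, " must be a single non-NA character string", call. = FALSE)
  }
  if (!allow_empty && nchar(x) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  }
  invisible(x)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences over \{A,C,G,T\}.
#' @return Character vector of the same length, reverse-complemented.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3", call. = FALSE)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @param width Line width for wrapping (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Each pipeline stage draws from its own RNG stream, seeded by a stable
#' hash of the master seed and a stage label, so adding or reordering
#' stages never perturbs another stage's draws.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
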