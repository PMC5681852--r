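#' Codon table with excluded start/stop codons
#'
#' Builds the standard genetic code together with the set of codons that are
#' excluded from the mutation space. Codon-structured mutation keeps reading
#' frames intact, and start/stop codons are kept out of the mutation space on
#' both the source and the target side so that no mutation can create or
#' destroy a translation signal. The default start set is the bacterial-style
#' \{ATG, GTG, TTG\}; the stop set is \{TAA, TAG, TGA\}. Amino-acid
#' assignment always follows the standard code (the start set only affects
#' exclusion, not translation).
#'
#' Neighbour sets for the four mutation categories (see
#' [mutation_categories()]) are precomputed for every non-excluded codon so
#' that repeated gene mutation is cheap.
#'
#' @param start_codons Character vector of start codons to exclude.
#' @param stop_codons Character vector of stop codons to exclude.
#' @return An object of class `codon_table`: a list with elements
#'   `codon_to_aa` (named character of length 64, stops as `"*"`),
#'   `start_codons`, `stop_codons`, `excluded`, `allowed`, and `neighbors`
#'   (per-category neighbour lists).
#' @examples
#' ct <- codon_table()
#' ct$codon_to_aa[["ATC"]] # "I"
#' length(ct$excluded)     # 6
#' @export
codon_table <- function(start_codons = c("ATG", "GTG", "TTG"),
                        stop_codons = c("TAA", "TAG", "TGA")) {
  code <- Biostrings::GENETIC_CODE
  codon_to_aa <- setNames(as.character(code), names(code))
  bad <- setdiff(c(start_codons, stop_codons), names(codon_to_aa))
  if (length(bad)) {
    stop("not valid codons: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  excluded <- union(start_codons, stop_codons)
  allowed <- setdiff(names(codon_to_aa), excluded)
  tab <- structure(
    list(codon_to_aa = codon_to_aa,
         start_codons = start_codons,
         stop_codons = stop_codons,
         excluded = excluded,
         allowed = allowed),
    class = "codon_table"
  )
  tab$neighbors <- precompute_neighbors(tab)
  tab
}

#' The four codon mutation categories
#'
#' C1: one-base silent; C2: one-base non-silent; C3: any two-base change;
#' C4: any three-base change. The base cost per event is (1, 1, 2, 3).
#'
#' @return A data frame with columns `label`, `n_bases`, `silent_constraint`
#'   (`"silent"`, `"non_silent"` or `"any"`).
#' @export
mutation_categories <- function() {
  data.frame(
    label = c("C1", "C2", "C3", "C4"),
    n_bases = c(1L, 1L, 2L, 3L),
    silent_constraint = c("silent", "non_silent", "any", "any"),
    stringsAsFactors = FALSE
  )
}

#' Translate a DNA sequence codon-by-codon
#'
#' @param seq DNA sequence over \{A,C,G,T\}, length divisible by 3.
#' @param table A [codon_table()].
#' @return Protein string, one symbol per codon, stops rendered as `"*"`.
#'   The empty sequence translates to `""`.
#' @examples
#' translate_dna("GCCACC") # "AT"
#' @export
translate_dna <- function(seq, table = codon_table()) {
  check_dna(seq, "sequence")
  codons <- split_codons(seq)
  if (length(codons) == 0L) return("")
  paste(unname(table$codon_to_aa[codons]), collapse = "")
}

#' Classify an ordered codon pair
#'
#' @param src,dst Distinct codons over \{A,C,G,T\}, neither in the excluded
#'   start/stop set.
#' @param table A [codon_table()].
#' @return A list with `distance` (Hamming distance, 1--3) and `silent`
#'   (logical: translations identical).
#' @examples
#' classify_codon_pair("ATC", "ATA") # distance 1, silent
#' @export
classify_codon_pair <- function(src, dst, table = codon_table()) {
  for (x in c(src, dst)) {
    if (nchar(x) != 3L || grepl("[^ACGT]", x)) {
      stop("codons must be length-3 strings over {A,C,G,T}", call. = FALSE)
    }
  }
  if (src == dst) stop("degenerate pair: src == dst", call. = FALSE)
  if (src %in% table$excluded || dst %in% table$excluded) {
    stop("excluded codon in pair: start/stop codons are outside the ",
         "mutation space", call. = FALSE)
  }
  d <- sum(strsplit(src, "")[[1]] != strsplit(dst, "")[[1]])
  list(distance = d,
       silent = table$codon_to_aa[[src]] == table$codon_to_aa[[dst]])
}

hamming3 <- function(a, b) {
  # vectorised Hamming distance between codon vectors
  (substr(a, 1, 1) != substr(b, 1, 1)) +
    (substr(a, 2, 2) != substr(b, 2, 2)) +
    (substr(a, 3, 3) != substr(b, 3, 3))
}

precompute_neighbors <- function(table) {
  allowed <- table$allowed
  aa <- table$codon_to_aa
  out <- list(C1 = list(), C2 = list(), C3 = list(), C4 = list())
  for (src in allowed) {
    others <- setdiff(allowed, src)
    d <- hamming3(src, others)
    silent <- aa[others] == aa[[src]]
    out$C1[[src]] <- others[d == 1 & silent]
    out$C2[[src]] <- others[d == 1 & !silent]
    out$C3[[src]] <- others[d == 2]
    out$C4[[src]] <- others[d == 3]
  }
  out
}

#' Category-compatible mutation targets of a codon
#'
#' @param src A non-excluded codon.
#' @param category One of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @param table A [codon_table()].
#' @return Character vector of target codons (possibly empty: e.g. TGG has
#'   no synonymous one-base neighbour, so its C1 set is empty).
#' @export
codon_neighbors <- function(src, category, table = codon_table()) {
  category <- match.arg(category, c("C1", "C2", "C3", "C4"))
  if (src %in% table$excluded) {
    stop("excluded codon: ", src, " is a start/stop codon", call. = FALSE)
  }
  nb <- table$neighbors[[category]][[src]]
  if (is.null(nb)) stop("not a valid codon: ", src, call. = FALSE)
  nb
}

#' Exhaustive census of the codon mutation space
#'
#' Enumerates every ordered pair of distinct codons outside the excluded
#' start/stop set and buckets them by Hamming distance and silence. Under
#' the default excluded set \{ATG, GTG, TTG, TAA, TAG, TGA\} this yields
#' 124 one-base silent, 356 one-base non-silent, 12 three-base silent and
#' 1400 three-base non-silent ordered pairs.
#'
#' @param table A [codon_table()].
#' @return A data frame with columns `category_label`, `distance`, `silent`,
#'   `count` (six rows: distance 1--3 x silent/non-silent).
#' @examples
#' codon_census()
#' @export
codon_census <- function(table = codon_table()) {
  allowed <- table$allowed
  aa <- table$codon_to_aa
  grid <- expand.grid(src = allowed, dst = allowed,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$src != grid$dst, ]
  d <- hamming3(grid$src, grid$dst)
  silent <- aa[grid$src] == aa[grid$dst]
  out <- expand.grid(distance = 1:3, silent = c(TRUE, FALSE),
                     KEEP.OUT.ATTRS = FALSE)
  out$count <- mapply(function(dd, ss) sum(d == dd & silent == ss),
                      out$distance, out$silent)
  out$category_label <- ifelse(
    out$distance == 1, ifelse(out$silent, "C1", "C2"),
    ifelse(out$distance == 2, "C3", "C4")
  )
  out <- out[order(out$distance, !out$silent),
             c("category_label", "distance", "silent", "count")]
  rownames(out) <- NULL
  out
}

#' Write the codon census as TSV
#'
#' @param census Data frame from [codon_census()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_census_tsv <- function(census, path) {
  write.table(census, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
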