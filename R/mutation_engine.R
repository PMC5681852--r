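#' Number of bases to mutate for a gene
#'
#' The mutation level I is the percentage of a gene's nucleotides to change,
#' so that the mutated copy shares roughly 100 - I percent nucleotide
#' identity with the donor gene. The base budget is N = L * I / 100,
#' rounded half away from zero.
#'
#' @param L Gene length in bases (divisible by 3).
#' @param I Mutation level in percent, in `[0, 100]`.
#' @return Integer base budget N.
#' @examples
#' mutation_budget(300, 10) # 30
#' mutation_budget(303, 5)  # 15 (15.15 rounds to 15)
#' @export
mutation_budget <- function(L, I) {
  stopifnot(length(L) == 1L, length(I) == 1L)
  if (L %% 3L != 0L) stop("gene length must be divisible by 3", call. = FALSE)
  if (I < 0 || I > 100) stop("mutation level must be in [0, 100]", call. = FALSE)
  # half-away-from-zero; the 1e-9 nudge guards float representation of L*I/100
  as.integer(floor(L * I / 100 + 0.5 + 1e-9))
}

#' Partition a base budget across the four mutation categories
#'
#' Event counts c1..c4 are made proportional to the user ratio r1:r2:r3:r4
#' by largest-remainder apportionment, then topped up with the cheapest
#' allowed category so that the base cost c1 + c2 + 2*c3 + 3*c4 equals N
#' exactly. Deterministic: no randomness is involved.
#'
#' @param N Total bases to change (non-negative integer).
#' @param ratio Numeric vector of four non-negative weights (r1, r2, r3, r4),
#'   not all zero.
#' @param I,L Optional metadata recorded in the plan (level and gene length).
#' @return An object of class `mutation_plan`: list with `c1`..`c4`, `N`,
#'   `ratio`, and optional `I`, `L`.
#' @examples
#' build_mutation_plan(7, c(1, 1, 1, 1)) # one event of each category
#' @export
build_mutation_plan <- function(N, ratio, I = NA_real_, L = NA_integer_) {
  stopifnot(length(ratio) == 4L, all(ratio >= 0), length(N) == 1L, N >= 0)
  if (all(ratio == 0)) stop("ratio must not be all zero", call. = FALSE)
  w <- c(1L, 1L, 2L, 3L) # base cost per event of C1..C4
  active <- ratio > 0
  block <- sum(ratio * w)
  k <- N / block
  target <- k * ratio
  cnt <- ifelse(active, floor(target), 0)
  rem <- N - sum(cnt * w)

  # largest-remainder pass: one extra event per category, most-deficient first
  frac <- target - cnt
  for (i in order(-frac, seq_len(4))) {
    if (active[i] && frac[i] > 0 && w[i] <= rem) {
      cnt[i] <- cnt[i] + 1
      rem <- rem - w[i]
    }
  }
  # top up with the cheapest allowed category
  costs <- sort(unique(w[active]))
  while (rem > 0) {
    fit <- costs[costs <= rem]
    if (length(fit)) {
      i <- which(active & w == fit[1])[1]
      take <- if (fit[1] == 1) rem else rem %/% fit[1]
      cnt[i] <- cnt[i] + take
      rem <- rem - take * fit[1]
    } else if (rem == 1 && active[4] && cnt[3] > 0) {
      # only costs {2,3} fit budgets; trade a two-base for a three-base event
      cnt[3] <- cnt[3] - 1
      cnt[4] <- cnt[4] + 1
      rem <- 0
    } else {
      stop("infeasible budget: N = ", N, " cannot be met with ratio ",
           paste(ratio, collapse = ":"), call. = FALSE)
    }
  }
  stopifnot(sum(cnt * w) == N)
  structure(
    list(c1 = as.integer(cnt[1]), c2 = as.integer(cnt[2]),
         c3 = as.integer(cnt[3]), c4 = as.integer(cnt[4]),
         N = as.integer(N), ratio = ratio, I = I, L = L),
    class = "mutation_plan"
  )
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf("mutation plan: N=%d bases, events C1=%d C2=%d C3=%d C4=%d (ratio %s)\n",
              x$N, x$c1, x$c2, x$c3, x$c4, paste(x$ratio, collapse = ":")))
  invisible(x)
}

n_events <- function(plan) plan$c1 + plan$c2 + plan$c3 + plan$c4

#' Apply a mutation plan to a gene
#'
#' Selects distinct internal codons uniformly at random (the first and last
#' codon are never touched, consistent with start/stop exclusion), assigns
#' each selected codon a category, and replaces it by a target codon drawn
#' uniformly from its category-compatible neighbour set. Each codon is
#' mutated at most once, so the Hamming distance between input and output is
#' exactly N. Codons whose current triplet is a start/stop codon are never
#' selected, and no mutation can create an internal stop.
#'
#' The most constrained categories are assigned first (C1, then C2, C3, C4)
#' against a random permutation of eligible codons; codons with an empty
#' neighbour set for a category (e.g. TGG for C1) are passed over. If a
#' category cannot be filled the function aborts with an error naming it.
#'
#' @param seq Gene sequence (length divisible by 3, at least 3 codons).
#' @param plan A [build_mutation_plan()] result.
#' @param table A [codon_table()].
#' @param gene_id Identifier recorded in the event table.
#' @return List with `seq` (mutated sequence) and `events`: a data frame
#'   with one row per changed base, columns `gene_id`, `position` (1-based
#'   in the gene), `ref`, `alt`, `codon_index` (1-based), `category`.
#' @export
mutate_gene <- function(seq, plan, table = codon_table(), gene_id = "gene") {
  check_dna(seq, "gene", allow_empty = FALSE)
  codons <- split_codons(seq)
  ncod <- length(codons)
  if (ncod < 3L) stop("gene must have at least 3 codons", call. = FALSE)

  empty_events <- data.frame(
    gene_id = character(0), position = integer(0), ref = character(0),
    alt = character(0), codon_index = integer(0), category = character(0),
    stringsAsFactors = FALSE
  )
  total <- n_events(plan)
  if (total == 0L) return(list(seq = seq, events = empty_events))

  internal <- 2:(ncod - 1L)
  eligible <- internal[!(codons[internal] %in% table$excluded)]
  if (length(eligible) < total) {
    stop("infeasible plan: ", total, " events but only ", length(eligible),
         " eligible internal codons", call. = FALSE)
  }
  pool <- sample(eligible)          # random permutation; assign greedily
  wanted <- c(C1 = plan$c1, C2 = plan$c2, C3 = plan$c3, C4 = plan$c4)
  picked_pos <- integer(0)
  picked_cat <- character(0)
  for (cat in c("C1", "C2", "C3", "C4")) {
    need <- wanted[[cat]]
    if (need == 0L) next
    ok <- lengths(table$neighbors[[cat]][codons[pool]]) > 0L
    if (sum(ok) < need) {
      stop("infeasible plan: not enough codons with ", cat,
           "-compatible targets (need ", need, ", have ", sum(ok), ")",
           call. = FALSE)
    }
    take <- pool[ok][seq_len(need)]
    picked_pos <- c(picked_pos, take)
    picked_cat <- c(picked_cat, rep(cat, need))
    pool <- setdiff(pool, take)
  }

  new_codons <- codons
  nbases <- plan$N
  e_pos <- integer(nbases); e_ref <- character(nbases)
  e_alt <- character(nbases); e_cod <- integer(nbases)
  e_cat <- character(nbases)
  k <- 0L
  for (j in seq_len(total)) {
    i <- picked_pos[j]
    cat <- picked_cat[j]
    src <- codons[i]
    nb <- table$neighbors[[cat]][[src]]
    dst <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    new_codons[i] <- dst
    for (b in 1:3) {
      rb <- substr(src, b, b)
      ab <- substr(dst, b, b)
      if (rb != ab) {
        k <- k + 1L
        e_pos[k] <- (i - 1L) * 3L + b
        e_ref[k] <- rb; e_alt[k] <- ab
        e_cod[k] <- i; e_cat[k] <- cat
      }
    }
  }
  o <- order(e_pos)
  events <- data.frame(
    gene_id = rep(gene_id, nbases), position = e_pos[o], ref = e_ref[o],
    alt = e_alt[o], codon_index = e_cod[o], category = e_cat[o],
    stringsAsFactors = FALSE
  )
  list(seq = paste(new_codons, collapse = ""), events = events)
}

#' Mutate a set of genes at one level and ratio
#'
#' Convenience wrapper: computes each gene's budget with [mutation_budget()],
#' builds its plan, and applies [mutate_gene()].
#'
#' @param genes Named character vector of in-frame gene sequences.
#' @param level Mutation level I in percent.
#' @param ratio Length-4 category ratio.
#' @param table A [codon_table()].
#' @param suffix If `TRUE` (default), mutated ids get a `_<level>` suffix,
#'   marking the divergence level of the transferred copy.
#' @return List with `seqs` (named character, mutated) and `events`
#'   (combined event data frame keyed by the original gene ids).
#' @export
mutate_genes <- function(genes, level, ratio, table = codon_table(),
                         suffix = TRUE) {
  stopifnot(length(genes) > 0, !is.null(names(genes)))
  out_seqs <- character(length(genes))
  ev <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    plan <- build_mutation_plan(mutation_budget(nchar(genes[[i]]), level),
                                ratio, I = level, L = nchar(genes[[i]]))
    res <- mutate_gene(genes[[i]], plan, table, gene_id = names(genes)[i])
    out_seqs[i] <- res$seq
    ev[[i]] <- res$events
  }
  names(out_seqs) <- if (suffix) paste0(names(genes), "_", level) else names(genes)
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  list(seqs = out_seqs, events = events)
}

#' Nucleotide identity of two equal-length sequences
#'
#' @param a,b Equal-length DNA sequences.
#' @return Percent of positions that match; 100 for empty input.
#' @export
nt_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  if (nchar(a) == 0L) return(100)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  100 * sum(av == bv) / length(av)
}

#' Amino-acid identity of two in-frame DNA sequences
#'
#' Positional identity of the two translations. Because mutated genes are
#' equal-length and gap-free by construction, positional comparison is
#' equivalent to an alignment-based protein comparison here; use
#' [write_protein_pair()] to export both proteins for external alignment.
#'
#' @param a,b Equal-length DNA sequences, lengths divisible by 3.
#' @param table A [codon_table()].
#' @return Percent of aligned amino-acid positions that match.
#' @export
aa_identity <- function(a, b, table = codon_table()) {
  pa <- translate_dna(a, table)
  pb <- translate_dna(b, table)
  nt_identity(pa, pb)
}

#' Export original/mutated protein pairs as FASTA
#'
#' @param original,mutated Named character vectors of in-frame DNA genes
#'   (same order).
#' @param path_original,path_mutated Output FASTA paths.
#' @param table A [codon_table()].
#' @return Invisibly, the two paths.
#' @export
write_protein_pair <- function(original, mutated, path_original, path_mutated,
                               table = codon_table()) {
  po <- vapply(original, translate_dna, character(1), table = table)
  pm <- vapply(mutated, translate_dna, character(1), table = table)
  ss <- Biostrings::AAStringSet(unname(po)); names(ss) <- names(original)
  Biostrings::writeXStringSet(ss, path_original)
  ss <- Biostrings::AAStringSet(unname(pm)); names(ss) <- names(mutated)
  Biostrings::writeXStringSet(ss, path_mutated)
  invisible(c(path_original, path_mutated))
}

#' Identity sweep across mutation levels and category ratios
#'
#' For each (level, ratio) combination, mutates every gene `replicates`
#' times and records the mean nucleotide and amino-acid identity between
#' donor and mutated copies. This is the correlation between nucleotide
#' divergence and the resulting protein change under different category
#' mixes: all-silent ratios leave the protein untouched at any level, while
#' ratios dominated by multi-base events track the nucleotide level closely.
#'
#' @param genes Named character vector of in-frame genes.
#' @param levels Numeric vector of mutation levels (percent).
#' @param ratios List of length-4 numeric ratios.
#' @param table A [codon_table()].
#' @param replicates Mutations per gene per combination (default 1).
#' @return Data frame with columns `level`, `ratio`, `mean_nt_identity`,
#'   `mean_aa_identity`.
#' @export
sweep_identity <- function(genes, levels, ratios, table = codon_table(),
                           replicates = 1L) {
  if (!is.list(ratios)) ratios <- list(ratios)
  rows <- list()
  for (ratio in ratios) {
    rlab <- paste(ratio, collapse = ":")
    for (lev in levels) {
      nts <- aas <- numeric(0)
      for (rep in seq_len(replicates)) {
        for (g in seq_along(genes)) {
          plan <- build_mutation_plan(
            mutation_budget(nchar(genes[[g]]), lev), ratio, I = lev)
          res <- mutate_gene(genes[[g]], plan, table, names(genes)[g])
          nts <- c(nts, nt_identity(genes[[g]], res$seq))
          aas <- c(aas, aa_identity(genes[[g]], res$seq, table))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, ratio = rlab,
        mean_nt_identity = mean(nts), mean_aa_identity = mean(aas),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mutation report
#'
#' One row per changed nucleotide, ordered by (gene_id, position), so the
#' report can be replayed onto the original genes to reproduce the mutated
#' ones byte-exactly (see [apply_mutation_report()]).
#'
#' @param events Event data frame from [mutate_gene()]/[mutate_genes()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_mutation_report <- function(events, path) {
  cols <- c("gene_id", "position", "ref", "alt", "codon_index", "category")
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(gene_id = character(0), position = integer(0),
                         ref = character(0), alt = character(0),
                         codon_index = integer(0), category = character(0))
  }
  events <- events[order(events$gene_id, events$position), cols, drop = FALSE]
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replay a mutation report onto original genes
#'
#' @param genes Named character vector of original gene sequences.
#' @param report Data frame as written by [write_mutation_report()] (or the
#'   path to such a TSV).
#' @return Named character vector of mutated sequences (ids unchanged).
#' @export
apply_mutation_report <- function(genes, report) {
  if (is.character(report) && length(report) == 1L) {
    report <- read.delim(report, stringsAsFactors = FALSE)
  }
  out <- genes
  for (gid in unique(report$gene_id)) {
    rows <- report[report$gene_id == gid, ]
    s <- strsplit(out[[gid]], "")[[1]]
    if (any(s[rows$position] != rows$ref)) {
      stop("report does not match gene ", gid, " at some position",
           call. = FALSE)
    }
    s[rows$position] <- rows$alt
    out[[gid]] <- paste(s, collapse = "")
  }
  out
}
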