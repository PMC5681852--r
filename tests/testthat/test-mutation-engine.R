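test_that("mutation budget is L*I/100 rounded half away from zero", {
  expect_identical(mutation_budget(300, 10), 30L)
  expect_identical(mutation_budget(300, 0), 0L)
  expect_identical(mutation_budget(303, 5), 15L)  # 15.15
  expect_identical(mutation_budget(330, 5), 17L)  # 16.5 rounds up
  expect_error(mutation_budget(300, 101), "\\[0, 100\\]")
  expect_error(mutation_budget(300, -1), "\\[0, 100\\]")
  expect_error(mutation_budget(301, 10), "divisible by 3")
})

test_that("plans hit the base budget exactly and honour zero ratios", {
  p <- build_mutation_plan(7, c(1, 1, 1, 1))
  expect_equal(c(p$c1, p$c2, p$c3, p$c4), c(1, 1, 1, 1))
  p <- build_mutation_plan(0, c(1, 1, 1, 1))
  expect_equal(c(p$c1, p$c2, p$c3, p$c4), c(0, 0, 0, 0))
  p <- build_mutation_plan(9, c(0, 0, 0, 1))
  expect_equal(c(p$c1, p$c2, p$c3, p$c4), c(0, 0, 0, 3))
  expect_error(build_mutation_plan(1, c(0, 0, 0, 1)), "infeasible")
  expect_error(build_mutation_plan(3, c(0, 0, 1, 0)), "infeasible")
  expect_error(build_mutation_plan(5, c(0, 0, 0, 0)), "all zero")

  set.seed(21)
  for (i in 1:200) {
    ratio <- sample(0:3, 4, replace = TRUE)
    if (all(ratio == 0)) ratio[1] <- 1
    N <- sample(0:90, 1)
    p <- tryCatch(build_mutation_plan(N, ratio), error = function(e) NULL)
    if (is.null(p)) next
    expect_identical(p$c1 + p$c2 + 2L * p$c3 + 3L * p$c4, as.integer(N))
    expect_true(all(c(p$c1, p$c2, p$c3, p$c4)[ratio == 0] == 0))
  }
})

test_that("plan construction is deterministic", {
  a <- build_mutation_plan(37, c(2, 1, 1, 3))
  b <- build_mutation_plan(37, c(2, 1, 1, 3))
  expect_identical(a[c("c1", "c2", "c3", "c4")], b[c("c1", "c2", "c3", "c4")])
})

test_that("gene mutation changes exactly N distinct bases in frame", {
  ct <- codon_table()
  set.seed(31)
  genes <- generate_gene_set(10, c(60, 120), table = ct)
  for (lev in c(5, 15, 30)) {
    for (g in seq_along(genes)) {
      gene <- genes[[g]]
      plan <- build_mutation_plan(mutation_budget(nchar(gene), lev),
                                  c(1, 1, 1, 1), I = lev)
      res <- mutate_gene(gene, plan, ct, gene_id = names(genes)[g])
      expect_identical(nchar(res$seq), nchar(gene))
      expect_identical(hamming_str(gene, res$seq), as.integer(plan$N))
      expect_identical(nrow(res$events), as.integer(plan$N))
      # first and last codons untouched, one mutation per codon at most
      expect_true(all(res$events$codon_index > 1))
      expect_true(all(res$events$codon_index < nchar(gene) / 3))
      per_codon <- table(res$events$codon_index)
      expect_true(all(per_codon <= 3))
      # no internal stops or excluded codons created
      out_codons <- substring(res$seq, seq(1, nchar(res$seq), 3),
                              seq(3, nchar(res$seq), 3))
      internal <- out_codons[-c(1, length(out_codons))]
      expect_false(any(internal %in% ct$stop_codons))
      # nucleotide identity is exactly 100 - 100 N / L
      expect_equal(nt_identity(gene, res$seq),
                   100 - 100 * plan$N / nchar(gene))
    }
  }
})

test_that("silent-only plans preserve the protein; C2-only plans change c2 residues", {
  ct <- codon_table()
  set.seed(32)
  gene <- generate_cds(120, ct)
  p_silent <- build_mutation_plan(18, c(1, 0, 0, 0))
  res <- mutate_gene(gene, p_silent, ct)
  expect_identical(translate_dna(res$seq, ct), translate_dna(gene, ct))
  expect_equal(aa_identity(gene, res$seq, ct), 100)

  p_ns <- build_mutation_plan(12, c(0, 1, 0, 0))
  res <- mutate_gene(gene, p_ns, ct)
  pa <- strsplit(translate_dna(gene, ct), "")[[1]]
  pb <- strsplit(translate_dna(res$seq, ct), "")[[1]]
  expect_identical(sum(pa != pb), 12L)
})

test_that("zero-level plans leave the gene untouched", {
  set.seed(33)
  gene <- generate_cds(60)
  plan <- build_mutation_plan(0, c(1, 1, 1, 1))
  res <- mutate_gene(gene, plan)
  expect_identical(res$seq, gene)
  expect_identical(nrow(res$events), 0L)
})

test_that("infeasible plans fail loudly, naming the category", {
  ct <- codon_table()
  # all internal codons TGG: no C1 target exists
  gene <- paste0("ATG", strrep("TGG", 5), "TAA")
  plan <- build_mutation_plan(2, c(1, 0, 0, 0))
  expect_error(mutate_gene(gene, plan, ct), "C1")
  # more events than internal codons
  gene2 <- paste0("ATG", strrep("AAA", 3), "TAA")
  plan2 <- build_mutation_plan(9, c(0, 1, 0, 0))
  expect_error(mutate_gene(gene2, plan2, ct), "eligible")
})

test_that("mutation is deterministic under a fixed seed", {
  gene <- withr::with_seed(34, generate_cds(100))
  plan <- build_mutation_plan(30, c(1, 0, 1, 1))
  a <- withr::with_seed(99, mutate_gene(gene, plan))
  b <- withr::with_seed(99, mutate_gene(gene, plan))
  expect_identical(a, b)
})

test_that("mutation reports replay byte-exactly, in memory and from disk", {
  ct <- codon_table()
  set.seed(35)
  genes <- generate_gene_set(5, c(60, 100), table = ct)
  res <- mutate_genes(genes, 10, c(1, 0, 1, 1), ct, suffix = FALSE)
  replayed <- apply_mutation_report(genes, res$events)
  expect_identical(unname(replayed), unname(res$seqs))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_report(res$events, path)
  replayed2 <- apply_mutation_report(genes, path)
  expect_identical(unname(replayed2), unname(res$seqs))

  # one C4 event writes exactly 3 rows; empty report is header-only
  gene <- genes[[1]]
  r4 <- mutate_gene(gene, build_mutation_plan(3, c(0, 0, 0, 1)), ct)
  expect_identical(nrow(r4$events), 3L)
  write_mutation_report(r4$events[0, ], path)
  expect_identical(length(readLines(path)), 1L)
})

test_that("identity helpers agree with direct computation", {
  expect_equal(nt_identity("ACGT", "ACGT"), 100)
  expect_equal(nt_identity("ACGT", "ACGA"), 75)
  expect_equal(nt_identity("", ""), 100)
  expect_error(nt_identity("ACG", "AC"), "length")
  expect_equal(aa_identity("GCC", "ACC"), 0)
  expect_equal(aa_identity("GCCGCC", "GCCGCC"), 100)
})

test_that("eligible codons are selected near-uniformly across seeds", {
  ct <- codon_table()
  gene <- paste0("ATG", strrep("GCC", 10), "TAA") # 10 identical internal codons
  plan <- build_mutation_plan(3, c(0, 0, 0, 1))
  set.seed(36)
  picks <- replicate(2000, mutate_gene(gene, plan, ct)$events$codon_index[1])
  tab <- table(factor(picks, levels = 2:11))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-6)
})

test_that("identity sweep is monotone and all-silent ratios stay at 100", {
  set.seed(37)
  genes <- generate_gene_set(10, c(60, 120))
  tab <- sweep_identity(genes, c(0, 10, 20), list(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  silent <- tab[tab$ratio == "1:0:0:0", ]
  expect_true(all(silent$mean_aa_identity == 100))
  expect_equal(silent$mean_nt_identity, 100 - silent$level, tolerance = 1e-9)
  c4 <- tab[tab$ratio == "0:0:0:1", ]
  expect_true(all(diff(c4$mean_aa_identity) <= 0))
  expect_true(all(tab$mean_aa_identity[tab$level == 0] == 100))
})
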