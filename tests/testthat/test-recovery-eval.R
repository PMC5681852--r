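make_hit <- function(query_id, subject_id, identity = 100, qlen = 100,
                     q_start = 1, q_end = qlen, s_start = 1, s_end = qlen,
                     bit_score = 2 * qlen) {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = identity, alignment_length = q_end - q_start + 1,
             mismatches = 0L, gap_opens = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, e_value = 0,
             bit_score = bit_score, stringsAsFactors = FALSE)
}

test_that("tabular hit files parse with canonical columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tc1\t100.00\t300\t0\t0\t1\t300\t501\t800\t0.0\t555",
               "g2\tc2\t98.90\t300\t3\t0\t1\t300\t800\t501\t0.0\t520"),
             path)
  hits <- read_hit_table(path)
  expect_identical(nrow(hits), 2L)
  expect_identical(names(hits)[1:2], c("query_id", "subject_id"))
  expect_equal(hits$percent_identity, c(100, 98.9))
  expect_true(hits$s_start[2] > hits$s_end[2]) # minus-strand encoding kept
  file.create(path2 <- withr::local_tempfile())
  expect_identical(nrow(read_hit_table(path2)), 0L)
})

test_that("exact matching reports occurrences on both strands", {
  set.seed(81)
  gene <- generate_cds(40)
  ctx <- generate_genome(500)
  contigs <- c(fwd = paste0(ctx, gene, ctx),
               rev = paste0(ctx, revcomp(gene), ctx),
               none = generate_genome(1200))
  hits <- exact_hits(c(g = gene), contigs)
  expect_setequal(hits$subject_id, c("fwd", "rev"))
  fwd <- hits[hits$subject_id == "fwd", ]
  expect_identical(fwd$s_start, 501L)
  expect_identical(fwd$s_end, 500L + nchar(gene))
  rev <- hits[hits$subject_id == "rev", ]
  expect_true(rev$s_start > rev$s_end)
  expect_identical(rev$s_end, 501L)
})

test_that("hits filter on identity and query coverage cutoffs", {
  qlen <- c(g1 = 100)
  keep <- make_hit("g1", "c", identity = 100)
  expect_identical(nrow(filter_hits(keep, qlen)), 1L)
  low_id <- make_hit("g1", "c", identity = 98.9)
  expect_identical(nrow(filter_hits(low_id, qlen)), 0L)
  expect_identical(nrow(filter_hits(low_id, qlen, min_identity = 98)), 1L)
  partial <- make_hit("g1", "c", identity = 100, q_start = 1, q_end = 98)
  expect_identical(nrow(filter_hits(partial, qlen)), 0L)
  at_cut <- make_hit("g1", "c", identity = 99, q_start = 1, q_end = 99)
  expect_identical(nrow(filter_hits(at_cut, qlen)), 1L)
  expect_error(filter_hits(make_hit("gX", "c"), qlen), "no length known")
})

test_that("flank matching finds recipient substrings on either strand", {
  set.seed(82)
  rec <- c(chr = generate_genome(30000))
  flank <- substr(rec[["chr"]], 2001, 4000)
  expect_true(match_flank_exact(flank, rec))
  expect_true(match_flank_exact(revcomp(flank), rec))
  expect_false(match_flank_exact(generate_genome(2000), rec))
  # a foreign margin under 5% of the flank does not mask the match
  contaminated <- paste0(strrep("T", 80), flank)
  expect_true(match_flank_exact(contaminated, rec, min_fraction = 0.95))
})

test_that("recovery requires a >1 kb matching flank on at least one side", {
  set.seed(83)
  com <- make_test_community(83, n_genes = 4L)
  planted <- plant_transfers(com$genes, com$recipients, flank = "AC")
  ev <- planted$events
  qlen <- setNames(nchar(planted$cassettes), names(planted$cassettes))

  ctx_pass <- perfect_contigs(com$recipients, planted$cassettes, ev, 1500L)
  hits <- filter_hits(exact_hits(planted$cassettes, ctx_pass), qlen)
  rec <- assess_recovery(ev, hits, ctx_pass, com$recipients)
  expect_true(all(rec$recovered))

  ctx_short <- perfect_contigs(com$recipients, planted$cassettes, ev, 500L)
  hits <- filter_hits(exact_hits(planted$cassettes, ctx_short), qlen)
  rec <- assess_recovery(ev, hits, ctx_short, com$recipients)
  expect_false(any(rec$recovered))

  ctx_none <- perfect_contigs(com$recipients, planted$cassettes, ev, 0L)
  hits <- filter_hits(exact_hits(planted$cassettes, ctx_none), qlen)
  rec <- assess_recovery(ev, hits, ctx_none, com$recipients)
  expect_false(any(rec$recovered))
  expect_true(all(rec$left_flank_len == 0 & rec$right_flank_len == 0))

  # genes with no qualifying hit are simply not recovered
  rec <- assess_recovery(ev, hits[0, ], ctx_pass, com$recipients)
  expect_false(any(rec$recovered))
  expect_true(all(is.na(rec$contig_id)))
})

test_that("one qualifying side suffices; 1000 bp flanks do not qualify", {
  set.seed(84)
  rec <- list(r1 = c(chr = generate_genome(50000)))
  gene <- generate_cds(60)
  ev <- data.frame(recipient_id = "r1", seq_id = "chr",
                   break_position = 20000L, gene_id = "g",
                   flank_length = 0L, cassette_length = nchar(gene),
                   stringsAsFactors = FALSE)
  chr <- rec$r1[["chr"]]
  left1500 <- substr(chr, 18501, 20000)
  right1000 <- substr(chr, 20001, 21000)
  contigs <- c(contig_g = paste0(left1500, gene, right1000))
  hits <- exact_hits(c(g = gene), contigs)
  out <- assess_recovery(ev, hits, contigs, rec)
  expect_true(out$recovered)
  expect_identical(out$left_flank_len, 1500L)
  expect_false(isTRUE(out$right_matches)) # 1000 is not > 1000, never tested

  contigs2 <- c(contig_g = paste0(substr(chr, 19001, 20000), gene, right1000))
  out2 <- assess_recovery(ev, exact_hits(c(g = gene), contigs2), contigs2, rec)
  expect_false(out2$recovered) # both flanks exactly 1000: strict cutoff

  contigs3 <- c(contig_g = paste0(substr(chr, 18999, 20000), gene, right1000))
  out3 <- assess_recovery(ev, exact_hits(c(g = gene), contigs3), contigs3, rec)
  expect_true(out3$recovered) # 1002 > 1000 qualifies
})

test_that("a >1 kb flank from the wrong genome does not count", {
  set.seed(85)
  rec <- list(r1 = c(chr = generate_genome(50000)))
  gene <- generate_cds(60)
  ev <- data.frame(recipient_id = "r1", seq_id = "chr",
                   break_position = 20000L, gene_id = "g",
                   flank_length = 0L, cassette_length = nchar(gene),
                   stringsAsFactors = FALSE)
  foreign <- generate_genome(1500)
  contigs <- c(contig_g = paste0(foreign, gene, foreign))
  out <- assess_recovery(ev, exact_hits(c(g = gene), contigs), contigs, rec)
  expect_false(out$recovered)
  expect_false(out$left_matches)
})

test_that("recovered counts are monotone in the identity and coverage cutoffs", {
  qlen <- c(g1 = 100, g2 = 100, g3 = 100, g4 = 100)
  hits <- rbind(
    make_hit("g1", "c1", identity = 100),
    make_hit("g2", "c2", identity = 99.2),
    make_hit("g3", "c3", identity = 98.7),
    make_hit("g4", "c4", identity = 100, q_start = 1, q_end = 98)
  )
  counts <- vapply(c(98, 98.5, 99, 99.5, 100), function(cut) {
    nrow(filter_hits(hits, qlen, min_identity = cut, min_coverage = cut))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 4)
  expect_identical(counts[3], 2)
})

test_that("summaries count per recipient and overall", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    recipient_id = c("r1", "r1", "r2"),
                    recovered = c(TRUE, FALSE, TRUE))
  s <- summarize_recovery(rec)
  expect_identical(s$recovered[s$recipient_id == "r1"], 1L)
  expect_identical(s$recovered[s$recipient_id == "overall"], 2L)
  expect_identical(s$total[s$recipient_id == "overall"], 3L)
})
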