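test_that("translation uses cds hints, six-frame ORFs, and flags failures", {
  tr <- translate_candidates(
    data.frame(id = "a", nt_seq = "ATGAAATGA", cds_start = 1, cds_end = 9))
  expect_equal(tr$protein, "MK")
  expect_equal(tr$status, "translated")

  # no hint: longest ORF across six frames, trailing stop removed
  tr <- translate_candidates(data.frame(id = "b", nt_seq = "TTATGGCCTAAT"),
                             min_orf_aa = 2)
  expect_equal(tr$protein, "MA")
  expect_equal(tr$cds_seq, "ATGGCCTAA")

  # reverse-strand ORF is found
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGCCGCTTAA")))
  tr <- translate_candidates(data.frame(id = "c", nt_seq = rc), min_orf_aa = 2)
  expect_equal(tr$protein, "MAA")

  # no start codon long enough -> untranslatable, excluded downstream
  tr <- translate_candidates(data.frame(id = "d", nt_seq = "AAAAAA"),
                             min_orf_aa = 5)
  expect_equal(tr$status, "untranslatable")

  # in-frame ambiguity becomes X
  tr <- translate_candidates(
    data.frame(id = "e", nt_seq = "ATGANATGA", cds_start = 1, cds_end = 9))
  expect_equal(tr$protein, "MX")

  expect_error(translate_candidates(
    data.frame(id = "f", nt_seq = "ATGAAA", cds_start = 1, cds_end = 5)),
    "cds hint")
  expect_error(translate_candidates(
    data.frame(id = c("x", "x"), nt_seq = c("ATG", "ATG"))), "duplicate")
  expect_error(translate_candidates(
    data.frame(id = "g", nt_seq = "ATGQQQ")), "non-nucleotide")
})

test_that("family assignment picks the best panel family above min identity", {
  base <- random_cds(60, seed = 101)
  prot <- translate_candidates(data.frame(id = "p", nt_seq = base))$protein
  other <- translate_candidates(
    data.frame(id = "q", nt_seq = random_cds(60, seed = 999)))$protein
  panel <- data.frame(family = c("defensin", "attacin"),
                      protein = c(prot, other))
  expect_identical(assign_family(prot, panel), "defensin")

  # protein engineered ~80% identical to the attacin entry: oracle is a
  # direct positional identity computation
  v <- strsplit(other, "")[[1]]
  idx <- seq(1, length(v), by = 5)
  v[idx] <- ifelse(v[idx] == "A", "G", "A")
  mut <- paste(v, collapse = "")
  expect_gt(positional_identity(mut, other), 0.75)
  expect_lt(positional_identity(mut, prot), 0.4)
  expect_identical(assign_family(mut, panel), "attacin")

  # nothing reaches min_identity -> unassigned
  expect_true(is.na(assign_family(prot, panel, min_identity = 1.01)))
  expect_error(assign_family("", panel), "empty")
})

test_that("coverage filter removes members below half the coding region", {
  base <- random_cds(80, seed = 11)
  full <- translate_candidates(data.frame(id = "full", nt_seq = base))$protein
  n <- nchar(full)
  frag40 <- substr(full, 1, floor(0.4 * n))
  frag50 <- substr(full, 1, ceiling(0.5 * n))
  res <- coverage_filter(c(full = full, frag40 = frag40, frag50 = frag50))
  expect_true(res$retained[res$id == "full"])
  expect_equal(res$coverage[res$id == "full"], 1)
  expect_false(res$retained[res$id == "frag40"])
  expect_lt(res$coverage[res$id == "frag40"], 0.5)
  # at the boundary the member is retained: the rule removes strictly
  # below one half
  expect_true(res$retained[res$id == "frag50"])
  # single member families are trivially retained
  one <- coverage_filter(c(solo = full))
  expect_true(one$retained)
})

test_that("difference counting matches direct codon comparison", {
  expect_equal(count_differences("ATGAAA", "ATGAAA")[1:3],
               list(nt_total = 0L, aa_changing = 0L, aa_diffs = 0L))
  # synonymous third-position change: AAA and AAG both encode Lys
  expect_equal(count_differences("ATGAAA", "ATGAAG")[1:3],
               list(nt_total = 1L, aa_changing = 0L, aa_diffs = 0L))
  # nonsynonymous first-position change: Lys vs Glu
  expect_equal(count_differences("ATGAAA", "ATGGAA")[1:3],
               list(nt_total = 1L, aa_changing = 1L, aa_diffs = 1L))
})

test_that("difference counting is symmetric and handles indels via gap columns", {
  a <- random_cds(40, seed = 5)
  # delete one internal codon from b
  b <- paste0(substr(a, 1, 30), substr(a, 34, nchar(a)))
  d_ab <- count_differences(a, b)
  d_ba <- count_differences(b, a)
  expect_equal(d_ab[1:3], d_ba[1:3])
  expect_equal(d_ab$gap_columns, 1L)
  # a codon-deletion-only variant carries no substitution counts, so the
  # redundancy rule collapses it
  expect_equal(d_ab$aa_diffs, 0L)
  expect_identical(adjudicate_pair(d_ab), "same_gene")
})

test_that("adjudication applies the redundancy and nucleotide-excess rules", {
  # zero or one amino-acid difference is redundant/allelic
  expect_identical(adjudicate_pair(list(nt_total = 3, aa_changing = 1, aa_diffs = 1)),
                   "same_gene")
  expect_identical(adjudicate_pair(list(nt_total = 0, aa_changing = 0, aa_diffs = 0)),
                   "same_gene")
  # few aa differences: distinct genes only when synonymous differences
  # exist (total nt differences exceed the aa-changing ones) -- the
  # coleoptericin-style two-aa-difference case
  expect_identical(adjudicate_pair(list(nt_total = 5, aa_changing = 2, aa_diffs = 2)),
                   "distinct_genes")
  expect_identical(adjudicate_pair(list(nt_total = 2, aa_changing = 2, aa_diffs = 2)),
                   "same_gene")
  # beyond the few-aa threshold genes always separate
  expect_identical(adjudicate_pair(list(nt_total = 6, aa_changing = 6, aa_diffs = 6)),
                   "distinct_genes")
  expect_identical(adjudicate_pair(list(nt_total = 6, aa_changing = 6, aa_diffs = 6),
                                   few_aa_threshold = 6),
                   "same_gene")
})

test_that("clustering is single linkage with logged conflicts and tie-broken representatives", {
  ids <- c("A", "B", "C")
  v <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
                  verdict = c("same_gene", "same_gene", "distinct_genes"))
  cl <- cluster_candidates(ids, c(300, 300, 300), v)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$members, "A;B;C")
  expect_equal(nrow(cl$conflicts), 1L)

  # no edges -> singletons
  v0 <- data.frame(a = character(0), b = character(0), verdict = character(0))
  cl <- cluster_candidates(c("w", "x", "y", "z"), rep(10, 4), v0)
  expect_equal(nrow(cl$clusters), 4L)
  expect_equal(sort(cl$clusters$representative), c("w", "x", "y", "z"))

  # representative: longest member, ties by smallest id
  v1 <- data.frame(a = "tx2", b = "tx1", verdict = "same_gene")
  cl <- cluster_candidates(c("tx2", "tx1"), c(300, 300), v1)
  expect_equal(cl$clusters$representative, "tx1")
})

test_that("curation conserves transcripts across terminal statuses", {
  spec <- family_sim_spec(n_genes = 2, alleles_per_gene = 2,
                          base_length_nt = 240, syn_subs_per_allele = 2,
                          nonsyn_subs_per_allele = 1, gene_syn_subs = 2,
                          gene_nonsyn_subs = 3, fragment_fraction = 0.25,
                          family = "def", seed = 21)
  fam <- simulate_family(spec)
  panel <- data.frame(family = "def", protein = translate_candidates(
    data.frame(id = "r", nt_seq = unname(fam$sequences[1])))$protein)
  # unrelated junk transcript exercises the unassigned path
  tx <- data.frame(id = c(names(fam$sequences), "junk"),
                   nt_seq = c(unname(fam$sequences), random_cds(80, seed = 77)))
  cur <- curate_candidates(tx, panel, min_orf_aa = 15)
  terminal <- c("untranslatable", "unassigned", "removed_low_coverage",
                "collapsed", "retained")
  expect_true(all(cur$transcripts$status %in% terminal))
  expect_equal(nrow(cur$transcripts), nrow(tx))
  # every filter decision is logged exactly once per transcript
  expect_equal(sort(unique(cur$log$id[cur$log$action != "conflict"])),
               sort(tx$id))
  # retained representatives are exactly one per gene cluster
  expect_equal(sum(cur$transcripts$status == "retained"), nrow(cur$genes))
  counts <- family_gene_counts(cur)
  expect_equal(attr(counts, "total"), sum(counts$n_genes))
})
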