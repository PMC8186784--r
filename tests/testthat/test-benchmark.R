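test_that("decoy allocation splits 99 as 25/25/25/24 with the deficit on 11", {
  alloc <- hlapresent:::decoy_length_allocation(99L)
  expect_identical(unname(alloc), c(25L, 25L, 25L, 24L))
  expect_identical(names(alloc), as.character(8:11))
  expect_identical(unname(hlapresent:::decoy_length_allocation(4L)),
                   rep(1L, 4L))
  expect_identical(sum(hlapresent:::decoy_length_allocation(101L)), 101L)
})

test_that("generate_decoys draws 99 per hit with balanced lengths", {
  prot <- generate_proteome(n_proteins = 1L, length_range = c(500L, 500L),
                            hits_per_protein = 1L, seed = 60L)
  bench <- generate_decoys(prot$hits, prot$proteome, decoys_per_hit = 99L,
                           seed = 61L)
  decoys <- bench[bench$label == 0L, ]
  expect_identical(nrow(decoys), 99L)
  expect_identical(as.integer(table(decoys$length)[as.character(8:11)]),
                   c(25L, 25L, 25L, 24L))
  expect_identical(sum(bench$label == 1L), 1L)
  # provenance: every decoy really is the recorded substring
  for (i in seq_len(nrow(decoys)))
    expect_identical(substr(prot$proteome[[decoys$source_protein[i]]],
                            decoys$offset[i],
                            decoys$offset[i] + decoys$length[i] - 1L),
                     decoys$peptide[i])
  # decoys never equal a hit
  expect_false(any(decoys$peptide %in% prot$hits$peptide))
  # minimal balanced case: one decoy of each length
  b4 <- generate_decoys(prot$hits, prot$proteome, decoys_per_hit = 4L,
                        seed = 62L)
  expect_identical(sort(b4$length[b4$label == 0L]), 8:11)
})

test_that("training-set members and duplicates are filtered; errors surface", {
  prot <- generate_proteome(n_proteins = 3L, length_range = c(300L, 400L),
                            hits_per_protein = 2L, seed = 63L)
  first <- generate_decoys(prot$hits, prot$proteome, seed = 64L)
  leak <- first$peptide[first$label == 0L][1:10]
  second <- generate_decoys(prot$hits, prot$proteome,
                            training_peptides = leak, seed = 64L)
  expect_false(any(leak %in% second$peptide))
  expect_false(any(duplicated(second$peptide)))
  # decoy:hit ratio after filtering is at most decoys_per_hit
  expect_lte(sum(second$label == 0L), 99L * nrow(prot$hits))

  bad_hits <- data.frame(peptide = "ACDEFGHIK", source_protein = "NOPE")
  expect_error(generate_decoys(bad_hits, prot$proteome),
               class = "hlapresent_lookup_error")
  expect_error(generate_decoys(prot$hits, prot$proteome, decoys_per_hit = 3L),
               class = "hlapresent_size_error")
})

test_that("a short source protein restricts decoy lengths with a warning", {
  proteome <- c(SHORT = paste(rep("ACDEFGHIKL", 1), collapse = ""))  # 10 aa
  hits <- data.frame(peptide = "ACDEFGHI", source_protein = "SHORT")
  w <- capture_warnings(
    bench <- generate_decoys(hits, proteome, decoys_per_hit = 8L, seed = 1L))
  expect_true(any(grepl("shorter than 11", w)))
  expect_true(any(grepl("taking all", w)))
  expect_true(all(bench$length[bench$label == 0L] %in% 8:10))
})

test_that("the three metrics match their formulas and a brute-force recount", {
  m <- compute_metrics(list(tp = 40L, fp = 60L, tn = 9840L, fn = 60L))
  expect_equal(m$sensitivity, 0.40)
  expect_equal(m$specificity, 9840 / 9900)
  expect_equal(m$ppv, 0.40)

  deg <- compute_metrics(list(tp = 0L, fp = 0L, tn = 100L, fn = 0L))
  expect_true(is.na(deg$ppv))
  expect_true(is.na(deg$sensitivity))
  expect_equal(deg$specificity, 1.0)

  set.seed(301)
  for (rep in 1:5) {
    truth <- rbinom(200L, 1L, 0.3)
    calls <- rbinom(200L, 1L, 0.4)
    got <- compute_metrics(confusion_counts(truth, calls))
    want <- brute_force_metrics(truth, calls)
    expect_equal(got, want)
    # metric identities
    cc <- confusion_counts(truth, calls)
    expect_equal(got$sensitivity + cc$fn / (cc$tp + cc$fn), 1)
    expect_equal(got$specificity + cc$fp / (cc$tn + cc$fp), 1)
  }
})

test_that("rank thresholding returns exactly the peptides at or below cutoff", {
  tab <- data.frame(peptide = sprintf("p%04d", 1:1000),
                    percentile_rank = seq(0.1, 100, by = 0.1))
  expect_identical(length(call_binders_by_rank(tab, 2.0)), 20L)
  expect_identical(length(call_binders_by_rank(tab, 100)), 1000L)
  expect_identical(call_binders_by_rank(tab[0, ]), character(0))
  bad <- data.frame(peptide = "p", percentile_rank = 0)
  expect_error(call_binders_by_rank(bad), class = "hlapresent_format_error")
  expect_error(call_binders_by_rank(data.frame(peptide = "p",
                                               percentile_rank = 101)),
               class = "hlapresent_format_error")
})

test_that("intersection combination is a monotone subset operation", {
  expect_identical(sort(combine_predictions(c("p1", "p2", "p3"),
                                            c("p2", "p3", "p4"))),
                   c("p2", "p3"))
  expect_identical(combine_predictions(c("p1"), character()), character())
  set.seed(55)
  universe <- sprintf("q%03d", 1:200)
  for (rep in 1:10) {
    a <- sample(universe, 60); b <- sample(universe, 80)
    comb <- combine_predictions(a, b)
    expect_true(all(comb %in% a) && all(comb %in% b))
    expect_lte(length(comb), min(length(a), length(b)))
    # monotone: enlarging either input never shrinks the output
    expect_gte(length(combine_predictions(union(a, sample(universe, 20)), b)),
               length(comb))
  }
})

test_that("combining raises PPV on a benchmark where FP sets barely overlap", {
  # constructed toy benchmark: 20 hits, 180 decoys
  hits <- sprintf("hit%02d", 1:20)
  decoys <- sprintf("dec%03d", 1:180)
  bench <- data.frame(peptide = c(hits, decoys),
                      label = rep(c(1L, 0L), c(20L, 180L)))
  # both predictors find 16 of the hits; their FP sets overlap in 2 decoys
  calls_a <- c(hits[1:16], decoys[1:20])
  calls_b <- c(hits[3:18], decoys[19:38])
  ppv_a <- evaluate_calls(bench, calls_a)$ppv
  ppv_b <- evaluate_calls(bench, calls_b)$ppv
  comb <- combine_predictions(calls_a, calls_b)
  ppv_c <- evaluate_calls(bench, comb)$ppv
  expect_gte(ppv_c, max(ppv_a, ppv_b))
})

test_that("a perfect oracle scores 1.0 on all three metrics", {
  prot <- generate_proteome(seed = 70L)
  bench <- generate_decoys(prot$hits, prot$proteome, seed = 71L)
  oracle_calls <- bench$peptide[bench$label == 1L]
  res <- evaluate_calls(bench, oracle_calls)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$ppv, 1)
})

test_that("false-positive overlap: Jaccard default, overlap-over-smaller flag", {
  expect_equal(false_positive_overlap(c("1", "2", "3", "4"),
                                      c("3", "4", "5", "6")), 2 / 6)
  expect_equal(false_positive_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(false_positive_overlap(c("a"), c("b")), 0)
  expect_true(is.na(false_positive_overlap(character(), character())))
  expect_equal(false_positive_overlap(c("1", "2", "3", "4"), c("3", "4"),
                                      method = "overlap"), 1)
})
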