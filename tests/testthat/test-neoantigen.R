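test_that("context extraction centers the mutant residue with 8-residue flanks", {
  set.seed(600)
  prot <- paste(sample(aa_alphabet(), 500L, replace = TRUE), collapse = "")
  proteome <- c(PROT1 = prot)
  wt <- substr(prot, 300, 300)
  mut <- setdiff(aa_alphabet(), wt)[1]
  ctx <- extract_context(list(protein_id = "PROT1", position = 300L,
                              wt_aa = wt, mut_aa = mut), proteome)
  expect_identical(nchar(ctx$context), 17L)
  expect_identical(ctx$mutation_index, 9L)
  expect_identical(substr(ctx$context, 9, 9), mut)
  # flanks are the wild-type sequence
  expect_identical(substr(ctx$context, 1, 8), substr(prot, 292, 299))
  expect_identical(substr(ctx$context, 10, 17), substr(prot, 301, 308))

  # mutation at position 1: no upstream flank
  wt1 <- substr(prot, 1, 1)
  ctx1 <- extract_context(list(protein_id = "PROT1", position = 1L,
                               wt_aa = wt1, mut_aa = setdiff(aa_alphabet(), wt1)[1]),
                          proteome)
  expect_identical(nchar(ctx1$context), 9L)
  expect_identical(ctx1$mutation_index, 1L)

  # wt mismatch and unknown protein are errors
  badwt <- setdiff(aa_alphabet(), c(wt, mut))[1]
  expect_error(extract_context(list(protein_id = "PROT1", position = 300L,
                                    wt_aa = badwt, mut_aa = mut), proteome),
               class = "hlapresent_reference_mismatch_error")
  expect_error(extract_context(list(protein_id = "NOPE", position = 1L,
                                    wt_aa = "A", mut_aa = "C"), proteome),
               class = "hlapresent_lookup_error")
})

test_that("a full 17-mer context yields 9 nine-mers and 38 candidates", {
  set.seed(601)
  ctx <- paste(sample(aa_alphabet(), 17L, replace = TRUE), collapse = "")
  w9 <- sliding_windows(ctx, 9L, lengths = 9L)
  expect_identical(nrow(w9), 9L)
  # first window ends on the mutation, last starts on it
  expect_identical(w9$mutation_offset[1], 9L)
  expect_identical(w9$mutation_offset[9], 1L)
  # honest enumeration within a 17-mer: 10/11-mers are clipped by the
  # context itself (8 + 9 + 8 + 7)
  all4 <- sliding_windows(ctx, 9L)
  expect_identical(nrow(all4), 32L)
  expect_identical(as.integer(table(all4$length)), c(8L, 9L, 8L, 7L))
  for (L in 8:11)
    expect_identical(sort(all4$sequence[all4$length == L]),
                     sort(brute_force_windows(ctx, 9L, L)))
  # every candidate contains the mutant residue at its recorded offset
  mut_char <- substr(ctx, 9, 9)
  expect_true(all(substr(all4$sequence, all4$mutation_offset,
                         all4$mutation_offset) == mut_char))
})

test_that("length-adaptive contexts give exactly L windows per length (38 total)", {
  prot <- generate_proteome(n_proteins = 1L, length_range = c(300L, 300L),
                            seed = 610L)
  pos <- 150L
  wt <- substr(prot$proteome[[1]], pos, pos)
  muts <- data.frame(gene = "G1", protein_id = names(prot$proteome)[1],
                     position = pos, wt_aa = wt,
                     mut_aa = setdiff(aa_alphabet(), wt)[1])
  cands <- generate_candidates(muts, prot$proteome)
  expect_identical(nrow(cands), 38L)
  expect_identical(as.integer(table(cands$length)), 8:11)
  # a near-terminus mutation emits only the windows that fit
  muts2 <- muts
  muts2$position <- 2L
  muts2$wt_aa <- substr(prot$proteome[[1]], 2L, 2L)
  muts2$mut_aa <- setdiff(aa_alphabet(), muts2$wt_aa)[1]
  c2 <- generate_candidates(muts2, prot$proteome)
  expect_identical(as.integer(table(c2$length)), c(2L, 2L, 2L, 2L))
})

test_that("clipped contexts match the brute-force enumerator on 1000 cases", {
  set.seed(602)
  for (case in 1:1000) {
    C <- sample(8:17, 1L)
    ctx <- paste(sample(aa_alphabet(), C, replace = TRUE), collapse = "")
    m <- sample.int(C, 1L)
    L <- sample(8:11, 1L)
    got <- sliding_windows(ctx, m, lengths = L)
    want <- brute_force_windows(ctx, m, L)   # enumerated by ascending start,
    expect_identical(got$sequence, want)     # i.e. mutation-last first
  }
  # mutation at context start, L = 9: exactly one window
  ctx <- paste(sample(aa_alphabet(), 17L, replace = TRUE), collapse = "")
  expect_identical(nrow(sliding_windows(ctx, 1L, lengths = 9L)), 1L)
  expect_error(sliding_windows(ctx, 18L), class = "hlapresent_lookup_error")
})

test_that("batch candidate generation validates wt, skips bad rows, never emits wild type", {
  prot <- generate_proteome(n_proteins = 5L, seed = 603L)
  muts <- generate_mutation_table(prot$proteome, n_mutations = 15L, seed = 604L)
  cands <- generate_candidates(muts, prot$proteome)
  expect_identical(nrow(attr(cands, "failed")), 0L)
  expect_gt(nrow(cands), 0L)
  for (i in seq_len(nrow(cands))) {
    mut <- muts[cands$mutation_id[i], ]
    # mutant residue sits at the recorded offset
    expect_identical(substr(cands$sequence[i], cands$mutation_offset[i],
                            cands$mutation_offset[i]), mut$mut_aa)
    # differs from the wild-type subsequence at exactly the mutation offset
    wt_start <- mut$position - (cands$mutation_offset[i] - 1L)
    wt_seq <- substr(prot$proteome[[mut$protein_id]], wt_start,
                     wt_start + cands$length[i] - 1L)
    diff <- which(strsplit(cands$sequence[i], "")[[1]] !=
                  strsplit(wt_seq, "")[[1]])
    expect_identical(diff, as.integer(cands$mutation_offset[i]))
  }

  # a deliberately corrupted row is reported and skipped
  bad <- muts
  bad$wt_aa[3] <- setdiff(aa_alphabet(), c(bad$wt_aa[3], bad$mut_aa[3]))[1]
  suppressMessages(cands2 <- generate_candidates(bad, prot$proteome))
  expect_identical(attr(cands2, "failed")$row, 3L)
  expect_false(3L %in% cands2$mutation_id)
})

test_that("candidate scoring combines calls by intersection over the panel", {
  prot <- generate_proteome(n_proteins = 1L, length_range = c(300L, 300L),
                            seed = 605L)
  wt <- substr(prot$proteome[[1]], 150L, 150L)
  muts <- data.frame(gene = "G1", protein_id = names(prot$proteome)[1],
                     position = 150L, wt_aa = wt,
                     mut_aa = setdiff(aa_alphabet(), wt)[1])
  cands <- generate_candidates(muts, prot$proteome)   # 38 candidates
  alleles <- sprintf("A*%02d:01", 1:20)
  saturating <- function(allele, peptides) rep(1L, length(peptides))
  res <- score_candidates(cands, saturating, alleles = alleles)
  expect_identical(nrow(res), 20L * 38L)
  expect_true(all(res$call_combined == 1L))
  expect_identical(attr(res, "neoantigen_mutations"), 1L)

  # empty external call set with combining enabled -> zero combined positives
  res0 <- score_candidates(cands, saturating, alleles = alleles,
                           external_calls = character())
  expect_identical(sum(res0$call_combined), 0L)
  expect_identical(attr(res0, "neoantigen_mutations"), integer(0))

  # a predictor demanding L at P2 calls exactly those candidates
  needs_L2 <- function(allele, peptides)
    as.integer(substr(peptides, 2, 2) == "L")
  resL <- score_candidates(cands, needs_L2, alleles = "A*02:01")
  expect_identical(resL$call_model,
                   as.integer(substr(cands$sequence, 2, 2) == "L"))
})

test_that("cohort frequencies reproduce the validated shared-neoantigen table", {
  # printed count pairs -> printed percentages
  pairs <- list(c(162, 9079, 1.78), c(20, 228, 8.77), c(6, 155, 3.87),
                c(2, 129, 1.55), c(3, 228, 1.32), c(6, 138, 4.35),
                c(508, 9079, 5.60), c(4, 34, 11.76))
  for (p in pairs)
    expect_equal(cohort_frequency(p[1], p[2]), p[3])
  expect_equal(cohort_frequency(0, 100), 0)
  expect_true(is.na(cohort_frequency(NA, 100)))
  expect_identical(neoantigen_key("A*03:01", "VVGAGDVGK"),
                   "HLA-A*03:01_VVGAGDVGK")
  expect_identical(neoantigen_key("HLA-A*03:01", "VVGAGDVGK"),
                   "HLA-A*03:01_VVGAGDVGK")
})
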