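# Shared fixtures and independent oracles. Oracles are deliberately
# brute-force and never call the code paths they check.

random_peptides <- function(n, lengths = 8:11, seed = 1L) {
  set.seed(seed)
  lens <- if (length(lengths) == 1L) rep(lengths, n)
    else sample(lengths, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = ""),
    character(1))
}

# oracle: every L-substring of `context` that covers position m, by
# explicit enumeration over all starts
brute_force_windows <- function(context, m, L) {
  C <- nchar(context)
  out <- character(0)
  for (s in seq_len(max(C - L + 1L, 0L))) {
    e <- s + L - 1L
    if (s <= m && m <= e) out <- c(out, substr(context, s, e))
  }
  out
}

# oracle: per-record recount of the three benchmark metrics
brute_force_metrics <- function(truth, calls) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && calls[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && calls[i] == 1) fp <- fp + 1
    if (truth[i] == 0 && calls[i] == 0) tn <- tn + 1
    if (truth[i] == 1 && calls[i] == 0) fn <- fn + 1
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# a small labeled table with both classes, unique sequences
toy_labeled_table <- function(n_pos = 50L, n_neg = 200L, seed = 1L) {
  peps <- unique(random_peptides(2L * (n_pos + n_neg), seed = seed))
  peps <- peps[seq_len(n_pos + n_neg)]
  data.frame(peptide = peps,
             label = rep(c(1L, 0L), c(n_pos, n_neg)),
             stringsAsFactors = FALSE)
}
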