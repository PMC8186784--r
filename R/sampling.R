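# Class rebalancing (under-sample decoys, over-sample hits) and stratified
# train/validation/test splitting. MS elution corpora are severely
# imbalanced -- globally ~39 decoys per hit, up to 72:1 for single alleles
# -- so training sets are rebalanced before fitting; evaluation partitions
# keep their natural balance.

#' Construct and validate a per-allele sampling plan
#'
#' @param allele allele name (gene*group:protein).
#' @param under fraction in (0, 1] of 0-labeled records to keep.
#' @param over integer >= 1; each 1-labeled record appears this many times.
#' @return list with class `sampling_plan`.
#' @export
sampling_plan <- function(allele, under, over) {
  allele <- validate_allele(allele)
  if (!is.numeric(under) || length(under) != 1L || is.na(under) ||
      under <= 0 || under > 1)
    cond_stop("under-sampling fraction must lie in (0, 1]", "hlapresent_plan_error")
  if (!is.numeric(over) || length(over) != 1L || is.na(over) ||
      over < 1 || over != as.integer(over))
    cond_stop("over-sampling factor must be an integer >= 1", "hlapresent_plan_error")
  structure(list(allele = allele, under = under, over = as.integer(over)),
            class = "sampling_plan")
}

#' Rebalance a labeled peptide table
#'
#' Under-sampling removes 0-labeled rows uniformly at random without
#' replacement, keeping `floor(under * n_negatives)`; over-sampling
#' duplicates every 1-labeled row so each appears `over` times. No new
#' sequences are ever fabricated. Duplicated positives carry a `.replica`
#' index so later partitioning can keep all replicas of a record together.
#'
#' @param dataset data.frame with `peptide` and `label` columns (both
#'   classes present).
#' @param plan a [sampling_plan()], or a list with `under` and `over`.
#' @param seed integer seed; the same seed reproduces the same selection.
#' @return rebalanced data.frame; class counts are reported via `message()`.
#' @examples
#' \dontrun{
#' plan <- sampling_plan("A*02:07", under = 0.7, over = 5)
#' balanced <- rebalance(peptides, plan, seed = 1)
#' }
#' @export
rebalance <- function(dataset, plan, seed = 1L) {
  if (!all(c("peptide", "label") %in% names(dataset)))
    cond_stop("dataset needs 'peptide' and 'label' columns",
              "hlapresent_format_error")
  pos <- which(dataset$label == 1L)
  neg <- which(dataset$label == 0L)
  if (!length(pos) || !length(neg))
    cond_stop("rebalance needs both classes present",
              "hlapresent_degenerate_class_error")
  n_keep <- floor(plan$under * length(neg))
  rng <- local_rng(seed)
  keep_neg <- sort(sample_vec(neg, n_keep))
  rng()
  out_neg <- dataset[keep_neg, , drop = FALSE]
  out_neg$.replica <- 1L
  reps <- rep(pos, each = plan$over)
  out_pos <- dataset[reps, , drop = FALSE]
  out_pos$.replica <- rep(seq_len(plan$over), times = length(pos))
  out <- rbind(out_pos, out_neg)
  rownames(out) <- NULL
  message(sprintf(
    "rebalance: %d positives (x%d) and %d of %d negatives (fraction %.2f) -> %.3f positive fraction",
    length(pos), plan$over, n_keep, length(neg), plan$under,
    nrow(out_pos) / nrow(out)))
  out
}

# Largest-remainder allocation of `total` draws across strata of sizes `n`,
# guaranteeing per-stratum counts within 1 of exact proportionality.
proportional_allocation <- function(n, total) {
  if (total == 0L) return(rep(0L, length(n)))
  quota <- total * n / sum(n)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    order_rem <- order(quota - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
  }
  pmin(as.integer(base), n)
}

#' Split a labeled table into train/validation/test partitions
#'
#' Stratified by label so all partitions have approximately the original
#' class balance (within one record per stratum). The test partition has
#' exactly `test_count` records; the validation partition takes
#' `round(validation_fraction * remainder)`; training gets the rest. When a
#' `.replica` column is present (from [rebalance()]), all replicas of one
#' source record land in the same partition.
#'
#' @param dataset labeled data.frame.
#' @param test_count exact test-partition size.
#' @param validation_fraction fraction in [0, 1) of the non-test remainder
#'   held out for early stopping; default 0.1.
#' @param seed integer seed.
#' @return list of data.frames: `train`, `validation`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(dataset, test_count, validation_fraction = 0.1,
                          seed = 1L) {
  n <- nrow(dataset)
  if (test_count >= n)
    cond_stop(sprintf("test_count (%d) must be smaller than the dataset (%d)",
                      test_count, n), "hlapresent_size_error")
  if (validation_fraction < 0 || validation_fraction >= 1)
    cond_stop("validation_fraction must lie in [0, 1)", "hlapresent_size_error")
  has_replica <- ".replica" %in% names(dataset)
  # partition at the level of source records so replicas travel together
  if (has_replica) {
    key <- paste(dataset$peptide, dataset$label, sep = "\r")
  } else {
    key <- as.character(seq_len(n))
  }
  first_row <- !duplicated(key)
  units <- data.frame(key = key[first_row], label = dataset$label[first_row],
                      stringsAsFactors = FALSE)
  rng <- local_rng(seed)
  assignment <- rep(NA_character_, nrow(units))
  labels <- sort(unique(units$label))
  sizes <- vapply(labels, function(l) sum(units$label == l), integer(1))
  test_alloc <- proportional_allocation(sizes, as.integer(test_count))
  for (j in seq_along(labels)) {
    idx <- which(units$label == labels[j])
    idx <- sample_vec(idx)
    n_test <- test_alloc[j]
    rest <- idx[seq_len(length(idx) - n_test)]
    assignment[idx[seq_len(n_test) + length(rest)]] <- "test"
    n_val <- round(validation_fraction * length(rest))
    if (n_val > 0) assignment[rest[seq_len(n_val)]] <- "validation"
    assignment[rest[assignment[rest] %in% NA]] <- "train"
  }
  rng()
  part <- assignment[match(key, units$key)]
  out <- list(train = dataset[part == "train", , drop = FALSE],
              validation = dataset[part == "validation", , drop = FALSE],
              test = dataset[part == "test", , drop = FALSE])
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

# sample() treats a length-1 numeric as 1:n; this always samples elements
sample_vec <- function(x, size = length(x), replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Evaluate `expr`-style seeded sampling without clobbering the caller's RNG
# stream: returns a restore function to call when done.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
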