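# Decoy-based benchmarking: build mono-allelic hit/decoy sets from a
# reference proteome, compute sensitivity / specificity / PPV, threshold
# percentile ranks, and combine two predictors by intersection.

# Per-length decoy allocation. decoys_per_hit is split as evenly as
# possible over lengths 8-11; any remainder goes to the shorter lengths
# first, leaving the deficit on length 11 (the rarest class in eluted
# ligand data). 99 -> 25/25/25/24.
decoy_length_allocation <- function(decoys_per_hit, lengths = 8:11) {
  base <- decoys_per_hit %/% length(lengths)
  rem <- decoys_per_hit %% length(lengths)
  counts <- base + as.integer(seq_along(lengths) <= rem)
  stats::setNames(counts, lengths)
}

#' Build a hit/decoy benchmark set from a reference proteome
#'
#' For every MS-identified hit, decoy peptides are sampled uniformly
#' without replacement from the substrings (lengths 8-11) of the hit's own
#' source protein that are not themselves MS hits, `decoys_per_hit` per hit
#' with a near-equal split over the four lengths (see
#' `decoy_length_allocation`; 99 gives 25/25/25/24). Afterwards any decoy
#' whose sequence appears in the model training data, and any later
#' duplicate of a sequence already sampled (first occurrence in seeded
#' order wins), are removed. Provenance (source protein, offset, length)
#' is retained for every record.
#'
#' @param hits data.frame with columns `peptide` and `source_protein` (ids
#'   resolvable in `proteome`).
#' @param proteome named character vector (see [read_fasta()]).
#' @param training_peptides character vector of sequences used in model
#'   training; excluded from the benchmark.
#' @param decoys_per_hit decoys drawn per hit before filtering (>= 4;
#'   default 99).
#' @param seed integer seed.
#' @return data.frame `peptide,label,source_protein,offset,length` with
#'   hits labeled 1 and decoys 0; attribute `decoys_per_hit` records the
#'   pre-filter draw.
#' @export
generate_decoys <- function(hits, proteome, training_peptides = character(),
                            decoys_per_hit = 99L, seed = 1L) {
  if (!all(c("peptide", "source_protein") %in% names(hits)))
    cond_stop("hits need 'peptide' and 'source_protein' columns",
              "hlapresent_format_error")
  if (decoys_per_hit < 4L)
    cond_stop("decoys_per_hit must be at least 4 (one per length)",
              "hlapresent_size_error")
  missing <- setdiff(hits$source_protein, names(proteome))
  if (length(missing))
    cond_stop(sprintf("protein(s) absent from FASTA: %s",
                      paste(utils::head(missing, 5), collapse = ",")),
              "hlapresent_lookup_error")
  hit_seqs <- unique(hits$peptide)
  rng <- local_rng(seed)
  on.exit(rng())
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    prot_id <- hits$source_protein[i]
    prot <- proteome[[prot_id]]
    plen <- nchar(prot)
    lengths_avail <- (8:11)[8:11 <= plen]
    if (length(lengths_avail) < 4L)
      warning(sprintf("protein %s is shorter than 11 aa; decoy lengths restricted to {%s}",
                      prot_id, paste(lengths_avail, collapse = ",")))
    alloc <- decoy_length_allocation(decoys_per_hit, lengths_avail)
    picked <- list()
    for (L in lengths_avail) {
      starts <- seq_len(plen - L + 1L)
      subs <- substring(prot, starts, starts + L - 1L)
      eligible <- which(!(subs %in% hit_seqs))
      want <- alloc[[as.character(L)]]
      if (length(eligible) < want) {
        warning(sprintf("protein %s: only %d eligible %d-mers (wanted %d); taking all",
                        prot_id, length(eligible), L, want))
        sel <- eligible
      } else {
        sel <- sample_vec(eligible, want)
      }
      if (length(sel))
        picked[[as.character(L)]] <- data.frame(
          peptide = subs[sel], label = 0L, source_protein = prot_id,
          offset = sel, length = L, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, picked)
  }
  decoys <- do.call(rbind, rows)
  rownames(decoys) <- NULL
  # filter: training-set members, then sequence duplicates (first kept)
  decoys <- decoys[!(decoys$peptide %in% training_peptides), , drop = FALSE]
  decoys <- decoys[!duplicated(decoys$peptide), , drop = FALSE]
  hit_off <- if ("offset" %in% names(hits)) hits$offset else NA_integer_
  hit_rows <- data.frame(peptide = hits$peptide, label = 1L,
                         source_protein = hits$source_protein,
                         offset = hit_off, length = nchar(hits$peptide),
                         stringsAsFactors = FALSE)
  hit_rows <- hit_rows[!(hit_rows$peptide %in% training_peptides), , drop = FALSE]
  hit_rows <- hit_rows[!duplicated(hit_rows$peptide), , drop = FALSE]
  out <- rbind(hit_rows, decoys)
  rownames(out) <- NULL
  attr(out, "decoys_per_hit") <- as.integer(decoys_per_hit)
  out
}

#' Confusion counts from truth labels and binary calls
#'
#' @param truth,calls 0/1 vectors of equal length.
#' @return list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, calls) {
  truth <- as.integer(truth); calls <- as.integer(calls)
  list(tp = sum(truth == 1L & calls == 1L),
       fp = sum(truth == 0L & calls == 1L),
       tn = sum(truth == 0L & calls == 0L),
       fn = sum(truth == 1L & calls == 0L))
}

#' Sensitivity, specificity and positive predictive value
#'
#' The three benchmark metrics: sensitivity (recall) = TP / (TP + FN),
#' specificity = TN / (TN + FP), PPV (precision) = TP / (TP + FP). A zero
#' denominator yields `NA` (an explicit undefined marker), never a silent 0.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see
#'   [confusion_counts()]).
#' @return list `sensitivity`, `specificity`, `ppv`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(tp, fp, tn, fn) < 0))
      cond_stop("confusion counts must be nonnegative", "hlapresent_format_error")
    list(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      ppv         = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
}

#' Call binders from a percentile-rank table
#'
#' Mirrors the conventional rank-threshold rule: peptides whose percentile
#' rank is at most `threshold_percent` (default 2, the "top 2%" rule) are
#' binders.
#'
#' @param rank_table data.frame with `peptide` and `percentile_rank`
#'   columns (ranks in (0, 100]), or a named numeric vector of ranks.
#' @param threshold_percent rank cutoff (default 2.0).
#' @return character vector of binder peptides.
#' @export
call_binders_by_rank <- function(rank_table, threshold_percent = 2.0) {
  if (is.numeric(rank_table)) {
    ranks <- rank_table
    peptides <- names(rank_table)
  } else {
    ranks <- rank_table$percentile_rank
    peptides <- rank_table$peptide
  }
  if (!length(ranks)) return(character())
  if (any(is.na(ranks)) || any(ranks <= 0 | ranks > 100))
    cond_stop("percentile ranks must lie in (0, 100]", "hlapresent_format_error")
  peptides[ranks <= threshold_percent]
}

#' Intersect two predictors' binder calls
#'
#' The ensemble rule: only peptides called positive by both methods remain
#' positive. The output is always a subset of each input.
#'
#' @param calls_a,calls_b character vectors (binder sets over the same
#'   benchmark).
#' @return character vector, the intersection.
#' @export
combine_predictions <- function(calls_a, calls_b) intersect(calls_a, calls_b)

#' Overlap fraction of two false-positive sets
#'
#' Jaccard index |A intersect B| / |A union B| by default; overlap over the
#' smaller set (`method = "overlap"`) is available as the alternative
#' reading. Two predictors with little false-positive overlap are good
#' candidates for intersection ensembling.
#'
#' @param fp_a,fp_b character vectors over the same benchmark.
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return fraction in [0, 1]; `NA` when both sets are empty.
#' @export
false_positive_overlap <- function(fp_a, fp_b,
                                   method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  fp_a <- unique(fp_a); fp_b <- unique(fp_b)
  if (!length(fp_a) && !length(fp_b)) return(NA_real_)
  inter <- length(intersect(fp_a, fp_b))
  denom <- switch(method,
                  jaccard = length(union(fp_a, fp_b)),
                  overlap = min(length(fp_a), length(fp_b)))
  if (denom == 0) return(NA_real_)
  inter / denom
}

#' Evaluate a set of binder calls against a benchmark
#'
#' Convenience wrapper: confusion counts plus the three metrics for one
#' predictor's calls on a hit/decoy benchmark.
#'
#' @param benchmark data.frame from [generate_decoys()] (columns `peptide`,
#'   `label`).
#' @param calls character vector of peptides called binders.
#' @return list with `counts` and the three metrics.
#' @export
evaluate_calls <- function(benchmark, calls) {
  pred <- as.integer(benchmark$peptide %in% calls)
  counts <- confusion_counts(benchmark$label, pred)
  c(list(counts = counts), compute_metrics(counts))
}
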