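# Neoantigen candidate extraction: mutation-centered context windows,
# sliding-window enumeration of 8-11mer candidates, scoring against allele
# models with optional intersection ensembling, and shared-neoantigen
# cohort frequencies.

#' Extract the mutant context around a driver missense mutation
#'
#' Takes the protein substring spanning `flank` wild-type residues on each
#' side of the mutated position (a 17-mer at the default `flank = 8`),
#' substitutes the mutant residue at the center, and clips at the protein
#' termini rather than padding -- a mutation 3 residues from the N-terminus
#' yields a shorter context with the mutation at index 4.
#'
#' @param mutation list or one-row data.frame with `protein_id`, `position`
#'   (1-based), `wt_aa`, `mut_aa`.
#' @param proteome named character vector of protein sequences.
#' @param flank wild-type residues kept on each side (default 8).
#' @return list `context` (mutant string), `mutation_index` (1-based index
#'   of the mutant residue within the context).
#' @export
extract_context <- function(mutation, proteome, flank = 8L) {
  pid <- as.character(mutation$protein_id)
  if (!pid %in% names(proteome))
    cond_stop(sprintf("protein %s absent from FASTA", pid),
              "hlapresent_lookup_error")
  prot <- proteome[[pid]]
  pos <- as.integer(mutation$position)
  if (pos < 1L || pos > nchar(prot))
    cond_stop(sprintf("position %d outside protein %s (length %d)",
                      pos, pid, nchar(prot)), "hlapresent_lookup_error")
  wt <- toupper(mutation$wt_aa); mut <- toupper(mutation$mut_aa)
  if (wt == mut)
    cond_stop("wild-type and mutant residues are identical",
              "hlapresent_reference_mismatch_error")
  have <- substr(prot, pos, pos)
  if (have != wt)
    cond_stop(sprintf("reference mismatch at %s:%d (expected %s, found %s)",
                      pid, pos, wt, have),
              "hlapresent_reference_mismatch_error")
  lo <- max(1L, pos - flank)
  hi <- min(nchar(prot), pos + flank)
  context <- substr(prot, lo, hi)
  m_idx <- pos - lo + 1L
  substr(context, m_idx, m_idx) <- mut
  list(context = context, mutation_index = m_idx)
}

#' Enumerate mutation-spanning candidate peptides by sliding windows
#'
#' For each requested length L, every L-substring of the context containing
#' the mutated residue is emitted, starting with the window in which the
#' mutation is the last residue and sliding until it is the first. With a
#' full two-sided flank of 8 this yields exactly L windows per length (9
#' nine-mers, 38 candidates over lengths 8-11); clipped contexts yield only
#' the windows that fit.
#'
#' @param context mutant context string (see [extract_context()]).
#' @param mutation_index 1-based index of the mutant residue in `context`.
#' @param lengths window lengths (default 8:11).
#' @return data.frame `sequence,length,mutation_offset,start`, where
#'   `mutation_offset` locates the mutant residue within the peptide and
#'   `start` the window within the context.
#' @export
sliding_windows <- function(context, mutation_index, lengths = 8:11) {
  C <- nchar(context)
  m <- as.integer(mutation_index)
  if (m < 1L || m > C)
    cond_stop("mutation index outside the context", "hlapresent_lookup_error")
  out <- lapply(lengths, function(L) {
    s_min <- max(1L, m - L + 1L)        # mutation at the last position
    s_max <- min(m, C - L + 1L)         # mutation at the first position
    if (s_max < s_min) return(NULL)
    starts <- s_min:s_max
    data.frame(sequence = substring(context, starts, starts + L - 1L),
               length = L,
               mutation_offset = m - starts + 1L,
               start = starts, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sequence = character(), length = integer(),
                      mutation_offset = integer(), start = integer())
  rownames(res) <- NULL
  res
}

#' Candidate peptides for a table of driver mutations
#'
#' Runs [extract_context()] and [sliding_windows()] for every mutation.
#' Each window length L gets its own mutation-centered context of
#' `2L - 1` residues (flank `L - 1`), so an interior mutation yields
#' exactly L windows per length -- 9 nine-mers, and 8+9+10+11 = 38
#' candidates over the four class I lengths; a fixed flank can be forced
#' with `flank`. Rows failing wild-type validation against the FASTA are
#' reported and skipped, not fatal.
#'
#' @param mutations data.frame with `gene`, `protein_id`, `position`,
#'   `wt_aa`, `mut_aa` (extra columns pass through by `mutation_id`).
#' @param proteome named character vector.
#' @param lengths window lengths (default 8:11).
#' @param flank context flank; `NULL` (default) uses the length-adaptive
#'   `L - 1`.
#' @return data.frame of candidates with `mutation_id`, `gene`, the window
#'   columns of [sliding_windows()], and attribute `failed` listing skipped
#'   rows with reasons.
#' @export
generate_candidates <- function(mutations, proteome, lengths = 8:11,
                                flank = NULL) {
  out <- vector("list", nrow(mutations))
  failed <- list()
  for (i in seq_len(nrow(mutations))) {
    mut <- mutations[i, ]
    res <- tryCatch({
      win <- do.call(rbind, lapply(lengths, function(L) {
        ctx <- extract_context(mut, proteome,
                               flank = if (is.null(flank)) L - 1L else flank)
        sliding_windows(ctx$context, ctx$mutation_index, L)
      }))
      if (nrow(win)) {
        win$mutation_id <- i
        win$gene <- mut$gene
        win$protein_id <- mut$protein_id
        win$protein_position <- mut$position
      }
      win
    }, hlapresent_error = function(e) {
      failed[[length(failed) + 1L]] <<- data.frame(
        row = i, reason = conditionMessage(e), stringsAsFactors = FALSE)
      message(sprintf("mutation row %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sequence = character(), length = integer(),
                      mutation_offset = integer(), start = integer(),
                      mutation_id = integer(), gene = character(),
                      protein_id = character(), protein_position = integer())
  rownames(res) <- NULL
  attr(res, "failed") <- if (length(failed)) do.call(rbind, failed)
    else data.frame(row = integer(), reason = character())
  res
}

#' Score candidate peptides across an allele panel
#'
#' For every (allele, candidate) pair, records the model's presentation
#' call, the external predictor's call when supplied, and the intersection
#' (combined) call. A mutation yields a putative neoantigen when at least
#' one of its candidates is combined-positive for at least one allele.
#'
#' @param candidates data.frame from [generate_candidates()] (needs
#'   `sequence` and `mutation_id`).
#' @param predictor either a named list of trained `hla_cnn` models (names
#'   are alleles) or a `function(allele, peptides)` returning 0/1 calls --
#'   the latter supports oracle predictors in tests.
#' @param alleles allele panel; defaults to the names of `predictor`.
#' @param external_calls optional character vector of
#'   `"<allele>_<peptide>"` keys called positive by the external predictor;
#'   when supplied, combined = model AND external.
#' @param threshold model call threshold on the presentation probability.
#' @return data.frame `allele,sequence,mutation_id,call_model,
#'   call_external,call_combined`; attribute `neoantigen_mutations` lists
#'   the mutation ids with at least one combined-positive candidate.
#' @export
score_candidates <- function(candidates, predictor, alleles = NULL,
                             external_calls = NULL, threshold = 0.5) {
  if (is.null(alleles)) {
    if (is.function(predictor))
      cond_stop("alleles must be given when predictor is a function",
                "hlapresent_config_error")
    alleles <- names(predictor)
  }
  rows <- vector("list", length(alleles))
  for (j in seq_along(alleles)) {
    al <- alleles[j]
    calls <- tryCatch({
      if (is.function(predictor)) {
        as.integer(predictor(al, candidates$sequence))
      } else {
        model <- predictor[[al]]
        if (is.null(model))
          cond_stop(sprintf("no model for allele %s", al),
                    "hlapresent_lookup_error")
        predict(model, candidates$sequence, threshold = threshold)$call
      }
    }, hlapresent_error = function(e) {
      message(sprintf("allele %s skipped: %s", al, conditionMessage(e)))
      NULL
    })
    if (is.null(calls)) next
    df <- data.frame(allele = al, sequence = candidates$sequence,
                     mutation_id = candidates$mutation_id,
                     call_model = calls, stringsAsFactors = FALSE)
    if (!is.null(external_calls)) {
      key <- paste0(al, "_", df$sequence)
      df$call_external <- as.integer(key %in% external_calls)
      df$call_combined <- as.integer(df$call_model == 1L & df$call_external == 1L)
    } else {
      df$call_external <- NA_integer_
      df$call_combined <- df$call_model
    }
    rows[[j]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(allele = character(), sequence = character(),
                      mutation_id = integer(), call_model = integer(),
                      call_external = integer(), call_combined = integer())
  rownames(out) <- NULL
  attr(out, "neoantigen_mutations") <-
    sort(unique(out$mutation_id[out$call_combined == 1L]))
  out
}

#' Cohort frequency of a shared neoantigen's driver mutation
#'
#' `100 * carriers / cohort_size`, rounded to 2 decimals -- the fraction of
#' patients in a cohort carrying the mutation, hence eligible for an
#' off-the-shelf vaccine targeting the neoantigen.
#'
#' @param carriers patients carrying the mutation.
#' @param cohort_size cohort total.
#' @return percent, rounded to 2 decimals; `NA` when counts are missing.
#' @export
cohort_frequency <- function(carriers, cohort_size) {
  if (length(carriers) != length(cohort_size))
    cond_stop("carriers and cohort_size must have equal length",
              "hlapresent_format_error")
  out <- rep(NA_real_, length(carriers))
  ok <- !is.na(carriers) & !is.na(cohort_size) & cohort_size >= 1
  out[ok] <- round(100 * carriers[ok] / cohort_size[ok], 2)
  out
}

#' Display key of a shared neoantigen
#'
#' @param allele allele name (with or without `HLA-` prefix).
#' @param peptide candidate peptide sequence.
#' @return string such as `"HLA-A*03:01_VVGAGDVGK"`.
#' @export
neoantigen_key <- function(allele, peptide) {
  paste0("HLA-", sub("^HLA-", "", allele), "_", peptide)
}
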