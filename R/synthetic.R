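# Seeded synthetic generators: motif-governed labeled peptide sets, toy
# proteomes with implanted hits, and driver-mutation tables. They emulate
# the statistical structure of real MS elution data -- anchored positives,
# proteome-like negatives, severe class imbalance -- so the whole pipeline
# is testable with no downloads. They do not model MS acquisition
# artifacts (detectability bias); see the methods vignette.

#' Specify a synthetic allele
#'
#' Describes the generative world for one allele: peptide length
#' distribution, anchor rules (position, allowed residues, adherence
#' probability), a background residue distribution, the class imbalance and
#' the positive-set size. The default mirrors an A*02:01-like motif --
#' leucine at P2 and valine/leucine at the C-terminus at adherence 0.9 --
#' with the global 39:1 decoy:hit imbalance of real MS corpora.
#'
#' @param name allele-style label.
#' @param length_weights named distribution over lengths 8-11 (sums to 1).
#' @param anchor_rules list of rules `list(position =, residues =,
#'   adherence =)`; `position = -1` means the C-terminal position of
#'   whatever length is drawn.
#' @param background `"uniform"` (default) or a named length-20
#'   probability vector over the amino-acid alphabet.
#' @param imbalance_ratio negatives per positive (>= 1; default 39).
#' @param n_positives number of 1-labeled peptides (default 2000).
#' @param seed integer seed.
#' @return list with class `synthetic_allele_spec`.
#' @export
synthetic_allele_spec <- function(
    name = "A*02:01",
    length_weights = c(`8` = 0.2, `9` = 0.4, `10` = 0.2, `11` = 0.2),
    anchor_rules = list(
      list(position = 2L, residues = "L", adherence = 0.9),
      list(position = -1L, residues = c("V", "L"), adherence = 0.9)),
    background = "uniform",
    imbalance_ratio = 39L,
    n_positives = 2000L,
    seed = 1L) {
  name <- validate_allele(name)
  if (abs(sum(length_weights) - 1) > 1e-9 || any(length_weights < 0))
    cond_stop("length_weights must be a distribution over lengths",
              "hlapresent_spec_error")
  if (!all(names(length_weights) %in% as.character(8:11)))
    cond_stop("length_weights names must be in 8..11", "hlapresent_spec_error")
  for (r in anchor_rules) {
    if (r$adherence < 0 || r$adherence > 1)
      cond_stop("anchor adherence must lie in [0, 1]", "hlapresent_spec_error")
    if (!all(r$residues %in% aa_alphabet()))
      cond_stop("anchor residues must be standard amino acids",
                "hlapresent_spec_error")
  }
  if (imbalance_ratio < 1)
    cond_stop("imbalance_ratio must be >= 1", "hlapresent_spec_error")
  bg <- if (identical(background, "uniform"))
    stats::setNames(rep(1 / 20, 20), aa_alphabet())
  else {
    if (!all(aa_alphabet() %in% names(background)) ||
        abs(sum(background) - 1) > 1e-9)
      cond_stop("background must be a distribution over all 20 residues",
                "hlapresent_spec_error")
    background[aa_alphabet()]
  }
  structure(list(name = name, length_weights = length_weights,
                 anchor_rules = anchor_rules, background = bg,
                 imbalance_ratio = as.integer(imbalance_ratio),
                 n_positives = as.integer(n_positives),
                 seed = as.integer(seed)),
            class = "synthetic_allele_spec")
}

resolve_position <- function(position, L) if (position < 0L) L + position + 1L else position

# analytic per-length generating PFM implied by a spec
spec_pfm <- function(spec, L) {
  f <- matrix(rep(spec$background, each = L), nrow = L,
              dimnames = list(paste0("P", seq_len(L)), aa_alphabet()))
  for (r in spec$anchor_rules) {
    pos <- resolve_position(r$position, L)
    if (pos < 1L || pos > L) next
    anchor <- stats::setNames(rep(0, 20), aa_alphabet())
    anchor[r$residues] <- 1 / length(r$residues)
    f[pos, ] <- r$adherence * anchor + (1 - r$adherence) * spec$background
  }
  structure(f, class = c("pfm", "matrix"), support = NA_integer_,
            length = L, allele = spec$name)
}

sample_background_peptides <- function(n, lengths, background) {
  chars <- sample(names(background), sum(lengths), replace = TRUE,
                  prob = background)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  flat <- paste(chars, collapse = "")
  substring(flat, starts, ends)
}

#' Generate a labeled synthetic dataset for one allele
#'
#' Positives are background draws with each anchor rule enforced
#' independently with its adherence probability; negatives are pure
#' background draws with the same length distribution. The negative count
#' is exactly `imbalance_ratio * n_positives`. With `exclusive = TRUE`,
#' negatives matching every anchor rule are rejected and resampled, giving
#' the constructed separability the classifier recovery tests rely on.
#'
#' @param spec a [synthetic_allele_spec()].
#' @param exclusive reject anchor-conforming negatives (default FALSE).
#' @return list: `data` (data.frame `peptide,allele,label`), `pfm` (named
#'   list of the generating position frequency matrices per length), and
#'   `spec`.
#' @export
generate_dataset <- function(spec, exclusive = FALSE) {
  rng <- local_rng(spec$seed)
  on.exit(rng())
  lens_avail <- as.integer(names(spec$length_weights))
  n_pos <- spec$n_positives
  n_neg <- spec$imbalance_ratio * n_pos
  pos_len <- sample_vec(lens_avail, n_pos, replace = TRUE,
                        prob = spec$length_weights)
  pos <- sample_background_peptides(n_pos, pos_len, spec$background)
  for (r in spec$anchor_rules) {
    enforce <- stats::runif(n_pos) < r$adherence
    repl <- sample(r$residues, n_pos, replace = TRUE)
    for (i in which(enforce)) {
      p <- resolve_position(r$position, pos_len[i])
      if (p >= 1L && p <= pos_len[i]) {
        substr(pos[i], p, p) <- repl[i]
      }
    }
  }
  neg_len <- sample_vec(lens_avail, n_neg, replace = TRUE,
                        prob = spec$length_weights)
  neg <- sample_background_peptides(n_neg, neg_len, spec$background)
  if (exclusive) {
    conforms <- function(pep) {
      L <- nchar(pep)
      all(vapply(spec$anchor_rules, function(r) {
        p <- resolve_position(r$position, L)
        p >= 1L && p <= L && substr(pep, p, p) %in% r$residues
      }, logical(1)))
    }
    bad <- which(vapply(neg, conforms, logical(1)))
    guard <- 0L
    while (length(bad) && guard < 100L) {
      neg[bad] <- sample_background_peptides(length(bad), neg_len[bad],
                                             spec$background)
      bad <- bad[vapply(neg[bad], conforms, logical(1))]
      guard <- guard + 1L
    }
  }
  data <- data.frame(peptide = c(pos, neg), allele = spec$name,
                     label = rep(c(1L, 0L), c(n_pos, n_neg)),
                     stringsAsFactors = FALSE)
  pfms <- lapply(lens_avail, function(L) spec_pfm(spec, L))
  names(pfms) <- lens_avail
  list(data = data, pfm = pfms, spec = spec)
}

#' Generate a toy proteome with implanted MS hits
#'
#' Random proteins (uniform residues) into which known hit peptides are
#' implanted at recorded offsets; the ground truth feeds the decoy
#' generator and its leakage tests. Byte-identical output under one seed.
#'
#' @param n_proteins number of proteins (default 10).
#' @param length_range integer range of protein lengths (default 200-400).
#' @param hits_per_protein implanted hits per protein (default 3).
#' @param hit_length length of implanted hits (default 9).
#' @param seed integer seed.
#' @return list: `proteome` (named character vector, ids `SYNP0001`...)
#'   and `hits` (data.frame `peptide,source_protein,offset`).
#' @export
generate_proteome <- function(n_proteins = 10L, length_range = c(200L, 400L),
                              hits_per_protein = 3L, hit_length = 9L,
                              seed = 1L) {
  if (min(length_range) < 11L)
    cond_stop("proteins must be at least 11 aa", "hlapresent_spec_error")
  rng <- local_rng(seed)
  on.exit(rng())
  aa <- aa_alphabet()
  proteome <- character(n_proteins)
  ids <- sprintf("SYNP%04d", seq_len(n_proteins))
  hit_rows <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    plen <- sample_vec(length_range[1]:length_range[2], 1L)
    prot <- paste(sample(aa, plen, replace = TRUE), collapse = "")
    # non-overlapping implant slots
    slots <- integer(0)
    tries <- 0L
    while (length(slots) < hits_per_protein && tries < 200L) {
      cand <- sample.int(plen - hit_length + 1L, 1L)
      if (all(abs(cand - slots) >= hit_length)) slots <- c(slots, cand)
      tries <- tries + 1L
    }
    peps <- character(length(slots))
    for (j in seq_along(slots)) {
      pep <- paste(sample(aa, hit_length, replace = TRUE), collapse = "")
      substr(prot, slots[j], slots[j] + hit_length - 1L) <- pep
      peps[j] <- pep
    }
    proteome[i] <- prot
    hit_rows[[i]] <- data.frame(peptide = peps, source_protein = ids[i],
                                offset = slots, stringsAsFactors = FALSE)
  }
  names(proteome) <- ids
  hits <- do.call(rbind, hit_rows)
  rownames(hits) <- NULL
  list(proteome = proteome, hits = hits)
}

#' Generate a synthetic driver-mutation table
#'
#' Missense mutations with valid wild-type residues at their stated
#' positions, random mutant residues, and synthetic carrier / cohort
#' counts. Positions deliberately include near-terminus cases (< `flank`
#' residues from an end) so context-clipping logic is exercised.
#'
#' @param proteome named character vector.
#' @param n_mutations rows to generate (default 20).
#' @param cohort_size synthetic cohort total (default 500).
#' @param flank flank used to classify near-terminus positions (default 8).
#' @param seed integer seed.
#' @return data.frame `gene,protein_id,position,wt_aa,mut_aa,carriers,
#'   cohort_size,cancer_type`.
#' @export
generate_mutation_table <- function(proteome, n_mutations = 20L,
                                    cohort_size = 500L, flank = 8L,
                                    seed = 1L) {
  if (!length(proteome))
    cond_stop("proteome is empty", "hlapresent_spec_error")
  rng <- local_rng(seed)
  on.exit(rng())
  aa <- aa_alphabet()
  ids <- names(proteome)
  n_term <- max(2L, n_mutations %/% 5L)   # guaranteed near-terminus coverage
  rows <- vector("list", n_mutations)
  for (i in seq_len(n_mutations)) {
    pid <- sample(ids, 1L)
    plen <- nchar(proteome[[pid]])
    pos <- if (i <= n_term %/% 2L) sample_vec(seq_len(min(flank, plen)), 1L)
      else if (i <= n_term) sample_vec(seq(max(1L, plen - flank + 1L), plen), 1L)
      else sample.int(plen, 1L)
    wt <- substr(proteome[[pid]], pos, pos)
    mut <- sample(setdiff(aa, wt), 1L)
    rows[[i]] <- data.frame(
      gene = sprintf("GENE%03d", i), protein_id = pid, position = pos,
      wt_aa = wt, mut_aa = mut,
      carriers = stats::rbinom(1L, cohort_size, 0.02),
      cohort_size = cohort_size,
      cancer_type = sample(c("PANCAN", "COAD", "LUAD", "BRCA"), 1L),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
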