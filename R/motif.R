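# Presentation-motif analysis: per-allele, per-length position frequency
# matrices, information-content anchor detection, amino-acid property-class
# profiles, and motif similarity.

#' Build a position frequency matrix from same-length peptides
#'
#' `freq[i, a]` is the fraction of peptides carrying residue `a` at
#' position `i`; every row sums to 1. Computed from MS-positive peptides of
#' one allele and one length, this is the presentation motif underlying a
#' sequence logo.
#'
#' @param peptides nonempty character vector, all the same length.
#' @param pseudocount added to every cell before normalization (default 0).
#' @param allele optional allele annotation.
#' @return matrix of class `pfm`, length x 20, rows `P1..PL`, columns the
#'   amino-acid alphabet; attributes `support` (peptide count), `length`
#'   and `allele`.
#' @export
build_pfm <- function(peptides, pseudocount = 0, allele = NULL) {
  if (!length(peptides))
    cond_stop("cannot build a motif from zero peptides", "hlapresent_size_error")
  peptides <- toupper(peptides)
  lens <- unique(nchar(peptides))
  if (length(lens) != 1L)
    cond_stop(sprintf("mixed peptide lengths: {%s}", paste(lens, collapse = ",")),
              "hlapresent_length_error")
  L <- lens
  chars <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                  nrow = length(peptides), ncol = L, byrow = TRUE)
  counts <- vapply(seq_len(L), function(i)
    tabulate(match(chars[, i], aa_alphabet()), nbins = 20L), integer(20))
  freq <- t(counts) + pseudocount
  freq <- freq / rowSums(freq)
  dimnames(freq) <- list(paste0("P", seq_len(L)), aa_alphabet())
  structure(freq, class = c("pfm", "matrix"),
            support = length(peptides), length = L, allele = allele)
}

#' Per-position information content of a motif
#'
#' Shannon information against a uniform background:
#' `IC(i) = log2(20) + sum_a f[i,a] * log2(f[i,a])` (with `0 log 0 = 0`),
#' ranging from 0 (uniform) to `log2(20)` (a single residue). Anchor
#' positions show up as high-IC rows.
#'
#' @param pfm a [build_pfm()] matrix.
#' @return numeric vector, one value per position.
#' @export
information_content <- function(pfm) {
  f <- unclass(pfm)
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- log2(20) + rowSums(plogp)
  stats::setNames(pmax(ic, 0), rownames(pfm))
}

#' Find anchor positions of a motif
#'
#' Returns the `k` positions with the highest information content; ties are
#' broken toward the smaller position index. For class I ligands this
#' typically recovers P2 and the C-terminal position.
#'
#' @param pfm a `pfm`.
#' @param k number of anchors (default 2).
#' @return integer vector of positions, sorted ascending.
#' @export
find_anchors <- function(pfm, k = 2L) {
  L <- nrow(pfm)
  if (k > L)
    cond_stop(sprintf("k = %d exceeds motif length %d", k, L),
              "hlapresent_size_error")
  ic <- information_content(pfm)
  ord <- order(-ic, seq_len(L))
  sort(ord[seq_len(k)])
}

#' Default amino-acid property classes
#'
#' The five-class scheme used to summarize motifs: acidic {D,E}, basic
#' {K,R,H}, hydrophobic {A,V,L,I,M,F,W,C}, polar {S,T,N,Q,Y}, neutral
#' {G,P}. The assignment is a documented package choice and can be replaced
#' by any complete mapping.
#'
#' @return named character vector, residue -> class.
#' @export
default_property_classes <- function() {
  c(D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
    W = "hydrophobic", C = "hydrophobic",
    S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
    G = "neutral", P = "neutral")
}

#' Property-class profile of a motif at chosen positions
#'
#' For each of the five property classes, the frequency mass it carries at
#' the given (typically anchor) positions, averaged over positions. The
#' fractions sum to 1. Hydrophobic enrichment at anchors is the canonical
#' class I signature.
#'
#' @param pfm a `pfm`.
#' @param positions positions to profile (e.g. from [find_anchors()]).
#' @param classes residue -> class mapping covering all 20 residues
#'   (default [default_property_classes()]).
#' @return named numeric vector over the classes present in `classes`.
#' @export
property_profile <- function(pfm, positions,
                             classes = default_property_classes()) {
  if (!all(aa_alphabet() %in% names(classes)))
    cond_stop("property class map must cover all 20 residues",
              "hlapresent_format_error")
  if (any(positions < 1L | positions > nrow(pfm)))
    cond_stop("positions outside motif length", "hlapresent_size_error")
  f <- unclass(pfm)[positions, , drop = FALSE]
  cls <- classes[colnames(f)]
  levels <- unique(unname(classes))
  prof <- vapply(levels, function(cl)
    mean(rowSums(f[, cls == cl, drop = FALSE])), numeric(1))
  stats::setNames(prof, levels)
}

#' Similarity of two same-length motifs
#'
#' Mean per-position cosine similarity between frequency rows; symmetric,
#' 1 for identical motifs, 0 for motifs with disjoint residue support at
#' every position. Alleles sharing anchors (e.g. leucine at P2 with a
#' hydrophobic C-terminus) score high even when they differ elsewhere.
#'
#' @param pfm_a,pfm_b `pfm` objects of equal length.
#' @return numeric scalar in [0, 1].
#' @export
motif_similarity <- function(pfm_a, pfm_b) {
  if (nrow(pfm_a) != nrow(pfm_b))
    cond_stop("motif lengths differ", "hlapresent_length_error")
  a <- unclass(pfm_a); b <- unclass(pfm_b)
  sims <- vapply(seq_len(nrow(a)), function(i) {
    na <- sqrt(sum(a[i, ]^2)); nb <- sqrt(sum(b[i, ]^2))
    sum(a[i, ] * b[i, ]) / (na * nb)
  }, numeric(1))
  mean(sims)
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm%s: %d-mer motif from %d peptides; anchors {%s}>\n",
              if (is.null(attr(x, "allele"))) "" else
                paste0(" ", attr(x, "allele")),
              attr(x, "length"), attr(x, "support"),
              paste(find_anchors(x), collapse = ", ")))
  invisible(x)
}

#' Write / read a motif as a position-by-residue CSV
#'
#' @param pfm a `pfm`.
#' @param path CSV path.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = seq_len(nrow(pfm)), unclass(pfm),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, aa_alphabet()])
  rownames(m) <- paste0("P", df$position)
  structure(m, class = c("pfm", "matrix"),
            support = NA_integer_, length = nrow(m), allele = NULL)
}
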