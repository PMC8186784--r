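# One-hot peptide codec: fixed 11 x 21 representation for 8-11mer peptides.

#' Amino-acid alphabet and encoding constants
#'
#' HLA class I ligands are encoded over the 20 standard amino acids in the
#' fixed order `ACDEFGHIKLMNPQRSTVWY`; a 21st symbol `Z` pads peptides
#' shorter than 11 residues. Columns 1-20 of an encoding follow this order,
#' column 21 is the pad. The mapping is fixed so encodings are bit-identical
#' across runs.
#'
#' @format `aa_alphabet()` returns the 20 residues; `enc_alphabet()` returns
#'   the 21 encoding symbols (residues plus `"Z"`).
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
enc_alphabet <- function() c(aa_alphabet(), "Z")

PEP_MIN <- 8L
PEP_MAX <- 11L
ENC_COLS <- 21L

cond_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hlapresent_error")))
}

#' Validate a peptide sequence
#'
#' Upper-cases the input, then checks length (8-11) and alphabet membership.
#'
#' @param sequence character scalar peptide.
#' @return the validated (upper-cased) sequence, invisibly usable.
#' @export
validate_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    cond_stop("peptide must be a single character string", "hlapresent_alphabet_error")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < PEP_MIN || n > PEP_MAX)
    cond_stop(sprintf("peptide length %d outside [%d, %d]: %s",
                      n, PEP_MIN, PEP_MAX, sequence),
              "hlapresent_length_error")
  bad <- setdiff(strsplit(sequence, "")[[1]], aa_alphabet())
  if (length(bad))
    cond_stop(sprintf("invalid residue(s) %s in peptide %s",
                      paste(unique(bad), collapse = ","), sequence),
              "hlapresent_alphabet_error")
  sequence
}

#' Validate an HLA allele name
#'
#' Accepts gene*group:protein nomenclature such as `"A*02:01"` or
#' `"B*57:01"`; an optional `HLA-` prefix is stripped.
#'
#' @param allele character scalar.
#' @return normalized allele name without the `HLA-` prefix.
#' @export
validate_allele <- function(allele) {
  if (!is.character(allele) || length(allele) != 1L || is.na(allele))
    cond_stop("allele must be a single character string", "hlapresent_allele_error")
  a <- sub("^HLA-", "", allele)
  if (!grepl("^[A-Z]+[0-9]?\\*[0-9]+:[0-9]+$", a))
    cond_stop(sprintf("allele '%s' does not match gene*group:protein nomenclature",
                      allele), "hlapresent_allele_error")
  a
}

#' Encode a peptide as a fixed 11 x 21 one-hot matrix
#'
#' Each residue occupies one row (one-hot over the 21 columns of
#' [enc_alphabet()]); rows beyond the peptide length are one-hot for the pad
#' symbol `Z` (suffix padding, so anchor position P2 sits on a fixed row for
#' every peptide length). Every row sums to exactly 1 and the whole matrix
#' sums to 11.
#'
#' @param sequence peptide string, 8-11 residues over the 20-letter alphabet
#'   (lowercase accepted).
#' @return integer matrix, 11 rows x 21 columns, with `source_length`
#'   attribute recording the unpadded length.
#' @examples
#' m <- encode_peptide("SIINFEKLV")
#' rowSums(m)          # all 1
#' attr(m, "source_length")
#' @export
encode_peptide <- function(sequence) {
  sequence <- validate_peptide(sequence)
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(c(chars, rep("Z", PEP_MAX - length(chars))), enc_alphabet())
  m <- matrix(0L, nrow = PEP_MAX, ncol = ENC_COLS,
              dimnames = list(paste0("P", seq_len(PEP_MAX)), enc_alphabet()))
  m[cbind(seq_len(PEP_MAX), idx)] <- 1L
  attr(m, "source_length") <- length(chars)
  m
}

#' Decode a one-hot matrix back to its peptide string
#'
#' Inverse of [encode_peptide()]: requires an 11 x 21 binary matrix in which
#' every row sums to 1 and pad (`Z`) rows occur only as a suffix.
#'
#' @param m matrix as produced by [encode_peptide()].
#' @return the peptide string; `decode_peptide(encode_peptide(p)) == p`.
#' @export
decode_peptide <- function(m) {
  if (!is.matrix(m) || nrow(m) != PEP_MAX || ncol(m) != ENC_COLS)
    cond_stop("encoding must be an 11 x 21 matrix", "hlapresent_matrix_error")
  if (any(!(m %in% c(0, 1))) || any(rowSums(m) != 1))
    cond_stop("every row of an encoding must be one-hot (binary, summing to 1)",
              "hlapresent_matrix_error")
  idx <- max.col(m, ties.method = "first")
  symbols <- enc_alphabet()[idx]
  pad <- symbols == "Z"
  if (any(pad) && any(!pad[seq(which(pad)[1], PEP_MAX)]))
    cond_stop("pad rows must form a suffix", "hlapresent_matrix_error")
  seq_chars <- symbols[!pad]
  n <- length(seq_chars)
  if (n < PEP_MIN || n > PEP_MAX)
    cond_stop(sprintf("decoded length %d outside [%d, %d]", n, PEP_MIN, PEP_MAX),
              "hlapresent_matrix_error")
  paste(seq_chars, collapse = "")
}

# Vectorized flat encoding used by the classifier: N x 231 matrix, row-major
# peptide layout (row i, column j) -> flat column (i-1)*21 + j.
encode_matrix <- function(peptides) {
  peptides <- toupper(peptides)
  n <- length(peptides)
  lens <- nchar(peptides)
  bad <- lens < PEP_MIN | lens > PEP_MAX
  if (any(bad))
    cond_stop(sprintf("peptide length outside [8, 11] at position(s) %s",
                      paste(utils::head(which(bad), 5), collapse = ",")),
              "hlapresent_length_error")
  padded <- vapply(seq_len(n), function(i)
    paste0(peptides[i], strrep("Z", PEP_MAX - lens[i])), character(1))
  chars <- matrix(unlist(strsplit(padded, ""), use.names = FALSE),
                  nrow = n, ncol = PEP_MAX, byrow = TRUE)
  idx <- match(chars, enc_alphabet())
  if (anyNA(idx))
    cond_stop("invalid residue in peptide input", "hlapresent_alphabet_error")
  dim(idx) <- dim(chars)
  X <- matrix(0, nrow = n, ncol = PEP_MAX * ENC_COLS)
  for (i in seq_len(PEP_MAX))
    X[cbind(seq_len(n), (i - 1L) * ENC_COLS + idx[, i])] <- 1
  X
}
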