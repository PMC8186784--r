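# Readers and writers for the plain-text formats the pipeline exchanges:
# CSV peptide tables, FASTA proteomes, CSV/YAML sampling plans.

#' Read a labeled peptide table from CSV
#'
#' Expects a header with a `peptide` column and optional `allele` and
#' `label` columns. Rows failing validation (length outside 8-11, bad
#' residue, malformed allele, label not in {0,1}) are reported with their
#' line numbers; in strict mode the read aborts, in lenient mode (default)
#' offending rows are skipped and returned in the `"skipped"` attribute.
#'
#' @param path CSV file path.
#' @param strict abort on the first malformed row instead of skipping.
#' @return data.frame with columns `peptide`, and `allele`/`label` when
#'   present; attribute `skipped` holds a data.frame of rejected rows with
#'   `line` and `reason`.
#' @export
read_peptide_table <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"peptide" %in% names(df))
    cond_stop(sprintf("%s: missing required 'peptide' column", path),
              "hlapresent_format_error")
  keep <- rep(TRUE, nrow(df))
  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    msg <- tryCatch({
      df$peptide[i] <- validate_peptide(df$peptide[i])
      if ("allele" %in% names(df) && !is.na(df$allele[i]) && nzchar(df$allele[i]))
        df$allele[i] <- validate_allele(df$allele[i])
      if ("label" %in% names(df) && !is.na(df$label[i]) &&
          !df$label[i] %in% c(0L, 1L))
        cond_stop("label must be 0 or 1", "hlapresent_format_error")
      NA_character_
    }, hlapresent_error = function(e) conditionMessage(e))
    if (!is.na(msg)) {
      if (strict)
        cond_stop(sprintf("%s line %d: %s", path, i + 1L, msg),
                  "hlapresent_format_error")
      keep[i] <- FALSE
      reasons[i] <- msg
    }
  }
  skipped <- data.frame(line = which(!keep) + 1L, reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(skipped))
    message(sprintf("%s: skipped %d malformed row(s) (lines %s)", path,
                    nrow(skipped), paste(skipped$line, collapse = ",")))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a peptide table to CSV
#'
#' @param df data.frame with at least a `peptide` column.
#' @param path output path.
#' @export
write_peptide_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header;
#' duplicate ids are an error. Wrapped sequence lines are concatenated.
#'
#' @param path FASTA file.
#' @return named character vector, id -> amino-acid sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L)
    cond_stop(sprintf("%s: empty FASTA", path), "hlapresent_format_error")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    cond_stop(sprintf("%s: duplicate FASTA ids (%s)", path,
                      paste(unique(ids[duplicated(ids)]), collapse = ",")),
              "hlapresent_format_error")
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write a named character vector of protein sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Extract a UniProt accession from a FASTA id
#'
#' For `sp|P01112|RASH_HUMAN`-style ids returns the middle token
#' (`P01112`); for plain ids returns the id unchanged.
#'
#' @param id FASTA record id (first header token).
#' @export
uniprot_accession <- function(id) {
  vapply(strsplit(id, "|", fixed = TRUE), function(parts) {
    if (length(parts) >= 3L && parts[1] %in% c("sp", "tr")) parts[2] else parts[1]
  }, character(1))
}

#' Read unlabeled peptides from a FASTA file (one peptide per record)
#'
#' @param path FASTA file.
#' @return character vector of validated peptides.
#' @export
read_peptide_fasta <- function(path) {
  seqs <- unname(read_fasta(path))
  vapply(seqs, validate_peptide, character(1))
}

#' Read a per-allele sampling plan from CSV or YAML
#'
#' A plan file gives, per allele, the under-sampling fraction applied to
#' 0-labeled records, the over-sampling factor applied to 1-labeled
#' records, and optionally the test-partition size. CSV needs columns
#' `allele,under,over[,test_count]`; YAML a list of mappings with the same
#' keys.
#'
#' @param path plan file (`.csv`, `.yml`/`.yaml`).
#' @return data.frame with one validated row per allele.
#' @export
read_sampling_plan <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(raw, function(r)
      data.frame(allele = r$allele, under = r$under, over = r$over,
                 test_count = if (is.null(r$test_count)) NA_integer_
                              else as.integer(r$test_count),
                 stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"test_count" %in% names(df)) df$test_count <- NA_integer_
  }
  need <- c("allele", "under", "over")
  if (!all(need %in% names(df)))
    cond_stop(sprintf("%s: plan needs columns %s", path,
                      paste(need, collapse = ",")), "hlapresent_format_error")
  for (i in seq_len(nrow(df)))
    sampling_plan(df$allele[i], df$under[i], df$over[i])
  if (anyDuplicated(df$allele))
    cond_stop("plan lists an allele more than once", "hlapresent_format_error")
  df
}

#' Per-allele training-set summary and rebalancing plan
#'
#' The packaged summary of the 20 high-frequency HLA-A/-B alleles the MS
#' training corpus covers: per allele, the number of MS hits (`label1`),
#' proteome decoys (`label0`), the train/test partition sizes, and the
#' under-/over-sampling proportions used to correct class imbalance.
#'
#' @return data.frame with columns
#'   `allele,label1,label0,train,test,under,over`.
#' @export
training_summary <- function() {
  path <- system.file("extdata", "allele_training_summary.csv",
                      package = "hlapresent", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a JSON run manifest next to an output file
#'
#' Records the command, arguments, seed, package version and timestamp so
#' any output can be reproduced.
#'
#' @param out_path the output the manifest describes.
#' @param command subcommand or function name.
#' @param args named list of arguments (must be JSON-serializable).
#' @param seed integer seed used for the run.
#' @export
write_manifest <- function(out_path, command, args, seed = NA_integer_) {
  manifest <- list(
    command = command,
    args = args,
    seed = seed,
    package = "hlapresent",
    version = as.character(utils::packageVersion("hlapresent")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
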