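#' Construct a FASTA dataset
#'
#' A `fasta_dataset` is a data frame with one row per sequence record and
#' columns `id`, `description`, `residues` and `label` (`"positive"`,
#' `"negative"` or `NA`). It is the container every other stage of the
#' pipeline consumes.
#'
#' @param id character vector of record identifiers.
#' @param residues character vector of sequences (same length as `id`).
#' @param description free-text header remainders; recycled if scalar.
#' @param label optional class labels (`"positive"`/`"negative"`), recycled.
#' @param source provenance tag (file path or generator name).
#' @return A `fasta_dataset` object.
#' @export
fasta_dataset <- function(id, residues, description = "", label = NA_character_,
                          source = "") {
  stopifnot(length(id) == length(residues))
  df <- data.frame(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    residues = as.character(residues),
    label = rep_len(as.character(label), length(id)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("fasta_dataset", "data.frame"), source = source)
}

#' @export
print.fasta_dataset <- function(x, ...) {
  cat(sprintf("<fasta_dataset> %d records (source: %s)\n",
              nrow(x), attr(x, "source") %||% ""))
  if (nrow(x) > 0) {
    lens <- nchar(x$residues)
    cat(sprintf("  lengths: %d-%d; labels: %s\n", min(lens), max(lens),
                paste(names(table(x$label, useNA = "ifany")), collapse = "/")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA file
#'
#' Parses a FASTA file into a [fasta_dataset()]. The record id is the first
#' whitespace-delimited token of the header, the rest of the header becomes the
#' description, sequence lines are concatenated and uppercased. An empty file
#' yields an empty dataset; a sequence line before any header or a missing file
#' is an error.
#'
#' @param path path to a FASTA file.
#' @param label optional class label applied to every record.
#' @return A [fasta_dataset()].
#' @export
read_fasta <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  fasta_dataset(id = ids, residues = toupper(as.character(set)),
                description = desc, label = label, source = path)
}

#' Write a FASTA dataset
#'
#' Writes records as FASTA with 60-column line wrapping. Headers are
#' `id description` (description omitted when empty).
#'
#' @param ds a [fasta_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  stopifnot(inherits(ds, "fasta_dataset"))
  set <- Biostrings::BStringSet(ds$residues)
  names(set) <- ifelse(nzchar(ds$description),
                       paste(ds$id, ds$description), ds$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Remove duplicate records
#'
#' Keeps the first record per id (`mode = "id"`, the default, matching
#' `seqkit rmdup`) or per exact residue string (`mode = "sequence"`);
#' order of first occurrence is preserved. The removed records are attached as
#' attribute `"removed"` (a data frame of id and reason) and can be written as
#' a TSV report via `report`.
#'
#' @param ds a [fasta_dataset()].
#' @param mode `"id"` or `"sequence"`.
#' @param report optional path for a TSV dedup report (columns id, reason).
#' @return The deduplicated [fasta_dataset()].
#' @export
dedup_records <- function(ds, mode = c("id", "sequence"), report = NULL) {
  stopifnot(inherits(ds, "fasta_dataset"))
  mode <- match.arg(mode)
  key <- if (mode == "id") ds$id else ds$residues
  keep <- !duplicated(key)
  removed <- data.frame(id = ds$id[!keep],
                        reason = rep(paste0("duplicate-", mode), sum(!keep)),
                        stringsAsFactors = FALSE)
  out <- ds[keep, , drop = FALSE]
  attr(out, "source") <- attr(ds, "source")
  class(out) <- class(ds)
  attr(out, "removed") <- removed
  if (!is.null(report))
    utils::write.table(removed, report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Sanitize residues to the A/C/G/T alphabet
#'
#' Uppercases residues and either strips every non-ACGT character
#' (`policy = "strip"`, counting removals) or raises on the first one
#' (`policy = "reject"`). A record left empty after stripping is an error:
#' downstream featurization is only defined on non-empty A/C/G/T strings.
#'
#' @param ds a [fasta_dataset()].
#' @param policy `"strip"` or `"reject"`.
#' @return The sanitized dataset, with attribute `"n_removed"` (total characters
#'   stripped).
#' @export
sanitize_records <- function(ds, policy = c("strip", "reject")) {
  stopifnot(inherits(ds, "fasta_dataset"))
  policy <- match.arg(policy)
  up <- toupper(ds$residues)
  bad <- nchar(up) - nchar(gsub("[^ACGT]", "", up))
  if (policy == "reject" && any(bad > 0))
    stop("non-ACGT characters in record(s): ",
         paste(utils::head(ds$id[bad > 0], 5), collapse = ", "))
  clean <- gsub("[^ACGT]", "", up)
  if (any(nchar(clean) == 0))
    stop("record(s) empty after sanitization: ",
         paste(utils::head(ds$id[nchar(clean) == 0], 5), collapse = ", "))
  ds$residues <- clean
  attr(ds, "n_removed") <- sum(bad)
  ds
}

#' Read a gene list (one identifier per line)
#'
#' @param path UTF-8 text file, one id per line; blank lines dropped.
#' @param dedup drop repeated ids (keeping first occurrence)?
#' @return character vector of ids.
#' @export
read_gene_list <- function(path, dedup = TRUE) {
  ids <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (dedup) ids <- ids[!duplicated(ids)]
  ids
}

#' Check id overlap between two datasets
#'
#' Optional guard against positive/negative contamination: returns the ids
#' present in both datasets (empty character vector when disjoint).
#'
#' @param a,b [fasta_dataset()] objects.
#' @return character vector of overlapping ids.
#' @export
overlap_ids <- function(a, b) intersect(a$id, b$id)
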