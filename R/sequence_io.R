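#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file of protein sequences into a
#' tibble of records. The record id is the first whitespace-delimited token
#' of the header line; sequences are uppercased with line breaks removed.
#'
#' @param path Path to a FASTA file.
#' @param sanitize Sanitization policy applied to each sequence: `"none"`
#'   keeps sequences verbatim, `"strict"` errors on any non-standard
#'   residue code, `"drop"` removes non-standard positions with a warning.
#' @return A tibble with columns `id` and `sequence`, one row per entry.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV", ">b", "GGA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, sanitize = c("none", "strict", "drop")) {
  sanitize <- match.arg(sanitize)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s",
                                      path, conditionMessage(e))))
  if (length(seqs) == 0L) {
    return(tibble(id = character(), sequence = character()))
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))
    abort(sprintf("FASTA entry %s has an empty header", bad[1]))
  }
  empty <- which(Biostrings::width(seqs) == 0L)
  if (length(empty) > 0) {
    abort(sprintf("FASTA entry '%s' (entry %d) has no sequence",
                  ids[empty[1]], empty[1]))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA ids: %s", paste(dup, collapse = ", ")))
  }
  sequence <- toupper(as.character(seqs))
  if (sanitize != "none") {
    sequence <- vapply(sequence, sanitize_sequence, character(1),
                       policy = sanitize, USE.NAMES = FALSE)
  }
  tibble(id = unname(ids), sequence = unname(sequence))
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with columns `id` and `sequence` (a
#'   `labeled_dataset` works too).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Sanitize a raw protein sequence
#'
#' Uppercases the sequence and handles non-standard residue codes
#' (B, Z, X, U, O, J, `*`, gaps, and anything else outside the 20 standard
#' one-letter codes).
#'
#' @param raw A non-empty character scalar.
#' @param policy `"strict"` errors on any non-standard code; `"drop"`
#'   removes non-standard positions and emits a warning.
#' @return The sanitized uppercase sequence.
#' @examples
#' sanitize_sequence("MKV", "strict")
#' suppressWarnings(sanitize_sequence("mkvX", "drop"))
#' @export
sanitize_sequence <- function(raw, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    abort("sequence must be a non-empty character scalar")
  }
  x <- toupper(gsub("\\s", "", raw))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (policy == "strict") {
      abort(sprintf("non-standard residue code(s) %s at position(s) %s",
                    paste(unique(chars[bad]), collapse = ", "),
                    paste(head(which(bad), 5), collapse = ", ")))
    }
    warn(sprintf("dropped %d non-standard residue(s): %s",
                 sum(bad), paste(unique(chars[bad]), collapse = ", ")))
    chars <- chars[!bad]
    if (length(chars) == 0L) abort("sequence empty after dropping non-standard residues")
    x <- paste(chars, collapse = "")
  }
  x
}

#' Read a label table from TSV
#'
#' Expects a two-column TSV with header `id<TAB>subtype`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` and `subtype`.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "subtype") %in% names(tab))) {
    abort(sprintf("label table %s must have columns 'id' and 'subtype'", path))
  }
  as_tibble(tab[, c("id", "subtype")])
}

#' Attach subtype labels to sequence records
#'
#' Joins a label table onto sequence records and fixes the ordered class
#' vocabulary. The class index of a subtype is its position in `classes`
#' (starting at 1); this ordering drives the one-vs-one pair indexing and
#' the sign convention of decision values downstream.
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param labels Tibble with columns `id` and `subtype`, or a named
#'   character vector `id -> subtype`.
#' @param classes Ordered character vector of subtype names. Defaults to
#'   the order of first appearance in `labels`.
#' @return A `labeled_dataset`: a tibble with columns `id`, `sequence`,
#'   `label`, carrying the ordered `classes` attribute. Record order is
#'   preserved exactly.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("MKV", "GGA"))
#' labs <- tibble::tibble(id = c("a", "b"), subtype = c("mG", "CS"))
#' attach_labels(recs, labs, classes = c("mG", "CS"))
#' @export
attach_labels <- function(records, labels, classes = NULL) {
  if (is.character(labels) && !is.null(names(labels))) {
    labels <- tibble(id = names(labels), subtype = unname(labels))
  }
  missing <- setdiff(records$id, labels$id)
  if (length(missing) > 0) {
    abort(sprintf("no label for record id(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lab <- setNames(labels$subtype, labels$id)[records$id]
  classes <- classes %||% unique(labels$subtype)
  unknown <- setdiff(unique(lab), classes)
  if (length(unknown) > 0) {
    abort(sprintf("subtype(s) not in the class vocabulary: %s",
                  paste(unknown, collapse = ", ")))
  }
  new_labeled_dataset(records$id, records$sequence, unname(lab), classes)
}

new_labeled_dataset <- function(id, sequence, label, classes) {
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate record ids: %s",
                  paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  out <- tibble(id = id, sequence = sequence, label = label)
  attr(out, "classes") <- classes
  class(out) <- c("labeled_dataset", class(out))
  out
}

#' Ordered class vocabulary of a labeled dataset
#'
#' @param dataset A `labeled_dataset`.
#' @return Character vector of subtype names; position = class index.
#' @export
dataset_classes <- function(dataset) {
  cls <- attr(dataset, "classes")
  if (is.null(cls)) abort("not a labeled_dataset: no class vocabulary attached")
  cls
}

#' Integer class indices of the labels in a labeled dataset
#'
#' @param dataset A `labeled_dataset`.
#' @return Integer vector, `match(label, dataset_classes(dataset))`.
#' @export
class_index <- function(dataset) {
  match(dataset$label, dataset_classes(dataset))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cls <- attr(x, "classes")
  cat(sprintf("# labeled_dataset: %d records, %d classes (%s)\n",
              nrow(x), length(cls), paste(cls, collapse = ", ")))
  NextMethod()
}
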