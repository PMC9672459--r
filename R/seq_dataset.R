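VALID_LABELS <- c("promoter", "non_promoter", "phage", "host")

#' Construct a sequence dataset
#'
#' A `seq_dataset` is a data frame with columns `id`, `seq` and `label`
#' holding identified DNA sequences and optional class labels. Sequences are
#' case-folded to uppercase; ids must be unique. Valid labels are
#' `"promoter"`, `"non_promoter"`, `"phage"` and `"host"` (or `NA` for
#' unlabeled records).
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of DNA sequences (same length as `id`).
#' @param label optional character vector of class labels (recycled).
#' @return An object of class `seq_dataset` (a data frame).
#' @examples
#' ds <- seq_dataset(c("p1", "p2"), c("ACGT", "ggca"), "promoter")
#' ds$seq
#' @export
seq_dataset <- function(id, seq, label = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length")
  label <- rep_len(as.character(label), length(id))
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence ids: ", paste(utils::head(dup, 5), collapse = ", "))
  bad <- !is.na(label) & !label %in% VALID_LABELS
  if (any(bad))
    stop("invalid labels: ", paste(unique(label[bad]), collapse = ", "),
         " (valid: ", paste(VALID_LABELS, collapse = ", "), ")")
  structure(
    data.frame(id = id, seq = seq, label = label, stringsAsFactors = FALSE),
    class = c("seq_dataset", "data.frame"))
}

#' @export
`[.seq_dataset` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "seq", "label") %in% names(out)))
    class(out) <- c("seq_dataset", "data.frame")
  out
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat("<seq_dataset> ", nrow(x), " sequence(s)\n", sep = "")
  if (nrow(x)) {
    cts <- class_counts(x)
    if (length(cts))
      cat("  labels: ", paste(names(cts), cts, sep = "=", collapse = ", "), "\n",
          sep = "")
    lens <- nchar(x$seq)
    cat("  lengths: ", min(lens), "-", max(lens), " bp\n", sep = "")
  }
  invisible(x)
}

#' Count records per class label
#'
#' @param ds a [seq_dataset()].
#' @return Named integer vector of label counts (unlabeled records excluded).
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "seq_dataset"))
  tab <- table(ds$label[!is.na(ds$label)])
  stats::setNames(as.integer(tab), names(tab))
}

#' Read sequences from a FASTA file
#'
#' Wraps [seqinr::read.fasta()] with the validation this package needs:
#' the file must be non-empty and start with a `>` header, ids must be
#' unique, and sequences are uppercased. Record order is preserved.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param labels optional path to a two-column TSV (`id<TAB>label`) or a named
#'   character vector of labels; ids present in the FASTA but absent from the
#'   label table get `NA`.
#' @return A [seq_dataset()].
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("empty FASTA file (no records): ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA at line ", first, ": expected '>' header, got: ",
         substr(lines[first], 1, 30))
  hdr <- which(startsWith(lines, ">"))
  empty_id <- hdr[!nzchar(trimws(substring(lines[hdr], 2)))]
  if (length(empty_id))
    stop("malformed FASTA at line ", empty_id[1], ": empty record id")
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (!length(recs)) stop("empty FASTA file (no records): ", path)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, as.character, character(1)))
  ds <- seq_dataset(unname(ids), unname(seqs))
  if (!is.null(labels)) {
    lab <- if (is.character(labels) && length(labels) == 1 && file.exists(labels))
      read_labels(labels) else labels
    ds$label <- unname(lab[ds$id])
    bad <- !is.na(ds$label) & !ds$label %in% VALID_LABELS
    if (any(bad)) stop("invalid labels: ",
                       paste(unique(ds$label[bad]), collapse = ", "))
  }
  ds
}

#' Read a label table
#'
#' @param path two-column TSV `id<TAB>label`; a header line `id label` is
#'   tolerated and skipped.
#' @return Named character vector mapping id to label.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("id", "label"))
  if (nrow(tab) && tab$id[1] == "id" && tab$label[1] == "label")
    tab <- tab[-1, , drop = FALSE]
  bad <- !tab$label %in% VALID_LABELS
  if (any(bad))
    stop("invalid labels in ", path, ": ",
         paste(unique(tab$label[bad]), collapse = ", "))
  stats::setNames(tab$label, tab$id)
}

#' Write a dataset to FASTA (and optionally its labels to TSV)
#'
#' Round-trip property: `read_fasta()` of the written file reproduces the
#' dataset (ids, sequences, order).
#'
#' @param ds a [seq_dataset()].
#' @param path output FASTA path.
#' @param labels_path optional path for a `id<TAB>label` TSV of the labeled
#'   records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, labels_path = NULL) {
  stopifnot(inherits(ds, "seq_dataset"))
  if (nrow(ds) == 0) {
    warning("writing empty FASTA file: ", path)
    cat("", file = path)
  } else {
    seqinr::write.fasta(as.list(ds$seq), names = ds$id, file.out = path,
                        nbchar = 80)
  }
  if (!is.null(labels_path)) {
    keep <- !is.na(ds$label)
    utils::write.table(ds[keep, c("id", "label")], labels_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Validate sequence records
#'
#' Enforces the model input contract: length at most `max_len` (the fixed
#' 99-bp input of the classifier) and alphabet restricted to A/C/G/T plus the
#' ambiguity code N. Over-long sequences are rejected, not truncated.
#'
#' @param ds a [seq_dataset()].
#' @param max_len maximum allowed sequence length (default 99).
#' @return `ds`, invisibly, with attribute `n_fraction` giving the fraction
#'   of N bases per record.
#' @export
validate_sequences <- function(ds, max_len = 99) {
  stopifnot(inherits(ds, "seq_dataset"))
  if (any(!nzchar(ds$seq)))
    stop("empty sequence for id: ", ds$id[which(!nzchar(ds$seq))[1]])
  lens <- nchar(ds$seq)
  if (any(lens > max_len)) {
    i <- which(lens > max_len)[1]
    stop("sequence '", ds$id[i], "' is ", lens[i], " bp, exceeds max_len = ",
         max_len)
  }
  clean <- gsub("[ACGTN]", "", ds$seq)
  if (any(nzchar(clean))) {
    i <- which(nzchar(clean))[1]
    stop("sequence '", ds$id[i], "' contains illegal character(s): ",
         paste(unique(seq_chars(clean[i])), collapse = ""))
  }
  n_frac <- vapply(ds$seq, function(s)
    sum(seq_chars(s) == "N") / nchar(s), numeric(1), USE.NAMES = FALSE)
  attr(ds, "n_fraction") <- n_frac
  invisible(ds)
}

#' Stratified train/test split
#'
#' Randomly partitions a labeled dataset into train and test subsets,
#' stratified by label so class ratios are preserved within one record per
#' class. Deterministic given `seed`.
#'
#' @param ds a fully labeled [seq_dataset()].
#' @param test_fraction fraction of each class assigned to the test set
#'   (strictly between 0 and 1; default 0.2).
#' @param seed integer seed.
#' @return List with elements `train` and `test`, both `seq_dataset`s.
#' @export
split_train_test <- function(ds, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(ds, "seq_dataset"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be strictly between 0 and 1")
  if (any(is.na(ds$label))) stop("all records must be labeled for splitting")
  cts <- table(ds$label)
  if (any(cts < 2))
    stop("cannot stratify: class '", names(cts)[which(cts < 2)[1]],
         "' has fewer than 2 members")
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(ds)), ds$label), function(idx) {
      n_test <- max(1L, min(length(idx) - 1L,
                            as.integer(round(length(idx) * test_fraction))))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = ds[-sort(test_idx), , drop = FALSE],
       test  = ds[sort(test_idx), , drop = FALSE])
}
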