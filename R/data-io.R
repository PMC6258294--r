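RNA_BASES <- c("A", "C", "G", "U")
MIRNA_LABELS <- c("positive", "negative", "unlabeled")

#' Normalise a raw nucleotide string to uppercase RNA
#'
#' Uppercases the string and converts thymine to uracil. Returns NA for
#' strings containing any character outside the DNA/RNA alphabet, so callers
#' can reject individual records rather than whole files.
#'
#' @param x character vector of raw sequences.
#' @return character vector over {A,C,G,U}, NA where a sequence was invalid.
#' @keywords internal
normalize_rna <- function(x) {
  out <- chartr("acgutT", "ACGUUU", x)
  bad <- grepl("[^ACGU]", out) | !nzchar(out)
  out[bad] <- NA_character_
  out
}

#' Construct a table of mature miRNA records
#'
#' The per-miRNA unit of the pipeline: one row per mature miRNA with its id,
#' normalised RNA sequence and class label, plus optional species, family and
#' abundance annotations.
#'
#' @param id non-empty character vector of identifiers.
#' @param sequence character vector of RNA sequences (already normalised).
#' @param label one of "positive", "negative", "unlabeled" (recycled).
#' @param species,family optional character annotations.
#' @param abundance optional non-negative numeric (read count or RPM).
#' @return data.frame with class \code{mirna_records}.
#' @export
mirna_records <- function(id, sequence, label = "unlabeled",
                          species = NA_character_, family = NA_character_,
                          abundance = NA_real_) {
  n <- length(sequence)
  stopifnot(length(id) == n)
  if (any(!nzchar(id)) || anyNA(id)) stop("record ids must be non-empty")
  label <- rep_len(as.character(label), n)
  if (!all(label %in% MIRNA_LABELS)) {
    stop("label must be one of: ", paste(MIRNA_LABELS, collapse = ", "))
  }
  if (any(grepl("[^ACGU]", sequence)) || anyNA(sequence)) {
    stop("sequences must be uppercase RNA (A/C/G/U); normalise first")
  }
  if (any(nchar(sequence) < 15)) {
    stop("mature miRNA sequences must be at least 15 nt")
  }
  abundance <- rep_len(as.numeric(abundance), n)
  if (any(abundance < 0, na.rm = TRUE)) stop("abundance must be >= 0")
  df <- data.frame(
    id = as.character(id), sequence = sequence, label = label,
    species = rep_len(as.character(species), n),
    family = rep_len(as.character(family), n),
    abundance = abundance,
    stringsAsFactors = FALSE
  )
  class(df) <- c("mirna_records", "data.frame")
  df
}

#' Read mature miRNA sequences from a FASTA file
#'
#' Reads a miRBase-style mature FASTA (header token before the first
#' whitespace becomes the id). Sequences are uppercased and T is converted to
#' U. Entries containing any other character are rejected individually and
#' reported via the \code{rejected} attribute.
#'
#' @param path path to a FASTA file.
#' @param label class label to assign to all records.
#' @return \code{mirna_records} data.frame; attribute \code{rejected} holds the
#'   ids of entries dropped for invalid characters.
#' @export
read_mirna_fasta <- function(path, label = "unlabeled") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>'): ", path)
  entry <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], entry[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  seqs <- seqs[as.character(seq_along(ids))]
  seqs[is.na(seqs)] <- ""
  norm <- normalize_rna(seqs)
  rejected <- ids[is.na(norm)]
  keep <- !is.na(norm)
  recs <- mirna_records(ids[keep], norm[keep], label = label)
  attr(recs, "rejected") <- rejected
  recs
}

#' Write records to a FASTA file
#'
#' @param records \code{mirna_records}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mirna_fasta <- function(records, path) {
  writeLines(paste0(">", records$id, "\n", records$sequence), path)
  invisible(path)
}

#' Read miRNA records from a delimited table
#'
#' Ingests supplementary-table-shaped delimited files with a header row
#' containing at least \code{id} and \code{sequence}, and optionally
#' \code{species}, \code{family} and \code{abundance}. The delimiter is
#' sniffed from the header (tab or comma).
#'
#' @param path path to a TSV/CSV file.
#' @param label class label for all rows.
#' @return \code{mirna_records} data.frame.
#' @export
read_sequence_table <- function(path, label) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  for (col in c("id", "sequence")) {
    if (!col %in% names(df)) stop("missing mandatory column: ", col)
  }
  seqs <- normalize_rna(df$sequence)
  if (anyNA(seqs)) {
    stop("invalid sequence characters in rows: ",
         paste(df$id[is.na(seqs)], collapse = ", "))
  }
  mirna_records(
    id = df$id, sequence = seqs, label = label,
    species = if ("species" %in% names(df)) df$species else NA_character_,
    family = if ("family" %in% names(df)) df$family else NA_character_,
    abundance = if ("abundance" %in% names(df)) df$abundance else NA_real_
  )
}

#' Remove duplicate sequences, keeping first occurrence
#'
#' @param records \code{mirna_records}.
#' @return records with unique sequences, input order preserved.
#' @export
deduplicate_records <- function(records) {
  records[!duplicated(records$sequence), , drop = FALSE]
}

#' Assemble a labeled positive/negative dataset
#'
#' Deduplicates each class and enforces that no sequence appears in both.
#'
#' @param positives,negatives \code{mirna_records}.
#' @return list with elements \code{positives} and \code{negatives}.
#' @export
labeled_dataset <- function(positives, negatives) {
  positives <- deduplicate_records(positives)
  negatives <- deduplicate_records(negatives)
  positives$label <- "positive"
  negatives$label <- "negative"
  overlap <- intersect(positives$sequence, negatives$sequence)
  if (length(overlap) > 0) {
    stop("sequences present in both classes: n = ", length(overlap))
  }
  structure(list(positives = positives, negatives = negatives),
            class = "labeled_dataset")
}

#' Build the unlabeled prediction pool
#'
#' Removes candidates whose sequence is already labeled (either class), keeps
#' only sequences of length >= 18 nt, deduplicates, and relabels as
#' "unlabeled".
#'
#' @param candidates \code{mirna_records}.
#' @param labeled \code{labeled_dataset}.
#' @param min_length minimum retained length in nt (inclusive).
#' @return \code{mirna_records} of unlabeled pool members.
#' @export
filter_unlabeled_pool <- function(candidates, labeled, min_length = 18L) {
  known <- c(labeled$positives$sequence, labeled$negatives$sequence)
  keep <- !(candidates$sequence %in% known) &
    nchar(candidates$sequence) >= min_length
  out <- deduplicate_records(candidates[keep, , drop = FALSE])
  out$label <- "unlabeled"
  out
}

#' Curate a negative (non-xenomiR) set from per-sample abundance tables
#'
#' For each sequencing sample, records are ranked by abundance and the lowest
#' 30\% (\code{floor(drop_fraction * n)} records) removed: rarely expressed
#' miRNAs are plausible false negatives, undetected in humans merely because
#' of low intake. Survivors from all samples are pooled (union), any sequence
#' present in the positive set is removed, and the result is deduplicated and
#' labeled negative. Abundance ties are broken by lexicographic sequence
#' order so the cut is deterministic.
#'
#' @param samples list of \code{mirna_records}, one per sequencing sample;
#'   every record must carry an abundance.
#' @param positives \code{mirna_records} of the positive class.
#' @param drop_fraction fraction of lowest-abundance records removed per
#'   sample (default 0.3).
#' @return \code{mirna_records} labeled "negative".
#' @export
curate_negatives <- function(samples, positives, drop_fraction = 0.3) {
  survivors <- lapply(samples, function(s) {
    if (anyNA(s$abundance)) stop("sample has records with missing abundance")
    n_drop <- floor(drop_fraction * nrow(s))
    ord <- order(s$abundance, s$sequence, decreasing = FALSE)
    drop_idx <- ord[seq_len(n_drop)]
    if (n_drop > 0) s[-drop_idx, , drop = FALSE] else s
  })
  pooled <- do.call(rbind, survivors)
  pooled <- pooled[!(pooled$sequence %in% positives$sequence), , drop = FALSE]
  pooled <- deduplicate_records(pooled)
  pooled$label <- "negative"
  rownames(pooled) <- NULL
  class(pooled) <- c("mirna_records", "data.frame")
  pooled
}
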