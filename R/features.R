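GAP_SYMBOL <- "-"
POSITION_WIDTH <- 24L
ONE_HOT_LENGTH <- 18L

#' All RNA k-mers in lexicographic order (A < C < G < U)
#' @param k motif length, 1..3.
#' @return character vector of length 4^k.
#' @keywords internal
all_kmers <- function(k) {
  out <- RNA_BASES
  for (i in seq_len(k - 1)) {
    out <- as.vector(t(outer(out, RNA_BASES, paste0)))
  }
  out
}

#' Seed region of a mature miRNA
#'
#' The seed region (nucleotides 2-8) is the primary target-recognition
#' segment of a mature miRNA.
#'
#' @param sequence RNA string of length >= 8.
#' @return the 7-nt seed substring.
#' @export
seed_region <- function(sequence) {
  if (nchar(sequence) < 8) stop("sequence shorter than 8 nt has no seed region")
  substr(sequence, 2L, 8L)
}

#' Sliding-window k-mer frequencies of an RNA sequence
#'
#' frequency(m) = number of length-k windows equal to m, divided by the
#' window count (length - k + 1). All 4^k motifs are reported (zeros
#' included) and the frequencies sum to 1.
#'
#' @param sequence RNA string.
#' @param k motif length in {1, 2, 3}.
#' @return named numeric vector over all 4^k motifs.
#' @export
kmer_frequencies <- function(sequence, k) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  n <- nchar(sequence)
  if (n < k) stop("sequence shorter than k")
  wins <- substring(sequence, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  counts <- table(factor(wins, levels = all_kmers(k)))
  freq <- as.numeric(counts) / (n - k + 1)
  names(freq) <- all_kmers(k)
  freq
}

#' Names of the full 129-feature schema, in stable order
#'
#' Order: length; 24 positional identities (pos01..pos24); 84 full-sequence
#' k-mer frequencies (4 one-mers, 16 two-mers, 64 three-mers, each
#' lexicographic); 20 seed-region k-mer frequencies (suffix "_seed").
#'
#' @return character vector of length 129.
#' @export
feature_schema <- function() {
  c("length",
    sprintf("pos%02d", seq_len(POSITION_WIDTH)),
    all_kmers(1), all_kmers(2), all_kmers(3),
    paste0(all_kmers(1), "_seed"), paste0(all_kmers(2), "_seed"))
}

#' Names of the 105 model features
#'
#' The classifier inputs: length plus all full-sequence and seed-region k-mer
#' frequencies. Positional identities are categorical and used only for
#' composition profiles, never as model inputs or in hypothesis tests.
#'
#' @return character vector of length 105.
#' @export
model_feature_names <- function() {
  setdiff(feature_schema(), sprintf("pos%02d", seq_len(POSITION_WIDTH)))
}

#' Extract the 129-feature encoding of one miRNA sequence
#'
#' @param sequence RNA string of length >= 8.
#' @return list of class \code{feature_vector} with components
#'   \code{length} (untruncated length in nt), \code{position_identity}
#'   (24 symbols over A/C/G/U/-, "-" marking positions beyond the sequence),
#'   \code{full_kmer_freq} (84 named frequencies over the full sequence) and
#'   \code{seed_kmer_freq} (20 named frequencies over the 7-nt seed).
#' @export
extract_features <- function(sequence) {
  n <- nchar(sequence)
  seed <- seed_region(sequence)
  chars <- strsplit(sequence, "")[[1]]
  pos <- rep(GAP_SYMBOL, POSITION_WIDTH)
  m <- min(n, POSITION_WIDTH)
  pos[seq_len(m)] <- chars[seq_len(m)]
  names(pos) <- sprintf("pos%02d", seq_len(POSITION_WIDTH))
  full <- c(kmer_frequencies(sequence, 1), kmer_frequencies(sequence, 2),
            kmer_frequencies(sequence, 3))
  seedf <- c(kmer_frequencies(seed, 1), kmer_frequencies(seed, 2))
  names(seedf) <- paste0(names(seedf), "_seed")
  structure(list(length = n, position_identity = pos,
                 full_kmer_freq = full, seed_kmer_freq = seedf),
            class = "feature_vector")
}

#' Numeric model-feature matrix for a set of records
#'
#' @param records \code{mirna_records}.
#' @return numeric matrix, one row per record (rownames = ids), 105 columns
#'   in \code{model_feature_names()} order.
#' @export
feature_matrix <- function(records) {
  stopifnot(nrow(records) > 0)
  rows <- lapply(records$sequence, function(s) {
    fv <- extract_features(s)
    c(length = fv$length, fv$full_kmer_freq, fv$seed_kmer_freq)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- records$id
  mat[, model_feature_names(), drop = FALSE]
}

#' Full 129-column feature table (for export)
#'
#' @param records \code{mirna_records}.
#' @return data.frame with an \code{id} column followed by the 129 named
#'   features in \code{feature_schema()} order; positional identities are
#'   characters, all other columns numeric.
#' @export
feature_table <- function(records) {
  mat <- feature_matrix(records)
  pos <- t(vapply(records$sequence,
                  function(s) extract_features(s)$position_identity,
                  character(POSITION_WIDTH)))
  df <- data.frame(id = records$id, length = mat[, "length"],
                   pos, stringsAsFactors = FALSE, row.names = NULL)
  df <- cbind(df, as.data.frame(mat[, setdiff(colnames(mat), "length"),
                                    drop = FALSE], row.names = NULL))
  stopifnot(identical(names(df)[-1], feature_schema()))
  df
}

#' One-hot encode the first L nucleotides of a sequence
#'
#' Position-major one-of-K coding with K = 4: per nucleotide the 4-bit block
#' is "0001" for A, "0010" for C, "0100" for G and "1000" for U. Sequences
#' shorter than L are padded with all-zero blocks at the end; longer
#' sequences are truncated at L.
#'
#' @param sequence non-empty RNA string.
#' @param L number of positions encoded (default 18).
#' @return integer vector of length L * 4.
#' @export
one_hot_encode <- function(sequence, L = ONE_HOT_LENGTH) {
  if (!nzchar(sequence)) stop("cannot encode an empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  if (any(!chars %in% RNA_BASES)) {
    stop("invalid symbol in sequence: ",
         paste(setdiff(chars, RNA_BASES), collapse = ","))
  }
  blocks <- rbind(A = c(0L, 0L, 0L, 1L), C = c(0L, 0L, 1L, 0L),
                  G = c(0L, 1L, 0L, 0L), U = c(1L, 0L, 0L, 0L))
  out <- integer(L * 4L)
  m <- min(length(chars), L)
  out[seq_len(m * 4L)] <- as.integer(t(blocks[chars[seq_len(m)], ,
                                              drop = FALSE]))
  out
}

#' Decode a one-hot vector back to its RNA prefix
#' @param bits integer vector of length L*4 as produced by
#'   \code{one_hot_encode}.
#' @return the encoded RNA prefix (padding blocks dropped).
#' @export
one_hot_decode <- function(bits) {
  stopifnot(length(bits) %% 4 == 0)
  mat <- matrix(bits, ncol = 4, byrow = TRUE)
  nz <- rowSums(mat) > 0
  if (!any(nz)) return("")
  codes <- apply(mat[nz, , drop = FALSE], 1, paste0, collapse = "")
  map <- c("0001" = "A", "0010" = "C", "0100" = "G", "1000" = "U")
  paste0(map[codes], collapse = "")
}

#' One-hot matrix for a set of records
#' @param records \code{mirna_records}.
#' @param L positions encoded per sequence (default 18).
#' @return integer matrix n x (L*4), rownames = ids.
#' @export
one_hot_matrix <- function(records, L = ONE_HOT_LENGTH) {
  mat <- t(vapply(records$sequence, one_hot_encode, integer(L * 4L), L = L))
  rownames(mat) <- records$id
  mat
}
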