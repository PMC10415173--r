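#' All k-mer words in lexicographic order
#'
#' The canonical feature ordering of the 4^k k-mer features: lexicographic
#' with A < C < G < T, i.e. the word at position `i` has [kmer_index()]
#' `i - 1`.
#'
#' @param k Word length (1 to 8).
#' @return Character vector of length 4^k.
#' @export
kmer_words <- function(k) {
  check_k(k)
  idx <- 0:(4L^k - 1L)
  word <- matrix("", length(idx), k)
  v <- idx
  for (pos in k:1) {
    word[, pos] <- DNA_BASES[v %% 4L + 1L]
    v <- v %/% 4L
  }
  apply(word, 1L, paste0, collapse = "")
}

#' Lexicographic rank of a k-mer
#'
#' Maps a DNA word to its 0-based lexicographic rank with A < C < G < T
#' (the base-4 value with A=0, C=1, G=2, T=3). This is the column index
#' (minus one) of the word in a profile matrix.
#'
#' @param word A character vector of words over \{A,C,G,T\} (all the same
#'   length).
#' @return Integer vector of ranks in `[0, 4^k)`.
#' @examples
#' kmer_index(c("AAA", "ACG", "TTT"))
#' @export
kmer_index <- function(word) {
  stopifnot(is.character(word), length(word) >= 1)
  k <- unique(nchar(word))
  if (length(k) != 1) {
    kb_stop("all words must have the same length", "kbalance_type_error")
  }
  check_k(k)
  chars <- strsplit(toupper(word), "", fixed = TRUE)
  vapply(chars, function(ch) {
    v <- match(ch, DNA_BASES) - 1L
    if (anyNA(v)) {
      kb_stop(paste0("ambiguous character in k-mer '", paste(ch, collapse = ""),
                     "': only A,C,G,T are indexable"),
              "kbalance_alphabet_error")
    }
    sum(v * 4L^((k - 1L):0L))
  }, 0) |> as.integer()
}

check_k <- function(k, max_k = 8L) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != round(k)) {
    kb_stop("`k` must be a single positive integer", "kbalance_type_error")
  }
  if (k > max_k) {
    kb_stop(paste0("`k` = ", k, " exceeds the ceiling of ", max_k,
                   " (4^k features would be ", 4^k, ")"),
            "kbalance_type_error")
  }
  invisible(as.integer(k))
}

#' Relative k-mer frequency profile of a single sequence
#'
#' Slides a window of width `k` along the sequence with step 1. Windows
#' containing any non-ACGT character are skipped; each remaining word is
#' counted and counts are divided by the number of counted (valid) windows,
#' so a valid profile lies on the probability simplex.
#'
#' @param sequence A single DNA sequence string.
#' @param k Word length.
#' @return A named numeric vector of length 4^k (names are [kmer_words()]),
#'   with attribute `valid_windows` giving the number of counted windows.
#'   A sequence shorter than `k`, or with no valid window, is an error of
#'   class `kbalance_invalid_profile`.
#' @examples
#' kmer_profile("ACGT", k = 3)
#' @export
kmer_profile <- function(sequence, k = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  k <- check_k(k)
  counts <- kmer_count_matrix(sequence, k)
  total <- sum(counts[1L, ])
  if (total == 0) {
    kb_stop(
      paste0("no valid k-mer window (length ", nchar(sequence),
             ", k = ", k, ")"),
      "kbalance_invalid_profile"
    )
  }
  values <- counts[1L, ] / total
  attr(values, "valid_windows") <- as.integer(total)
  values
}

# counts via Biostrings; step-1 windows with ambiguity codes match no word
# and so are excluded from both numerator and denominator
kmer_count_matrix <- function(sequences, k) {
  seqs <- normalize_dna(sequences)
  padded <- ifelse(nchar(seqs) < k, strrep("N", k), seqs)  # short -> 0 windows
  d <- Biostrings::DNAStringSet(padded)
  m <- Biostrings::oligonucleotideFrequency(d, width = k, step = 1)
  colnames(m) <- kmer_words(k)
  m
}

#' k-mer profiles for a set of sequences
#'
#' Computes the relative k-mer frequency profile of every record and returns
#' them as a tibble: one row per record with a valid profile, `id` (and
#' `label`, if present) followed by `valid_windows` and the 4^k k-mer
#' columns in lexicographic order. Records with no valid window (too short,
#' or all windows ambiguous) are dropped with a message; their IDs are kept
#' in the `dropped` attribute.
#'
#' @param data A tibble with columns `id` and `sequence` (and optionally
#'   `label`), e.g. from [read_fasta()] or [generate_dataset()].
#' @param k Word length (default 3, i.e. 64 features).
#' @return A tibble of profiles with attributes `k`, `kmers` (feature
#'   column names) and `dropped` (IDs of invalid records).
#' @export
kmer_profiles <- function(data, k = 3L) {
  check_seq_tbl(data)
  k <- check_k(k)
  if (nrow(data) == 0) {
    kb_stop("no input records", "kbalance_empty_input")
  }
  counts <- kmer_count_matrix(data$sequence, k)
  totals <- rowSums(counts)
  keep <- totals > 0
  if (!any(keep)) {
    kb_stop("all records have zero valid k-mer windows", "kbalance_invalid_profile")
  }
  dropped <- data$id[!keep]
  if (length(dropped) > 0) {
    inform(paste0("dropped ", length(dropped),
                  " record(s) with no valid k-mer window: ",
                  paste(head(dropped, 5), collapse = ", ")))
  }
  values <- counts[keep, , drop = FALSE] / totals[keep]
  out <- tibble(id = data$id[keep])
  if ("label" %in% names(data)) out$label <- data$label[keep]
  out$valid_windows <- as.integer(totals[keep])
  out <- dplyr::bind_cols(out, as_tibble(values))
  attr(out, "k") <- k
  attr(out, "kmers") <- colnames(values)
  attr(out, "dropped") <- dropped
  out
}

#' Extract the numeric feature matrix from a profile tibble
#'
#' @param profiles A profile tibble from [kmer_profiles()], or any data
#'   frame whose k-mer columns are named by DNA words (all other columns
#'   are treated as metadata), or a plain numeric matrix (returned as is).
#' @return A numeric matrix (rows = records, columns = k-mer features),
#'   with row names taken from `id` when available.
#' @export
profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    storage.mode(profiles) <- "double"
    return(profiles)
  }
  stopifnot(is.data.frame(profiles))
  feat <- profile_feature_names(profiles)
  m <- as.matrix(profiles[feat])
  if ("id" %in% names(profiles)) rownames(m) <- profiles$id
  m
}

profile_feature_names <- function(profiles) {
  feat <- attr(profiles, "kmers")
  if (is.null(feat)) {
    feat <- grep("^[ACGT]+$", names(profiles), value = TRUE)
  }
  if (length(feat) == 0) {
    kb_stop("no k-mer feature columns found", "kbalance_type_error")
  }
  feat
}

#' Write / read a profile matrix as TSV
#'
#' The TSV has a header row of k-mer words in lexicographic order after the
#' leading `id` (and optional `label`, `valid_windows`) columns; values are
#' written with 10 significant digits.
#'
#' @param profiles A profile tibble from [kmer_profiles()].
#' @param path Output (input) file path.
#' @return `path` invisibly; for `read_profiles`, the profile tibble.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.data.frame(profiles))
  feat <- profile_feature_names(profiles)
  out <- profiles
  out[feat] <- lapply(out[feat], function(v) signif(v, 10))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  feat <- grep("^[ACGT]+$", names(out), value = TRUE)
  if (length(feat) == 0 || length(unique(nchar(feat))) != 1) {
    kb_stop(paste0("'", path, "' is not a k-mer profile table"),
            "kbalance_parse_error")
  }
  k <- unique(nchar(feat))
  if (!identical(feat, kmer_words(k))) {
    kb_stop("profile columns are not the full lexicographic k-mer set",
            "kbalance_parse_error")
  }
  attr(out, "k") <- as.integer(k)
  attr(out, "kmers") <- feat
  out
}
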