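#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a tibble of sequence
#' records. Sequence IDs are the header token up to the first whitespace.
#' Sequences are upper-cased and RNA `U` is folded to `T`; any character
#' outside the IUPAC nucleotide alphabet is an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, one row per record,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", ">s2", "TTTTAAAA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  seqs <- read_xstringset(path, format = "fasta")
  as_seq_tbl(seqs, path)
}

#' Read DNA sequences from a FASTQ file
#'
#' Quality strings are discarded; only IDs and sequences are kept, with the
#' same normalisation as [read_fasta()].
#'
#' @inheritParams read_fasta
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- read_xstringset(path, format = "fastq")
  as_seq_tbl(seqs, path)
}

read_xstringset <- function(path, format) {
  if (!file.exists(path)) {
    kb_stop(paste0("file not found: ", path), "kbalance_io_error")
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      kb_stop(
        paste0("failed to parse ", format, " file '", path, "': ",
               conditionMessage(e), first_bad_line(path, format)),
        "kbalance_parse_error"
      )
    }
  )
  if (length(seqs) == 0) {
    kb_stop(paste0("no records in ", format, " file '", path, "' (line 1)"),
            "kbalance_parse_error")
  }
  seqs
}

# best-effort line diagnostic for parse failures
first_bad_line <- function(path, format) {
  lines <- tryCatch(readLines(path, n = 1000L, warn = FALSE),
                    error = function(e) character(0))
  if (length(lines) == 0) return(" (empty file, line 1)")
  if (format == "fasta" && !startsWith(trimws(lines[[1]]), ">")) {
    return(" (expected '>' header at line 1)")
  }
  ""
}

as_seq_tbl <- function(seqs, path) {
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) {
    kb_stop(paste0("empty sequence ID in '", path, "'"), "kbalance_parse_error")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    kb_stop(
      paste0("duplicate sequence ID(s) in '", path, "': ",
             paste(dup, collapse = ", ")),
      "kbalance_duplicate_id_error"
    )
  }
  sequence <- normalize_dna(unname(as.character(seqs)), what = path)
  tibble(id = ids, sequence = sequence)
}

normalize_dna <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), x)
  if (any(bad)) {
    kb_stop(
      paste0("non-IUPAC characters in ", what, " (record ",
             which(bad)[[1]], ")"),
      "kbalance_alphabet_error"
    )
  }
  if (any(nchar(x) < 1)) {
    kb_stop(paste0("zero-length sequence in ", what), "kbalance_parse_error")
  }
  x
}

#' Write sequence records to a FASTA file
#'
#' @param data A tibble with columns `id` and `sequence` (as returned by
#'   [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 70L) {
  check_seq_tbl(data)
  s <- Biostrings::BStringSet(data$sequence)
  names(s) <- data$id
  Biostrings::writeXStringSet(s, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a sequence-ID to taxon-label table
#'
#' Reads a two-or-more-column TSV mapping sequence IDs to taxon labels at a
#' single rank. A first line starting with `#`, or equal to `id<TAB>label`,
#' is treated as a header. Extra columns are ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    kb_stop(paste0("file not found: ", path), "kbalance_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    kb_stop(paste0("empty label file '", path, "'"), "kbalance_parse_error")
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- startsWith(lines[[1]], "#") ||
    identical(tolower(first[seq_len(min(2, length(first)))]), c("id", "label"))
  rows <- if (has_header) lines[-1] else lines
  if (length(rows) == 0) {
    kb_stop(paste0("no data rows in label file '", path, "'"),
            "kbalance_parse_error")
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  offset <- if (has_header) 1L else 0L
  bad <- which(vapply(parts, length, 1L) < 2L |
                 !nzchar(vapply(parts, function(p) trimws(p[1] %||% ""), "")) |
                 !nzchar(vapply(parts, function(p) trimws(p[2] %||% ""), "")))
  if (length(bad) > 0) {
    kb_stop(
      paste0("missing id or label in '", path, "' at row ", bad[[1]] + offset),
      "kbalance_parse_error"
    )
  }
  out <- tibble(
    id = vapply(parts, function(p) trimws(p[[1]]), ""),
    label = vapply(parts, function(p) trimws(p[[2]]), "")
  )
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0) {
    kb_stop(paste0("duplicate IDs in label file: ", paste(dup, collapse = ", ")),
            "kbalance_duplicate_id_error")
  }
  out
}

#' Attach taxon labels to sequence records
#'
#' Joins a label table onto sequence records by `id`. The join is total:
#' a record without a label is an error, so downstream code can rely on a
#' complete `label` column.
#'
#' @param data A tibble with an `id` column (sequences or profiles).
#' @param labels A tibble with columns `id` and `label`, from [read_labels()].
#' @return `data` with a `label` column appended.
#' @export
join_labels <- function(data, labels) {
  stopifnot(is.data.frame(data), is.data.frame(labels))
  idx <- match(data$id, labels$id)
  if (anyNA(idx)) {
    missing <- data$id[which(is.na(idx))]
    kb_stop(
      paste0("no label for record(s): ",
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) paste0(" (and ", length(missing) - 5, " more)")),
      "kbalance_join_error"
    )
  }
  dplyr::mutate(data, label = labels$label[idx])
}

#' Cut sequences into fixed-length fragments
#'
#' Each sequence is cut into consecutive, non-overlapping windows of exactly
#' `length` nucleotides; a trailing remainder shorter than `length` is
#' dropped. Fragment IDs are `"<parent id>:<start>-<end>"` with 0-based
#' half-open coordinates. A record shorter than `length` yields no fragments.
#'
#' @param data A tibble with columns `id` and `sequence`; an optional
#'   `label` column is carried through to the fragments.
#' @param length Fragment length in nucleotides (default 1500, the sample
#'   length the pipeline is designed around).
#' @return A tibble of fragments with columns `id`, `sequence` (and `label`
#'   if present in the input).
#' @export
fragment_sequences <- function(data, length = 1500L) {
  check_seq_tbl(data)
  stopifnot(length >= 1)
  length <- as.integer(length)
  n_frag <- nchar(data$sequence) %/% length
  rows <- rep.int(seq_len(nrow(data)), n_frag)
  if (length(rows) == 0) {
    out <- tibble(id = character(0), sequence = character(0))
    if ("label" %in% names(data)) out$label <- character(0)
    return(out)
  }
  frag_i <- sequence(n_frag) - 1L    # 0-based fragment index within parent
  start <- frag_i * length           # 0-based half-open coordinates
  end <- start + length
  out <- tibble(
    id = paste0(data$id[rows], ":", start, "-", end),
    sequence = substring(data$sequence[rows], start + 1L, end)
  )
  if ("label" %in% names(data)) out$label <- data$label[rows]
  out
}

check_seq_tbl <- function(data) {
  if (!is.data.frame(data) || !all(c("id", "sequence") %in% names(data))) {
    kb_stop("expected a data frame with columns `id` and `sequence`",
            "kbalance_type_error")
  }
  invisible(data)
}
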