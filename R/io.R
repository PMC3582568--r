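#' Read a small-RNA FASTQ file
#'
#' Reads Phred+33 FASTQ into a read table. Sequences are uppercased and U is
#' normalized to T so that all internal sequences use the DNA alphabet.
#'
#' @param path FASTQ file path.
#' @return tibble with columns `id`, `sequence`, `qualities` (Phred+33
#'   string, same length as the sequence).
#' @export
read_srna_fastq <- function(path) {
  parsed <- tryCatch({
    reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
    # quality extraction can also fail on malformed records, so it lives
    # inside the same tryCatch as the parse itself
    list(reads = reads,
         quals = as.character(S4Vectors::mcols(reads)$qualities))
  },
  error = function(e) {
    bad <- fastq_bad_line(path)
    if (!is.na(bad)) {
      stop("malformed FASTQ record in ", path, " near line ", bad,
           call. = FALSE)
    }
    stop("failed to parse FASTQ ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  tibble::tibble(
    id = names(parsed$reads),
    sequence = unname(normalize_seq(as.character(parsed$reads))),
    qualities = unname(parsed$quals)
  )
}

# locate the first structurally broken 4-line FASTQ record
fastq_bad_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    if (!startsWith(lines[i], "@")) return(i)
    if (i + 3L > n) return(i)
    if (!startsWith(lines[i + 2L], "+")) return(i + 2L)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) return(i + 3L)
    i <- i + 4L
  }
  NA_integer_
}

#' Read a small-RNA FASTA file
#'
#' @param path FASTA file path.
#' @return tibble with columns `id`, `sequence`, `qualities` (`NA`: FASTA
#'   carries no base qualities, so quality filtering is skipped downstream).
#' @export
read_srna_fasta <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble::tibble(
    id = names(reads),
    sequence = normalize_seq(as.character(reads)),
    qualities = NA_character_
  )
}

#' Clean raw small-RNA reads: adapter trimming and filtering
#'
#' The 3' adapter is removed at the leftmost exact match of the first
#' `seed_len` (default 7) bases of `adapter3`; everything from the match on
#' is discarded. Reads are then dropped when the trimmed sequence contains N,
#' when any remaining base quality is below `min_quality` (only when
#' qualities are present), or when the trimmed length falls outside
#' `[min_len, max_len]`. Input order is preserved.
#'
#' @param reads tibble from [read_srna_fastq()] / [read_srna_fasta()].
#' @param adapter3 3' adapter sequence (at least `seed_len` nt).
#' @param min_quality minimum per-base Phred score (default 20).
#' @param min_len,max_len post-trim length bounds (defaults 14 and 30 nt,
#'   the insert size range of single-end small-RNA protocols).
#' @param seed_len length of the exact adapter prefix used as match seed.
#' @return tibble of retained reads (`id`, `sequence`, `qualities`), with
#'   attribute `n_input` recording the input read count.
#' @export
clean_reads <- function(reads, adapter3, min_quality = 20, min_len = 14,
                        max_len = 30, seed_len = 7) {
  stopifnot(min_len <= max_len, nzchar(adapter3))
  adapter3 <- normalize_seq(adapter3)
  if (nchar(adapter3) < seed_len) {
    stop("adapter3 must be at least seed_len (", seed_len, ") nt")
  }
  seed <- substr(adapter3, 1, seed_len)
  seqs <- normalize_seq(reads$sequence)
  hit <- regexpr(seed, seqs, fixed = TRUE)
  trim_to <- ifelse(hit > 0, hit - 1L, nchar(seqs))
  trimmed <- substr(seqs, 1L, trim_to)
  quals <- reads$qualities
  tq <- ifelse(is.na(quals), NA_character_, substr(quals, 1L, trim_to))
  len <- nchar(trimmed)
  ok_len <- len >= min_len & len <= max_len
  ok_n <- !grepl("N", trimmed, fixed = TRUE)
  ok_q <- vapply(tq, function(q) {
    if (is.na(q) || !nzchar(q)) return(TRUE)
    min(utf8ToInt(q)) - 33L >= min_quality
  }, logical(1), USE.NAMES = FALSE)
  keep <- ok_len & ok_n & ok_q
  out <- tibble::tibble(id = reads$id[keep], sequence = trimmed[keep],
                        qualities = tq[keep])
  attr(out, "n_input") <- nrow(reads)
  out
}

#' Collapse cleaned reads into unique sequence tags
#'
#' One row per distinct sequence across all libraries, with one raw-count
#' column per library. Per-library column sums equal the cleaned read counts
#' (conservation).
#'
#' @param libraries named list: library id -> cleaned read tibble (or a
#'   character vector of sequences).
#' @return tibble with columns `sequence`, `length` and one integer count
#'   column per library, ordered by decreasing total count then sequence.
#' @export
collapse_tags <- function(libraries) {
  stopifnot(length(libraries) > 0, !is.null(names(libraries)))
  seqs_by_lib <- lapply(libraries, function(x) {
    if (is.data.frame(x)) x$sequence else as.character(x)
  })
  empty <- vapply(seqs_by_lib, length, integer(1)) == 0
  if (any(empty)) {
    warning("empty library: ", paste(names(libraries)[empty], collapse = ", "))
  }
  long <- dplyr::bind_rows(lapply(names(seqs_by_lib), function(lib) {
    s <- seqs_by_lib[[lib]]
    if (!length(s)) return(NULL)
    dplyr::count(tibble::tibble(library = lib, sequence = s),
                 .data$library, .data$sequence, name = "count")
  }))
  if (is.null(long) || !nrow(long)) {
    out <- tibble::tibble(sequence = character(), length = integer())
    for (lib in names(libraries)) out[[lib]] <- integer()
    return(out)
  }
  wide <- tidyr::pivot_wider(long, names_from = "library",
                             values_from = "count", values_fill = 0L)
  for (lib in names(libraries)) {
    if (!lib %in% names(wide)) wide[[lib]] <- 0L
  }
  wide <- wide[, c("sequence", names(libraries))]
  wide$length <- nchar(wide$sequence)
  wide <- wide[, c("sequence", "length", names(libraries))]
  tot <- rowSums(as.matrix(wide[, names(libraries), drop = FALSE]))
  wide[order(-tot, wide$sequence), ]
}

#' Library ids of a tag table
#'
#' @param tags tag tibble from [collapse_tags()].
#' @return character vector of library column names.
#' @export
tag_libraries <- function(tags) {
  setdiff(names(tags), c("sequence", "length"))
}

#' Read length distribution of a library
#'
#' Raw counts weight each tag by its library count; unique counts weight
#' each detected tag by one. The redundancy ratio (raw/unique) highlights
#' length classes dominated by highly expressed sequences (21-nt miRNAs)
#' versus diverse ones (24-nt siRNAs).
#'
#' @param tags tag tibble from [collapse_tags()].
#' @param library library id (a count column of `tags`).
#' @return tibble with `length`, `raw`, `unique`, `redundancy`.
#' @export
length_distribution <- function(tags, library) {
  stopifnot(library %in% tag_libraries(tags))
  dat <- tags[tags[[library]] > 0, ]
  out <- dat |>
    dplyr::group_by(length = .data$length) |>
    dplyr::summarise(raw = sum(.data[[library]]), unique = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(redundancy = .data$raw / .data$unique) |>
    dplyr::arrange(.data$length)
  out
}

#' Write tags of one library as collapsed FASTA
#'
#' Header dialect: `>t<serial>_x<count>`, serial numbers assigned in table
#' order over tags with a positive count in the library.
#'
#' @param tags tag tibble.
#' @param path output path.
#' @param library library id.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path, library) {
  stopifnot(library %in% tag_libraries(tags))
  dat <- tags[tags[[library]] > 0, ]
  set <- Biostrings::DNAStringSet(dat$sequence)
  names(set) <- sprintf("t%d_x%d", seq_len(nrow(dat)), dat[[library]])
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read collapsed FASTA back into a tag table
#'
#' @param path collapsed FASTA path (headers `t<serial>_x<count>`).
#' @param library library id for the count column.
#' @return tag tibble with columns `sequence`, `length`, `<library>`.
#' @export
read_collapsed_fasta <- function(path, library = "library1") {
  set <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub("^t[0-9]+_x([0-9]+).*$", "\\1", names(set)))
  if (anyNA(counts)) stop("header not in t<serial>_x<count> dialect")
  seqs <- unname(as.character(set))
  out <- tibble::tibble(sequence = seqs, length = nchar(seqs))
  out[[library]] <- counts
  out
}

#' Write/read a tag table as TSV
#'
#' @param tags tag tibble.
#' @param path TSV path.
#' @return `path` (write) or the tag tibble (read).
#' @export
write_tag_table <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  tibble::as_tibble(read.delim(path, check.names = FALSE,
                               stringsAsFactors = FALSE))
}
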