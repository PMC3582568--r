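#' Coerce a reference set to a named sequence vector
#'
#' @param x named character vector, `DNAStringSet`, FASTA path or a tibble
#'   with `id`/`sequence` columns.
#' @return named uppercase DNA character vector.
#' @export
as_reference <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      is.null(names(x))) {
    set <- Biostrings::readDNAStringSet(x)
    out <- normalize_seq(as.character(set))
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- normalize_seq(as.character(x))
    names(out) <- names(x)
    return(out)
  }
  if (is.data.frame(x)) {
    out <- normalize_seq(x$sequence)
    names(out) <- if ("id" %in% names(x)) x$id else x$name
    return(out)
  }
  out <- normalize_seq(x)
  if (is.null(names(out)) && length(out)) {
    names(out) <- paste0("ref_", seq_along(out))
  }
  out
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Assign each tag to an RNA class with a fixed precedence
#'
#' A tag matching a reference of class C as an exact substring (either
#' strand) is assigned the earliest matching class in `precedence`; tags
#' matching no reference are `"unannotated"` (the mappable pool carried
#' forward to miRNA identification).
#'
#' @param tags tag tibble from [collapse_tags()].
#' @param refs named list: class label -> reference set (see
#'   [as_reference()]).
#' @param precedence ordered class labels covering `names(refs)`.
#' @return the tag tibble with `class` and `ref_id` columns appended.
#' @export
classify_tags <- function(tags,
                          refs,
                          precedence = c("rRNA", "tRNA", "snRNA", "snoRNA",
                                         "repeat", "mRNA")) {
  stopifnot(setequal(names(refs), intersect(precedence, names(refs))),
            all(names(refs) %in% precedence),
            anyDuplicated(precedence) == 0)
  refs <- lapply(refs, as_reference)
  for (cl in names(refs)) {
    if (!length(refs[[cl]])) stop("empty reference set for class ", cl)
  }
  order_cl <- intersect(precedence, names(refs))
  class <- rep("unannotated", nrow(tags))
  ref_id <- rep(NA_character_, nrow(tags))
  seqs <- tags$sequence
  rcs <- if (nrow(tags)) revcomp(seqs) else character()
  for (cl in order_cl) {
    rv <- refs[[cl]]
    todo <- which(class == "unannotated")
    if (!length(todo)) break
    for (i in todo) {
      hit <- which(grepl(seqs[i], rv, fixed = TRUE) |
                     grepl(rcs[i], rv, fixed = TRUE))
      if (length(hit)) {
        class[i] <- cl
        ref_id[i] <- names(rv)[hit[1]]
      }
    }
  }
  out <- tags
  out$class <- class
  out$ref_id <- ref_id
  out
}

#' Per-class raw and unique totals (RNA-class accounting table)
#'
#' Reproduces the accounting identity: per library, class totals plus the
#' unannotated (mappable) pool sum to the library total.
#'
#' @param assignments output of [classify_tags()].
#' @return tibble with `class` and, per library, `raw_<lib>` and
#'   `unique_<lib>` columns; includes a `total` row.
#' @export
class_totals <- function(assignments) {
  libs <- setdiff(tag_libraries(assignments), c("class", "ref_id"))
  per_class <- assignments |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(libs),
      list(raw = ~sum(.x), unique = ~sum(.x > 0)),
      .names = "{.fn}_{.col}"
    ), .groups = "drop")
  total <- assignments |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(libs),
      list(raw = ~sum(.x), unique = ~sum(.x > 0)),
      .names = "{.fn}_{.col}"
    ))
  total$class <- "total"
  dplyr::bind_rows(total, per_class)
}

#' Derive the miRNA family from a miRNA id
#'
#' Strips the trailing lowercase variant suffix (`miR398a` -> `miR398`),
#' keeping ids listed in `exceptions` as their own family (miRBase treats
#' e.g. miR166l as a distinct family label in this dataset).
#'
#' @param id character vector of miRNA ids.
#' @param exceptions ids returned unchanged.
#' @return character vector of family labels.
#' @export
mirna_family <- function(id, exceptions = c("miR166l")) {
  fam <- ifelse(id %in% exceptions, id,
                sub("^((?:[a-z]{3}-)?miR[0-9]+)[a-z]*$", "\\1", id))
  fam
}

#' Identify known miRNAs by bounded-mismatch matching
#'
#' A tag is reported as a known miRNA when it aligns end-to-end to a mature
#' miRNA sequence with at most `max_mismatch` substitutions after allowing at
#' most `max_end_diff` nt of total terminal trimming/extension. Each tag maps
#' to at most one miRNA id: fewest substitutions, ties broken to the
#' lexicographically smallest id. Only tags of 15-26 nt are considered.
#'
#' @param tags tag tibble (typically the unannotated pool).
#' @param mature_db mature miRNA reference (see [as_reference()]); names are
#'   miRNA ids.
#' @param max_mismatch maximum substitutions (default 1).
#' @param max_end_diff maximum total terminal trimming/extension in nt
#'   (default 2).
#' @param family_exceptions passed to [mirna_family()].
#' @return tibble of hits: tag columns plus `mirna_id`, `family`,
#'   `mismatches`.
#' @export
match_known_mirnas <- function(tags, mature_db, max_mismatch = 1,
                               max_end_diff = 2,
                               family_exceptions = c("miR166l")) {
  mature <- as_reference(mature_db)
  dat <- tags[tags$length >= 15 & tags$length <= 26, , drop = FALSE]
  if (!nrow(dat)) {
    out <- dat
    out$mirna_id <- character(0)
    out$family <- character(0)
    out$mismatches <- integer(0)
    return(out)
  }
  m <- .match_mature_cpp(dat$sequence, unname(mature), names(mature),
                         as.integer(max_mismatch), as.integer(max_end_diff))
  hit <- m[, 1] > 0
  out <- dat[hit, , drop = FALSE]
  out$mirna_id <- names(mature)[m[hit, 1]]
  out$family <- mirna_family(out$mirna_id, exceptions = family_exceptions)
  out$mismatches <- m[hit, 2]
  out
}

#' Map a tag to its perfect-match genome loci
#'
#' All perfect-match occurrences on both strands, 0-based half-open
#' coordinates.
#'
#' @param sequences character vector of tag sequences.
#' @param genome genome reference (see [as_reference()]).
#' @return tibble with `sequence`, `contig`, `start`, `end`, `strand`.
#' @export
map_to_genome <- function(sequences, genome) {
  genome <- as_reference(genome)
  stopifnot(length(genome) > 0)
  subjects <- lapply(genome, Biostrings::DNAString)
  out <- list()
  for (s in unique(sequences)) {
    pat_f <- Biostrings::DNAString(s)
    pat_r <- Biostrings::reverseComplement(pat_f)
    for (ctg in names(subjects)) {
      mf <- Biostrings::matchPattern(pat_f, subjects[[ctg]])
      if (length(mf)) {
        out[[length(out) + 1]] <- tibble::tibble(
          sequence = s, contig = ctg,
          start = BiocGenerics::start(mf) - 1L,
          end = BiocGenerics::end(mf), strand = "+")
      }
      mr <- Biostrings::matchPattern(pat_r, subjects[[ctg]])
      if (length(mr)) {
        out[[length(out) + 1]] <- tibble::tibble(
          sequence = s, contig = ctg,
          start = BiocGenerics::start(mr) - 1L,
          end = BiocGenerics::end(mr), strand = "-")
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sequence = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$sequence, .data$contig,
                 .data$start, .data$strand)
}

#' Summarize known-miRNA presence across libraries
#'
#' Detection in a library means a positive raw count. Families are counted
#' as distinct `family` labels (derived with [mirna_family()] when absent).
#'
#' @param known tibble with a miRNA id column (`name` or `mirna_id`),
#'   optionally `family`, plus one count column per library.
#' @param libraries count columns; default: all numeric columns other than
#'   `length`/`mismatches`.
#' @return one-row tibble: `n_mirnas`, `n_families`, one `detected_<lib>`
#'   column per library, `n_in_at_least_two`, `n_shared_all`.
#' @export
summarize_presence <- function(known, libraries = NULL) {
  idcol <- intersect(c("name", "mirna_id", "id"), names(known))[1]
  if (is.na(idcol)) stop("no miRNA id column (name/mirna_id/id)")
  if (is.null(libraries)) {
    num <- names(known)[vapply(known, is.numeric, logical(1))]
    libraries <- setdiff(num, c("length", "mismatches"))
  }
  cm <- as.matrix(known[, libraries, drop = FALSE])
  stopifnot(all(cm >= 0))
  fam <- if ("family" %in% names(known)) known$family else
    mirna_family(known[[idcol]])
  det <- cm > 0
  npos <- rowSums(det)
  out <- tibble::tibble(n_mirnas = nrow(known),
                        n_families = length(unique(fam)))
  for (lib in libraries) out[[paste0("detected_", lib)]] <- sum(det[, lib])
  out$n_in_at_least_two <- sum(npos >= 2)
  out$n_shared_all <- sum(npos == length(libraries))
  out
}

#' Packaged table of conserved watermelon miRNAs
#'
#' The published count matrix of 39 conserved miRNAs (30 families) across
#' the three graft-combination libraries (Wm_Wm: self-grafted control;
#' Wm_BG: bottle gourd rootstock; Wm_Sq: squash rootstock), used as a worked
#' example and as the fixture for presence summaries.
#'
#' @return tibble with `family`, `name`, `sequence`, `length`, and raw
#'   counts `Wm_Wm`, `Wm_BG`, `Wm_Sq`.
#' @export
conserved_mirna_table <- function() {
  path <- system.file("extdata", "conserved_mirnas_watermelon.tsv",
                      package = "clamir")
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Write genome loci as GFF3
#'
#' @param loci tibble from [map_to_genome()] (0-based half-open), optionally
#'   with `id` and `type` columns.
#' @param path output path.
#' @param source source field (default "clamir").
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path, source = "clamir") {
  type <- if ("type" %in% names(loci)) loci$type else "miRNA"
  id <- if ("id" %in% names(loci)) loci$id else loci$sequence
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$contig, source, type,
                     loci$start + 1L, loci$end, loci$strand, id))
  writeLines(lines, path)
  invisible(path)
}
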