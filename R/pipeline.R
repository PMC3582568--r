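#' Build or validate a pipeline configuration
#'
#' A configuration names the library FASTQ files, the reference files, the
#' control library and the analysis thresholds. It can be given as a named
#' list or a YAML file with the same fields.
#'
#' @param libraries named character: library id -> FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param control control library id (must be in `names(libraries)`).
#' @param genome genome FASTA path (required; novel calling needs it).
#' @param references named character: RNA class -> FASTA path. Classes must
#'   be drawn from the precedence order.
#' @param mature mature-miRNA FASTA path (`NULL` to skip known matching).
#' @param transcripts transcript FASTA path (`NULL` to skip targets).
#' @param out output directory.
#' @param precedence RNA-class precedence used by [classify_tags()].
#' @param thresholds named list overriding defaults: `mfei`, `min_reads`,
#'   `p`, `min_log2fc`, `target_cutoff`, plus any [criteria_thresholds()]
#'   field.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated config (class `clamir_pipeline_config`).
#' @export
pipeline_config <- function(libraries, adapter, control, genome,
                            references = character(), mature = NULL,
                            transcripts = NULL, out = "clamir_out",
                            precedence = c("rRNA", "tRNA", "snRNA",
                                           "snoRNA", "repeat", "mRNA"),
                            thresholds = list(), seed = 1L) {
  cfg <- list(libraries = unlist(libraries), adapter = adapter,
              control = control, genome = genome,
              references = unlist(references), mature = mature,
              transcripts = transcripts, out = out,
              precedence = precedence, thresholds = thresholds,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  need <- c("libraries", "adapter", "control", "genome", "out")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) fail("missing field(s): ",
                            paste(missing, collapse = ", "))
  cfg$libraries <- unlist(cfg$libraries)
  cfg$references <- unlist(cfg$references)
  if (length(cfg$libraries) < 2 || is.null(names(cfg$libraries)) ||
      any(names(cfg$libraries) == "")) {
    fail("'libraries' must name at least two FASTQ files")
  }
  if (!cfg$control %in% names(cfg$libraries)) {
    fail("control library '", cfg$control, "' not among libraries")
  }
  if (is.null(cfg$precedence)) {
    cfg$precedence <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "mRNA")
  }
  if (length(cfg$references)) {
    extra <- setdiff(names(cfg$references), cfg$precedence)
    if (length(extra)) fail("reference class(es) outside precedence: ",
                            paste(extra, collapse = ", "))
  }
  for (p in c(cfg$libraries, genome = cfg$genome, cfg$references,
              mature = cfg$mature, transcripts = cfg$transcripts)) {
    if (!file.exists(p)) fail("file not found: ", p)
  }
  th <- modifyList(list(mfei = 0.9, min_reads = 50, p = 0.001,
                        min_log2fc = 1.0, target_cutoff = 4.0),
                   as.list(cfg$thresholds))
  if (th$p <= 0 || th$p >= 1) fail("'p' threshold must be in (0, 1)")
  if (th$min_log2fc < 0) fail("'min_log2fc' must be >= 0")
  if (th$mfei < 0) fail("'mfei' must be >= 0")
  if (th$min_reads < 0) fail("'min_reads' must be >= 0")
  if (th$target_cutoff < 0) fail("'target_cutoff' must be >= 0")
  cfg$thresholds <- th
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "clamir_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields as in [pipeline_config()]. Relative file
#'   paths are resolved against the YAML file's directory.
#' @return validated config.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (f in c("genome", "mature", "transcripts")) cfg[[f]] <- rel(cfg[[f]])
  if (!is.null(cfg$libraries)) {
    cfg$libraries <- vapply(cfg$libraries, rel, character(1))
  }
  if (!is.null(cfg$references)) {
    cfg$references <- vapply(cfg$references, rel, character(1))
  }
  validate_pipeline_config(cfg)
}

write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full small-RNA analysis pipeline
#'
#' Stages: clean -> collapse -> classify -> known -> novel -> differential
#' expression -> targets. Writes, under `config$out`: the collapsed tag
#' table, per-library length distributions, the class-annotation summary,
#' known- and novel-miRNA tables, precursor GFF3, one DE table per
#' treatment library, a target table and a `manifest.yaml` (package version,
#' config hash, per-stage counts, per-library read accounting). Reruns with
#' an identical config reproduce byte-identical outputs; with
#' `resume = TRUE` stages whose outputs already exist are reloaded instead
#' of recomputed.
#'
#' @param config a [pipeline_config()], a named list, or a YAML path.
#' @param resume reuse existing stage outputs in `config$out`.
#' @param quiet suppress progress messages.
#' @return a list of class `clamir_run`: `tags`, `length_dist`,
#'   `class_totals`, `known`, `novel`, `de` (named list per treatment),
#'   `targets`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "clamir_pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  say <- function(...) if (!quiet) message("[clamir] ", ...)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  libs <- names(config$libraries)
  manifest <- list(
    package = "clamir",
    version = as.character(utils::packageVersion("clamir")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    started = NA, # timestamps would break byte-identical reruns
    stages = list())
  paths <- c()
  stage_failed <- function(stage, err) {
    manifest$stages[[stage]] <- list(status = "failed",
                                     error = conditionMessage(err))
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    stop("stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  # --- clean + collapse -------------------------------------------------
  tags_path <- file.path(out, "tags.tsv")
  accounting <- NULL
  if (resume && file.exists(tags_path) &&
      file.exists(file.path(out, "accounting.tsv"))) {
    say("resume: reusing ", tags_path)
    tags <- read_tag_table(tags_path)
    accounting <- tibble::as_tibble(
      utils::read.delim(file.path(out, "accounting.tsv")))
  } else {
    res <- tryCatch({
      cleaned <- list()
      acc <- list()
      for (lib in libs) {
        say("clean: ", lib)
        reads <- read_srna_fastq(config$libraries[[lib]])
        cl <- clean_reads(reads, adapter3 = config$adapter)
        cleaned[[lib]] <- cl$sequence
        acc[[lib]] <- tibble::tibble(library = lib,
                                     raw = attr(cl, "n_input"),
                                     clean = nrow(cl),
                                     discarded = attr(cl, "n_input") -
                                       nrow(cl))
      }
      say("collapse")
      list(tags = collapse_tags(cleaned), acc = dplyr::bind_rows(acc))
    }, error = function(e) e)
    if (inherits(res, "error")) stage_failed("clean_collapse", res)
    tags <- res$tags
    accounting <- res$acc
    write_tag_table(tags, tags_path)
    write_tsv(accounting, file.path(out, "accounting.tsv"))
  }
  paths["tags"] <- tags_path
  paths["accounting"] <- file.path(out, "accounting.tsv")
  manifest$stages$clean_collapse <- list(
    status = "ok", n_tags = nrow(tags),
    reads = stats::setNames(as.list(accounting$raw), accounting$library),
    clean = stats::setNames(as.list(accounting$clean), accounting$library))

  # length distributions
  ld <- dplyr::bind_rows(lapply(libs, function(lib) {
    dplyr::mutate(length_distribution(tags, lib), library = lib,
                  .before = 1)
  }))
  paths["length_dist"] <- write_tsv(ld, file.path(out,
                                                  "length_distribution.tsv"))

  # --- classify ---------------------------------------------------------
  res <- tryCatch({
    refs <- lapply(config$references, function(p) {
      fa <- read_srna_fasta(p)
      stats::setNames(fa$sequence, fa$id)
    })
    say("classify: ", length(refs), " class reference(s)")
    classify_tags(tags, refs, precedence = config$precedence)
  }, error = function(e) e)
  if (inherits(res, "error")) stage_failed("classify", res)
  classified <- res
  totals_tbl <- class_totals(classified)
  paths["classified"] <- write_tsv(classified,
                                   file.path(out, "classified_tags.tsv"))
  paths["class_totals"] <- write_tsv(totals_tbl,
                                     file.path(out, "class_totals.tsv"))
  # accounting identity: raw = discarded + sum over classes (incl.
  # unannotated) of clean per-library reads
  for (lib in libs) {
    cls_sum <- sum(classified[[lib]])
    raw <- accounting$raw[accounting$library == lib]
    disc <- accounting$discarded[accounting$library == lib]
    if (cls_sum + disc != raw) {
      stage_failed("classify", simpleError(sprintf(
        "accounting identity violated for %s: %d classified + %d discarded != %d raw",
        lib, cls_sum, disc, raw)))
    }
  }
  manifest$stages$classify <- list(status = "ok",
                                   accounting_identity = "verified")

  unann <- classified[classified$class == "unannotated",
                      c("sequence", "length", libs)]

  # --- known miRNAs -----------------------------------------------------
  known <- NULL
  mature_db <- NULL
  if (!is.null(config$mature)) {
    res <- tryCatch({
      fa <- read_srna_fasta(config$mature)
      db <- stats::setNames(fa$sequence, fa$id)
      say("known: matching against ", length(db), " mature miRNAs")
      list(hits = match_known_mirnas(unann, db), db = db)
    }, error = function(e) e)
    if (inherits(res, "error")) stage_failed("known", res)
    known <- res$hits
    mature_db <- res$db
    paths["known"] <- write_tsv(known, file.path(out, "known_mirnas.tsv"))
    unann <- unann[!unann$sequence %in% known$sequence, , drop = FALSE]
  }
  manifest$stages$known <- list(status = "ok",
                                n_hits = if (is.null(known)) 0L else
                                  nrow(known))

  # --- novel miRNAs -----------------------------------------------------
  novel_path <- file.path(out, "novel_mirnas.tsv")
  if (resume && file.exists(novel_path)) {
    say("resume: reusing ", novel_path)
    novel <- tibble::as_tibble(utils::read.delim(novel_path))
  } else {
    res <- tryCatch({
      gfa <- read_srna_fasta(config$genome)
      genome <- stats::setNames(gfa$sequence, gfa$id)
      say("novel: scanning ", sum(rowSums(as.matrix(unann[, libs])) >
                                    th$min_reads), " candidate tag(s)")
      extra <- intersect(names(config$thresholds),
                         setdiff(names(formals(criteria_thresholds)),
                                 c("min_mfei", "min_reads")))
      thr <- do.call(criteria_thresholds,
                     c(list(min_mfei = th$mfei, min_reads = th$min_reads),
                       config$thresholds[extra]))
      call_novel_mirnas(unann, genome, thresholds = thr)
    }, error = function(e) e)
    if (inherits(res, "error")) stage_failed("novel", res)
    novel <- res
    write_tsv(novel, novel_path)
  }
  paths["novel"] <- novel_path
  if (nrow(novel)) {
    gff <- tibble::tibble(contig = novel$contig, start = novel$window_start,
                          end = novel$window_end, strand = novel$strand,
                          id = novel$id, type = "miRNA_primary_transcript")
    paths["gff3"] <- write_loci_gff3(gff, file.path(out,
                                                    "novel_precursors.gff3"))
  }
  manifest$stages$novel <- list(status = "ok", n_called = nrow(novel))

  # --- differential expression -----------------------------------------
  res <- tryCatch({
    counts <- dplyr::bind_rows(
      if (!is.null(known) && nrow(known)) {
        known |>
          dplyr::group_by(id = .data$mirna_id) |>
          dplyr::summarise(dplyr::across(dplyr::all_of(libs), sum),
                           .groups = "drop")
      },
      if (nrow(novel)) novel[, c("id", libs)])
    de <- list()
    if (!is.null(counts) && nrow(counts)) {
      totals <- vapply(libs, function(l) sum(counts[[l]]), numeric(1))
      for (trt in setdiff(libs, config$control)) {
        say("de: ", trt, " vs ", config$control)
        de[[trt]] <- call_differential(counts, config$control, trt,
                                       totals = totals,
                                       p_threshold = th$p,
                                       fc_threshold = th$min_log2fc)
      }
    }
    list(counts = counts, de = de)
  }, error = function(e) e)
  if (inherits(res, "error")) stage_failed("de", res)
  de <- res$de
  if (!is.null(res$counts)) {
    paths["mirna_counts"] <- write_tsv(res$counts,
                                       file.path(out, "mirna_counts.tsv"))
  }
  for (trt in names(de)) {
    p <- file.path(out, sprintf("de_%s_vs_%s.tsv", trt, config$control))
    write_de_table(de[[trt]], p)
    paths[paste0("de_", trt)] <- p
  }
  manifest$stages$de <- list(
    status = "ok",
    n_significant = lapply(de, function(d) sum(d$significant)))

  # --- targets ----------------------------------------------------------
  # scanned set: all identified miRNAs (detected known + called novel)
  mir_set <- dplyr::bind_rows(
    if (!is.null(known) && nrow(known) && !is.null(mature_db)) {
      ids <- sort(unique(known$mirna_id))
      tibble::tibble(id = ids, sequence = unname(mature_db[ids]))
    },
    if (nrow(novel)) novel[, c("id", "sequence")])
  targets <- NULL
  if (!is.null(config$transcripts) && !is.null(mir_set) && nrow(mir_set)) {
    res <- tryCatch({
      tfa <- read_srna_fasta(config$transcripts)
      tx <- stats::setNames(tfa$sequence, tfa$id)
      say("targets: ", nrow(mir_set), " miRNA(s) vs ", length(tx),
          " transcript(s)")
      dplyr::bind_rows(lapply(seq_len(nrow(mir_set)), function(i) {
        predict_targets(mir_set$sequence[i], tx,
                        cutoff = th$target_cutoff,
                        mirna_id = mir_set$id[i])
      }))
    }, error = function(e) e)
    if (inherits(res, "error")) stage_failed("targets", res)
    targets <- res
    paths["targets"] <- write_tsv(targets, file.path(out, "targets.tsv"))
  }
  manifest$stages$targets <- list(status = "ok",
                                  n_hits = if (is.null(targets)) 0L else
                                    nrow(targets))

  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  paths["manifest"] <- file.path(out, "manifest.yaml")
  say("done: ", out)
  structure(list(tags = tags, length_dist = ld, class_totals = totals_tbl,
                 accounting = accounting, known = known, novel = novel,
                 de = de, targets = targets, manifest = manifest,
                 paths = paths, config = config),
            class = "clamir_run")
}

#' @export
print.clamir_run <- function(x, ...) {
  cat("<clamir_run>\n")
  cat("  libraries:", paste(names(x$config$libraries), collapse = ", "),
      "\n")
  cat("  tags:", nrow(x$tags), "\n")
  cat("  known miRNA hits:", if (is.null(x$known)) 0 else nrow(x$known),
      "\n")
  cat("  novel miRNAs:", nrow(x$novel), "\n")
  for (trt in names(x$de)) {
    cat("  de", trt, "vs", x$config$control, ":",
        sum(x$de[[trt]]$significant), "significant\n")
  }
  cat("  output:", x$config$out, "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x a `clamir_run`.
#' @param ... unused.
#' @return tibble with per-stage counts.
#' @export
glance.clamir_run <- function(x, ...) {
  tibble::tibble(
    n_libraries = length(x$config$libraries),
    n_raw_reads = sum(x$accounting$raw),
    n_clean_reads = sum(x$accounting$clean),
    n_tags = nrow(x$tags),
    n_known_hits = if (is.null(x$known)) 0L else nrow(x$known),
    n_novel = nrow(x$novel),
    n_de_significant = sum(vapply(x$de, function(d) sum(d$significant),
                                  numeric(1))),
    n_target_hits = if (is.null(x$targets)) 0L else nrow(x$targets))
}
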