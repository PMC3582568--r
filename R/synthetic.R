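#' Configuration of the synthetic small-RNA study
#'
#' Defines the toy genome, reference sets and library mixture emulating the
#' statistical structure of a plant small-RNA sequencing experiment: planted
#' miRNA hairpins (criteria-passing and single-criterion decoys), dominant
#' rRNA contamination, a 21-24 nt dominated read-length profile and three
#' libraries (a self-graft control and two rootstock treatments).
#'
#' @param genome_size genome length in nt (single contig).
#' @param n_pass criteria-passing hairpins planted.
#' @param n_decoy decoy hairpins planted (each violating one named
#'   criterion; classes cycled over c2-c6).
#' @param n_known synthetic known mature miRNAs (matched by the known-miRNA
#'   step, no genomic precursor required).
#' @param n_rrna,n_trna,n_snrna,n_snorna,n_repeat,n_mrna reference sequences
#'   per contaminant class.
#' @param n_transcripts,transcript_len transcript reference for target
#'   prediction; the first transcripts carry planted complementary sites.
#' @param adapter 3' adapter appended to simulated reads.
#' @param libraries library ids; the first is the control.
#' @param read_len simulated raw read length.
#' @param mix mixture weights over read components: named numeric
#'   (`mirna`, `contaminant`, `background`), summing to 1.
#' @return a list of class `clamir_config`.
#' @export
synthetic_config <- function(genome_size = 200000, n_pass = 20, n_decoy = 10,
                             n_known = 15, n_rrna = 3, n_trna = 5,
                             n_snrna = 2, n_snorna = 2, n_repeat = 2,
                             n_mrna = 5, n_transcripts = 20,
                             transcript_len = 800,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             libraries = c("Wm_Wm", "Wm_BG", "Wm_Sq"),
                             read_len = 40,
                             mix = c(mirna = 0.55, contaminant = 0.30,
                                     background = 0.15)) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, length(libraries) >= 2)
  structure(as.list(environment()), class = "clamir_config")
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# contaminant class sizes and fragment-length profile (weights per 14-30 nt)
contaminant_classes <- function(config) {
  tibble::tibble(
    class = c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "mRNA"),
    n_refs = c(config$n_rrna, config$n_trna, config$n_snrna,
               config$n_snorna, config$n_repeat, config$n_mrna),
    ref_len = c(1500, 75, 150, 110, 500, 1000),
    weight = c(0.73, 0.13, 0.01, 0.01, 0.07, 0.05)) # rRNA dominates
}

contaminant_length_weights <- function() {
  len <- 14:30
  w <- c(rep(0.40 / 7, 7),   # 14-20
         rep(0.37 / 4, 4),   # 21-24
         rep(0.23 / 6, 6))   # 25-30
  stats::setNames(w, len)
}

plant_free_position <- function(occupied, len, genome_size) {
  for (k in 1:200) {
    pos <- sample.int(genome_size - len, 1)
    if (!any(pos < occupied$end + 50 & pos + len + 50 > occupied$start)) {
      return(pos)
    }
  }
  stop("infeasible config: no room to plant a ", len, " nt element")
}

# substitute arm positions opposite `at` (1-based mature positions) with a
# non-pairing base, creating symmetric 1x1 internal loops; keeps the star
# arm from being an exact reverse complement (so the mature tag maps to a
# single genomic locus)
mismatch_star <- function(mature, at) {
  mlen <- nchar(mature)
  mb <- strsplit(mature, "")[[1]]
  arm <- strsplit(revcomp(mature), "")[[1]]
  for (p in at) {
    comp <- c(A = "T", T = "A", G = "C", C = "G")[[mb[p]]]
    bad <- setdiff(c("A", "C", "G", "T"), comp)
    if (mb[p] == "G") bad <- setdiff(bad, "T")  # no wobble partners
    if (mb[p] == "T") bad <- setdiff(bad, "G")
    arm[mlen - p + 1L] <- sample(bad, 1)
  }
  paste(arm, collapse = "")
}

build_pass_hairpin <- function(adapter_seed) {
  mature_len <- sample(20:24, 1, prob = c(.10, .40, .20, .15, .15))
  mature <- rand_seq(mature_len, gc = 0.5)
  if (grepl(adapter_seed, mature, fixed = TRUE)) return(NULL)
  ext <- rand_seq(sample(5:10, 1), gc = 0.5)
  loop <- rand_seq(sample(4:8, 1), gc = 0.3)
  arm3 <- mismatch_star(mature, c(4L, mature_len - 4L))
  precursor <- paste0(ext, mature, loop, arm3, revcomp(ext))
  list(mature = mature, precursor = precursor,
       mature_offset = nchar(ext))  # 0-based offset of mature in precursor
}

build_decoy_hairpin <- function(type, adapter_seed) {
  pick <- function(n, gc = 0.5) rand_seq(n, gc)
  if (type == "c2") {
    # mature straddles the terminal loop by 4 of 21 nt
    arm <- pick(25)
    loop <- pick(6, gc = 0.3)
    ext <- pick(8)
    precursor <- paste0(ext, arm, loop, revcomp(arm), revcomp(ext))
    mature <- paste0(substr(arm, 9, 25), substr(loop, 1, 4))
    off <- nchar(ext) + 8L
  } else if (type == "c3") {
    # 13-nt one-sided bulge in the stem below the mature arm
    mature <- pick(21)
    ext <- pick(10)
    loop <- pick(6, gc = 0.3)
    bulge <- paste(rep("C", 13), collapse = "")
    precursor <- paste0(ext, mature, loop, mismatch_star(mature, c(4L, 17L)),
                        bulge, revcomp(ext))
    off <- nchar(ext)
  } else if (type == "c4") {
    # 5-nt one-sided bulge inside the mature span (5 biased errors > 4)
    mature <- pick(21)
    ext <- pick(8)
    loop <- pick(6, gc = 0.3)
    arm3 <- revcomp(paste0(substr(mature, 1, 7), substr(mature, 13, 21)))
    precursor <- paste0(ext, mature, loop, arm3, revcomp(ext))
    off <- nchar(ext)
  } else if (type == "c5") {
    # three symmetric 1x1 internal loops in the mature: 15 paired, not > 15
    mature <- pick(21)
    ext <- pick(8)
    loop <- pick(6, gc = 0.3)
    mb <- strsplit(mature, "")[[1]]
    arm3b <- strsplit(revcomp(mature), "")[[1]]
    # positions 5, 11, 17 of the mature; matching arm positions from 3' end
    for (p in c(5L, 11L, 17L)) {
      q <- 21L - p + 1L
      comp <- c(A = "T", T = "A", G = "C", C = "G")[[mb[p]]]
      bad <- setdiff(c("A", "C", "G", "T"), comp)
      # avoid wobble partners of the mature base
      if (mb[p] == "G") bad <- setdiff(bad, "T")
      if (mb[p] == "T") bad <- setdiff(bad, "G")
      arm3b[q] <- sample(bad, 1)
    }
    precursor <- paste0(ext, mature, loop, paste(arm3b, collapse = ""),
                        revcomp(ext))
    off <- nchar(ext)
  } else { # c6: AT-only stem with a long C loop -> MFEI below threshold
    mature <- paste(sample(c("A", "T"), 21, TRUE), collapse = "")
    ext <- paste(sample(c("A", "T"), 6, TRUE), collapse = "")
    loop <- paste(rep("C", 50), collapse = "")
    mb <- strsplit(mature, "")[[1]]
    arm3 <- strsplit(revcomp(mature), "")[[1]]
    for (p in c(4L, 17L)) {  # A<->T flips create pure mismatches (no G)
      arm3[21L - p + 1L] <- mb[p]
    }
    precursor <- paste0(ext, mature, loop, paste(arm3, collapse = ""),
                        revcomp(ext))
    off <- nchar(ext)
  }
  if (grepl(adapter_seed, mature, fixed = TRUE)) return(NULL)
  list(mature = mature, precursor = precursor, mature_offset = off,
       violates = type)
}

#' Generate a synthetic genome, reference sets and truth record
#'
#' Criteria-passing hairpins are constructed arm-first (a sampled mature
#' sequence, a near-complementary opposing arm, a short terminal loop and a
#' closing stem extension), planted into a random genome and verified in
#' situ with [evaluate_criteria()] over the default candidate windows before
#' acceptance; draws failing verification are resampled. Decoys are built to
#' violate one named criterion each and verified to pass no window.
#'
#' @param config see [synthetic_config()].
#' @param seed integer seed; all outputs are reproducible from
#'   `(config, seed)` alone.
#' @param thresholds criteria thresholds used for in-situ verification.
#' @return a list of class `clamir_truth`: `genome` (named character),
#'   `refs` (named list of class references), `mature_db` (known matures),
#'   `transcripts`, `hairpins` (tibble: id, type, violates, mature,
#'   precursor, contig, strand, mature_start/end 0-based half-open),
#'   `known` (tibble id/family/sequence), `target_sites` (tibble),
#'   `config`, `seed`.
#' @export
generate_reference <- function(config = synthetic_config(), seed = 1,
                               thresholds = criteria_thresholds()) {
  set.seed(seed)
  seed7 <- substr(normalize_seq(config$adapter), 1, 7)
  hp_max_len <- 150L
  need <- (config$n_pass + config$n_decoy) * (hp_max_len + 100L)
  if (config$genome_size < need + 1000L) {
    stop("infeasible config: genome too small for ",
         config$n_pass + config$n_decoy, " hairpins")
  }
  genome <- rand_seq(config$genome_size, gc = 0.42)

  # contaminant and mRNA references
  cls <- contaminant_classes(config)
  refs <- list()
  for (i in seq_len(nrow(cls))) {
    n <- cls$n_refs[i]
    refs[[cls$class[i]]] <- stats::setNames(
      vapply(seq_len(n), function(k) rand_seq(cls$ref_len[i], gc = 0.52),
             character(1)),
      sprintf("%s_%d", cls$class[i], seq_len(n)))
  }

  # synthetic known mature miRNAs
  known_seq <- character(config$n_known)
  for (i in seq_len(config$n_known)) {
    repeat {
      len <- sample(c(21L, 22L), 1, prob = c(.7, .3))
      s <- rand_seq(len, gc = 0.5)
      if (!grepl(seed7, s, fixed = TRUE) && !s %in% known_seq) break
    }
    known_seq[i] <- s
  }
  known <- tibble::tibble(id = sprintf("syn-miR%d", 100 + seq_len(config$n_known)),
                          family = sprintf("syn-miR%d", 100 + seq_len(config$n_known)),
                          sequence = known_seq)

  # plant hairpins, verifying each against the growing genome
  occupied <- tibble::tibble(start = integer(), end = integer())
  decoy_types <- rep(c("c2", "c3", "c4", "c5", "c6"),
                     length.out = config$n_decoy)
  plan <- c(rep("pass", config$n_pass), decoy_types)
  rows <- list()
  for (h in seq_along(plan)) {
    type <- plan[h]
    placed <- FALSE
    for (attempt in 1:40) {
      hp <- if (type == "pass") build_pass_hairpin(seed7) else
        build_decoy_hairpin(type, seed7)
      if (is.null(hp)) next
      plen <- nchar(hp$precursor)
      pos <- plant_free_position(occupied, plen, config$genome_size)
      strand <- sample(c("+", "-"), 1)
      insert <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
      cand_genome <- genome
      substr(cand_genome, pos, pos + plen - 1L) <- insert
      mlen <- nchar(hp$mature)
      if (strand == "+") {
        ms <- pos - 1L + hp$mature_offset            # 0-based
      } else {
        ms <- pos - 1L + plen - hp$mature_offset - mlen
      }
      locus <- tibble::tibble(contig = "chr1", start = ms, end = ms + mlen,
                              strand = strand)
      g <- c(chr1 = cand_genome)
      hits <- map_to_genome(hp$mature, g)
      if (nrow(hits) != 1) next
      cands <- extract_precursor_candidates(locus, g)
      if (!nrow(cands)) next
      rep_all <- dplyr::bind_rows(lapply(seq_len(nrow(cands)), function(w) {
        evaluate_criteria(cands$precursor[w], cands$structure[w],
                          cands$mature_start[w], cands$mature_end[w],
                          mfe = cands$mfe[w], thresholds = thresholds)
      }))
      ok <- if (type == "pass") {
        any(rep_all$overall)
      } else {
        crit_col <- c(c2 = "c2_mature_in_arm", c3 = "c3_stem",
                      c4 = "c4_bulges", c5 = "c5_pairing",
                      c6 = "c6_energy")[[type]]
        !any(rep_all$overall) &&
          any(!rep_all[[crit_col]] %in% TRUE)
      }
      if (!ok) next
      genome <- cand_genome
      occupied <- dplyr::bind_rows(occupied,
                                   tibble::tibble(start = pos,
                                                  end = pos + plen))
      hp_type <- if (type == "pass") "pass" else "decoy"
      hp_violates <- if (type == "pass") NA_character_ else type
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("hp%02d", h),
        type = hp_type,
        violates = hp_violates,
        mature = hp$mature, precursor = hp$precursor,
        contig = "chr1", strand = strand,
        mature_start = ms, mature_end = ms + mlen)
      placed <- TRUE
      break
    }
    if (!placed) stop("failed to plant a verified ", type, " hairpin")
  }
  hairpins <- dplyr::bind_rows(rows)

  # transcripts; the first ones carry perfect complementary sites for the
  # first known miRNAs (planted target truth)
  transcripts <- stats::setNames(
    vapply(seq_len(config$n_transcripts),
           function(k) rand_seq(config$transcript_len, gc = 0.45),
           character(1)),
    sprintf("tx_%02d", seq_len(config$n_transcripts)))
  n_sites <- min(5L, config$n_known, config$n_transcripts)
  sites <- list()
  for (i in seq_len(n_sites)) {
    site <- revcomp(known$sequence[i])
    pos <- 100L + 40L * i
    tx <- names(transcripts)[i]
    s <- transcripts[[tx]]
    substr(s, pos, pos + nchar(site) - 1L) <- site
    transcripts[[tx]] <- s
    sites[[i]] <- tibble::tibble(mirna_id = known$id[i], transcript = tx,
                                 start = pos - 1L,
                                 end = pos - 1L + nchar(site))
  }

  structure(list(
    genome = c(chr1 = genome),
    refs = refs,
    mature_db = stats::setNames(known$sequence, known$id),
    transcripts = transcripts,
    hairpins = hairpins,
    known = known,
    target_sites = dplyr::bind_rows(sites),
    config = config,
    seed = seed
  ), class = "clamir_truth")
}

#' Default planted fold-change map
#'
#' Log2 fold changes applied to treatment libraries relative to the control:
#' a few known and novel miRNAs are shifted by +/-3 (8-fold), the rest form
#' the planted null set.
#'
#' @param truth a `clamir_truth` object.
#' @return tibble with `id`, `sequence`, `library`, `log2fc`.
#' @export
default_de_config <- function(truth) {
  libs <- truth$config$libraries
  pass <- truth$hairpins[truth$hairpins$type == "pass", ]
  pick_known <- truth$known[seq_len(min(4, nrow(truth$known))), ]
  pick_novel <- pass[seq_len(min(4, nrow(pass))), ]
  dplyr::bind_rows(
    tibble::tibble(id = pick_known$id[1:2], sequence = pick_known$sequence[1:2],
                   library = libs[2], log2fc = c(3, -3)),
    tibble::tibble(id = pick_novel$id[1:2], sequence = pick_novel$mature[1:2],
                   library = libs[2], log2fc = c(3, -3)),
    tibble::tibble(id = pick_known$id[3:4], sequence = pick_known$sequence[3:4],
                   library = libs[3], log2fc = c(3, -3)),
    tibble::tibble(id = pick_novel$id[3:4], sequence = pick_novel$mature[3:4],
                   library = libs[3], log2fc = c(3, -3)))
}

#' Simulate three small-RNA libraries from a synthetic truth
#'
#' Reads per library are a multinomial draw from a mixture of mature miRNAs
#' (known + planted hairpins, with 1-mismatch sequencing variants at rate
#' 0.02), class contaminant fragments (rRNA-dominated) and genomic
#' background. Planted fold changes scale treatment-library proportions.
#' The 3' adapter is appended, reads are padded to `read_len`, and sparse
#' low-quality/N reads are planted. The truth is updated with per-tag
#' expected clean counts (exact bookkeeping of the emitted reads).
#'
#' @param truth a `clamir_truth` from [generate_reference()].
#' @param de_config fold-change map, see [default_de_config()]; `NULL` for
#'   none.
#' @param depth reads per library (>= 1e4).
#' @param seed integer seed.
#' @param dir output directory for FASTQ files.
#' @return the updated `clamir_truth`, with `fastq` (named paths),
#'   `expected_tags` (tibble sequence x library expected clean counts),
#'   `tag_origin` (component/class per planted tag), `fold_changes`,
#'   `planted_len_fraction` (planted 21-24 nt raw fraction) and
#'   `depth`.
#' @export
simulate_libraries <- function(truth, de_config = default_de_config(truth),
                               depth = 1e5, seed = truth$seed,
                               dir = tempfile("clamir_sim_")) {
  stopifnot(inherits(truth, "clamir_truth"), depth >= 1e4)
  set.seed(seed + 1L)
  config <- truth$config
  libs <- config$libraries
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # --- mixture tag pool -----------------------------------------------
  mirna_tags <- tibble::tibble(
    sequence = c(truth$known$sequence, truth$hairpins$mature),
    id = c(truth$known$id, truth$hairpins$id),
    component = "mirna")
  w_mirna <- rlnorm(nrow(mirna_tags), meanlog = 0, sdlog = 0.8)
  w_mirna <- pmax(w_mirna, 0.35)  # keep every planted miRNA above ~50 reads
  cls <- contaminant_classes(config)
  lw <- contaminant_length_weights()
  contam <- list()
  for (i in seq_len(nrow(cls))) {
    class <- cls$class[i]
    nfrag <- 12L * cls$n_refs[i]
    rv <- truth$refs[[class]]
    frag <- character(nfrag)
    for (k in seq_len(nfrag)) {
      len <- as.integer(sample(names(lw), 1, prob = lw))
      ref <- rv[[sample.int(length(rv), 1)]]
      st <- sample.int(nchar(ref) - len, 1)
      frag[k] <- substr(ref, st, st + len - 1L)
    }
    contam[[class]] <- tibble::tibble(sequence = frag, id = class,
                                      component = "contaminant",
                                      class = class,
                                      class_weight = cls$weight[i])
  }
  contam <- dplyr::bind_rows(contam)
  # genomic background is highly diverse in real libraries: many distinct
  # species, each observed a handful of times (well under any calling gate)
  n_bg <- 2500L
  bg_len <- sample(20:25, n_bg, TRUE)
  bg_start <- sample.int(config$genome_size - 30L, n_bg)
  bg <- tibble::tibble(
    sequence = substring(truth$genome[["chr1"]], bg_start,
                         bg_start + bg_len - 1L),
    id = "background", component = "background")

  pool <- dplyr::bind_rows(
    dplyr::mutate(mirna_tags, weight = w_mirna / sum(w_mirna) *
                    config$mix[["mirna"]]),
    contam |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(weight = .data$class_weight / dplyr::n() *
                      config$mix[["contaminant"]]) |>
      dplyr::ungroup() |>
      dplyr::select(-"class", -"class_weight"),
    dplyr::mutate(bg, weight = config$mix[["background"]] / n_bg))
  pool$weight <- pool$weight / sum(pool$weight)

  # drop planted tags containing the adapter seed (cannot survive trimming)
  seed7 <- substr(normalize_seq(config$adapter), 1, 7)
  bad <- grepl(seed7, pool$sequence, fixed = TRUE)
  if (any(bad)) pool <- pool[!bad, ]
  pool$weight <- pool$weight / sum(pool$weight)

  # per-library proportions with planted fold changes
  probs <- stats::setNames(rep(list(pool$weight), length(libs)), libs)
  if (!is.null(de_config) && nrow(de_config)) {
    for (r in seq_len(nrow(de_config))) {
      lib <- de_config$library[r]
      i <- match(de_config$sequence[r], pool$sequence)
      if (!is.na(i)) probs[[lib]][i] <- probs[[lib]][i] * 2^de_config$log2fc[r]
    }
    for (lib in libs) probs[[lib]] <- probs[[lib]] / sum(probs[[lib]])
  }

  # planted 21-24 nt raw fraction (control library mixture)
  len_pool <- nchar(pool$sequence)
  planted_frac <- sum(probs[[libs[1]]][len_pool >= 21 & len_pool <= 24])

  # --- draw reads, mutate, write FASTQ --------------------------------
  fastq <- character(0)
  expected <- list()
  for (lib in libs) {
    counts <- as.integer(rmultinom(1, size = depth, prob = probs[[lib]]))
    seqs <- rep(pool$sequence, counts)
    n <- length(seqs)
    ord <- sample.int(n)  # shuffle read order
    seqs <- seqs[ord]
    # 1-mismatch variants on miRNA-derived reads
    is_mirna <- rep(pool$component == "mirna", counts)[ord]
    mut <- which(is_mirna & runif(n) < 0.02)
    for (i in mut) {
      s <- seqs[i]
      p <- sample.int(nchar(s), 1)
      b <- substr(s, p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    # assemble reads: tag + adapter, padded with random bases to read_len
    reads <- paste0(seqs, config$adapter)
    short <- nchar(reads) < config$read_len
    if (any(short)) {
      pad_n <- config$read_len - nchar(reads[short])
      reads[short] <- paste0(reads[short],
                             vapply(pad_n, rand_seq, character(1)))
    }
    reads <- substr(reads, 1, config$read_len)
    quals <- strrep("I", config$read_len)
    quals <- rep(quals, n)
    lowq <- runif(n) < 0.005
    for (i in which(lowq)) {
      p <- sample.int(nchar(seqs[i]), 1)  # low-quality base inside the tag
      substr(quals[i], p, p) <- "#"
    }
    withn <- runif(n) < 0.002 & !lowq
    for (i in which(withn)) {
      p <- sample.int(nchar(seqs[i]), 1)
      substr(reads[i], p, p) <- "N"
    }
    # exact bookkeeping of what a correct cleaner retains
    hit <- regexpr(seed7, reads, fixed = TRUE)
    trimmed <- substr(reads, 1, ifelse(hit > 0, hit - 1L, nchar(reads)))
    tlen <- nchar(trimmed)
    keep <- tlen >= 14 & tlen <= 30 & !grepl("N", trimmed, fixed = TRUE) &
      !lowq
    tab <- table(trimmed[keep])
    expected[[lib]] <- tibble::tibble(sequence = names(tab),
                                      count = as.integer(tab))
    path <- file.path(dir, paste0(lib, ".fastq"))
    ids <- sprintf("@%s_read%d", lib, seq_len(n))
    writeLines(paste(ids, reads, "+", quals, sep = "\n"), path)
    fastq[lib] <- path
  }
  wide <- tidyr::pivot_wider(
    dplyr::bind_rows(expected, .id = "library"),
    names_from = "library", values_from = "count", values_fill = 0L)
  truth$fastq <- fastq
  truth$expected_tags <- wide
  truth$tag_origin <- pool[, c("sequence", "id", "component")]
  truth$fold_changes <- de_config
  truth$planted_len_fraction <- planted_frac
  truth$depth <- depth
  truth$sim_seed <- seed
  truth
}

#' Recovery metrics of calls against the planted truth
#'
#' @param calls novel-miRNA calls from [call_novel_mirnas()] (or a
#'   character vector of called mature sequences).
#' @param truth a `clamir_truth` after [simulate_libraries()].
#' @param de optional `clamir_de` result for DE power / type-I metrics
#'   (treatment library taken from its attributes).
#' @param min_reads pooled-count condition defining recoverable hairpins.
#' @param seed seed recorded with the calls (e.g. a pipeline manifest
#'   seed); when given it must match the truth's seed lineage.
#' @return one-row tibble: `sensitivity`, `specificity` (decoy rejection),
#'   `n_recoverable`, `n_called_true`, `n_decoys`, per-criterion decoy
#'   rejection columns `reject_<criterion>`, and when `de` is given
#'   `de_power` and `de_type1`.
#' @export
evaluate_recovery <- function(calls, truth, de = NULL, min_reads = 50,
                              seed = NULL) {
  stopifnot(inherits(truth, "clamir_truth"))
  if (!is.null(seed) && !identical(as.integer(seed),
                                   as.integer(truth$seed))) {
    stop("seed mismatch: calls and truth are not from the same lineage")
  }
  called_seq <- if (is.character(calls)) calls else calls$sequence
  libs <- truth$config$libraries
  et <- truth$expected_tags
  pooled <- stats::setNames(
    rowSums(as.matrix(et[, intersect(libs, names(et)), drop = FALSE])),
    et$sequence)
  hp <- truth$hairpins
  hp$pooled <- unname(pooled[hp$mature])
  hp$pooled[is.na(hp$pooled)] <- 0
  recov <- hp[hp$type == "pass" & hp$pooled > min_reads, ]
  decoys <- hp[hp$type == "decoy" & hp$pooled > min_reads, ]
  out <- tibble::tibble(
    n_recoverable = nrow(recov),
    n_called_true = sum(recov$mature %in% called_seq),
    sensitivity = ifelse(nrow(recov) > 0,
                         mean(recov$mature %in% called_seq), NA_real_),
    n_decoys = nrow(decoys),
    specificity = ifelse(nrow(decoys) > 0,
                         mean(!decoys$mature %in% called_seq), NA_real_))
  for (cr in sort(unique(decoys$violates))) {
    d <- decoys[decoys$violates == cr, ]
    out[[paste0("reject_", cr)]] <- mean(!d$mature %in% called_seq)
  }
  if (!is.null(de)) {
    lib <- attr(de, "treatment")
    fc <- truth$fold_changes
    planted <- fc[fc$library == lib, ]
    sig <- de$id[de$significant]
    # resolve each planted miRNA to its id in the de table: the truth id
    # directly (known miRNAs) or, via the calls table, the assigned novel id
    resolve <- function(id, sequence) {
      if (id %in% de$id) return(id)
      if (!is.character(calls) && "sequence" %in% names(calls)) {
        j <- match(sequence, calls$sequence)
        if (!is.na(j)) return(calls$id[j])
      }
      NA_character_
    }
    planted_de_ids <- vapply(seq_len(nrow(planted)), function(r) {
      resolve(planted$id[r], planted$sequence[r])
    }, character(1))
    out$de_power <- if (nrow(planted)) {
      mean(planted_de_ids %in% sig)
    } else NA_real_
    # everything in the de table not resolved to a planted change is null
    all_planted_ids <- vapply(seq_len(nrow(fc)), function(r) {
      resolve(fc$id[r], fc$sequence[r])
    }, character(1))
    null_ids <- setdiff(de$id, all_planted_ids)
    out$de_type1 <- mean(null_ids %in% sig)
  }
  out
}

#' Write synthetic reference files and the truth record
#'
#' Emits the genome, per-class references, mature miRNAs and transcripts as
#' FASTA, plus the truth as JSON (`truth.json`). Sequences are written in
#' deterministic order so identical `(config, seed)` yield identical bytes.
#'
#' @param truth a `clamir_truth` object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_reference <- function(truth, dir) {
  stopifnot(inherits(truth, "clamir_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fa <- function(x, path) {
    writeLines(paste0(">", names(x), "\n", unname(x)), path)
    path
  }
  paths <- c(genome = write_fa(truth$genome, file.path(dir, "genome.fa")),
             mature = write_fa(truth$mature_db, file.path(dir, "mature.fa")),
             transcripts = write_fa(truth$transcripts,
                                    file.path(dir, "transcripts.fa")))
  for (class in names(truth$refs)) {
    if (!length(truth$refs[[class]])) next
    paths[class] <- write_fa(truth$refs[[class]],
                             file.path(dir, paste0(tolower(class), ".fa")))
  }
  tr <- truth
  tr$genome <- NULL; tr$refs <- NULL; tr$mature_db <- NULL
  tr$transcripts <- NULL
  tr$config <- unclass(tr$config)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(tr), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
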