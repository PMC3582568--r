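tiny_config <- function() {
  synthetic_config(genome_size = 12000, n_pass = 1, n_decoy = 1,
                   n_known = 3, n_rrna = 2, n_trna = 2, n_snrna = 1,
                   n_snorna = 1, n_repeat = 1, n_mrna = 2,
                   n_transcripts = 3, transcript_len = 400)
}

# Two independent generations of the same (config, seed), built once per
# session: folding-heavy, so every determinism test below shares them.
tiny_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(t1 = generate_reference(tiny_config(), seed = 3),
                     t2 = generate_reference(tiny_config(), seed = 3))
    }
    cache
  }
})

test_that("generate_reference is reproducible from (config, seed) alone", {
  t1 <- tiny_pair()$t1
  t2 <- tiny_pair()$t2
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$refs, t2$refs)
  expect_identical(as.data.frame(t1$hairpins), as.data.frame(t2$hairpins))
  expect_identical(t1$mature_db, t2$mature_db)
  # the genome is not degenerate and the hairpins landed in it
  expect_equal(nchar(t1$genome[["chr1"]]), 12000L)
  expect_true(all(vapply(t1$hairpins$mature, function(m) {
    grepl(m, t1$genome[["chr1"]], fixed = TRUE) ||
      grepl(revcomp_chr(m), t1$genome[["chr1"]], fixed = TRUE)
  }, logical(1))))
})

test_that("write_reference emits byte-identical files for the same lineage", {
  t1 <- tiny_pair()$t1
  t2 <- tiny_pair()$t2
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_reference(t1, d1)
  p2 <- write_reference(t2, d2)
  expect_setequal(names(p1), names(p2))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("file", nm))
  }
  # truth JSON parses and carries the seed
  tr <- jsonlite::read_json(p1[["truth"]])
  expect_equal(tr$seed, 3)
})

test_that("an infeasible genome size errors before any planting", {
  cfg <- synthetic_config(genome_size = 2000, n_pass = 20, n_decoy = 10)
  expect_error(generate_reference(cfg, seed = 1), "infeasible")
})

test_that("planted hairpins verify and decoys record a violated criterion", {
  truth <- small_fixture()
  hp <- truth$hairpins
  expect_equal(sum(hp$type == "pass"), truth$config$n_pass)
  expect_equal(sum(hp$type == "decoy"), truth$config$n_decoy)
  expect_true(all(is.na(hp$violates[hp$type == "pass"])))
  expect_true(all(hp$violates[hp$type == "decoy"] %in%
                    c("c2", "c3", "c4", "c5", "c6")))
  # each planted mature maps to exactly one genomic locus
  for (m in hp$mature) {
    expect_equal(nrow(map_to_genome(m, truth$genome)), 1L)
  }
  # re-verify a subset with the checker (full re-verification would repeat
  # the generator's own in-situ scan; recovery tests cover the rest)
  check <- c(which(hp$type == "pass")[1:2], which(hp$type == "decoy")[1:2])
  for (i in check) {
    locus <- tibble::tibble(contig = hp$contig[i], start = hp$mature_start[i],
                            end = hp$mature_end[i], strand = hp$strand[i])
    cands <- extract_precursor_candidates(locus, truth$genome)
    ok <- vapply(seq_len(nrow(cands)), function(w) {
      evaluate_criteria(cands$precursor[w], cands$structure[w],
                        cands$mature_start[w], cands$mature_end[w],
                        mfe = cands$mfe[w])$overall
    }, logical(1))
    if (hp$type[i] == "pass") {
      expect_true(any(ok), label = paste("pass hairpin", hp$id[i]))
    } else {
      expect_false(any(ok), label = paste("decoy hairpin", hp$id[i]))
    }
  }
})

test_that("simulate_libraries is seed-deterministic down to FASTQ bytes", {
  truth <- tiny_pair()$t1
  s1 <- simulate_libraries(truth, depth = 1e4, seed = 3,
                           dir = withr::local_tempdir())
  s2 <- simulate_libraries(truth, depth = 1e4, seed = 3,
                           dir = withr::local_tempdir())
  expect_identical(as.data.frame(s1$expected_tags),
                   as.data.frame(s2$expected_tags))
  for (lib in names(s1$fastq)) {
    expect_identical(readLines(s1$fastq[[lib]]),
                     readLines(s2$fastq[[lib]]))
  }
})

test_that("planted fold changes are realized within sampling error", {
  truth <- small_fixture()
  fc <- truth$fold_changes
  et <- truth$expected_tags
  ctl <- truth$config$libraries[1]
  # null miRNA tags estimate the per-library normalization distortion
  mirna_seqs <- c(truth$known$sequence, truth$hairpins$mature)
  null_seqs <- setdiff(intersect(mirna_seqs, et$sequence), fc$sequence)
  for (r in seq_len(nrow(fc))) {
    lib <- fc$library[r]
    i <- match(fc$sequence[r], et$sequence)
    expect_false(is.na(i), label = paste("planted tag present", fc$id[r]))
    null_ratio <- median(et[[lib]][match(null_seqs, et$sequence)] /
                           et[[ctl]][match(null_seqs, et$sequence)])
    realized <- (et[[lib]][i] / et[[ctl]][i]) / null_ratio
    target <- 2^fc$log2fc[r]
    expect_gt(realized, target * 0.7,
              label = paste("fold change of", fc$id[r], "in", lib))
    expect_lt(realized, target * 1.4,
              label = paste("fold change of", fc$id[r], "in", lib))
  }
})

test_that("the planted 21-24 nt fraction is in range and realized", {
  truth <- small_fixture()
  expect_gte(truth$planted_len_fraction, 0.70)
  expect_lte(truth$planted_len_fraction, 0.85)
  tags <- small_tags()
  ctl <- truth$config$libraries[1]
  raw_frac <- sum(tags[[ctl]][tags$length >= 21 & tags$length <= 24]) /
    sum(tags[[ctl]])
  expect_lt(abs(raw_frac - truth$planted_len_fraction), 0.02)
})

test_that("a zero-contaminant mixture yields no class-annotated tags", {
  # the mixture only affects simulation, so the generated truth is reusable
  truth <- tiny_pair()$t1
  truth$config$mix <- c(mirna = 0.85, contaminant = 0, background = 0.15)
  truth <- simulate_libraries(truth, depth = 1e4, seed = 3,
                              dir = withr::local_tempdir())
  et <- truth$expected_tags
  tags <- tibble::tibble(sequence = et$sequence,
                         length = nchar(et$sequence))
  for (lib in truth$config$libraries) tags[[lib]] <- et[[lib]]
  cls <- classify_tags(tags, truth$refs)
  expect_true(all(cls$class == "unannotated"))
})

test_that("one-mismatch sequencing variants of matures appear in the reads", {
  truth <- small_fixture()
  et <- truth$expected_tags
  mirna_seqs <- c(truth$known$sequence, truth$hairpins$mature)
  is_variant <- vapply(et$sequence, function(s) {
    if (s %in% mirna_seqs) return(FALSE)
    same_len <- mirna_seqs[nchar(mirna_seqs) == nchar(s)]
    any(vapply(same_len, function(m) {
      sum(utf8ToInt(m) != utf8ToInt(s)) == 1L
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_gt(sum(is_variant), 0L)
  # variants are rare relative to their parents (rate ~2%)
  libs <- truth$config$libraries
  pooled <- rowSums(as.matrix(et[, libs]))
  frac <- sum(pooled[is_variant]) /
    sum(pooled[et$sequence %in% mirna_seqs | is_variant])
  expect_lt(frac, 0.06)
})

test_that("evaluate_recovery handles perfect and empty callers", {
  truth <- small_fixture()
  pass <- truth$hairpins$mature[truth$hairpins$type == "pass"]
  perfect <- evaluate_recovery(pass, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  nothing <- evaluate_recovery(character(0), truth)
  expect_equal(nothing$sensitivity, 0)
  expect_equal(nothing$specificity, 1)
  everything <- evaluate_recovery(truth$hairpins$mature, truth)
  expect_equal(everything$specificity, 0)
  expect_true(all(unlist(everything[grep("^reject_",
                                         names(everything))]) == 0))
})

test_that("evaluate_recovery rejects a mismatched seed lineage", {
  truth <- small_fixture()
  expect_error(evaluate_recovery(character(0), truth, seed = 8),
               "seed mismatch")
  expect_silent(evaluate_recovery(character(0), truth, seed = 7))
})
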