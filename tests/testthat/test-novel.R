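# ---- hand-built criteria fixtures --------------------------------------
# Ten dot-bracket structures with hand-derived criterion outcomes, built
# independently of the generator and the folding engine (structure strings
# and energies are supplied directly).

seq_gc50 <- function(n) strrep("AG", ceiling(n / 2)) |> substr(1, n)

criteria_fixtures <- function() {
  st1 <- paste0(strrep("(", 25), strrep(".", 6), strrep(")", 25)) # n=56
  st3 <- paste0(strrep("(", 18), strrep(".", 6), strrep(")", 18)) # n=42
  st4 <- paste0(strrep("(", 6), strrep(".", 12), strrep("(", 16),
                "....", strrep(")", 16), strrep(")", 6))          # n=60
  st5 <- paste0(strrep("(", 10), strrep(".", 9), strrep("(", 12),
                "....", strrep(")", 12), strrep(")", 10))         # n=57
  st6 <- paste0("(((((..(((((..(((((..((((", "....",
                "))))..)))))..)))))..)))))")                      # n=54
  st8 <- paste0(strrep("(", 47), strrep(".", 6), strrep(")", 47)) # n=100
  st9 <- "((((....))))..((((....))))"                             # n=26
  list(
    # 1: textbook precursor, all six criteria pass
    list(st = st1, ms = 1, me = 21, mfe = -50, overall = TRUE),
    # 2: mature straddles the terminal loop -> c2 (and c5) fail
    list(st = st1, ms = 20, me = 40, mfe = -50, overall = FALSE,
         expect = list(c2_mature_in_arm = FALSE, c5_pairing = FALSE)),
    # 3: 18 stem pairs, threshold is strict -> c3 fails
    list(st = st3, ms = 1, me = 18, mfe = -40, overall = FALSE,
         expect = list(c3_stem = FALSE, c5_pairing = TRUE)),
    # 4: 12-nt one-sided stem bulge (not < 12) -> c3 fails, c4 unaffected
    list(st = st4, ms = 19, me = 34, mfe = -50, overall = FALSE,
         expect = list(c3_stem = FALSE, c4_bulges = TRUE)),
    # 5: 9-nt biased bulge inside the mature span -> c4 fails
    list(st = st5, ms = 5, me = 30, mfe = -50, overall = FALSE,
         expect = list(c3_stem = TRUE, c4_bulges = FALSE,
                       c5_pairing = TRUE)),
    # 6: exactly 15 mature pairs (threshold strict) -> only c5 fails
    list(st = st6, ms = 1, me = 21, mfe = -50, overall = FALSE,
         expect = list(c3_stem = TRUE, c4_bulges = TRUE,
                       c5_pairing = FALSE, c6_energy = TRUE)),
    # 7: weak energy, MFEI 0.714 -> only c6 fails
    list(st = st1, ms = 1, me = 21, mfe = -20, overall = FALSE,
         expect = list(c2_mature_in_arm = TRUE, c6_energy = FALSE)),
    # 8: MFEI exactly 0.9 -> boundary excluded, c6 fails
    list(st = st8, ms = 1, me = 21, mfe = -45, overall = FALSE,
         expect = list(c6_energy = FALSE)),
    # 9: two terminal loops -> not a hairpin
    list(st = st9, ms = 1, me = 10, mfe = -10, overall = FALSE,
         expect = list(c1_hairpin = FALSE)),
    # 10: non-negative energy -> c6 fails even on a perfect stem
    list(st = st1, ms = 1, me = 21, mfe = 0, overall = FALSE,
         expect = list(c6_energy = FALSE))
  )
}

test_that("hand-built structures get the hand-derived criterion outcomes", {
  for (k in seq_along(criteria_fixtures())) {
    fx <- criteria_fixtures()[[k]]
    rep <- evaluate_criteria(seq_gc50(nchar(fx$st)), fx$st, fx$ms, fx$me,
                             mfe = fx$mfe)
    expect_equal(rep$overall, fx$overall, label = paste("fixture", k))
    for (flag in names(fx$expect)) {
      expect_equal(rep[[flag]], fx$expect[[flag]],
                   label = paste("fixture", k, flag))
    }
  }
})

test_that("the MFEI gate is strict at 0.9", {
  st <- paste0(strrep("(", 47), strrep(".", 6), strrep(")", 47))
  s <- seq_gc50(100)
  at <- evaluate_criteria(s, st, 1, 21, mfe = -45)     # MFEI = 0.9
  above <- evaluate_criteria(s, st, 1, 21, mfe = -45.1)
  expect_false(at$c6_energy)
  expect_true(above$c6_energy)
  expect_equal(at$mfei, 0.9)
})

test_that("evaluate_criteria rejects a mature span outside the precursor", {
  st <- paste0(strrep("(", 25), strrep(".", 6), strrep(")", 25))
  expect_error(evaluate_criteria(seq_gc50(56), st, 40, 60, mfe = -50),
               "outside")
  expect_error(evaluate_criteria(seq_gc50(56), st, 0, 10, mfe = -50),
               "outside")
})

# ---- precursor window extraction ---------------------------------------

test_that("window combinations respect the total-length cap", {
  set.seed(5)
  genome <- c(chr1 = random_dna(1200))
  locus <- tibble::tibble(contig = "chr1", start = 600L, end = 621L,
                          strand = "+")
  cands <- extract_precursor_candidates(locus, genome)
  # 16 flank pairs minus (150,150) whose total 321 exceeds 300
  expect_equal(nrow(cands), 15L)
  expect_false(any(cands$flank5 == 150 & cands$flank3 == 150))
  expect_true(all(nchar(cands$precursor) <= 300))
  expect_true(all(!cands$truncated))
  # the mature span always excises the tag itself
  tag <- substr(genome[["chr1"]], 601, 621)
  expect_true(all(substr(cands$precursor, cands$mature_start,
                         cands$mature_end) == tag))
})

test_that("windows over a contig end are truncated and flagged", {
  set.seed(6)
  genome <- c(chr1 = random_dna(120))
  locus <- tibble::tibble(contig = "chr1", start = 10L, end = 31L,
                          strand = "+")
  cands <- extract_precursor_candidates(locus, genome)
  expect_true(all(cands$truncated[cands$flank5 > 10]))
  expect_true(all(cands$window_start >= 0 & cands$window_end <= 120))
})

test_that("minus-strand precursors are reverse-complemented correctly", {
  set.seed(7)
  tag <- random_dna(21)
  genome <- c(chr1 = paste0(random_dna(200), revcomp_chr(tag),
                            random_dna(200)))
  locus <- map_to_genome(tag, genome)
  expect_equal(locus$strand, "-")
  cands <- extract_precursor_candidates(locus, genome)
  expect_true(all(substr(cands$precursor, cands$mature_start,
                         cands$mature_end) == tag))
})

# ---- calling on the synthetic fixture ----------------------------------

test_that("call_novel_mirnas recovers planted hairpins and rejects decoys", {
  truth <- small_fixture()
  tags <- small_tags()
  cls <- classify_tags(tags, truth$refs)
  unann <- cls[cls$class == "unannotated", names(tags)]
  known <- match_known_mirnas(unann, truth$mature_db)
  unann <- unann[!unann$sequence %in% known$sequence, ]
  calls <- call_novel_mirnas(unann, truth$genome)
  rec <- evaluate_recovery(calls, truth, seed = 7)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$specificity, 1)
  # ids follow the cla-miR<n> series ordered by pooled count
  expect_equal(calls$id, sprintf("cla-miR%d", seq_len(nrow(calls))))
  expect_true(all(diff(calls$total) <= 0))
  # reported best window actually passes all criteria
  for (i in seq_len(nrow(calls))) {
    rep <- evaluate_criteria(calls$precursor[i], calls$structure[i],
                             calls$mature_start[i], calls$mature_end[i],
                             mfe = calls$mfe[i])
    expect_true(rep$overall)
  }
})

test_that("the pooled-count gate is strictly greater than min_reads", {
  truth <- small_fixture()
  hp <- truth$hairpins[truth$hairpins$type == "pass", ][1, ]
  tags <- tibble::tibble(sequence = hp$mature, length = nchar(hp$mature),
                         lib1 = 50L)
  expect_equal(nrow(call_novel_mirnas(tags, truth$genome)), 0L)
  tags$lib1 <- 51L
  expect_equal(nrow(call_novel_mirnas(tags, truth$genome)), 1L)
})

# ---- dinucleotide shuffle ----------------------------------------------

dinuc_counts <- function(s) {
  b <- strsplit(s, "")[[1]]
  table(paste0(b[-length(b)], b[-1]))
}

test_that("dinucleotide shuffle preserves composition and end bases", {
  set.seed(77)
  for (k in 1:10) {
    s <- random_dna(sample(30:80, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(as.list(dinuc_counts(sh)), as.list(dinuc_counts(s)))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)),
                 substr(s, nchar(s), nchar(s)))
  }
})

test_that("short sequences pass through the shuffle unchanged", {
  expect_equal(dinucleotide_shuffle("AC"), "AC")
})
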