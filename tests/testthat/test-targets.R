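# Exhaustive alignment-enumeration oracle: every placement of at most one
# gap (in whichever strand is shorter) is scored with plain loops.
oracle_duplex <- function(mirna, site, scoring = target_scoring()) {
  mi <- strsplit(mirna, "")[[1]]
  st <- rev(strsplit(site, "")[[1]])  # site read 3'->5'
  lm <- length(mi)
  ls <- length(st)
  w <- function(p) if (p >= scoring$core[1] && p <= scoring$core[2]) 2 else 1
  pen1 <- function(m, s) {
    ms <- paste0(m, s)
    if (ms %in% c("AT", "TA", "GC", "CG")) 0
    else if (ms %in% c("GT", "TG")) scoring$wobble
    else scoring$mismatch
  }
  if (ls == lm) {
    return(sum(vapply(seq_len(lm),
                      function(i) pen1(mi[i], st[i]) * w(i), numeric(1))))
  }
  best <- Inf
  if (ls == lm + 1) {
    for (g in seq_len(ls)) {          # gap in the miRNA row at column g
      sc <- scoring$gap * w(min(g, lm))
      for (col in seq_len(ls)) {
        if (col == g) next
        i <- if (col < g) col else col - 1L
        sc <- sc + pen1(mi[i], st[col]) * w(i)
      }
      best <- min(best, sc)
    }
  } else {
    for (g in seq_len(lm)) {          # gap in the site row at miRNA pos g
      sc <- scoring$gap * w(g)
      for (i in seq_len(lm)) {
        if (i == g) next
        col <- if (i < g) i else i - 1L
        sc <- sc + pen1(mi[i], st[col]) * w(i)
      }
      best <- min(best, sc)
    }
  }
  best
}

test_that("a perfect reverse-complement site scores 0", {
  set.seed(41)
  mi <- random_dna(21)
  aln <- score_duplex(mi, revcomp_chr(mi))
  expect_equal(aln$score, 0)
  expect_equal(aln$n_match, 21L)
  expect_equal(aln$n_gap, 0L)
  expect_equal(aln$aln_pairs, strrep("|", 21))
})

test_that("hand-scored single-position defects get the documented penalties", {
  # miRNA with G at position 5 and A at position 20, elsewhere A/C only so
  # the perfect site has no accidental wobbles
  mi <- paste0("CACC", "G", strrep("CA", 7), "C", "A")  # 21 nt
  expect_equal(nchar(mi), 21)
  expect_equal(substr(mi, 5, 5), "G")
  expect_equal(substr(mi, 20, 20), "C")
  site <- revcomp_chr(mi)
  # G:U wobble at miRNA position 5 (in core): site base opposite pos 5 is
  # site index 21 - 5 + 1 = 17, change C -> T
  site_wob <- site
  substr(site_wob, 17, 17) <- "T"
  aln <- score_duplex(mi, site_wob)
  expect_equal(aln$score, 1.0)     # 0.5 doubled in core
  expect_equal(aln$n_wobble, 1L)
  # mismatch at miRNA position 20 (outside core): site index 2 pairs it;
  # the complementary base there is G, and C:A is a plain mismatch
  site_mm <- site
  expect_equal(substr(site_mm, 2, 2), "G")
  substr(site_mm, 2, 2) <- "A"
  aln2 <- score_duplex(mi, site_mm)
  expect_equal(aln2$score, 1.0)    # 1.0 not doubled
  expect_equal(aln2$n_mismatch, 1L)
})

test_that("score_duplex equals the enumeration oracle (site length ±1)", {
  set.seed(57)
  for (k in 1:60) {
    lm <- sample(18:22, 1)
    mi <- random_dna(lm)
    ls <- lm + sample(-1:1, 1)
    site <- if (runif(1) < 0.5) {
      # near-complementary site with a few defects
      s <- revcomp_chr(mi)
      s <- substr(paste0(s, random_dna(2)), 1, ls)
      for (j in sample.int(ls, 3)) {
        substr(s, j, j) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    } else {
      random_dna(ls)
    }
    expect_equal(score_duplex(mi, site)$score, oracle_duplex(mi, site),
                 tolerance = 1e-9,
                 label = sprintf("duplex %s vs %s", mi, site))
  }
})

test_that("score_duplex rejects site lengths off by more than one", {
  mi <- "ACGTACGTACGTACGTACGTA"
  expect_error(score_duplex(mi, substr(mi, 1, 19)), "± 1")
})

test_that("an exact reverse-complement site is found at exact coordinates", {
  set.seed(63)
  mi <- random_dna(21)
  left <- random_dna(150)
  tx <- c(tx1 = paste0(left, revcomp_chr(mi), random_dna(150)))
  hits <- predict_targets(mi, tx, mirna_id = "miRX")
  exact <- hits[hits$score == 0, ]
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$transcript, "tx1")
  expect_equal(exact$start, 150L)            # 0-based half-open
  expect_equal(exact$end, 171L)
  expect_equal(substr(tx[["tx1"]], exact$start + 1, exact$end),
               revcomp_chr(mi))
  expect_equal(exact$mirna_id, "miRX")
})

test_that("a planted one-core-mismatch site is reported with score 2.0", {
  set.seed(65)
  mi <- random_dna(21)
  site <- revcomp_chr(mi)
  # mismatch opposite miRNA position 7 (core): site index 21 - 7 + 1 = 15
  b <- substr(site, 15, 15)
  # pick a replacement that is neither complementary nor a wobble partner
  m7 <- substr(mi, 7, 7)
  repl <- setdiff(c("A", "C", "G", "T"),
                  c(b, chartr("ACGT", "TGCA", m7),
                    if (m7 == "G") "T" else if (m7 == "T") "G" else NULL))[1]
  substr(site, 15, 15) <- repl
  tx <- c(tx1 = paste0(random_dna(100), site, random_dna(100)))
  hits <- predict_targets(mi, tx)
  expect_true(any(abs(hits$score - 2.0) < 1e-9 & hits$start == 100L))
})

test_that("random transcripts rarely contain sites at the default cutoff", {
  set.seed(71)
  n_hit <- 0L
  for (k in 1:100) {
    mi <- random_dna(21)
    tx <- c(t1 = random_dna(1000))
    if (nrow(predict_targets(mi, tx)) > 0) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 5L)  # >= 95% of trials hit-free
})

test_that("the score cutoff is monotone", {
  set.seed(83)
  mi <- random_dna(21)
  tx <- c(t1 = paste0(random_dna(80), revcomp_chr(mi), random_dna(80),
                      revcomp_chr(mi), random_dna(80)))
  # degrade the second copy a little
  for (c_small in c(0, 2)) {
    lo <- predict_targets(mi, tx, cutoff = c_small)
    hi <- predict_targets(mi, tx, cutoff = 4)
    key <- function(h) paste(h$transcript, h$start, h$end)
    expect_true(all(key(lo) %in% key(hi)))
    expect_true(all(lo$score <= c_small))
  }
})

test_that("hits are sorted by score then transcript id", {
  set.seed(97)
  mi <- random_dna(21)
  deg <- revcomp_chr(mi)
  substr(deg, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(deg, 3, 3))[1]
  tx <- c(tb = paste0(random_dna(50), revcomp_chr(mi), random_dna(50)),
          ta = paste0(random_dna(50), deg, random_dna(50)))
  hits <- predict_targets(mi, tx)
  expect_true(all(diff(hits$score) >= 0))
  same <- split(hits$transcript, hits$score)
  for (grp in same) expect_equal(grp, sort(grp))
})

test_that("planted sites in the synthetic truth are all recovered", {
  truth <- small_fixture()
  ts <- truth$target_sites
  for (r in seq_len(nrow(ts))) {
    mi <- truth$mature_db[[ts$mirna_id[r]]]
    hits <- predict_targets(mi, truth$transcripts, mirna_id = ts$mirna_id[r])
    hit <- hits[hits$transcript == ts$transcript[r] &
                  hits$start == ts$start[r], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$score, 0)
  }
})
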