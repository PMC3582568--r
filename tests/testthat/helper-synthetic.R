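# Shared small-scale synthetic fixture, generated once per test session.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(genome_size = 60000, n_pass = 5, n_decoy = 5,
                              n_known = 6, n_transcripts = 8)
      truth <- generate_reference(cfg, seed = 7)
      truth <- simulate_libraries(truth, depth = 2e4, seed = 7,
                                  dir = file.path(tempdir(), "clamir_small"))
      cache <<- truth
    }
    cache
  }
})

# clean + collapse the small fixture's libraries once
small_tags <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- small_fixture()
      cleaned <- lapply(truth$fastq, function(p) {
        clean_reads(read_srna_fastq(p), adapter3 = truth$config$adapter)
      })
      cache <<- collapse_tags(lapply(cleaned, function(x) x$sequence))
    }
    cache
  }
})

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
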