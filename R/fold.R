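#' Folding energy parameters
#'
#' Parameter table (version 1) of the nearest-neighbor energy model used by
#' [fold_rna()]: stacking energies for the sixteen Watson-Crick stacks plus
#' G:T wobble combinations, logarithmic hairpin/bulge/internal-loop penalties,
#' and an affine multibranch term. All energies are in kcal/mol at a fixed
#' nominal temperature. The same table drives both the C++ dynamic program
#' and the R re-evaluator [structure_energy()], so reported energies are
#' reproducible from the returned structure alone.
#'
#' Externally folded structures (e.g. Vienna output) can be imported with
#' [read_vienna()] and carried through the downstream criteria unchanged.
#'
#' @param max_loop maximum number of unpaired bases allowed in a single
#'   bulge/internal loop during folding (larger loops are never proposed by
#'   the DP; imported structures are evaluated as-is).
#' @return a list with elements `stack` (6x6 matrix, pair order
#'   AT, TA, GC, CG, GT, TG), `hairpin`, `bulge`, `internal` (each
#'   `c(a, b)` for `a + b * log(n / n0)`), `multi` (`c(closing, branch,
#'   unpaired)`), `max_loop` and `version`.
#' @export
fold_params <- function(max_loop = 30L) {
  pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
  stack <- matrix(c(
    # inner:  AT    TA    GC    CG    GT    TG     (outer pair = row)
            -0.9, -1.1, -2.1, -2.2, -0.6, -1.4,   # AT
            -1.3, -0.9, -2.1, -2.4, -1.0, -1.3,   # TA
            -2.4, -2.2, -3.3, -3.4, -1.5, -2.5,   # GC
            -2.1, -2.1, -2.4, -3.3, -1.4, -2.1,   # CG
            -1.3, -1.4, -2.1, -2.5, -0.5, -0.4,   # GT
            -1.0, -0.6, -1.4, -1.5, -0.3, -0.5    # TG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  list(
    stack    = stack,
    hairpin  = c(5.0, 1.75),   # a + b * log(n/3), n >= 3
    bulge    = c(3.8, 1.75),   # a + b * log(n),   n >= 1
    internal = c(4.0, 1.75),   # a + b * log(n/2), n >= 2
    multi    = c(4.6, 0.4, 0.1),
    max_loop = as.integer(max_loop),
    version  = "clamir-nn-1"
  )
}

normalize_seq <- function(sequence) {
  s <- toupper(sequence)
  s <- chartr("U", "T", s)
  s
}

#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Computes the minimum-energy nested structure (no pseudoknots, hairpin
#' loops of at least 3 unpaired bases, Watson-Crick and G:T(U) wobble pairs)
#' under the model in [fold_params()]. Deterministic: energy ties are broken
#' toward fewer pairs (unpaired preferred), then by a fixed decomposition
#' order (hairpin, stack, interior loop, multibranch; leftmost branch first).
#'
#' @param sequence nucleotide string (A/C/G/T; U is normalized to T), length
#'   at least 10.
#' @param params energy parameters, see [fold_params()].
#' @return an object of class `clamir_fold`: list with `sequence`,
#'   `structure` (dot-bracket), `energy` (kcal/mol, `<= 0`), `params_version`.
#' @examples
#' fold_rna("GGGGAAAACCCC")
#' @export
fold_rna <- function(sequence, params = fold_params()) {
  s <- normalize_seq(sequence)
  if (nchar(s) < 10) stop("unfoldable: sequence shorter than 10 nt")
  if (grepl("[^ACGT]", s)) stop("sequence alphabet must be A/C/G/T(U)")
  res <- .fold_mfe_cpp(s, params$stack, params$hairpin, params$bulge,
                       params$internal, params$multi, params$max_loop)
  structure(
    list(sequence = s, structure = res$structure, energy = res$energy,
         params_version = params$version),
    class = "clamir_fold"
  )
}

#' @export
print.clamir_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.2f", x$energy), ")\n",
      sep = "")
  invisible(x)
}

#' Parse a dot-bracket string into a pairing vector
#'
#' @param structure dot-bracket string using `(`, `)` and `.`.
#' @return integer vector: `p[i]` is the 1-based partner of position `i`,
#'   `NA` if unpaired.
#' @export
dot_bracket_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  p <- rep(NA_integer_, length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      j <- open[length(open)]
      open <- open[-length(open)]
      p[j] <- i
      p[i] <- j
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  p
}

#' Recompute the energy of a structure from its dot-bracket string
#'
#' Independent (non-DP) evaluation of the energy model in [fold_params()]
#' by loop decomposition: each base pair closes a hairpin, a stacked pair,
#' a bulge/internal loop or a multibranch loop; the external region is free.
#'
#' @param sequence nucleotide string.
#' @param structure matching dot-bracket string.
#' @param params energy parameters, see [fold_params()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure, params = fold_params()) {
  s <- normalize_seq(sequence)
  if (nchar(s) != nchar(structure)) stop("sequence/structure length mismatch")
  p <- dot_bracket_pairs(structure)
  b <- strsplit(s, "")[[1]]
  pair_name <- function(i, j) paste0(b[i], b[j])
  valid <- rownames(params$stack)
  e <- 0
  opens <- which(!is.na(p) & p > seq_along(p))
  for (i in opens) {
    j <- p[i]
    pn <- pair_name(i, j)
    if (!pn %in% valid) stop("non-WC/wobble pair ", pn, " at (", i, ",", j, ")")
    # children: pairs directly inside (i, j)
    k <- i + 1
    children <- list()
    unpaired <- 0L
    while (k < j) {
      if (is.na(p[k])) {
        unpaired <- unpaired + 1L
        k <- k + 1
      } else {
        children[[length(children) + 1]] <- c(k, p[k])
        k <- p[k] + 1
      }
    }
    nb <- length(children)
    if (nb == 0) {
      if (unpaired < 3) stop("hairpin loop shorter than 3 at (", i, ",", j, ")")
      e <- e + params$hairpin[1] + params$hairpin[2] * log(unpaired / 3)
    } else if (nb == 1) {
      k <- children[[1]][1]; l <- children[[1]][2]
      d5 <- k - i - 1L; d3 <- j - l - 1L
      if (d5 + d3 == 0) {
        e <- e + params$stack[pn, pair_name(k, l)]
      } else if (d5 == 0 || d3 == 0) {
        e <- e + params$bulge[1] + params$bulge[2] * log(d5 + d3)
      } else {
        e <- e + params$internal[1] + params$internal[2] * log((d5 + d3) / 2)
      }
    } else {
      e <- e + params$multi[1] + params$multi[2] * (nb + 1) +
        params$multi[3] * unpaired
    }
  }
  e
}

#' Folding metrics: MFE, AMFE and MFEI
#'
#' AMFE is the absolute minimum free energy per 100 nt; MFEI is AMFE divided
#' by the G+C percentage of the sequence. MFEI is reported positive (computed
#' on |MFE|). Both are standard discriminators of miRNA precursors, whose
#' MFEI typically exceeds that of tRNA/rRNA/mRNA fragments.
#'
#' Either pass a `clamir_fold` object, or pass `mfe`, `length` and `gc`
#' directly.
#'
#' @param fold a `clamir_fold` object (optional).
#' @param mfe minimum free energy, kcal/mol (usually negative).
#' @param length sequence length, nt.
#' @param gc G+C fraction in `[0, 1]`.
#' @return a tibble with columns `length`, `gc`, `mfe`, `amfe`, `mfei`
#'   (`mfei` is `NA` when `gc == 0`).
#' @examples
#' compute_metrics(mfe = -60, length = 100, gc = 0.5) # AMFE 60, MFEI 1.2
#' @export
compute_metrics <- function(fold = NULL, mfe = NULL, length = NULL, gc = NULL) {
  if (!is.null(fold)) {
    stopifnot(inherits(fold, "clamir_fold"))
    mfe <- fold$energy
    length <- nchar(fold$sequence)
    b <- strsplit(fold$sequence, "")[[1]]
    gc <- mean(b %in% c("G", "C"))
  }
  stopifnot(is.numeric(mfe), is.numeric(length), is.numeric(gc),
            length > 0, gc >= 0, gc <= 1)
  amfe <- abs(mfe) * 100 / length
  mfei <- if (gc > 0) amfe / (gc * 100) else NA_real_
  tibble::tibble(length = length, gc = gc, mfe = mfe, amfe = amfe, mfei = mfei)
}

#' Decompose a hairpin structure into arms, terminal loop and bulges
#'
#' Accepts a `clamir_fold` object or a dot-bracket string. A structure
#' qualifies as a hairpin when it contains exactly one terminal loop (one
#' innermost base pair); multibranch structures and structures with two or
#' more separate stem-loops are rejected.
#'
#' @param structure `clamir_fold` object or dot-bracket string.
#' @return a list of class `clamir_hairpin` with elements `is_hairpin`,
#'   `arm5`/`arm3` (1-based inclusive spans `c(start, end)`), `loop` (span),
#'   `n_stem_pairs`, `bulges` (tibble: `side` in `"5p"/"3p"/"internal"`,
#'   `size`, `n5`, `n3`, spans, `biased`, `biased_errors`), `paired`
#'   (logical per position), and `n` (structure length). When not a hairpin,
#'   `is_hairpin` is `FALSE` and the remaining fields are `NULL`.
#' @examples
#' decompose_hairpin("((((....))))")
#' @export
decompose_hairpin <- function(structure) {
  db <- if (inherits(structure, "clamir_fold")) structure$structure else structure
  p <- dot_bracket_pairs(db)
  n <- length(p)
  opens <- which(!is.na(p) & p > seq_len(n))
  not_hairpin <- function() {
    structure(list(is_hairpin = FALSE, n = n, paired = !is.na(p)),
              class = "clamir_hairpin")
  }
  if (!length(opens)) return(not_hairpin())
  # terminal loops: pairs with no pair strictly inside
  inner <- vapply(opens, function(i) {
    j <- p[i]
    span <- seq(i + 1, j - 1)
    length(span) > 0 && all(is.na(p[span]))
  }, logical(1))
  if (sum(inner) != 1) return(not_hairpin())
  it <- opens[inner]
  jt <- p[it]
  # all pairs must nest around the terminal loop (always true if single loop)
  if (!all(opens <= it & p[opens] >= jt)) return(not_hairpin())
  f <- min(opens)
  l <- p[f]
  # walk the stem outermost -> innermost collecting bulges
  ord <- sort(opens)
  bul <- list()
  for (k in seq_along(ord)[-length(ord)]) {
    i1 <- ord[k]; j1 <- p[i1]
    i2 <- ord[k + 1]; j2 <- p[i2]
    d5 <- i2 - i1 - 1L
    d3 <- j1 - j2 - 1L
    if (d5 + d3 > 0) {
      bul[[length(bul) + 1]] <- tibble::tibble(
        side = if (d3 == 0) "5p" else if (d5 == 0) "3p" else "internal",
        size = d5 + d3, n5 = d5, n3 = d3,
        start5 = if (d5 > 0) i1 + 1L else NA_integer_,
        end5   = if (d5 > 0) i2 - 1L else NA_integer_,
        start3 = if (d3 > 0) j2 + 1L else NA_integer_,
        end3   = if (d3 > 0) j1 - 1L else NA_integer_,
        biased = (d5 == 0 || d3 == 0),
        biased_errors = abs(d5 - d3)
      )
    }
  }
  bulges <- if (length(bul)) dplyr::bind_rows(bul) else tibble::tibble(
    side = character(), size = integer(), n5 = integer(), n3 = integer(),
    start5 = integer(), end5 = integer(), start3 = integer(),
    end3 = integer(), biased = logical(), biased_errors = integer())
  structure(list(
    is_hairpin = TRUE,
    arm5 = c(f, it), arm3 = c(jt, l),
    loop = c(it + 1L, jt - 1L),
    n_stem_pairs = length(opens),
    bulges = bulges,
    paired = !is.na(p),
    n = n
  ), class = "clamir_hairpin")
}

#' @export
print.clamir_hairpin <- function(x, ...) {
  if (!x$is_hairpin) {
    cat("<not a hairpin>\n")
  } else {
    cat("<hairpin> stem pairs:", x$n_stem_pairs,
        " loop:", x$loop[1], "-", x$loop[2],
        " bulges:", nrow(x$bulges), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-position view of a folded structure
#'
#' @param x a `clamir_fold` object.
#' @param ... unused.
#' @return tibble with `position`, `base`, `symbol`, `partner`, `paired`.
#' @export
tidy.clamir_fold <- function(x, ...) {
  p <- dot_bracket_pairs(x$structure)
  tibble::tibble(
    position = seq_along(p),
    base = strsplit(x$sequence, "")[[1]],
    symbol = strsplit(x$structure, "")[[1]],
    partner = p,
    paired = !is.na(p)
  )
}

#' One-row summary of a folded structure
#'
#' @param x a `clamir_fold` object.
#' @param ... unused.
#' @return tibble with `length`, `gc`, `mfe`, `amfe`, `mfei`, `n_pairs`.
#' @export
glance.clamir_fold <- function(x, ...) {
  m <- compute_metrics(x)
  m$n_pairs <- sum(!is.na(dot_bracket_pairs(x$structure))) / 2L
  m
}

#' Read a Vienna-format structure file
#'
#' Vienna format: a `>`-header line, the sequence line, then the dot-bracket
#' line with an optional trailing `(energy)`. Use this to import externally
#' folded structures (e.g. RNAfold/mFold output converted to Vienna) in place
#' of the in-package folding model.
#'
#' @param path file path.
#' @return a list of `clamir_fold` objects (named by header when present).
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    name <- NULL
    if (startsWith(lines[i], ">")) {
      name <- sub("^>\\s*", "", lines[i])
      i <- i + 1
    }
    seq <- normalize_seq(lines[i])
    sl <- lines[i + 1]
    m <- regmatches(sl, regexec("^([.()]+)\\s*(\\((-?[0-9.]+)\\))?\\s*$", sl))[[1]]
    if (!length(m)) stop("malformed Vienna structure line: ", sl)
    db <- m[2]
    energy <- if (nzchar(m[4])) as.numeric(m[4]) else
      structure_energy(seq, db)
    if (nchar(db) != nchar(seq)) stop("Vienna sequence/structure length mismatch")
    fd <- structure(list(sequence = seq, structure = db, energy = energy,
                         params_version = "imported"), class = "clamir_fold")
    out[[length(out) + 1]] <- fd
    if (!is.null(name)) names(out)[length(out)] <- name
    i <- i + 2
  }
  out
}

#' Write structures to a Vienna-format file
#'
#' @param folds a `clamir_fold` object or list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(folds, path) {
  if (inherits(folds, "clamir_fold")) folds <- list(folds)
  nm <- names(folds)
  if (is.null(nm)) nm <- paste0("structure_", seq_along(folds))
  lines <- unlist(lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    c(paste0(">", nm[i]), f$sequence,
      sprintf("%s (%.2f)", f$structure, f$energy))
  }))
  writeLines(lines, path)
  invisible(path)
}
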