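## DNA primitives and nearest-neighbor thermodynamics.
##
## All coordinates in this package are 0-based half-open on the forward strand;
## conversion to 1-based happens only inside substr() calls and at I/O boundaries.

.DNA_RE <- "[^ACGTN]"

assert_dna <- function(x, what = "sequence", allow_n = TRUE, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single non-NA character string", what),
          class = "pmedit_input_error")
  }
  if (!allow_empty && nchar(x) == 0L) {
    abort(sprintf("%s must be non-empty", what), class = "pmedit_input_error")
  }
  bad <- regexpr(if (allow_n) .DNA_RE else "[^ACGT]", x)
  if (bad > 0L) {
    abort(sprintf("%s contains illegal character '%s' at position %d",
                  what, substr(x, bad, bad), bad),
          class = "pmedit_input_error")
  }
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed. `N` maps to `N`; the empty string maps to
#' itself. Vectorized over `seq`.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}` (uppercase).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AAAACC")
reverse_complement <- function(seq) {
  if (!is.character(seq)) abort("seq must be character", class = "pmedit_input_error")
  bad <- grepl(.DNA_RE, seq)
  if (any(bad)) {
    assert_dna(seq[bad][1], what = "seq")  # raises with position info
  }
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' GC fraction of a DNA sequence
#'
#' @param seq A single DNA sequence (non-empty).
#' @return `(#G + #C) / length`, a fraction in `[0, 1]`. `N` counts toward the
#'   denominator only.
#' @export
gc_fraction <- function(seq) {
  assert_dna(seq, what = "seq")
  stringr::str_count(seq, "[GC]") / nchar(seq)
}

## Unified nearest-neighbor parameters (SantaLucia-98-style duplex table).
## dH in kcal/mol, dS in cal/(mol*K).
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
## Duplex initiation, per terminal base pair.
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.9872  # cal/(mol*K)

## Raw nearest-neighbor Tm, no length cap (internal; assumes clean ACGT input).
.tm_nn <- function(seq, salt_mM = 50, oligo_nM = 50) {
  n <- nchar(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  steps <- paste0(b[-n], b[-1])
  dh <- sum(.NN_DH[steps]) + .INIT_DH[[b[1]]] + .INIT_DH[[b[n]]]
  ds <- sum(.NN_DS[steps]) + .INIT_DS[[b[1]]] + .INIT_DS[[b[n]]] +
    0.368 * (n - 1) * log(salt_mM / 1000)
  1000 * dh / (ds + .GAS_R * log(oligo_nM * 1e-9 / 4)) - 273.15
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of an oligonucleotide bound to its perfect
#' complement, from the unified nearest-neighbor dH/dS table with monovalent
#' salt correction `dS + 0.368 (n-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15`.
#'
#' @param seq Oligo sequence, 2-60 nt, `{A,C,G,T}` only.
#' @param salt_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Total oligo concentration in nM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, salt_mM = 50, oligo_nM = 50) {
  assert_dna(seq, what = "seq", allow_n = FALSE)
  n <- nchar(seq)
  if (n < 2L || n > 60L) {
    abort(sprintf("seq length must be in [2, 60], got %d", n),
          class = "pmedit_input_error")
  }
  .tm_nn(seq, salt_mM = salt_mM, oligo_nM = oligo_nM)
}

## Position-wise thermodynamic profile of a template, for O(1) window Tm/GC.
tm_profile <- function(template, salt_mM = 50, oligo_nM = 50) {
  n <- nchar(template)
  b <- strsplit(template, "", fixed = TRUE)[[1]]
  steps <- paste0(b[-n], b[-1])
  list(
    n = n, bases = b,
    dh_c = c(0, cumsum(unname(.NN_DH[steps]))),   # length n; sum steps a..b-1 = dh_c[b]-dh_c[a]
    ds_c = c(0, cumsum(unname(.NN_DS[steps]))),
    gc_c = c(0L, cumsum(b %in% c("G", "C"))),     # length n+1
    n_c  = c(0L, cumsum(b == "N")),
    salt_mM = salt_mM, oligo_nM = oligo_nM
  )
}

## Vectorized window Tm over a profile; start0 0-based, len window length.
## Windows containing N get NA.
tm_window <- function(p, start0, len) {
  i1 <- start0 + 1L
  last <- start0 + len
  dh <- (p$dh_c[last] - p$dh_c[i1]) + .INIT_DH[p$bases[i1]] + .INIT_DH[p$bases[last]]
  ds <- (p$ds_c[last] - p$ds_c[i1]) + .INIT_DS[p$bases[i1]] + .INIT_DS[p$bases[last]] +
    0.368 * (len - 1) * log(p$salt_mM / 1000)
  tm <- 1000 * dh / (ds + .GAS_R * log(p$oligo_nM * 1e-9 / 4)) - 273.15
  tm[(p$n_c[last + 1L] - p$n_c[i1]) > 0L] <- NA_real_
  unname(tm)
}

gc_window <- function(p, start0, len) {
  unname((p$gc_c[start0 + len + 1L] - p$gc_c[start0 + 1L]) / len)
}

#' Sentinel returned when no stable duplex or hairpin exists
#' @export
NO_DUPLEX_TM <- -Inf

#' Heteroduplex/homoduplex melting temperature (ungapped screen)
#'
#' Slides `a` against `reverse_complement(b)` over every ungapped offset, finds
#' maximal complementary runs, and returns the nearest-neighbor Tm of the most
#' stable run. Runs shorter than `min_run` nucleotides are ignored; when no run
#' qualifies the sentinel [NO_DUPLEX_TM] (`-Inf`) is returned. The homodimer
#' screen is `duplex_tm(a, a)`; a perfect duplex `duplex_tm(s, reverse_complement(s))`
#' equals `melting_temperature(s)`.
#'
#' @param a,b DNA sequences (non-empty, no N).
#' @param salt_mM,oligo_nM Passed to the nearest-neighbor model.
#' @param min_run Minimum complementary run length (default 4).
#' @return Tm in degrees Celsius, or `-Inf`.
#' @export
duplex_tm <- function(a, b, salt_mM = 50, oligo_nM = 50, min_run = 4L) {
  assert_dna(a, "a", allow_n = FALSE); assert_dna(b, "b", allow_n = FALSE)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(reverse_complement(b), "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  best <- NO_DUPLEX_TM
  for (off in (-(la - 1L)):(lb - 1L)) {
    i <- max(1L, 1L - off):min(la, lb - off)
    eq <- av[i] == bv[i + off]
    r <- rle(eq)
    if (!any(r$values & r$lengths >= min_run)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      run_seq <- substr(a, i[1] + starts[k] - 1L, i[1] + ends[k] - 1L)
      tm <- .tm_nn(run_seq, salt_mM = salt_mM, oligo_nM = oligo_nM)
      if (tm > best) best <- tm
    }
  }
  best
}

#' Hairpin melting temperature (intramolecular screen)
#'
#' Finds inverted-repeat stems within `seq` (complementary anti-diagonal runs
#' with a loop of at least `min_loop` unpaired bases) and returns the
#' nearest-neighbor Tm of the most stable stem, or [NO_DUPLEX_TM] when no stem
#' of `min_stem` or more base pairs exists. A coarse screen, not a partition
#' function.
#'
#' @param seq DNA sequence (no N).
#' @param salt_mM,oligo_nM Passed to the nearest-neighbor model.
#' @param min_stem Minimum stem length in base pairs (default 4).
#' @param min_loop Minimum loop length in nucleotides (default 3).
#' @return Tm in degrees Celsius, or `-Inf`.
#' @export
hairpin_tm <- function(seq, salt_mM = 50, oligo_nM = 50, min_stem = 4L, min_loop = 3L) {
  assert_dna(seq, "seq", allow_n = FALSE)
  n <- nchar(seq)
  if (n < 2L * min_stem + min_loop) return(NO_DUPLEX_TM)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", b)
  best <- NO_DUPLEX_TM
  ## pairs (i, j), i < j, b[i] complementary to b[j]; stems run along i+j = s+1.
  for (s in (2L * min_stem + min_loop):(2L * n - 2L * min_stem - min_loop)) {
    i_max <- (s - min_loop) %/% 2L          # innermost admissible i (loop = j-i-1 >= min_loop)
    i_min <- max(1L, s + 1L - n)
    if (i_max - i_min + 1L < min_stem) next
    ii <- i_min:i_max
    eq <- b[ii] == comp[s + 1L - ii]
    r <- rle(eq)
    if (!any(r$values & r$lengths >= min_stem)) next
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_stem)) {
      i0 <- ii[1] + ends[k] - r$lengths[k]
      stem <- substr(seq, i0, i0 + r$lengths[k] - 1L)
      tm <- .tm_nn(stem, salt_mM = salt_mM, oligo_nM = oligo_nM)
      if (tm > best) best <- tm
    }
  }
  best
}

#' Find all exact occurrences of a query on both genome strands
#'
#' Reports 0-based half-open start coordinates on the forward strand. A hit on
#' the minus strand means `reverse_complement(query)` occurs at that forward
#' position.
#'
#' @param query DNA sequence, length >= 11.
#' @param genome A genome as returned by [read_genome_fasta()] or
#'   [generate_fixture()] (named character vector of contigs).
#' @return A tibble with columns `contig`, `start` (0-based), `strand`.
#' @export
find_exact_matches <- function(query, genome) {
  assert_dna(query, "query")
  if (nchar(query) < 11L) {
    abort("query must be at least 11 nt", class = "pmedit_input_error")
  }
  contigs <- as_genome(genome)
  rcq <- reverse_complement(query)
  one <- function(pattern, contig_seq) {
    m <- gregexpr(pattern, contig_seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  out <- imap(contigs, function(s, nm) {
    fwd <- one(query, s)
    rev <- one(rcq, s)
    tibble(
      contig = nm,
      start = c(fwd, rev),
      strand = c(rep("+", length(fwd)), rep("-", length(rev)))
    )
  })
  arrange(bind_rows(out), .data$contig, .data$start, .data$strand)
}

## Coerce the genome representations used across the package to a plain named
## character vector of contigs.
as_genome <- function(genome) {
  if (inherits(genome, "pm_genome")) return(unclass(genome))
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("contig_", seq_along(genome))
    return(genome)
  }
  abort("genome must be a pm_genome or a named character vector of contigs",
        class = "pmedit_input_error")
}

## k-mer index of a genome: per contig, a named list kmer -> 0-based start
## positions. Built once per batch and reused by the off-target scanner.
genome_kmer_index <- function(genome, k) {
  contigs <- as_genome(genome)
  idx <- lapply(contigs, function(s) {
    n <- nchar(s)
    if (n < k) return(list())
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    split(0:(n - k), kmers)
  })
  structure(list(k = k, index = idx), class = "pm_kmer_index")
}
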