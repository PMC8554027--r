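## Off-target evaluation of homologous arms (seed-and-extend gapless scan) and
## 3'-end mis-priming warnings for primers.

empty_hits <- function() {
  tibble(contig = character(), start = integer(), strand = character(),
         identity = double(), aligned_length = integer())
}

#' Scan a homologous arm for secondary genomic matches
#'
#' Seed-and-extend search: every exact `offtarget_seed_len`-mer of the arm
#' (both strands) is looked up in the genome; each seed hit defines an ungapped
#' diagonal along which the full arm is compared to the genome, and diagonals
#' with identity at least `offtarget_identity_threshold` over at least half the
#' arm length are reported. Hits overlapping the intended locus are excluded.
#' Gapless extension only: paralogs that differ by indels are a documented
#' limitation.
#'
#' @param arm Arm sequence (length >= `offtarget_seed_len`).
#' @param genome A `pm_genome`.
#' @param intended Optional intended locus to exclude: list or one-row data
#'   frame with `contig`, `start`, `end` (0-based half-open, forward strand).
#' @param params A [design_parameters()] object.
#' @param index Optional precomputed [genome_kmer_index()] at the seed length
#'   (built on the fly otherwise; pass one when scanning many arms).
#' @return A tibble of hits: `contig`, `start` (0-based), `strand`, `identity`,
#'   `aligned_length`.
#' @export
scan_arm <- function(arm, genome, intended = NULL, params = design_parameters(),
                     index = NULL) {
  assert_dna(arm, "arm")
  k <- params$offtarget_seed_len
  thr <- params$offtarget_identity_threshold
  la <- nchar(arm)
  if (la < k) {
    abort(sprintf("arm (%d nt) shorter than the seed length (%d)", la, k),
          class = "pmedit_input_error")
  }
  contigs <- as_genome(genome)
  if (is.null(index)) index <- genome_kmer_index(contigs, k)
  stopifnot(index$k == k)
  min_alen <- ceiling(la / 2)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") arm else reverse_complement(arm)
    qv <- strsplit(q, "", fixed = TRUE)[[1]]
    seeds <- substring(q, 1:(la - k + 1L), k:la)
    for (nm in names(contigs)) {
      tab <- index$index[[nm]]
      pos_lists <- tab[seeds]
      qpos <- rep(0:(la - k), lengths(pos_lists))
      gpos <- unlist(pos_lists, use.names = FALSE)
      if (length(gpos) == 0L) next
      diags <- unique(gpos - qpos)
      gv <- strsplit(contigs[[nm]], "", fixed = TRUE)[[1]]
      nc <- length(gv)
      for (d in diags) {
        qlo <- max(0L, -d)                      # 0-based arm offset
        qhi <- min(la, nc - d)
        alen <- qhi - qlo
        if (alen < min_alen) next
        matches <- sum(qv[(qlo + 1L):qhi] == gv[(d + qlo + 1L):(d + qhi)])
        identity <- matches / alen
        if (identity >= thr) {
          out[[length(out) + 1L]] <- tibble(
            contig = nm, start = as.integer(d + qlo), strand = strand,
            identity = identity, aligned_length = as.integer(alen)
          )
        }
      }
    }
  }
  hits <- if (length(out)) bind_rows(out) else empty_hits()
  if (!is.null(intended) && nrow(hits) > 0L) {
    keep <- !(hits$contig == intended$contig &
                hits$start < intended$end &
                (hits$start + hits$aligned_length) > intended$start)
    hits <- hits[keep, ]
  }
  arrange(dplyr::distinct(hits), .data$contig, .data$start, .data$strand)
}

#' Mis-priming warnings for a primer's 3' end
#'
#' Reports every genomic occurrence (either strand) of the primer's 3'-terminal
#' `misprime_kmer`-mer outside the intended binding site. These are warnings:
#' a shared 3' word does not guarantee mis-amplification, but flags loci worth
#' checking.
#'
#' @param primer A `pm_primer`, or a plain primer sequence.
#' @param genome A `pm_genome`.
#' @param intended Optional intended 3'-end locus to exclude (list with
#'   `contig`, `start`, `end`, 0-based half-open forward-strand coordinates of
#'   the terminal k-mer's template footprint).
#' @param params A [design_parameters()] object.
#' @return A tibble of warnings: `contig`, `start` (0-based), `strand`.
#' @export
scan_primer_3prime <- function(primer, genome, intended = NULL,
                               params = design_parameters()) {
  seq <- if (inherits(primer, "pm_primer")) primer$full else primer
  assert_dna(seq, "primer")
  k <- params$misprime_kmer
  if (nchar(seq) < k) {
    abort(sprintf("primer (%d nt) shorter than misprime_kmer (%d)", nchar(seq), k),
          class = "pmedit_input_error")
  }
  kmer <- substr(seq, nchar(seq) - k + 1L, nchar(seq))
  hits <- find_exact_matches(kmer, genome)
  if (!is.null(intended) && nrow(hits) > 0L) {
    keep <- !(hits$contig == intended$contig &
                hits$start < intended$end &
                (hits$start + k) > intended$start)
    hits <- hits[keep, ]
  }
  hits
}

## Genomic footprint (0-based half-open, forward strand) of a primer's
## 3'-terminal k-mer, for intended-site exclusion. Edited-context coordinates
## at or beyond the junction window end are shifted back to wild-type
## coordinates by the edit length.
primer_kmer_footprint <- function(res, p, k) {
  if (p$role == "test-primer-2") return(NULL)       # binds the vector, not the genome
  shift_at <- res$w + res$overlap_len
  to_wild <- function(x) ifelse(x >= shift_at, x - res$edited$shift, x)
  if (p$orientation == "fwd") {
    lo <- p$match_end - k
    hi <- p$match_end
  } else {
    lo <- p$match_start
    hi <- p$match_start + k
  }
  list(contig = res$locus$contig,
       start = res$locus$context_start + to_wild(lo),
       end = res$locus$context_start + to_wild(hi))
}
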