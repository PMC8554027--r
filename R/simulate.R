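## In-silico verification of a design: simulate PCR of both arm amplicons,
## overlap-join them with the vector into the circular suicide plasmid, then
## simulate both single-crossover events (integration and resolution).

#' Simulate overlap assembly of a design into the circular plasmid
#'
#' Rebuilds both PCR products from the actual primer strings (5' tail + genomic
#' span + reverse complement of the reverse primer's tail), checks that the
#' three 20-mer junctions (vector/UHA, UHA/DHA via the junction window,
#' DHA/vector) agree exactly, and returns the circular plasmid sequence in
#' canonical rotation (starting at vector position 0). A disagreeing junction
#' raises an error of class `pmedit_assembly_error` (reason
#' `ASSEMBLY_JUNCTION_MISMATCH`); this never happens for an unmodified valid
#' design.
#'
#' @param result A `pm_design_result`.
#' @param vector The vector backbone sequence used for the design.
#' @return The circular plasmid as a string (class `pm_plasmid`), with
#'   attributes `vector_len` and `insert_len`.
#' @export
assemble_in_silico <- function(result, vector) {
  stopifnot(inherits(result, "pm_design_result"))
  ov <- result$overlap_len
  E <- result$edited$edited
  w <- result$w
  p <- result$primers
  ## PCR products from the primers as ordered oligos.
  amp_uha <- paste0(p[["primer-1"]]$tail,
                    substr(E, result$u_start + 1L, w),
                    reverse_complement(p[["primer-2"]]$tail))
  amp_dha <- paste0(p[["primer-3"]]$tail,
                    substr(E, w + ov + 1L, result$d_end),
                    reverse_complement(p[["primer-4"]]$tail))
  nv <- nchar(vector)
  frag_head <- function(x) substr(x, 1L, ov)
  frag_tail <- function(x) substr(x, nchar(x) - ov + 1L, nchar(x))
  if (result$convention == "swapped") {
    ## The insert sits inverted in the circle: traverse rc(DHA amp), rc(UHA amp).
    amp_a <- reverse_complement(amp_dha)
    amp_b <- reverse_complement(amp_uha)
  } else {
    amp_a <- amp_uha
    amp_b <- amp_dha
  }
  junctions <- list(
    c("vector/arm", frag_tail(vector), frag_head(amp_a)),
    c("arm/arm", frag_tail(amp_a), frag_head(amp_b)),
    c("arm/vector", frag_tail(amp_b), frag_head(vector))
  )
  for (j in junctions) {
    if (j[2] != j[3]) {
      abort(sprintf("ASSEMBLY_JUNCTION_MISMATCH at %s junction: %s vs %s", j[1], j[2], j[3]),
            class = "pmedit_assembly_error")
    }
  }
  circle <- paste0(vector,
                   substr(amp_a, ov + 1L, nchar(amp_a)),
                   substr(amp_b, ov + 1L, nchar(amp_b) - ov))
  structure(circle, vector_len = nv,
            insert_len = nchar(circle) - nv, class = "pm_plasmid")
}

#' @export
print.pm_plasmid <- function(x, ...) {
  cat(sprintf("<pm_plasmid> circular, %d nt (vector %d + insert %d)\n",
              nchar(x), attr(x, "vector_len"), attr(x, "insert_len")))
  invisible(x)
}

#' Simulate integration and resolution of the suicide plasmid
#'
#' Models the first single crossover (integration of the circular plasmid into
#' the chromosome through the shared upstream or downstream homology) to
#' produce the integrant used for verification-1 PCR (test-primer-1/2; the
#' test-primer-2 site exists only on the integrant, never on wild type, which
#' is the false-positive check), then the second crossover, which resolves the
#' integrant into either the revertant (wild type) or the edited genome.
#'
#' @param result A `pm_design_result`.
#' @param genome The `pm_genome` the task was designed against.
#' @param plasmid Optional `pm_plasmid` from [assemble_in_silico()]; when
#'   `NULL` it is reassembled from `result` and `vector`.
#' @param vector Vector backbone sequence (needed when `plasmid` is `NULL` and
#'   for the crossover layout).
#' @param crossover Which arm mediates integration (default `"UHA"`).
#' @return A list: `integrant` (the contig carrying the integrated plasmid),
#'   `edited_genome` and `revertant` (`pm_genome`s), and the verification
#'   amplicon lengths `ver1_len` (on the integrant) / `ver2_len` (on the
#'   edited genome).
#' @export
predict_edited_genome <- function(result, genome, plasmid = NULL, vector = NULL,
                                  crossover = c("UHA", "DHA")) {
  stopifnot(inherits(result, "pm_design_result"))
  crossover <- match.arg(crossover)
  if (is.null(plasmid)) {
    if (is.null(vector)) {
      abort("supply either an assembled plasmid or the vector sequence",
            class = "pmedit_input_error")
    }
    plasmid <- assemble_in_silico(result, vector)
  }
  contigs <- as_genome(genome)
  el <- result$edited
  loc <- result$locus
  G <- contigs[[loc$contig]]
  c0 <- loc$context_start
  E <- el$edited
  nG <- nchar(G)
  ctx_len <- el$context_len
  w <- result$w
  ov <- result$overlap_len

  ## Edited chromosome: context replaced by its edited form.
  g_edit <- paste0(substr(G, 1L, c0), E, substr(G, c0 + ctx_len + 1L, nG))
  edited_genome <- contigs
  edited_genome[[loc$contig]] <- g_edit

  ## Integrant: open the circle at the crossover point inside the shared
  ## homology and splice it into the chromosome. Upstream of the junction
  ## window, edited and wild-type coordinates agree; downstream they are
  ## shifted by the edit length.
  circle_from <- function(k) {
    ## plasmid = vector + E[u_start:d_end]; insert position k (edited coords)
    ## sits at circle offset vector_len + (k - u_start).
    off <- attr(plasmid, "vector_len") + (k - result$u_start)
    paste0(substr(plasmid, off + 1L, nchar(plasmid)), substr(plasmid, 1L, off))
  }
  if (result$convention == "swapped") {
    abort("crossover simulation supports the 'paper' vector end convention only",
          class = "pmedit_input_error")
  }
  if (crossover == "UHA") {
    gx <- c0 + w                               # wild coord == edited coord (< w)
    opened <- circle_from(w)
  } else {
    kE <- w + ov                               # first base after the window
    gx <- c0 + kE - el$shift
    opened <- circle_from(kE)
  }
  integrant <- paste0(substr(G, 1L, gx), opened, substr(G, gx + 1L, nG))

  tp1 <- result$primers[["test-primer-1"]]
  tp2 <- result$primers[["test-primer-2"]]
  tp3 <- result$primers[["test-primer-3"]]
  list(
    integrant = integrant,
    edited_genome = new_genome(edited_genome, attr(genome, "name") %||% "genome"),
    revertant = new_genome(contigs, attr(genome, "name") %||% "genome"),
    ver1_len = unname((result$d_end - tp1$match_start) + tp2$match_end),
    ver2_len = unname(tp3$match_end - tp1$match_start),
    crossover = crossover
  )
}
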