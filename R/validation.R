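## Pre-design input checks: the sequence-length rule, mutation centrality, and
## exact anchoring of each task context in the target genome. Checks run in a
## fixed order (structure at parse time, then length, centrality, anchoring)
## and the first failing check wins.

ok_report <- function(id) {
  tibble(id = id, status = "ok", reason = NA_character_, message = NA_character_)
}

fail_report <- function(id, reason, message) {
  tibble(id = id, status = "failed", reason = reason, message = message)
}

#' Check the context-length rule
#'
#' A task context must be strictly longer than
#' `UHA_max + DHA_max + UIS_max + DIS2_min` so that the arms and both
#' genome-side verification primers can be designed without re-reading the
#' genome around the locus.
#'
#' @param task One task row (tibble with `id`, `context`, ...).
#' @param params A [design_parameters()] object.
#' @return A one-row validation report tibble (`status` "ok" or "failed",
#'   reason `LENGTH_TOO_SHORT` on failure).
#' @export
check_length_rule <- function(task, params = design_parameters()) {
  bound <- params$uha_max + params$dha_max + params$uis_max + params$dis2_min
  len <- nchar(task$context)
  if (len > bound) {
    ok_report(task$id)
  } else {
    fail_report(task$id, "LENGTH_TOO_SHORT",
                sprintf("context length %d must exceed UHA_max + DHA_max + UIS_max + DIS2_min = %d",
                        len, bound))
  }
}

#' Check that the mutation site is centered enough
#'
#' The site must leave at least `UIS_max + UHA_max` bases strictly upstream
#' (counted as `index - 1`) and at least `DHA_max + DIS2_min` bases downstream
#' (`length - index`), so every optional design region fits inside the context.
#' Both comparisons are inclusive.
#'
#' @inheritParams check_length_rule
#' @return A one-row validation report (`MUTATION_NOT_CENTERED` on failure).
#' @export
check_mutation_centrality <- function(task, params = design_parameters()) {
  up <- task$index - 1L
  down <- nchar(task$context) - task$index
  need_up <- params$uis_max + params$uha_max
  need_down <- params$dha_max + params$dis2_min
  if (up >= need_up && down >= need_down) {
    ok_report(task$id)
  } else {
    fail_report(task$id, "MUTATION_NOT_CENTERED",
                sprintf("site leaves %d nt upstream (need >= %d) and %d nt downstream (need >= %d)",
                        up, need_up, down, need_down))
  }
}

#' Anchor a task context in the genome
#'
#' The full context must match the genome exactly (100% identity over its full
#' length), on the forward strand, at exactly one locus. Zero matches, multiple
#' matches (e.g. a duplicated locus) and reverse-strand-only matches are
#' distinct failures; reverse-strand contexts are rejected with guidance rather
#' than auto-flipped, because flipping would silently change the meaning of
#' `index`, `ref` and `alt`.
#'
#' @param task One task row.
#' @param genome A `pm_genome`.
#' @return A `pm_locus` (list with `id`, `contig`, `strand`, `context_start`,
#'   `mut_genome_pos`, 0-based) on success, otherwise a one-row validation
#'   report.
#' @export
anchor_in_genome <- function(task, genome) {
  hits <- find_exact_matches(task$context, genome)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  if (nrow(hits) == 0L) {
    return(fail_report(task$id, "CONTEXT_NOT_IN_GENOME",
                       "context has no exact match in the genome; it must be strictly consistent with the target"))
  }
  if (nrow(fwd) == 0L) {
    return(fail_report(task$id, "CONTEXT_REVERSE_STRAND",
                       "context matches only the reverse strand; reverse-complement the row (and re-map index/ref/alt) and resubmit"))
  }
  if (nrow(hits) > 1L) {
    return(fail_report(task$id, "CONTEXT_MULTIMAPPED",
                       sprintf("context matches the genome at %d loci; the target must be unique", nrow(hits))))
  }
  structure(list(
    id = task$id,
    contig = fwd$contig[1],
    strand = "+",
    context_start = fwd$start[1],
    mut_genome_pos = fwd$start[1] + task$index - 1L
  ), class = "pm_locus")
}

#' Run all pre-design checks on one task
#'
#' Fixed order: length rule, centrality, genome anchoring; the first failing
#' check produces the (single) failure report.
#'
#' @inheritParams anchor_in_genome
#' @param params A [design_parameters()] object.
#' @return A `pm_locus` on success, otherwise a one-row validation report.
#' @export
validate_task <- function(task, genome, params = design_parameters()) {
  r <- check_length_rule(task, params)
  if (r$status == "failed") return(r)
  r <- check_mutation_centrality(task, params)
  if (r$status == "failed") return(r)
  anchor_in_genome(task, genome)
}

#' @export
print.pm_locus <- function(x, ...) {
  cat(sprintf("<pm_locus '%s'> %s:%d (+), mutation at %d (0-based)\n",
              x$id, x$contig, x$context_start, x$mut_genome_pos))
  invisible(x)
}
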