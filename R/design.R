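## The design engine: apply the edit, derive the optional design regions
## (ODRs), construct the three 20-bp assembly overhangs, and optimize the seven
## primers. Geometry, in edited-context 0-based coordinates with `w` the start
## of the 20-nt junction window and `m` the edited position:
##
##   test-primer-1>   primer-1>                    <primer-2
##   ----------------[UHA ......................[window]]-------------
##                                 primer-3>     [window].... DHA ....]   <primer-4   <test-primer-3
##
## UHA = edited[u_start : w+20], DHA = edited[w : d_end]; the two arms share
## the junction window, which carries the mutation.

#' Apply a mutation task to its anchored context
#'
#' Builds the edited context (substitution, insertion after `index`, or
#' deletion at `index`) and extracts the 20-nt junction window covering the
#' mutation, with the edited base at 0-based window offset `window_offset`
#' (default 9; an inserted base occupies offsets 9-10 together with the first
#' downstream base).
#'
#' @param locus A `pm_locus` from [anchor_in_genome()] / [validate_task()].
#' @param task The corresponding task row.
#' @param params A [design_parameters()] object.
#' @return A `pm_edited_locus`: list with the edited context, junction window,
#'   window start `w`, edited position `m`, and the length shift of the edit.
#' @export
build_edited_locus <- function(locus, task, params = design_parameters()) {
  stopifnot(inherits(locus, "pm_locus"))
  ctx <- task$context
  i <- task$index
  if (task$kind == "substitution") {
    edited <- paste0(substr(ctx, 1L, i - 1L), task$alt, substr(ctx, i + 1L, nchar(ctx)))
    m <- i - 1L
  } else if (task$kind == "insertion") {
    edited <- paste0(substr(ctx, 1L, i), task$alt, substr(ctx, i + 1L, nchar(ctx)))
    m <- i
  } else {
    edited <- paste0(substr(ctx, 1L, i - 1L), substr(ctx, i + 1L, nchar(ctx)))
    m <- i - 1L
  }
  ov <- params$overlap_len
  w <- m - params$window_offset
  if (w < 0L || w + ov > nchar(edited)) {
    return(failed_task(task$id, "primer_design", "DESIGN_WINDOW_CLIPPED",
                       sprintf("edit at position %d leaves no room for the %d-nt junction window", m, ov)))
  }
  window <- substr(edited, w + 1L, w + ov)
  if (grepl("N", window, fixed = TRUE)) {
    return(failed_task(task$id, "primer_design", "DESIGN_WINDOW_CLIPPED",
                       "junction window contains N"))
  }
  structure(list(
    id = task$id, task = task, locus = locus,
    edited = edited, window = window, w = w, m = m,
    shift = nchar(edited) - nchar(ctx), context_len = nchar(ctx)
  ), class = "pm_edited_locus")
}

#' Derive the optional design regions
#'
#' Returns, in edited-context coordinates (vector coordinates for `odr_dis1`),
#' the inclusive 0-based bounds within which each primer anchor may be placed:
#' `odr_uha` - allowed start positions of primer-1's match (UHA length in
#' `[uha_min, uha_max]`); `odr_dha` - allowed end positions of primer-4's match
#' (DHA length in `[dha_min, dha_max]`); `odr_dis1` - allowed end positions of
#' test-primer-2's match on the vector, measured from the DHA-vector junction
#' into the backbone (truncated at the vector end); and, once the arms are
#' fixed (`uha_start`/`dha_end` supplied), `odr_uis` for test-primer-1 and
#' `odr_dis2` for test-primer-3.
#'
#' @param edited A `pm_edited_locus`.
#' @param vector Vector backbone sequence.
#' @param params A [design_parameters()] object.
#' @param uha_start,dha_end Chosen arm anchors (0-based); when `NULL` the
#'   verification-primer regions are returned relative to the widest arm
#'   bounds.
#' @return Named list of inclusive `c(lo, hi)` integer ranges, or a
#'   `failed_task` row with reason `ODR_EMPTY` naming the region.
#' @export
compute_design_regions <- function(edited, vector, params = design_parameters(),
                                   uha_start = NULL, dha_end = NULL) {
  stopifnot(inherits(edited, "pm_edited_locus"))
  w <- edited$w
  ov <- params$overlap_len
  ne <- nchar(edited$edited)
  nv <- nchar(vector)
  rng <- function(lo, hi, name) {
    lo <- as.integer(lo); hi <- as.integer(hi)
    if (lo > hi) {
      failed_task(edited$id, "primer_design", "ODR_EMPTY",
                  sprintf("optional design region %s is empty ([%d, %d])", name, lo, hi))
    } else c(lo, hi)
  }
  odr_uha <- rng(max(0L, w + ov - params$uha_max), w + ov - params$uha_min, "ODR_UHA")
  if (is_failure(odr_uha)) return(odr_uha)
  odr_dha <- rng(w + params$dha_min, min(ne, w + params$dha_max), "ODR_DHA")
  if (is_failure(odr_dha)) return(odr_dha)
  odr_dis1 <- rng(params$dis1_min, min(nv, params$dis1_max), "ODR_DIS1")
  if (is_failure(odr_dis1)) return(odr_dis1)
  u0 <- uha_start %||% odr_uha[1]
  u1 <- uha_start %||% odr_uha[2]
  odr_uis <- rng(max(0L, u0 - params$uis_max), u1 - params$uis_min, "ODR_UIS")
  if (is_failure(odr_uis)) return(odr_uis)
  d0 <- dha_end %||% odr_dha[1]
  d1 <- dha_end %||% odr_dha[2]
  odr_dis2 <- rng(d0 + params$dis2_min, min(ne, d1 + params$dis2_max), "ODR_DIS2")
  if (is_failure(odr_dis2)) return(odr_dis2)
  list(odr_uha = odr_uha, odr_dha = odr_dha, odr_uis = odr_uis,
       odr_dis1 = odr_dis1, odr_dis2 = odr_dis2)
}

#' Construct the four 20-bp assembly overhangs
#'
#' The 5' tails that generate the three assembly junctions: primer-1 and
#' primer-4 carry the two vector-terminus overlaps, primer-3 carries the
#' junction window (the 20 bp of edited sequence covering the mutation) and
#' primer-2 its reverse complement. Under the default `"paper"` convention the
#' UHA abuts the vector terminus at the *end* of the supplied top strand, so
#' `tail(primer-1)` is the vector's last 20 nt and `tail(primer-4)` the reverse
#' complement of its first 20 nt; `"swapped"` mirrors the assignment (the
#' insert then sits inverted in the circle). Both conventions produce three
#' mutually complementary junctions; see the methods vignette for why the
#' assignment is forced by top-strand overlap logic.
#'
#' @param edited A `pm_edited_locus`.
#' @param vector Vector backbone sequence (length >= 40).
#' @param convention `"paper"` or `"swapped"`.
#' @param overlap_len Overlap length (default 20).
#' @return Named list of four tails (`primer_1`, `primer_2`, `primer_3`,
#'   `primer_4`).
#' @export
make_overhangs <- function(edited, vector, convention = c("paper", "swapped"),
                           overlap_len = 20L) {
  stopifnot(inherits(edited, "pm_edited_locus"))
  convention <- match.arg(convention)
  nv <- nchar(vector)
  if (nv < 2L * overlap_len) {
    abort(sprintf("vector too short (%d nt) for two %d-nt overlaps", nv, overlap_len),
          class = "pmedit_input_error")
  }
  v_head <- substr(vector, 1L, overlap_len)
  v_tail <- substr(vector, nv - overlap_len + 1L, nv)
  if (convention == "paper") {
    t1 <- v_tail
    t4 <- reverse_complement(v_head)
  } else {
    t1 <- reverse_complement(v_head)
    t4 <- v_tail
  }
  list(primer_1 = t1,
       primer_2 = reverse_complement(edited$window),
       primer_3 = edited$window,
       primer_4 = t4)
}

#' Optimize one primer within its optional design region
#'
#' Enumerates every admissible `(start, length)` with the match length in
#' `[match_len_min, match_len_max]` and the anchor inside `odr` (for forward
#' primers `odr` bounds the 0-based match start; for reverse primers the
#' exclusive match end). Candidates whose Tm or GC fall outside the configured
#' windows, or whose match contains `N`, are rejected. Admissible candidates
#' are scored with
#' `penalty = w_tm |Tm - tm_opt| + w_gc |GC - gc_opt| * 100 +
#'  w_dimer max(0, homodimer_tm - max_self_dimer_tm) +
#'  w_hairpin max(0, hairpin_tm - max_self_dimer_tm)`
#' (dimer terms computed on the full tailed oligo) and the minimum-penalty
#' candidate is returned, ties broken by shorter length then smaller start.
#' Anchored primers (primer-2/3) are the degenerate case of a single-position
#' `odr`, so only the length varies.
#'
#' @param template Template sequence (edited context, or the vector backbone).
#' @param odr Inclusive 0-based `c(lo, hi)` anchor range.
#' @param orientation `"fwd"` or `"rev"`.
#' @param params A [design_parameters()] object.
#' @param tail 5' tail to prepend (default none).
#' @param role Primer role name used in reports.
#' @param task_id Task id used in failure rows.
#' @return A `pm_primer` (list), or a `failed_task` row whose message names the
#'   dominant rejection reason over all considered candidates.
#' @export
pick_primer <- function(template, odr, orientation = c("fwd", "rev"),
                        params = design_parameters(), tail = "",
                        role = "primer", task_id = role) {
  orientation <- match.arg(orientation)
  nt <- nchar(template)
  lens <- params$match_len_min:params$match_len_max
  anchors <- odr[1]:odr[2]
  cand <- tidyr::expand_grid(anchor = anchors, len = lens)
  if (orientation == "fwd") {
    cand$start <- cand$anchor                     # 0-based match start
    cand$end <- cand$anchor + cand$len            # exclusive end
  } else {
    cand$end <- cand$anchor                       # exclusive match end
    cand$start <- cand$anchor - cand$len
  }
  cand <- cand[cand$start >= 0L & cand$end <= nt, ]
  if (nrow(cand) == 0L) {
    return(failed_task(task_id, "primer_design", "NO_CANDIDATE",
                       sprintf("%s: no admissible (start, length) fits the template", role)))
  }
  prof <- tm_profile(template, salt_mM = params$salt_mM, oligo_nM = params$oligo_nM)
  cand$tm <- tm_window(prof, cand$start, cand$len)
  cand$gc <- gc_window(prof, cand$start, cand$len)
  has_n <- is.na(cand$tm)
  low_tm <- !has_n & cand$tm < params$tm_min
  high_tm <- !has_n & cand$tm > params$tm_max
  bad_gc <- !has_n & !low_tm & !high_tm & (cand$gc < params$gc_min | cand$gc > params$gc_max)
  ok <- !(has_n | low_tm | high_tm | bad_gc)
  if (!any(ok)) {
    reasons <- c(`considered` = nrow(cand), `too many Ns` = sum(has_n),
                 `low tm` = sum(low_tm), `high tm` = sum(high_tm),
                 `GC content failed` = sum(bad_gc))
    msg <- paste(names(reasons), reasons, sep = " ", collapse = ", ")
    dominant <- names(which.max(reasons[-1]))
    return(failed_task(task_id, "primer_design", "PRIMER_REJECTED",
                       sprintf("%s: no acceptable primer (%s; dominant: %s)", role, msg, dominant)))
  }
  cand <- cand[ok, ]
  cand$partial <- params$w_tm * abs(cand$tm - params$tm_opt) +
    params$w_gc * abs(cand$gc - params$gc_opt) * 100
  cand <- cand[order(cand$partial, cand$len, cand$start), ]
  ## Branch and bound: dimer/hairpin penalties are non-negative, so once the
  ## partial penalty exceeds the best full penalty no later candidate can win.
  best <- NULL
  best_total <- Inf
  for (r in seq_len(nrow(cand))) {
    if (cand$partial[r] > best_total + 1e-9) break
    match_fwd <- substr(template, cand$start[r] + 1L, cand$end[r])
    match_seq <- if (orientation == "fwd") match_fwd else reverse_complement(match_fwd)
    full <- paste0(tail, match_seq)
    hd <- duplex_tm(full, full, salt_mM = params$salt_mM, oligo_nM = params$oligo_nM)
    hp <- hairpin_tm(full, salt_mM = params$salt_mM, oligo_nM = params$oligo_nM)
    total <- cand$partial[r] +
      params$w_dimer * max(0, hd - params$max_self_dimer_tm) +
      params$w_hairpin * max(0, hp - params$max_self_dimer_tm)
    better <- total < best_total - 1e-9 ||
      (abs(total - best_total) <= 1e-9 &&
         (cand$len[r] < best$match_len ||
            (cand$len[r] == best$match_len && cand$start[r] < best$match_start)))
    if (is.null(best) || better) {
      best_total <- total
      best <- list(
        role = role, orientation = orientation,
        tail = tail, match = match_seq, full = full,
        match_start = cand$start[r], match_end = cand$end[r],
        match_len = cand$len[r],
        tm = cand$tm[r], gc = cand$gc[r],
        homodimer_tm = hd, hairpin_tm = hp,
        penalty = total
      )
    }
  }
  structure(best, class = "pm_primer")
}

#' @export
print.pm_primer <- function(x, ...) {
  cat(sprintf("<pm_primer %s> %s (%s, match %d nt, Tm %.1f C, GC %.2f, penalty %.2f)\n",
              x$role, x$full, x$orientation, x$match_len, x$tm, x$gc, x$penalty))
  invisible(x)
}

.PRIMER_ROLES <- c("primer-1", "primer-2", "primer-3", "primer-4",
                   "test-primer-1", "test-primer-2", "test-primer-3")

#' Design one point-mutation editing task end to end
#'
#' Runs validation, applies the edit, derives the design regions and
#' overhangs, and optimizes the seven primers: primer-1/2 (UHA amplicon),
#' primer-3/4 (DHA amplicon), test-primer-1/2 (verification of the first
#' crossover on the integrant) and test-primer-1/3 (verification of the second
#' crossover on the edited genome). Computes the two edited arm sequences, the
#' four expected amplicon lengths, and the full homo-/heterodimer Tm matrix
#' over the seven primers (pairs above `max_cross_dimer_tm` are recorded as
#' warnings, never failures).
#'
#' @param task One task row (see [read_mutation_table()]).
#' @param genome A `pm_genome`.
#' @param vector Vector backbone sequence.
#' @param params A [design_parameters()] object.
#' @return A `pm_design_result`, or a `failed_task` row (stage `validation` or
#'   `primer_design`) for the first failing step.
#' @export
design_task <- function(task, genome, vector, params = design_parameters()) {
  v <- validate_task(task, genome, params)
  if (is.data.frame(v)) {
    return(failed_task(task$id, "validation", v$reason, v$message))
  }
  el <- build_edited_locus(v, task, params)
  if (is_failure(el)) return(el)
  regions <- compute_design_regions(el, vector, params)
  if (is_failure(regions)) return(regions)
  tails <- make_overhangs(el, vector, convention = params$vector_end_convention,
                          overlap_len = params$overlap_len)
  E <- el$edited
  w <- el$w
  ov <- params$overlap_len

  p1 <- pick_primer(E, regions$odr_uha, "fwd", params, tail = tails$primer_1,
                    role = "primer-1", task_id = task$id)
  if (is_failure(p1)) return(p1)
  p2 <- pick_primer(E, c(w, w), "rev", params, tail = tails$primer_2,
                    role = "primer-2", task_id = task$id)
  if (is_failure(p2)) return(p2)
  p3 <- pick_primer(E, c(w + ov, w + ov), "fwd", params, tail = tails$primer_3,
                    role = "primer-3", task_id = task$id)
  if (is_failure(p3)) return(p3)
  p4 <- pick_primer(E, regions$odr_dha, "rev", params, tail = tails$primer_4,
                    role = "primer-4", task_id = task$id)
  if (is_failure(p4)) return(p4)

  u_start <- p1$match_start
  d_end <- p4$match_end
  regions2 <- compute_design_regions(el, vector, params,
                                     uha_start = u_start, dha_end = d_end)
  if (is_failure(regions2)) return(regions2)
  tp1 <- pick_primer(E, regions2$odr_uis, "fwd", params,
                     role = "test-primer-1", task_id = task$id)
  if (is_failure(tp1)) return(tp1)
  tp2 <- pick_primer(vector, regions2$odr_dis1, "rev", params,
                     role = "test-primer-2", task_id = task$id)
  if (is_failure(tp2)) return(tp2)
  tp3 <- pick_primer(E, regions2$odr_dis2, "rev", params,
                     role = "test-primer-3", task_id = task$id)
  if (is_failure(tp3)) return(tp3)

  primers <- list(p1, p2, p3, p4, tp1, tp2, tp3)
  names(primers) <- .PRIMER_ROLES
  uha <- substr(E, u_start + 1L, w + ov)
  dha <- substr(E, w + 1L, d_end)
  amplicons <- c(
    uha = 2L * ov + (w - u_start),
    dha = (d_end - w) + ov,
    verification_1 = (d_end - tp1$match_start) + tp2$match_end,
    verification_2 = tp3$match_end - tp1$match_start
  )

  full_seqs <- map_chr(primers, "full")
  dimers <- tidyr::expand_grid(a = .PRIMER_ROLES, b = .PRIMER_ROLES) |>
    filter(.data$a <= .data$b) |>
    mutate(tm = purrr::map2_dbl(.data$a, .data$b, function(a, b) {
      duplex_tm(full_seqs[[a]], full_seqs[[b]],
                salt_mM = params$salt_mM, oligo_nM = params$oligo_nM)
    }))
  cross <- dimers[dimers$a != dimers$b, ]
  warnings <- cross[cross$tm > params$max_cross_dimer_tm, ]

  structure(list(
    id = task$id, task = task, locus = v, edited = el,
    primers = primers,
    pairs = tibble(
      pair = c("UHA", "DHA", "verification-1", "verification-2"),
      forward = c("primer-1", "primer-3", "test-primer-1", "test-primer-1"),
      reverse = c("primer-2", "primer-4", "test-primer-2", "test-primer-3")
    ),
    uha = uha, dha = dha,
    u_start = u_start, d_end = d_end, w = w,
    amplicons = amplicons,
    dimers = dimers,
    dimer_warnings = warnings,
    convention = params$vector_end_convention,
    overlap_len = ov
  ), class = "pm_design_result")
}

#' @export
print.pm_design_result <- function(x, ...) {
  cat(sprintf("<pm_design_result '%s'> %s at %s:%d\n", x$id, x$task$kind,
              x$locus$contig, x$locus$mut_genome_pos))
  cat(sprintf("  UHA %d nt, DHA %d nt; amplicons %s\n", nchar(x$uha), nchar(x$dha),
              paste(sprintf("%s=%d", names(x$amplicons), x$amplicons), collapse = ", ")))
  for (p in x$primers) {
    cat(sprintf("  %-14s %s\n", p$role, p$full))
  }
  invisible(x)
}

## One wide summary row per successful task, for design_results.csv.
result_summary_row <- function(res) {
  cols <- list(task_id = res$id, kind = res$task$kind,
               contig = res$locus$contig, mut_genome_pos = res$locus$mut_genome_pos)
  for (p in res$primers) {
    key <- gsub("-", "_", p$role)
    cols[[paste0(key, "_seq")]] <- p$full
    cols[[paste0(key, "_match_len")]] <- p$match_len
    cols[[paste0(key, "_tm")]] <- round(p$tm, 2)
    cols[[paste0(key, "_gc")]] <- round(p$gc, 3)
  }
  cols$uha_seq <- res$uha
  cols$uha_len <- nchar(res$uha)
  cols$dha_seq <- res$dha
  cols$dha_len <- nchar(res$dha)
  cols$amplicon_uha <- unname(res$amplicons[["uha"]])
  cols$amplicon_dha <- unname(res$amplicons[["dha"]])
  cols$amplicon_verification_1 <- unname(res$amplicons[["verification_1"]])
  cols$amplicon_verification_2 <- unname(res$amplicons[["verification_2"]])
  self <- res$dimers[res$dimers$a == res$dimers$b, ]
  cross <- res$dimers[res$dimers$a != res$dimers$b, ]
  cols$worst_homodimer_tm <- round(max(self$tm), 2)
  cols$worst_heterodimer_tm <- round(max(cross$tm), 2)
  as_tibble(cols)
}

primer_rows <- function(res) {
  bind_rows(lapply(res$primers, function(p) {
    tibble(task_id = res$id, role = p$role, orientation = p$orientation,
           tail = p$tail, match = p$match, full = p$full,
           match_start = p$match_start, match_end = p$match_end,
           match_len = p$match_len, tm = p$tm, gc = p$gc,
           homodimer_tm = p$homodimer_tm, hairpin_tm = p$hairpin_tm,
           penalty = p$penalty)
  }))
}
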