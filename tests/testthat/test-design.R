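# Shared fixture for the design-engine tests; regenerated per file, seeded.
fx_design <- generate_fixture(fixture_spec(
  seed = 31, n_tasks = 9,
  task_kinds = c(substitution = 1, insertion = 1, deletion = 1)
))

anchored_pair <- function(fx, kind = NULL) {
  rows <- if (is.null(kind)) seq_len(nrow(fx$tasks)) else which(fx$tasks$kind == kind)
  task <- fx$tasks[rows[1], ]
  list(task = task, locus = validate_task(task, fx$genome))
}

test_that("build_edited_locus applies each edit kind and centers the junction window", {
  for (kind in c("substitution", "insertion", "deletion")) {
    ap <- anchored_pair(fx_design, kind)
    el <- build_edited_locus(ap$locus, ap$task, design_parameters())
    expect_s3_class(el, "pm_edited_locus")
    ctx <- ap$task$context
    shift <- c(substitution = 0L, insertion = 1L, deletion = -1L)[[kind]]
    expect_equal(nchar(el$edited), nchar(ctx) + shift)
    expect_equal(nchar(el$window), 20L)
    if (kind == "substitution") {
      d <- which(strsplit(el$edited, "")[[1]] != strsplit(ctx, "")[[1]])
      expect_equal(d, ap$task$index)                      # Hamming distance exactly 1
      expect_equal(substr(el$window, 10, 10), ap$task$alt) # edit at 0-based offset 9
    }
    if (kind == "insertion") {
      expect_equal(substr(el$window, 10, 10), ap$task$alt)
      # removing the inserted base restores the original context
      rebuilt <- paste0(substr(el$edited, 1, el$m), substr(el$edited, el$m + 2, nchar(el$edited)))
      expect_equal(rebuilt, ctx)
    }
    # outside the edit the window matches the genome around the site
    expect_equal(substr(el$edited, el$w + 1, el$w + 9),
                 substr(ctx, el$w + 1, el$w + 9))
  }
})

test_that("an edit too close to the context end clips the junction window", {
  ap <- anchored_pair(fx_design, "substitution")
  task <- ap$task
  task$index <- 5L
  task$ref <- substr(task$context, 5, 5)
  task$alt <- setdiff(c("A", "C", "G", "T"), task$ref)[1]
  el <- build_edited_locus(ap$locus, task, design_parameters())
  expect_true(is.data.frame(el))
  expect_equal(el$reason, "DESIGN_WINDOW_CLIPPED")
})

test_that("optional design regions have the arithmetic sizes the length ranges imply", {
  ap <- anchored_pair(fx_design, "substitution")
  el <- build_edited_locus(ap$locus, ap$task, design_parameters())
  fxv <- fx_design$vector

  # degenerate range: a single admissible anchor
  p_deg <- design_parameters(uha_min = 600, uha_max = 600)
  r <- compute_design_regions(el, fxv, p_deg)
  expect_equal(r$odr_uha[1], r$odr_uha[2])
  expect_equal(r$odr_uha[1], el$w + 20L - 600L)

  # [500, 800] leaves 301 candidate anchor positions
  p <- design_parameters(uha_min = 500, uha_max = 800)
  r <- compute_design_regions(el, fxv, p)
  expect_equal(r$odr_uha[2] - r$odr_uha[1] + 1L, 301L)

  # vector-side region is truncated at the vector end
  p_long <- design_parameters(dis1_min = 50, dis1_max = nchar(fxv) + 500)
  r <- compute_design_regions(el, fxv, p_long)
  expect_equal(r$odr_dis1[2], nchar(fxv))
  # and empties out (with the region named) when even the minimum does not fit
  p_bad <- design_parameters(dis1_min = nchar(fxv) + 1, dis1_max = nchar(fxv) + 500)
  r <- compute_design_regions(el, fxv, p_bad)
  expect_true(is.data.frame(r))
  expect_equal(r$reason, "ODR_EMPTY")
  expect_match(r$message, "ODR_DIS1")
})

test_that("overhangs are 20 nt, mutually consistent, and junction-complementary", {
  ap <- anchored_pair(fx_design, "substitution")
  el <- build_edited_locus(ap$locus, ap$task, design_parameters())
  v <- fx_design$vector
  nv <- nchar(v)
  for (conv in c("paper", "swapped")) {
    tails <- make_overhangs(el, v, convention = conv)
    expect_true(all(nchar(unlist(tails)) == 20L))
    expect_equal(tails$primer_2, reverse_complement(tails$primer_3))
    expect_equal(tails$primer_3, el$window)
  }
  # default geometry: UHA amplicon starts with the vector terminus it abuts,
  # DHA amplicon ends with the (rc of the) other terminus, so all three
  # junctions of the circle share identical 20-mers
  tails <- make_overhangs(el, v, convention = "paper")
  expect_equal(tails$primer_1, substr(v, nv - 19L, nv))
  expect_equal(tails$primer_4, reverse_complement(substr(v, 1L, 20L)))
})

test_that("pick_primer returns the single admissible window when only one exists", {
  set.seed(32)
  tpl <- random_seq(60)
  p <- design_parameters(tm_min = 0, tm_max = 200, gc_min = 0, gc_max = 1)
  pr <- pick_primer(tpl, c(10, 10), "fwd", p, role = "x")
  expect_s3_class(pr, "pm_primer")
  expect_equal(pr$match_start, 10L)
  expect_gte(pr$match_len, 18L)
  expect_lte(pr$match_len, 25L)
  expect_equal(pr$match, substr(tpl, 11, 10 + pr$match_len))
})

test_that("pick_primer equals the exhaustive brute-force oracle", {
  set.seed(33)
  p <- design_parameters()
  for (i in 1:12) {
    tpl <- random_seq(400)
    odr <- c(40, 80)
    orient <- if (i %% 2 == 0) "fwd" else "rev"
    if (orient == "rev") odr <- c(320, 360)
    tail <- if (i %% 3 == 0) random_seq(20) else ""
    got <- pick_primer(tpl, odr, orient, p, tail = tail, role = "x", task_id = "x")
    want <- oracle_pick_primer(tpl, odr, orient, p, tail = tail)
    if (is.null(want)) {
      expect_true(is.data.frame(got))
    } else {
      expect_equal(got$match_start, want$start)
      expect_equal(got$match_len, want$len)
      expect_equal(got$match, want$match)
      expect_equal(got$penalty, want$penalty, tolerance = 1e-9)
    }
  }
})

test_that("impossible constraints fail with the dominant rejection reason", {
  set.seed(34)
  tpl <- random_seq(300)
  p <- design_parameters(tm_min = 90, tm_max = 95, tm_opt = 92)
  r <- pick_primer(tpl, c(50, 100), "fwd", p, role = "primer-1", task_id = "t")
  expect_true(is.data.frame(r))
  expect_equal(r$reason, "PRIMER_REJECTED")
  expect_match(r$message, "low tm")   # nothing reaches a 90 C threshold
})

test_that("design_task produces the full seven-primer contract", {
  ap <- anchored_pair(fx_design, "substitution")
  res <- design_task(ap$task, fx_design$genome, fx_design$vector)
  expect_s3_class(res, "pm_design_result")
  p <- design_parameters()

  expect_length(res$primers, 7L)
  expect_equal(nrow(res$pairs), 4L)
  lens <- purrr::map_int(res$primers, "match_len")
  expect_true(all(lens >= 18L & lens <= 25L))
  tails <- purrr::map_chr(res$primers, "tail")
  expect_true(all(nchar(tails[c("primer-1", "primer-2", "primer-3", "primer-4")]) == 20L))
  expect_true(all(tails[c("test-primer-1", "test-primer-2", "test-primer-3")] == ""))

  expect_gte(nchar(res$uha), p$uha_min); expect_lte(nchar(res$uha), p$uha_max)
  expect_gte(nchar(res$dha), p$dha_min); expect_lte(nchar(res$dha), p$dha_max)

  # verification primer placement: UIS and DIS2 spans within their ranges
  uis <- res$u_start - res$primers[["test-primer-1"]]$match_start
  expect_gte(uis, p$uis_min); expect_lte(uis, p$uis_max)
  dis2 <- res$primers[["test-primer-3"]]$match_end - res$d_end
  expect_gte(dis2, p$dis2_min); expect_lte(dis2, p$dis2_max)
  dis1 <- res$primers[["test-primer-2"]]$match_end
  expect_gte(dis1, p$dis1_min); expect_lte(dis1, p$dis1_max)

  # amplicon arithmetic: 40 nt of tails plus the genomic span
  expect_equal(unname(res$amplicons["uha"]), 40L + (res$w - res$u_start))
  expect_equal(unname(res$amplicons["dha"]), 20L + (res$d_end - res$w))
})

test_that("design_task is deterministic", {
  ap <- anchored_pair(fx_design, "substitution")
  r1 <- design_task(ap$task, fx_design$genome, fx_design$vector)
  r2 <- design_task(ap$task, fx_design$genome, fx_design$vector)
  expect_identical(lapply(r1$primers, unclass), lapply(r2$primers, unclass))
  expect_identical(r1$amplicons, r2$amplicons)
})

test_that("indels shift the verification-2 amplicon by the edit length", {
  for (kind in c("insertion", "deletion")) {
    ap <- anchored_pair(fx_design, kind)
    res <- design_task(ap$task, fx_design$genome, fx_design$vector)
    if (is.data.frame(res)) next   # authentic primer failure on this fixture
    shift <- if (kind == "insertion") 1L else -1L
    tp1 <- res$primers[["test-primer-1"]]
    tp3 <- res$primers[["test-primer-3"]]
    # expected product on the *unedited* genome from the same primer sites
    wild_len <- (tp3$match_end - res$edited$shift) - tp1$match_start
    expect_equal(unname(res$amplicons["verification_2"]), wild_len + shift)
    expect_equal(res$edited$shift, shift)
  }
})
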