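fx_sim <- generate_fixture(fixture_spec(
  seed = 41, n_tasks = 9,
  task_kinds = c(substitution = 1, insertion = 1, deletion = 1)
))

first_result <- function(fx, kind) {
  rows <- which(fx$tasks$kind == kind)
  for (r in rows) {
    res <- design_task(fx$tasks[r, ], fx$genome, fx$vector)
    if (inherits(res, "pm_design_result")) return(res)
  }
  NULL
}

test_that("assembly closes the circle with the expected length and a unique junction window", {
  res <- first_result(fx_sim, "substitution")
  expect_false(is.null(res))
  pl <- assemble_in_silico(res, fx_sim$vector)
  insert_len <- res$d_end - res$u_start
  expect_equal(nchar(pl), nchar(fx_sim$vector) + insert_len)
  # canonical rotation starts at vector position 0
  expect_true(startsWith(as.character(pl), fx_sim$vector))
  # the circle contains the full junction window exactly once
  doubled <- paste0(pl, substr(pl, 1, 100))  # catch origin-spanning occurrences too
  expect_equal(lengths(gregexpr(res$edited$window, doubled, fixed = TRUE)), 1L)
  # the edited insert is carried verbatim
  expect_true(grepl(substr(res$edited$edited, res$u_start + 1, res$d_end), pl, fixed = TRUE))
})

test_that("corrupting one tail base trips the junction mismatch guard", {
  res <- first_result(fx_sim, "substitution")
  bad <- res
  t1 <- bad$primers[["primer-1"]]$tail
  flip <- setdiff(c("A", "C", "G", "T"), substr(t1, 1, 1))[1]
  bad$primers[["primer-1"]]$tail <- paste0(flip, substr(t1, 2, nchar(t1)))
  expect_error(assemble_in_silico(bad, fx_sim$vector),
               "ASSEMBLY_JUNCTION_MISMATCH", class = "pmedit_assembly_error")
})

test_that("the swapped convention also assembles, with the insert inverted", {
  p <- design_parameters(vector_end_convention = "swapped")
  rows <- which(fx_sim$tasks$kind == "substitution")
  res <- NULL
  for (r in rows) {
    cand <- design_task(fx_sim$tasks[r, ], fx_sim$genome, fx_sim$vector, params = p)
    if (inherits(cand, "pm_design_result")) { res <- cand; break }
  }
  expect_false(is.null(res))
  pl <- assemble_in_silico(res, fx_sim$vector)
  expect_equal(nchar(pl), nchar(fx_sim$vector) + (res$d_end - res$u_start))
  insert <- substr(res$edited$edited, res$u_start + 1, res$d_end)
  expect_true(grepl(reverse_complement(insert), pl, fixed = TRUE))
})

test_that("both crossovers produce the dictated genome edits and verification products", {
  for (kind in c("substitution", "insertion", "deletion")) {
    res <- first_result(fx_sim, kind)
    if (is.null(res)) next
    task <- res$task
    sim <- predict_edited_genome(res, fx_sim$genome, vector = fx_sim$vector)
    g0 <- unclass(fx_sim$genome)[[res$locus$contig]]
    g1 <- unclass(sim$edited_genome)[[res$locus$contig]]
    pos <- res$locus$context_start + task$index - 1L   # 0-based site

    if (kind == "substitution") {
      expect_equal(nchar(g1), nchar(g0))
      diff <- which(strsplit(g1, "")[[1]] != strsplit(g0, "")[[1]])
      expect_equal(diff, pos + 1L)                      # Hamming distance 1, at the site
      expect_equal(substr(g1, pos + 1, pos + 1), task$alt)
    } else if (kind == "insertion") {
      expect_equal(nchar(g1), nchar(g0) + 1L)
      expect_equal(substr(g1, pos + 2, pos + 2), task$alt)
      expect_equal(paste0(substr(g1, 1, pos + 1), substr(g1, pos + 3, nchar(g1))), g0)
    } else {
      expect_equal(nchar(g1), nchar(g0) - 1L)
      expect_equal(g1, paste0(substr(g0, 1, pos), substr(g0, pos + 2, nchar(g0))))
    }

    # revertant path: identical to the input genome
    expect_identical(unclass(sim$revertant)[[res$locus$contig]], g0)

    # verification-1: the test-primer-2 site exists on the integrant only
    tp2 <- res$primers[["test-primer-2"]]$full
    on_wild <- grepl(tp2, g0, fixed = TRUE) ||
      grepl(reverse_complement(tp2), g0, fixed = TRUE)
    expect_false(on_wild)
    expect_true(grepl(reverse_complement(tp2), sim$integrant, fixed = TRUE))

    # measure both verification products on the simulated molecules and
    # compare against the reported lengths
    tp1 <- res$primers[["test-primer-1"]]$match
    tp3 <- res$primers[["test-primer-3"]]$match
    s1 <- regexpr(tp1, sim$integrant, fixed = TRUE)
    e2 <- regexpr(reverse_complement(tp2), sim$integrant, fixed = TRUE)
    expect_equal((as.integer(e2) + nchar(tp2) - 1L) - as.integer(s1) + 1L,
                 sim$ver1_len)
    s1e <- regexpr(tp1, g1, fixed = TRUE)
    e3 <- regexpr(reverse_complement(tp3), g1, fixed = TRUE)
    expect_equal((as.integer(e3) + nchar(tp3) - 1L) - as.integer(s1e) + 1L,
                 sim$ver2_len)
  }
})

test_that("integration through either arm duplicates the crossed arm", {
  res <- first_result(fx_sim, "substitution")
  for (xo in c("UHA", "DHA")) {
    sim <- predict_edited_genome(res, fx_sim$genome, vector = fx_sim$vector, crossover = xo)
    # the integrant carries the whole plasmid plus the chromosome
    g0 <- unclass(fx_sim$genome)[[res$locus$contig]]
    expect_equal(nchar(sim$integrant),
                 nchar(g0) + nchar(fx_sim$vector) + (res$d_end - res$u_start))
    expect_true(grepl(fx_sim$vector, sim$integrant, fixed = TRUE))
  }
})
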