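# The printed length rule uses UHA_max + DHA_max + UIS_max + DIS2_min; these
# parameter values reproduce the documented boundary: 800+800+100+80 = 1780.
boundary_params <- function() {
  design_parameters(uha_max = 800, dha_max = 800, uis_max = 100,
                    dis2_min = 80, dis2_max = 300)
}

test_that("the context-length rule is a strict inequality over the stated sum", {
  p <- boundary_params()
  set.seed(21)
  mk <- function(n) tibble::tibble(id = "t", context = random_seq(n), index = n %/% 2)
  expect_equal(check_length_rule(mk(1800), p)$status, "ok")       # 1800 > 1780
  r <- check_length_rule(mk(1780), p)                              # not strict
  expect_equal(r$status, "failed")
  expect_equal(r$reason, "LENGTH_TOO_SHORT")
  expect_match(r$message, "1780")
  expect_equal(check_length_rule(mk(10000), design_parameters())$status, "ok")
})

test_that("centrality requires the documented inclusive margins on both sides", {
  p <- design_parameters()   # needs >= 1100 upstream, >= 850 downstream
  set.seed(22)
  ctx <- random_seq(2400)
  mk <- function(i) tibble::tibble(id = "t", context = ctx, index = i)
  expect_equal(check_mutation_centrality(mk(1200), p)$status, "ok")
  r <- check_mutation_centrality(mk(10), p)
  expect_equal(r$status, "failed")
  expect_equal(r$reason, "MUTATION_NOT_CENTERED")
  # boundary: index - 1 == required upstream margin is accepted (inclusive)
  expect_equal(check_mutation_centrality(mk(1101), p)$status, "ok")
  expect_equal(check_mutation_centrality(mk(1100), p)$status, "failed")
  # downstream boundary: len - index == 850
  expect_equal(check_mutation_centrality(mk(1550), p)$status, "ok")
  expect_equal(check_mutation_centrality(mk(1551), p)$status, "failed")
})

test_that("anchoring distinguishes unique, absent, multimapped and reverse-strand contexts", {
  set.seed(23)
  g1 <- random_seq(20000)
  ctx <- substr(g1, 5001, 6800)                      # genome[5000:6800), 0-based
  genome <- structure(c(c1 = g1), class = "pm_genome")
  task <- tibble::tibble(id = "t", context = ctx, index = 900)

  loc <- anchor_in_genome(task, genome)
  expect_s3_class(loc, "pm_locus")
  expect_equal(loc$context_start, 5000L)
  expect_equal(loc$mut_genome_pos, 5899L)

  # one changed base: strict consistency fails
  ctx2 <- paste0(substr(ctx, 1, 899), setdiff(c("A","C","G","T"), substr(ctx, 900, 900))[1],
                 substr(ctx, 901, nchar(ctx)))
  r <- anchor_in_genome(tibble::tibble(id = "t", context = ctx2, index = 900), genome)
  expect_equal(r$reason, "CONTEXT_NOT_IN_GENOME")

  # locus duplicated on a second contig
  gdup <- structure(c(c1 = g1, c2 = paste0(random_seq(500), ctx, random_seq(500))),
                    class = "pm_genome")
  r <- anchor_in_genome(task, gdup)
  expect_equal(r$reason, "CONTEXT_MULTIMAPPED")

  # reverse-strand-only match is rejected with guidance, not auto-flipped
  r <- anchor_in_genome(tibble::tibble(id = "t", context = reverse_complement(ctx), index = 900),
                        genome)
  expect_equal(r$reason, "CONTEXT_REVERSE_STRAND")
  expect_match(r$message, "reverse-complement")
})

test_that("anchoring agrees with the naive full-scan oracle", {
  fx <- generate_fixture(fixture_spec(seed = 24, n_tasks = 4, genome_length = 30000))
  for (r in seq_len(nrow(fx$tasks))) {
    loc <- anchor_in_genome(fx$tasks[r, ], fx$genome)
    want <- oracle_find_matches(fx$tasks$context[r], unclass(fx$genome))
    expect_equal(nrow(want), 1L)
    expect_equal(loc$context_start, want$start[1])
    expect_equal(loc$contig, want$contig[1])
    expect_equal(loc$context_start, fx$ledger$context_start[r])
  }
})

test_that("validate_task applies checks in order and the first failure wins", {
  fx <- generate_fixture(fixture_spec(seed = 25, n_tasks = 1))
  task <- fx$tasks[1, ]
  # healthy task anchors
  expect_s3_class(validate_task(task, fx$genome), "pm_locus")
  # too-short context fails the length rule before anchoring is even attempted
  short <- task
  short$context <- substr(task$context, 1, 1500)
  short$index <- 750L
  r <- validate_task(short, fx$genome)
  expect_equal(r$reason, "LENGTH_TOO_SHORT")
  # long but off-center context fails centrality, not anchoring
  off <- task
  off$context <- substr(unclass(fx$genome)[[1]], 101, 2500)
  off$index <- 30L
  off$ref <- substr(off$context, 30, 30)
  r <- validate_task(off, fx$genome)
  expect_equal(r$reason, "MUTATION_NOT_CENTERED")
  # a context not from this genome fails at the anchoring stage
  set.seed(26)
  alien <- task
  alien$context <- random_seq(2400)
  alien$ref <- substr(alien$context, alien$index, alien$index)
  r <- validate_task(alien, fx$genome)
  expect_equal(r$reason, "CONTEXT_NOT_IN_GENOME")
})
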