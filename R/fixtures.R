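## Seeded synthetic fixture generator: a random genome, a toy linearized
## backbone, a mutation task table whose contexts are verbatim genome slices,
## and a ground-truth ledger for assertions. Same spec, same bytes.

#' Describe a synthetic fixture
#'
#' @param seed Integer RNG seed; the whole fixture is a pure function of the
#'   spec.
#' @param genome_length Total genome length in nt (default 50,000).
#' @param n_contigs Number of contigs; lengths split evenly (default 1).
#' @param gc_bias Genome GC fraction (default 0.5).
#' @param n_tasks Number of mutation tasks (default 10).
#' @param task_kinds Sampling weights for task kinds, named vector over
#'   `substitution`, `insertion`, `deletion` (default substitutions only).
#' @param context_length Context length per task (default 2,400: the smallest
#'   round size that satisfies the default length rule with the site centered).
#' @param vector_length Toy backbone length (default 3,000).
#' @param planted_duplications List of duplications to plant, each a list with
#'   `contig`, `start` (0-based), `len`, `dest_contig`, `dest`, and optional
#'   `mut_rate` (per-base substitution rate applied to the copy).
#' @return A `pm_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 50000L, n_contigs = 1L,
                         gc_bias = 0.5, n_tasks = 10L,
                         task_kinds = c(substitution = 1, insertion = 0, deletion = 0),
                         context_length = 2400L, vector_length = 3000L,
                         planted_duplications = NULL) {
  kinds <- c(substitution = 0, insertion = 0, deletion = 0)
  kinds[names(task_kinds)] <- task_kinds
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs), gc_bias = gc_bias,
    n_tasks = as.integer(n_tasks), task_kinds = kinds,
    context_length = as.integer(context_length),
    vector_length = as.integer(vector_length),
    planted_duplications = planted_duplications
  ), class = "pm_fixture_spec")
}

## Evaluate an expression with a private RNG stream, restoring global state.
with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic fixture
#'
#' Builds the genome, toy backbone, task table and ground-truth ledger
#' described by `spec`, optionally writing them as standard files
#' (`genome.fasta`, `vector.txt`, `mutations.csv`, `ledger.csv`). Task
#' contexts are verbatim genome slices with the edit site at the context
#' midpoint, so every generated task anchors uniquely and passes the default
#' validation checks.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Optional directory to write the files into.
#' @return A list: `genome` (`pm_genome`), `vector` (string), `tasks` (task
#'   tibble), `ledger` (tibble of ground-truth coordinates: `id`, `contig`,
#'   `context_start`, `mut_genome_pos`, `index`, `kind`, `ref`, `alt`),
#'   `spec`, and `paths` when written.
#' @export
generate_fixture <- function(spec = fixture_spec(), outdir = NULL) {
  stopifnot(inherits(spec, "pm_fixture_spec"))
  cl <- spec$context_length
  with_fixture_seed(spec$seed, {
    contig_len <- spec$genome_length %/% spec$n_contigs
    if (contig_len < cl) {
      abort(sprintf("contig length %d cannot host a %d-nt task context", contig_len, cl),
            class = "pmedit_input_error")
    }
    contigs <- setNames(
      vapply(seq_len(spec$n_contigs), function(i) random_dna(contig_len, spec$gc_bias), ""),
      paste0("contig_", seq_len(spec$n_contigs))
    )
    for (dup in spec$planted_duplications) {
      src <- substr(contigs[[dup$contig]], dup$start + 1L, dup$start + dup$len)
      if (!is.null(dup$mut_rate) && dup$mut_rate > 0) {
        b <- strsplit(src, "", fixed = TRUE)[[1]]
        flip <- which(stats::runif(length(b)) < dup$mut_rate)
        for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
        src <- paste(b, collapse = "")
      }
      dest <- contigs[[dup$dest_contig]]
      if (dup$dest + dup$len > nchar(dest)) {
        abort("planted duplication does not fit in the destination contig",
              class = "pmedit_input_error")
      }
      contigs[[dup$dest_contig]] <- paste0(
        substr(dest, 1L, dup$dest), src,
        substr(dest, dup$dest + dup$len + 1L, nchar(dest))
      )
    }
    vec <- random_dna(spec$vector_length, 0.5)
    while (substr(vec, 1L, 20L) ==
           substr(vec, spec$vector_length - 19L, spec$vector_length)) {
      vec <- random_dna(spec$vector_length, 0.5)   # distinct termini, essentially never hit
    }

    index <- cl %/% 2L
    kinds <- sample(names(spec$task_kinds), spec$n_tasks, replace = TRUE,
                    prob = spec$task_kinds)
    rows <- vector("list", spec$n_tasks)
    for (t in seq_len(spec$n_tasks)) {
      contig <- sample(names(contigs), 1L)
      start <- sample.int(nchar(contigs[[contig]]) - cl + 1L, 1L) - 1L
      ctx <- substr(contigs[[contig]], start + 1L, start + cl)
      at <- substr(ctx, index, index)
      if (kinds[t] == "substitution") {
        ref <- at; alt <- sample(setdiff(c("A", "C", "G", "T"), at), 1L)
      } else if (kinds[t] == "deletion") {
        ref <- at; alt <- "-"
      } else {
        ref <- "-"; alt <- sample(c("A", "C", "G", "T"), 1L)
      }
      rows[[t]] <- tibble(
        id = sprintf("task_%03d", t), context = ctx, index = index,
        ref = ref, alt = alt, contig = contig, context_start = start
      )
    }
    raw <- bind_rows(rows)
    tasks <- mutation_tasks(raw$id, raw$context, raw$index, raw$ref, raw$alt)
    ledger <- raw |>
      select("id", "contig", "context_start", "index", "ref", "alt") |>
      mutate(mut_genome_pos = .data$context_start + .data$index - 1L,
             kind = tasks$kind[match(.data$id, tasks$id)])
    genome <- new_genome(contigs, sprintf("fixture_seed%d", spec$seed))
    out <- list(genome = genome, vector = vec, tasks = tasks,
                ledger = ledger, spec = spec)
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      paths <- c(genome = file.path(outdir, "genome.fasta"),
                 vector = file.path(outdir, "vector.txt"),
                 mutations = file.path(outdir, "mutations.csv"),
                 ledger = file.path(outdir, "ledger.csv"))
      write_genome_fasta(genome, paths[["genome"]])
      write_vector_txt(vec, paths[["vector"]])
      readr::write_csv(
        select(raw, sequence_id = "id", sequence = "context", index = "index",
               nucleotide_before = "ref", nucleotide_after = "alt"),
        paths[["mutations"]], progress = FALSE)
      readr::write_csv(ledger, paths[["ledger"]], progress = FALSE)
      out$paths <- paths
    }
    out
  })
}
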