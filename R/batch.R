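## Batch front end: run every task independently, collect successes, failures
## and off-target reports, and expose the whole run as one tidy object.

#' Design a batch of point-mutation editing tasks
#'
#' Runs [design_task()] on every row of `tasks` (task failures never abort the
#' batch), then evaluates off-target risk of both homologous arms and 3'-end
#' mis-priming of all seven primers for each successful design. Row-level parse
#' failures attached to `tasks` (see [read_mutation_table()]) are carried into
#' the failure ledger.
#'
#' @param tasks Task tibble from [read_mutation_table()], [mutation_tasks()] or
#'   [generate_fixture()].
#' @param genome A `pm_genome`.
#' @param vector Vector backbone sequence.
#' @param params A [design_parameters()] object.
#' @param offtarget Evaluate arm off-targets and mis-priming (default TRUE).
#' @return A `pm_design` object: list with `results` (named list of
#'   `pm_design_result`), `summary` (one wide row per success), `primers`
#'   (long tibble, 7 rows per success), `failures`, `offtargets`, `params`.
#' @export
design_batch <- function(tasks, genome, vector, params = design_parameters(),
                         offtarget = TRUE) {
  stopifnot(is.data.frame(tasks))
  failures <- list(task_failures(tasks))
  results <- list()
  for (r in seq_len(nrow(tasks))) {
    task <- tasks[r, ]
    res <- design_task(task, genome, vector, params)
    if (is_failure(res)) {
      failures[[length(failures) + 1L]] <- res
    } else {
      results[[res$id]] <- res
    }
  }
  offtargets <- list(tibble(task_id = character(), query = character(),
                            contig = character(), start = integer(),
                            strand = character(), identity = double(),
                            aligned_length = integer()))
  if (offtarget && length(results) > 0L) {
    arm_index <- genome_kmer_index(genome, params$offtarget_seed_len)
    for (res in results) {
      span <- list(contig = res$locus$contig,
                   start = res$locus$context_start,
                   end = res$locus$context_start + res$edited$context_len)
      for (arm_name in c("UHA", "DHA")) {
        arm <- if (arm_name == "UHA") res$uha else res$dha
        hits <- scan_arm(arm, genome, intended = span, params = params,
                         index = arm_index)
        if (nrow(hits) > 0L) {
          offtargets[[length(offtargets) + 1L]] <-
            mutate(hits, task_id = res$id, query = arm_name, .before = 1)
        }
      }
      for (p in res$primers) {
        fp <- primer_kmer_footprint(res, p, params$misprime_kmer)
        mp <- scan_primer_3prime(p, genome, intended = fp, params = params)
        if (nrow(mp) > 0L) {
          offtargets[[length(offtargets) + 1L]] <-
            mutate(mp, task_id = res$id, query = p$role, .before = 1,
                   identity = 1.0, aligned_length = params$misprime_kmer)
        }
      }
    }
  }
  structure(list(
    results = results,
    summary = if (length(results)) bind_rows(lapply(results, result_summary_row)) else
      tibble(task_id = character()),
    primers = if (length(results)) bind_rows(lapply(results, primer_rows)) else
      tibble(task_id = character(), role = character(), full = character()),
    failures = bind_rows(failures),
    offtargets = bind_rows(offtargets),
    params = params,
    n_tasks = nrow(tasks) + nrow(task_failures(tasks))
  ), class = "pm_design")
}

#' @export
print.pm_design <- function(x, ...) {
  cat(sprintf("<pm_design> %d task(s): %d designed, %d failed, %d off-target warning(s)\n",
              x$n_tasks, length(x$results), nrow(x$failures), nrow(x$offtargets)))
  invisible(x)
}

#' Tidy the primers of a design batch
#'
#' @param x A `pm_design`.
#' @param ... Unused.
#' @return One row per designed primer: task, role, sequences, match
#'   coordinates, Tm, GC, dimer screens and penalty.
#' @export
tidy.pm_design <- function(x, ...) {
  x$primers
}

#' One-row summary of a design batch
#'
#' @param x A `pm_design`.
#' @param ... Unused.
#' @return A one-row tibble: task counts, success rate, worst dimer Tm,
#'   off-target warning count.
#' @export
glance.pm_design <- function(x, ...) {
  tibble(
    n_tasks = x$n_tasks,
    n_designed = length(x$results),
    n_failed = nrow(x$failures),
    success_rate = if (x$n_tasks > 0) length(x$results) / x$n_tasks else NA_real_,
    n_offtarget_warnings = nrow(x$offtargets),
    worst_heterodimer_tm = if (nrow(x$summary) > 0)
      max(x$summary$worst_heterodimer_tm) else NA_real_
  )
}

#' Plot primer thermodynamics of a design batch
#'
#' Tm against GC content for every designed primer, colored by role, with the
#' configured acceptance windows drawn as a rectangle.
#'
#' @param object A `pm_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pm_design <- function(object, ...) {
  p <- object$params
  ggplot2::ggplot(object$primers, ggplot2::aes(x = .data$gc, y = .data$tm,
                                               colour = .data$role)) +
    ggplot2::annotate("rect", xmin = p$gc_min, xmax = p$gc_max,
                      ymin = p$tm_min, ymax = p$tm_max,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "GC fraction (match)", y = "Tm (°C, match)",
                  colour = "primer role",
                  title = "Designed primers against the acceptance window") +
    ggplot2::theme_minimal()
}

#' Run a full batch from input files
#'
#' Reads the genome FASTA, vector TXT and mutation CSV, designs every task,
#' writes the four output CSVs, and logs a summary line. Task-level failures
#' never abort the run; unreadable or malformed input files raise errors.
#'
#' @param genome Path to the genome FASTA.
#' @param vector Path to the vector TXT.
#' @param mutations Path to the mutation task CSV.
#' @param outdir Output directory for the four CSVs.
#' @param params A `pm_params` object, or path to a key-value parameter file.
#' @param offtarget Evaluate off-target risk (default TRUE).
#' @param quiet Suppress log messages (default FALSE).
#' @return The `pm_design` object, invisibly.
#' @export
run_batch <- function(genome, vector, mutations, outdir,
                      params = design_parameters(), offtarget = TRUE,
                      quiet = FALSE) {
  if (is.character(params)) params <- read_params_file(params)
  g <- read_genome_fasta(genome)
  v <- read_vector_txt(vector)
  tasks <- read_mutation_table(mutations)
  batch <- design_batch(tasks, g, v, params = params, offtarget = offtarget)
  paths <- write_design_outputs(batch, outdir)
  if (!quiet) {
    message(sprintf("pmedit: %d task(s) -> %d designed, %d failed, %d off-target warning(s); outputs in %s",
                    batch$n_tasks, length(batch$results), nrow(batch$failures),
                    nrow(batch$offtargets), outdir))
  }
  invisible(batch)
}
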