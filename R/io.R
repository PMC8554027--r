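## Readers and writers for every file the tool touches: genome FASTA, linear
## vector TXT, mutation task CSV, and the four result CSVs.

#' Read a multi-record genome FASTA file
#'
#' Sequences are uppercased; lowercase bases and arbitrary line wrapping are
#' tolerated. Record ids are the first whitespace-delimited token of each
#' header. Empty files, duplicate ids and non-`{A,C,G,T,N}` characters are
#' typed parse errors naming the offending record and offset.
#'
#' @param path Path to a FASTA file.
#' @param name Optional genome name (default: file base name).
#' @return A `pm_genome`: named character vector of contigs with a `name`
#'   attribute.
#' @export
read_genome_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("genome file not found: %s", path), class = "pmedit_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)),
                              class = "pmedit_parse_error")
  )
  if (length(set) == 0L) {
    abort(sprintf("FASTA file '%s' contains no records", path), class = "pmedit_parse_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate FASTA record id '%s' in %s", dup[1], path),
          class = "pmedit_parse_error")
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) {
      abort(sprintf("FASTA record '%s' is empty", ids[i]), class = "pmedit_parse_error")
    }
    bad <- regexpr(.DNA_RE, seqs[i])
    if (bad > 0L) {
      abort(sprintf("FASTA record '%s' contains illegal character '%s' at offset %d",
                    ids[i], substr(seqs[i], bad, bad), bad),
            class = "pmedit_parse_error")
    }
  }
  new_genome(setNames(seqs, ids), name %||% sub("\\.[^.]*$", "", basename(path)))
}

new_genome <- function(contigs, name = "genome") {
  structure(contigs, name = name, class = "pm_genome")
}

#' @export
print.pm_genome <- function(x, ...) {
  cat(sprintf("<pm_genome '%s'> %d contig(s), %s nt total\n",
              attr(x, "name"), length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `pm_genome` or named character vector of contigs.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  contigs <- as_genome(genome)
  set <- Biostrings::DNAStringSet(unname(contigs))
  names(set) <- names(contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a linearized vector backbone from a plain-text file
#'
#' The file must contain the raw top-strand sequence (5' to 3') of the
#' linearized backbone, optionally wrapped over several lines; all whitespace
#' is stripped. FASTA headers are rejected with instructions, since a header
#' would otherwise be silently absorbed into the sequence.
#'
#' @param path Path to the TXT file.
#' @param min_len Minimum accepted length (default 60).
#' @return The vector sequence as a single uppercase string.
#' @export
read_vector_txt <- function(path, min_len = 60L) {
  if (!file.exists(path)) {
    abort(sprintf("vector file not found: %s", path), class = "pmedit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(trimws(lines), ">"))) {
    abort("vector file looks like FASTA; supply the raw linear sequence as plain text (no '>' header)",
          class = "pmedit_parse_error")
  }
  seq <- toupper(gsub("\\s", "", paste(lines, collapse = "")))
  if (nchar(seq) < min_len) {
    abort(sprintf("vector sequence too short (%d nt < %d)", nchar(seq), min_len),
          class = "pmedit_parse_error")
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    abort(sprintf("vector sequence contains illegal character '%s' at offset %d",
                  substr(seq, bad, bad), bad),
          class = "pmedit_parse_error")
  }
  seq
}

#' Write a vector backbone as plain text
#' @param vector Vector sequence string.
#' @param path Output path.
#' @param width Line wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_vector_txt <- function(vector, path, width = 80L) {
  n <- nchar(vector)
  starts <- seq(1L, n, by = width)
  writeLines(substring(vector, starts, pmin(starts + width - 1L, n)), path)
  invisible(path)
}

.TASK_HEADER_SYNONYMS <- list(
  id = c("id", "sequence_id", "seq_id", "name"),
  context = c("context", "sequence", "target_sequence", "sequence_without_mutation"),
  index = c("index", "mutation_index", "site", "position"),
  ref = c("ref", "nucleotide_before", "before", "ref_allele", "base_before"),
  alt = c("alt", "nucleotide_after", "after", "alt_allele", "base_after")
)

#' Read a mutation task table (CSV)
#'
#' The CSV must have a header row with five columns: sequence id, target
#' sequence without the mutation, 1-based index of the mutation site within
#' that sequence, and the nucleotide before/after the edit (`-` marks the
#' absent side of an insertion or deletion). Common header spellings
#' (`sequence_id`, `nucleotide_before`, ...) are accepted.
#'
#' Edit semantics: a substitution replaces the base at `index`; a deletion
#' (`alt = "-"`) removes the base at `index`; an insertion (`ref = "-"`)
#' inserts `alt` immediately *after* position `index`.
#'
#' Row-level problems (non-integer or out-of-range index, `ref` disagreeing
#' with the context, duplicate ids, multi-nucleotide alleles) do not abort the
#' batch: offending rows are collected into a failure ledger attached as
#' attribute `"failures"` and retrievable with [task_failures()].
#'
#' @param path Path to the CSV file.
#' @return A tibble of parsed tasks with columns `id`, `context`, `index`,
#'   `ref`, `alt`, `kind`, plus a `"failures"` attribute.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("mutation table not found: %s", path), class = "pmedit_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(raw))))
  canon <- rep(NA_character_, length(nm))
  for (target in names(.TASK_HEADER_SYNONYMS)) {
    hit <- which(nm %in% .TASK_HEADER_SYNONYMS[[target]])
    if (length(hit) == 0L) {
      abort(sprintf("mutation table is missing a '%s' column (accepted headers: %s)",
                    target, paste(.TASK_HEADER_SYNONYMS[[target]], collapse = ", ")),
            class = "pmedit_parse_error")
    }
    canon[hit[1]] <- target
  }
  df <- setNames(raw[, !is.na(canon)], canon[!is.na(canon)])[, names(.TASK_HEADER_SYNONYMS)]
  parse_mutation_rows(df)
}

#' Build mutation tasks from vectors
#'
#' In-memory equivalent of [read_mutation_table()], applying the same row-level
#' structural checks and failure ledger.
#'
#' @param id,context,index,ref,alt Task fields (recycled to common length).
#' @return A task tibble with a `"failures"` attribute.
#' @export
mutation_tasks <- function(id, context, index, ref, alt) {
  parse_mutation_rows(tibble(
    id = as.character(id), context = as.character(context),
    index = as.character(index), ref = as.character(ref), alt = as.character(alt)
  ))
}

parse_mutation_rows <- function(df) {
  fails <- list()
  rows <- list()
  seen <- character(0)
  for (r in seq_len(nrow(df))) {
    id <- df$id[r]
    fail <- function(reason, msg) {
      fails[[length(fails) + 1L]] <<- failed_task(id %||% sprintf("row_%d", r),
                                                  "validation", reason, msg)
    }
    if (is.na(id) || !nzchar(id)) { fail("BAD_ID", sprintf("row %d has an empty id", r)); next }
    if (id %in% seen) { fail("DUPLICATE_ID", sprintf("id '%s' appears more than once", id)); next }
    ctx <- toupper(df$context[r] %||% "")
    if (is.na(ctx) || grepl("[^ACGT]", ctx) || !nzchar(ctx)) {
      fail("BAD_SEQUENCE", "context must be a non-empty A/C/G/T sequence"); next
    }
    idx <- suppressWarnings(as.integer(df$index[r]))
    if (is.na(idx) || idx < 1L || idx > nchar(ctx)) {
      fail("BAD_INDEX", sprintf("index '%s' is not an integer in [1, %d]", df$index[r], nchar(ctx)))
      next
    }
    ref <- toupper(trimws(df$ref[r])); alt <- toupper(trimws(df$alt[r]))
    if (is.na(ref) || is.na(alt) ||
        !grepl("^[ACGT-]+$", ref) || !grepl("^[ACGT-]+$", alt) || (ref == "-" && alt == "-")) {
      fail("BAD_ALLELE", sprintf("ref/alt must be single bases or '-', got '%s'/'%s'", ref, alt))
      next
    }
    if (nchar(ref) > 1L || nchar(alt) > 1L) {
      fail("MULTI_NT_EDIT", "only single-nucleotide substitutions, insertions or deletions are supported")
      next
    }
    kind <- if (ref == "-") "insertion" else if (alt == "-") "deletion" else "substitution"
    if (kind == "substitution" && ref == alt) {
      fail("BAD_ALLELE", sprintf("ref and alt are both '%s'; no edit requested", ref)); next
    }
    if (kind != "insertion" && substr(ctx, idx, idx) != ref) {
      fail("REF_MISMATCH", sprintf("context has '%s' at index %d, task says ref '%s'",
                                   substr(ctx, idx, idx), idx, ref))
      next
    }
    seen <- c(seen, id)
    rows[[length(rows) + 1L]] <- tibble(id = id, context = ctx, index = idx,
                                        ref = ref, alt = alt, kind = kind)
  }
  tasks <- if (length(rows)) bind_rows(rows) else
    tibble(id = character(), context = character(), index = integer(),
           ref = character(), alt = character(), kind = character())
  attr(tasks, "failures") <- if (length(fails)) bind_rows(fails) else empty_failures()
  tasks
}

#' Retrieve the row-level failure ledger of a task table
#' @param tasks A task tibble from [read_mutation_table()] or [mutation_tasks()].
#' @return A failure tibble (possibly empty).
#' @export
task_failures <- function(tasks) {
  attr(tasks, "failures") %||% empty_failures()
}

failed_task <- function(id, stage, reason, message) {
  tibble(id = id, stage = stage, reason = reason, message = message)
}

empty_failures <- function() {
  tibble(id = character(), stage = character(), reason = character(), message = character())
}

is_failure <- function(x) is.data.frame(x) && all(c("stage", "reason") %in% names(x))

#' Write the four design output files
#'
#' Writes `design_results.csv` (one row per successful task: the seven primers
#' with match lengths, Tm and GC, arm sequences and lengths, the four amplicon
#' lengths and worst homo-/heterodimer Tm), `primer_order.csv` (primer name
#' `<taskid>-<role>` and full sequence, ready for a synthesis vendor),
#' `failed_task.csv` (task id, stage, reason code, message) and
#' `evaluation_result.csv` (per-arm/per-primer off-target hits). Files are
#' deterministic: no timestamps, stable ordering.
#'
#' @param batch A `pm_design` object from [design_batch()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_design_outputs <- function(batch, outdir) {
  stopifnot(inherits(batch, "pm_design"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    design_results = file.path(outdir, "design_results.csv"),
    primer_order = file.path(outdir, "primer_order.csv"),
    failed_task = file.path(outdir, "failed_task.csv"),
    evaluation_result = file.path(outdir, "evaluation_result.csv")
  )
  readr::write_csv(batch$summary, paths[["design_results"]], progress = FALSE)
  order_tbl <- batch$primers |>
    mutate(primer = paste0(.data$task_id, "-", .data$role)) |>
    select("primer", sequence = "full")
  readr::write_csv(order_tbl, paths[["primer_order"]], progress = FALSE)
  readr::write_csv(batch$failures, paths[["failed_task"]], progress = FALSE)
  readr::write_csv(batch$offtargets, paths[["evaluation_result"]], progress = FALSE)
  invisible(paths)
}
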