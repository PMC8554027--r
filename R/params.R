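#' Design parameters
#'
#' All tunable lengths, thermodynamic thresholds and scoring weights used by the
#' design engine. Lengths are in nucleotides, temperatures in degrees Celsius,
#' GC content as fractions in `[0, 1]`.
#'
#' The homologous-arm ranges (`uha_*`, `dha_*`) bound the upstream/downstream
#' arm lengths; `uis_*` positions test-primer-1 upstream of the UHA; `dis1_*`
#' positions test-primer-2 on the vector backbone measured from the DHA-vector
#' junction; `dis2_*` positions test-primer-3 downstream of the DHA in the
#' genome. `match_len_min`/`match_len_max` bound every primer's 3'-end
#' template-matching region (18-25 nt) and `overlap_len` is the assembly
#' overhang length (20 nt); these two are fixed by the editing chemistry and
#' should normally not be changed.
#'
#' @param uha_min,uha_max Upstream homologous arm length range (default 500-800).
#' @param dha_min,dha_max Downstream homologous arm length range (default 500-800).
#' @param uis_min,uis_max Upstream internal sequence span (default 50-300).
#' @param dis1_min,dis1_max Downstream internal sequence span on the vector (default 50-300).
#' @param dis2_min,dis2_max Downstream internal sequence span in the genome (default 50-300).
#' @param match_len_min,match_len_max Primer 3'-match length bounds (default 18, 25).
#' @param overlap_len Assembly overlap length (default 20).
#' @param tm_min,tm_opt,tm_max Melting temperature window and optimum (default 57/60/63).
#' @param gc_min,gc_opt,gc_max GC content window and optimum (default
#'   0.20/0.50/0.80, the windows conventional in PCR primer design).
#' @param max_self_dimer_tm Homodimer/hairpin Tm ceiling before penalty (default 35).
#' @param max_cross_dimer_tm Heterodimer Tm ceiling before a warning (default 35).
#' @param w_tm,w_gc,w_dimer,w_hairpin Penalty weights (default 1.0/0.2/0.5/0.5).
#' @param offtarget_identity_threshold Minimum identity to report an arm hit (default 0.8).
#' @param offtarget_seed_len Exact seed length for the arm scanner (default 11).
#' @param misprime_kmer Length of the 3'-terminal exact word used for
#'   mis-priming warnings (default 12).
#' @param salt_mM,oligo_nM Nearest-neighbor model conditions used by the design
#'   engine. The default 164 mM is the monovalent equivalent of a standard PCR
#'   buffer (50 mM KCl plus 1.5 mM MgCl2 and 0.6 mM dNTP, via the
#'   `120 * sqrt([Mg] - [dNTP])` conversion); oligo concentration 50 nM.
#' @param window_offset 0-based offset of the edited base within the 20-nt
#'   junction window (default 9, i.e. centered).
#' @param vector_end_convention Which vector terminus abuts the UHA in the
#'   assembled circle: `"paper"` (insert follows the vector top strand) or
#'   `"swapped"` (insert inverted). See the methods vignette.
#' @return An object of class `pm_params` (a validated named list).
#' @export
design_parameters <- function(uha_min = 500, uha_max = 800,
                              dha_min = 500, dha_max = 800,
                              uis_min = 50, uis_max = 300,
                              dis1_min = 50, dis1_max = 300,
                              dis2_min = 50, dis2_max = 300,
                              match_len_min = 18, match_len_max = 25,
                              overlap_len = 20,
                              tm_min = 57, tm_opt = 60, tm_max = 63,
                              gc_min = 0.20, gc_opt = 0.50, gc_max = 0.80,
                              max_self_dimer_tm = 35,
                              max_cross_dimer_tm = 35,
                              w_tm = 1.0, w_gc = 0.2, w_dimer = 0.5, w_hairpin = 0.5,
                              offtarget_identity_threshold = 0.8,
                              offtarget_seed_len = 11,
                              misprime_kmer = 12,
                              salt_mM = 164, oligo_nM = 50,
                              window_offset = 9,
                              vector_end_convention = c("paper", "swapped")) {
  p <- list(
    uha_min = as.integer(uha_min), uha_max = as.integer(uha_max),
    dha_min = as.integer(dha_min), dha_max = as.integer(dha_max),
    uis_min = as.integer(uis_min), uis_max = as.integer(uis_max),
    dis1_min = as.integer(dis1_min), dis1_max = as.integer(dis1_max),
    dis2_min = as.integer(dis2_min), dis2_max = as.integer(dis2_max),
    match_len_min = as.integer(match_len_min), match_len_max = as.integer(match_len_max),
    overlap_len = as.integer(overlap_len),
    tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
    gc_min = gc_min, gc_opt = gc_opt, gc_max = gc_max,
    max_self_dimer_tm = max_self_dimer_tm,
    max_cross_dimer_tm = max_cross_dimer_tm,
    w_tm = w_tm, w_gc = w_gc, w_dimer = w_dimer, w_hairpin = w_hairpin,
    offtarget_identity_threshold = offtarget_identity_threshold,
    offtarget_seed_len = as.integer(offtarget_seed_len),
    misprime_kmer = as.integer(misprime_kmer),
    salt_mM = salt_mM, oligo_nM = oligo_nM,
    window_offset = as.integer(window_offset),
    vector_end_convention = match.arg(vector_end_convention)
  )
  validate_params(p)
  structure(p, class = "pm_params")
}

validate_params <- function(p) {
  pairs <- list(
    c("uha_min", "uha_max"), c("dha_min", "dha_max"), c("uis_min", "uis_max"),
    c("dis1_min", "dis1_max"), c("dis2_min", "dis2_max"),
    c("match_len_min", "match_len_max")
  )
  for (pr in pairs) {
    if (p[[pr[1]]] > p[[pr[2]]]) {
      abort(sprintf("%s (%s) must be <= %s (%s)", pr[1], p[[pr[1]]], pr[2], p[[pr[2]]]),
            class = "pmedit_input_error")
    }
  }
  if (!(p$tm_min <= p$tm_opt && p$tm_opt <= p$tm_max)) {
    abort("require tm_min <= tm_opt <= tm_max", class = "pmedit_input_error")
  }
  if (!(p$gc_min <= p$gc_opt && p$gc_opt <= p$gc_max)) {
    abort("require gc_min <= gc_opt <= gc_max", class = "pmedit_input_error")
  }
  if (p$overlap_len < 10L) {
    abort("overlap_len below 10 nt cannot support overlap assembly",
          class = "pmedit_input_error")
  }
  invisible(p)
}

#' @export
print.pm_params <- function(x, ...) {
  cat("<pm_params>\n")
  cat(sprintf("  arms: UHA [%d, %d], DHA [%d, %d] nt\n", x$uha_min, x$uha_max, x$dha_min, x$dha_max))
  cat(sprintf("  verification spans: UIS [%d, %d], DIS1 [%d, %d], DIS2 [%d, %d] nt\n",
              x$uis_min, x$uis_max, x$dis1_min, x$dis1_max, x$dis2_min, x$dis2_max))
  cat(sprintf("  primer match %d-%d nt, overlap %d nt\n",
              x$match_len_min, x$match_len_max, x$overlap_len))
  cat(sprintf("  Tm [%g, %g] opt %g C; GC [%g, %g] opt %g\n",
              x$tm_min, x$tm_max, x$tm_opt, x$gc_min, x$gc_max, x$gc_opt))
  cat(sprintf("  dimer ceilings: self %g, cross %g C; vector end: %s\n",
              x$max_self_dimer_tm, x$max_cross_dimer_tm, x$vector_end_convention))
  invisible(x)
}

#' Read a key-value parameter file
#'
#' Plain-text `key = value` pairs, one per line; `#` starts a comment. Keys are
#' the argument names of [design_parameters()]; unknown keys are an error.
#'
#' @param path Path to the parameter file.
#' @param base Parameter set to override (default [design_parameters()]).
#' @return A `pm_params` object.
#' @export
read_params_file <- function(path, base = design_parameters()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- unclass(base)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort(sprintf("malformed parameter line: '%s'", ln), class = "pmedit_parse_error")
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(out)) {
      abort(sprintf("unknown parameter '%s'", key), class = "pmedit_parse_error")
    }
    out[[key]] <- if (key == "vector_end_convention") val else as.numeric(val)
  }
  do.call(design_parameters, out)
}
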