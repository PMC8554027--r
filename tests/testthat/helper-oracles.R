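# Independent oracles, written against the published models before the package
# implementation and kept free of any package internals. Each re-derives its
# quantity the slow, obvious way.

# Plain nearest-neighbor Tm: explicit dinucleotide loop over the unified
# dH/dS table, duplex initiation per terminal base, monovalent salt entropy
# correction, Tm = 1000 dH / (dS + R ln(C/4)) - 273.15.
oracle_tm <- function(seq, salt_mM = 50, oligo_nM = 50) {
  dh_tab <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
              CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
              GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
              TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  ds_tab <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
              CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
              GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
              TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  dh <- 0; ds <- 0
  n <- nchar(seq)
  for (i in 1:(n - 1)) {
    step <- substr(seq, i, i + 1)
    dh <- dh + dh_tab[[step]]
    ds <- ds + ds_tab[[step]]
  }
  for (end in c(substr(seq, 1, 1), substr(seq, n, n))) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(salt_mM / 1000)
  1000 * dh / (ds + 1.9872 * log(oligo_nM * 1e-9 / 4)) - 273.15
}

oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

# Best ungapped duplex between a and b: try every alignment offset of a
# against reverse_complement(b), take complementary runs >= min_run, score each
# with oracle_tm, keep the maximum.
oracle_duplex_tm <- function(a, b, salt_mM = 50, oligo_nM = 50, min_run = 4) {
  b2 <- oracle_revcomp(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b2, "")[[1]]
  best <- -Inf
  for (off in (-(length(av) - 1)):(length(bv) - 1)) {
    run <- 0
    for (i in 1:(length(av) + 1)) {   # one past the end flushes the last run
      hit <- i <= length(av) && i + off >= 1 && i + off <= length(bv) &&
        av[i] == bv[i + off]
      if (hit) {
        run <- run + 1
      } else {
        if (run >= min_run) {
          sub <- substr(a, i - run, i - 1)
          best <- max(best, oracle_tm(sub, salt_mM, oligo_nM))
        }
        run <- 0
      }
    }
  }
  best
}

# Maximal inverted-repeat stems of >= min_stem pairs separated by >= min_loop
# unpaired bases, each scored as a perfect duplex of its 5' half. A stem is
# grown inward from every outermost pair that cannot be extended outward, so
# every maximal stem is scored exactly once.
oracle_hairpin_tm <- function(seq, salt_mM = 50, oligo_nM = 50,
                              min_stem = 4, min_loop = 3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  pair <- function(i, j) i >= 1 && j <= n && i < j && b[i] == comp[[b[j]]]
  best <- -Inf
  for (i in 1:n) {
    for (j in 1:n) {
      if (j - i - 1 < min_loop || !pair(i, j)) next
      if (pair(i - 1, j + 1)) next               # not the outermost pair of its stem
      k <- 1
      while (pair(i + k, j - k) && (j - k) - (i + k) - 1 >= min_loop) k <- k + 1
      if (k >= min_stem) {
        best <- max(best, oracle_tm(substr(seq, i, i + k - 1), salt_mM, oligo_nM))
      }
    }
  }
  best
}

# Naive exact-occurrence scan over both strands, position by position.
oracle_find_matches <- function(query, contigs) {
  rcq <- oracle_revcomp(query)
  out <- NULL
  for (nm in names(contigs)) {
    s <- contigs[[nm]]
    lq <- nchar(query)
    for (p in 0:(nchar(s) - lq)) {
      sub <- substr(s, p + 1, p + lq)
      if (sub == query) out <- rbind(out, data.frame(contig = nm, start = p, strand = "+"))
      if (sub == rcq) out <- rbind(out, data.frame(contig = nm, start = p, strand = "-"))
    }
  }
  if (is.null(out)) data.frame(contig = character(), start = integer(), strand = character())
  else out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# Naive sliding-identity off-target scan: at every ungapped offset of the arm
# against every contig (both strands), compute identity over the overlap and
# report offsets above threshold covering at least half the arm, excluding the
# intended locus.
oracle_scan_arm <- function(arm, contigs, intended = NULL,
                            thr = 0.8, min_cov = 0.5) {
  la <- nchar(arm)
  min_alen <- ceiling(la * min_cov)
  out <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") arm else oracle_revcomp(arm)
    qv <- strsplit(q, "")[[1]]
    for (nm in names(contigs)) {
      gv <- strsplit(contigs[[nm]], "")[[1]]
      nc <- length(gv)
      for (d in (-(la - min_alen)):(nc - min_alen)) {
        qlo <- max(0, -d); qhi <- min(la, nc - d)
        alen <- qhi - qlo
        if (alen < min_alen) next
        ident <- sum(qv[(qlo + 1):qhi] == gv[(d + qlo + 1):(d + qhi)]) / alen
        if (ident >= thr) {
          out <- rbind(out, data.frame(contig = nm, start = d + qlo, strand = strand,
                                       identity = ident, aligned_length = alen))
        }
      }
    }
  }
  if (!is.null(out) && !is.null(intended)) {
    keep <- !(out$contig == intended$contig & out$start < intended$end &
                (out$start + out$aligned_length) > intended$start)
    out <- out[keep, , drop = FALSE]
  }
  if (is.null(out)) data.frame(contig = character(), start = integer(), strand = character(),
                               identity = double(), aligned_length = integer())
  else out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# Exhaustive primer search: every (anchor, length) in the ODR, full penalty for
# every admissible candidate, argmin with the (penalty, length, start)
# tie-break. Independent of pick_primer's vectorization and pruning.
oracle_pick_primer <- function(template, odr, orientation, params, tail = "") {
  best <- NULL
  for (anchor in odr[1]:odr[2]) {
    for (len in params$match_len_min:params$match_len_max) {
      if (orientation == "fwd") { start <- anchor; end <- anchor + len }
      else { end <- anchor; start <- anchor - len }
      if (start < 0 || end > nchar(template)) next
      fwd <- substr(template, start + 1, end)
      if (grepl("N", fwd, fixed = TRUE)) next
      tm <- oracle_tm(fwd, params$salt_mM, params$oligo_nM)
      gc <- nchar(gsub("[AT]", "", fwd)) / len
      if (tm < params$tm_min || tm > params$tm_max) next
      if (gc < params$gc_min || gc > params$gc_max) next
      match_seq <- if (orientation == "fwd") fwd else oracle_revcomp(fwd)
      full <- paste0(tail, match_seq)
      hd <- oracle_duplex_tm(full, full, params$salt_mM, params$oligo_nM)
      hp <- oracle_hairpin_tm(full, params$salt_mM, params$oligo_nM)
      pen <- params$w_tm * abs(tm - params$tm_opt) +
        params$w_gc * abs(gc - params$gc_opt) * 100 +
        params$w_dimer * max(0, hd - params$max_self_dimer_tm) +
        params$w_hairpin * max(0, hp - params$max_self_dimer_tm)
      cand <- list(start = start, end = end, len = len, penalty = pen, match = match_seq)
      if (is.null(best) || pen < best$penalty - 1e-9 ||
          (abs(pen - best$penalty) <= 1e-9 &&
             (len < best$len || (len == best$len && start < best$start)))) {
        best <- cand
      }
    }
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
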