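---
title: "Designing arms and primers for suicide-plasmid point mutation editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing arms and primers for suicide-plasmid point mutation editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmedit)
```

## The editing chemistry pmedit designs for

Counter-selection allelic exchange introduces a genomic point mutation in two
rounds of single-crossover homologous recombination. A suicide vector (one
that cannot replicate in the host, classically a pK18*mobsacB* derivative)
carries two homologous arms flanking the desired edit: an upstream arm (UHA)
and a downstream arm (DHA), both amplified from the chromosome and carrying
the mutation at their shared junction. Integration of the plasmid (first
crossover, selected with the resistance marker) duplicates the targeted locus;
counter-selection (e.g. *sacB* on sucrose) then forces a second crossover that
excises the vector, leaving either the wild-type or the edited allele —
theoretically at a 50/50 ratio.

For every requested edit, one batch run of `design_batch()` must therefore
produce:

* **two homologous arms** (UHA, DHA) amplified by primer pairs 1/2 and 3/4;
* **three 20-bp assembly overlaps** introduced as primer 5′ tails, so the two
  amplicons and the linearized backbone assemble into a circle by
  overlap-based cloning (Gibson/CPEC/TEDA chemistry);
* **three verification primers**: test-primer-1 upstream of the UHA in the
  genome, test-primer-2 in the backbone downstream of the DHA junction
  (the test-primer-1/2 product exists only on the integrant, which is the
  false-positive screen after the first crossover), and test-primer-3
  downstream of the DHA in the genome (the test-primer-1/3 product spans the
  edit on the resolved genome and is the sequencing template).

Seven primers in four pairs per task, each a 5′ tail (possibly empty) plus a
3′ template-matching region of 18–25 nt.

## Geometry

All internal coordinates are 0-based half-open on the forward strand;
1-based conventions appear only in the task CSV (the mutation `index`) and in
error messages. After validation the edit is applied to the task context and a
20-nt **junction window** is extracted with the edited base at window offset
9 (configurable via `window_offset`): the window is the overlap shared by the
UHA and DHA amplicons, so both arms carry the mutation and either integration
orientation can deliver it. For an insertion the inserted base sits at offsets
9–10; for a deletion the first base after the deleted one takes offset 9.
Centering gives both primer-2 and primer-3 tails at least 9 nt of flanking
context around the edit.

With `w` the window start in the edited context:

* UHA = `edited[u_start, w + 20)`, its length constrained to
  `[uha_min, uha_max]`; primer-1's match starts at `u_start`, so the optional
  design region (ODR) of primer-1 is the interval of start positions that keep
  the UHA inside its length range.
* DHA = `edited[w, d_end)` with `d_end` the end of primer-4's match,
  constrained to `[dha_min, dha_max]`.
* primer-2 and primer-3 have **anchored 3′ termini** immediately flanking the
  window (`w` and `w + 20`); only their match length varies. The anchor is
  forced by the chemistry — the mutation must sit inside the overlap, which
  fixes where the tails begin — and positional freedom exists only for
  primers 1/4 and the test primers.
* test-primer-1 starts `[uis_min, uis_max]` upstream of the chosen UHA start;
  test-primer-2's match ends `[dis1_min, dis1_max]` into the backbone from the
  DHA–vector junction; test-primer-3's match ends `[dis2_min, dis2_max]`
  downstream of the chosen DHA end.

Two pre-design checks implement the published input rules. The context must be
strictly longer than `UHA_max + DHA_max + UIS_max + DIS2_min` (the
genome-side spans a design can need), and the site must be centered enough:
at least `UIS_max + UHA_max` bases strictly upstream (counted as `index - 1`)
and `DHA_max + DIS2_min` downstream (`length - index`), both inclusive. The
rule set is applied in a fixed order — length, centrality, anchoring — and the
first failure wins, so every task produces exactly one diagnosis. "Strictly
consistent with the genome" is implemented literally: the context must match
the genome exactly, once, on the forward strand. Reverse-strand matches are
rejected with guidance instead of being auto-flipped, because flipping would
silently change the meaning of `index`, `ref` and `alt`.

## Vector end assignment

The backbone file supplies the linearized vector's top strand 5′→3′. For the
assembled circle `vector + insert` to close under overlap logic, each junction
must be a 20-mer shared between the *tail* of one fragment's top strand and
the *head* of the next. Enumerating every cyclic order and orientation of the
three fragments shows exactly two closing assignments: either the UHA amplicon
begins with the vector's **last** 20 nt and the DHA amplicon ends with its
first 20 nt (`vector_end_convention = "paper"`, the default; the insert
follows the vector in the circle), or the mirrored assignment with the insert
inverted (`"swapped"`). The naive reading "primer-1 gets the 5′-terminal
vector sequence, primer-4 the reverse complement of the 3′-terminal sequence"
closes no circle in any orientation, which is why `make_overhangs()` assigns
ends by junction geometry rather than by that wording; users whose backbone
file is written in the opposite direction can select `"swapped"` rather than
re-editing the file. `assemble_in_silico()` re-derives both PCR products from
the primer strings, verifies all three junctions exactly, and returns the
circle in canonical rotation; a corrupted tail raises
`ASSEMBLY_JUNCTION_MISMATCH`. The crossover simulator
(`predict_edited_genome()`) supports the default convention.

## Primer optimization

Every admissible `(start, length)` combination inside a primer's ODR with
length 18–25 nt is enumerated and scored:

```
penalty = w_tm * |Tm - tm_opt|
        + w_gc * |GC - gc_opt| * 100
        + w_dimer   * max(0, homodimer_tm - max_self_dimer_tm)
        + w_hairpin * max(0, hairpin_tm  - max_self_dimer_tm)
```

Candidates outside the hard Tm or GC windows, or containing `N`, are rejected;
the minimum-penalty candidate wins, with ties (within 1e-9) broken by shorter
length then smaller start. Tm and GC are computed on the 3′ match (the
annealing region); the dimer and hairpin screens run on the full tailed oligo,
since tails participate in secondary structure. The implementation prunes with
a branch-and-bound over a penalty lower bound, which is exact because the
dimer terms are non-negative; the test suite checks equality against an
exhaustive brute-force enumeration. When no candidate survives, the failure
message tallies every rejection cause and names the dominant one — the
actionable hint for relaxing Tm or GC, mirroring how primer-design tools
report infeasibility. Heterodimer Tm is computed for all 21 primer pairs of a
task and reported; pairs above `max_cross_dimer_tm` are warnings, never
failures, since no rejection rule is established for them.

### Thermodynamics

Melting temperatures come from the unified nearest-neighbor dH/dS table with
duplex initiation per terminal base and the monovalent salt entropy correction
`dS + 0.368 (n-1) ln[Na+]`, as `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15`.
The low-level functions (`melting_temperature()`, `duplex_tm()`,
`hairpin_tm()`) default to a bare 50 mM monovalent / 50 nM oligo reference.
The *design engine* default is `salt_mM = 164`: the monovalent equivalent of a
standard PCR buffer (50 mM KCl with 1.5 mM MgCl₂ and 0.6 mM dNTP, via the
`120·sqrt([Mg] - [dNTP])` conversion). This matters: under bare 50 mM even
25-mers have median Tm around 58 °C, so requiring Tm ∈ [57, 63] would reject
the anchored primer-2/3 — which offer only eight length candidates — for most
loci. At PCR-buffer salt the same window is well matched to 18–25-mers, and
roughly 83% of random fixture tasks design completely; the remainder fail
honestly at extreme-composition junctions and are reported with their
dominant cause. The GC window defaults to [0.20, 0.80], the conventional
bounds in PCR primer design, with optimum 0.50.

`duplex_tm()` is a screening model, not a partition function: the best
ungapped complementary alignment between two oligos, scored as a perfect
duplex of its longest complementary run (runs shorter than 4 nt are ignored;
`-Inf` marks "no stable duplex"). `hairpin_tm()` analogously scores maximal
inverted-repeat stems of ≥ 4 bp around loops of ≥ 3 nt. Internal loops,
bulges and RNA parameters are out of scope.

## Off-target evaluation

Arms are screened with a seed-and-extend scanner: every exact 11-mer of the
arm (both strands) seeds an ungapped diagonal against the genome, and
diagonals with identity ≥ 0.8 over at least half the arm length are reported,
excluding the intended locus. An internal scanner rather than an external
alignment program keeps hits bit-reproducible and dependency-free; seed
length, identity and coverage thresholds are configurable, and the gapless
extension means indel-containing paralogs are a documented blind spot. Each
primer additionally gets a mis-priming check: genomic occurrences of its
3′-terminal 12-mer outside the intended site are reported as warnings.

## The synthetic fixture generator

`generate_fixture()` emulates the three inputs from a seed: a uniform-random
genome with optional GC bias and planted duplications, a random 3-kb backbone
with distinct 20-nt termini, and a task table whose contexts are verbatim
genome slices with the edit at the context midpoint, plus a ground-truth
coordinate ledger. Defaults — one 50-kb contig, 2,400-nt contexts — were
chosen once: 2,400 is the smallest round context length that satisfies the
default length rule (sum bound 1,950) and the centrality margins (1,100
upstream, 850 downstream) with a centered site; 50 kb keeps the naive test
oracles fast while leaving 20-mers overwhelmingly unique. The generator is a
pure function of its spec (same seed, same bytes) and restores the caller's
RNG state.

What passing fixture tests show — and what they do not: random uniform
sequence has no repeat structure, skewed composition, or indel-diverged
paralogs beyond what is explicitly planted, so success rates and off-target
counts on real genomes (which carry IS elements, rRNA operons and paralogous
families) will differ. The structural guarantees (arm/overlap/match-length
contracts, assembly closure, exact edit delivery) are
composition-independent.

## Numerical and edge-case choices

* Ties in the optimizer resolve by (penalty, shorter length, smaller start)
  with a 1e-9 penalty tolerance, making batches bit-reproducible.
* Degenerate ODRs (`uha_min == uha_max`) are valid single-position regions;
  empty ODRs (e.g. a backbone shorter than `dis1_min`) fail the task with the
  region named.
* The vector-side verification region is truncated at the backbone end when
  `dis1_max` overshoots it.
* An edit within 10 nt of a context end cannot host the junction window and
  fails as `DESIGN_WINDOW_CLIPPED` (normally pre-empted by the centrality
  rule).
* `N` is tolerated in genomes but forbidden inside any primer match or
  junction window.
* Insertions insert *after* the 1-based `index`; deletions remove the base
  *at* `index`. Multi-nucleotide edits are rejected per row.
* Outputs are CSV with fixed headers and no timestamps; re-running a batch on
  identical inputs reproduces identical bytes.

## Problem sizes used by the test suite

The shipped tests run the full pipeline on seeded fixtures of 50-kb genomes:
a 12-task structural batch, a 200-task mixed substitution/insertion/deletion
round-trip through assembly and both crossovers, 50-template optimizer-oracle
comparisons, 100-oligo Tm-oracle comparisons (tolerance 0.01 °C), naive
off-target oracle comparisons, and a 1,000-task throughput batch. These sizes
exercise every code path while keeping the independent brute-force oracles
(quadratic or worse) tractable.

## Known limitations

* Gapless off-target extension; no E-value statistics.
* Secondary-structure screens are run-based heuristics, not partition
  functions.
* One mutation per task; fragment-scale edits and other editing chemistries
  (CRISPR/Cas, recombineering) are out of scope.
* The crossover simulator models clean, exact recombination within the shared
  homology; it validates design geometry, not recombination efficiency.
* No attempt is made to reproduce any specific external tool's internal
  penalty function; the scoring model is fully specified above and exposed in
  `design_parameters()`.
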