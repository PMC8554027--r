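# pmedit

Batch design of homologous arms and primers for introducing single genomic
point mutations (substitutions, insertions, deletions) into bacterial
chromosomes by **suicide-plasmid counter-selection editing** with
overlap-based vector assembly.

Strain engineers who edit *Corynebacterium glutamicum* (or any bacterium with
a working allelic-exchange system) by two rounds of single-crossover
recombination need, for *every* mutation: an upstream and a downstream
homologous arm carrying the edit at their junction, four cloning primers whose
5′ tails create the three 20-bp assembly overlaps, and three easily-forgotten
verification primers for the two crossover screens. Designing these by hand
does not scale to the hundreds or thousands of mutations that reverse
engineering of evolved strains calls for. `pmedit` automates the whole batch:
input validation against the target genome, primer optimization, off-target
screening, and an in-silico verification of every design.

## The design problem

For a requested edit, the package:

1. **validates** the task — the context sequence must exceed
   `UHA_max + DHA_max + UIS_max + DIS2_min` in length, hold the mutation site
   near its middle, and match the genome exactly once on the forward strand;
2. applies the edit and extracts the 20-nt **junction window** covering the
   mutation (edited base at window offset 9);
3. derives the **optional design regions (ODRs)** from the configured length
   ranges (arms 500–800 nt by default; verification spans 50–300 nt) and
   constructs the four 20-bp overhang tails — the junction window and its
   reverse complement for primer-3/2, the two vector termini for primer-1/4;
4. **optimizes all seven primers** over every admissible (start, length) with
   3′ matches of 18–25 nt, minimizing
   `w_tm·|Tm − Tm_opt| + w_gc·|GC − GC_opt|·100 + dimer and hairpin
   penalties`, under hard Tm/GC windows. Melting temperatures use the unified
   nearest-neighbor ΔH/ΔS model with salt correction
   `ΔS + 0.368(n−1)ln[Na⁺]`;
5. screens both arms genome-wide with a **seed-and-extend** scanner (11-nt
   seeds, gapless extension, identity ≥ 0.8 over ≥ 50% of the arm) and each
   primer's 3′-terminal 12-mer for mis-priming;
6. **verifies** the design by simulating PCR of both amplicons, overlap
   assembly into the circular suicide plasmid (all three junctions checked
   exactly), plasmid integration (first crossover), and resolution into the
   edited genome (second crossover).

Results land in four CSVs — `design_results`, `primer_order` (vendor-ready),
`failed_task` (with the dominant rejection cause per failure), and
`evaluation_result` (off-target hits) — and batches are bit-reproducible.

## Worked example

```r
library(pmedit)

# seeded synthetic inputs: 50-kb genome, 3-kb backbone, 4 substitution tasks
fx <- generate_fixture(fixture_spec(seed = 19, n_tasks = 4))
batch <- design_batch(fx$tasks, fx$genome, fx$vector)
batch
#> <pm_design> 4 task(s): 4 designed, 0 failed, 0 off-target warning(s)

res <- batch$results[[1]]
res
#> <pm_design_result 'task_001'> substitution at contig_1:2047
#>   UHA 572 nt, DHA 773 nt; amplicons uha=592, dha=793, verification_1=1836, verification_2=1749
#>   primer-1       TTCGACAGGCAGGCGTCACCGCTTACGATGCGGAAATCTCAC
#>   primer-2       ACGTGAGTTGTATTGTCGGCTGAGCAACCTCGGAGCTCTAAT
#>   primer-3       GCCGACAATACAACTCACGTTTCGCGACACGTAGCCTG
#>   primer-4       AGGAGAGATAGCTTCACAGATAATCCGCTATTCCCGAGTTCG
#>   test-primer-1  GCCGGAGTTTCATAGTCTGGAA
#>   test-primer-2  CATTGGGAAATTCGACTCTGGC
#>   test-primer-3  ATAGGTCGCCCAAAAAGCCA
```

`task_001` asks for a substitution at genome position 2,047 (0-based). The
design delivers a 572-nt upstream and a 773-nt downstream arm; the first 20 nt
of primer-1/2/3/4 are the assembly tails (primer-3's tail *is* the edited
junction window, primer-2's its reverse complement), the remainder the 18–25-nt
template matches. The UHA amplicon will run 592 nt (arm plus the two tails),
and the two verification PCRs are expected at 1,836 nt on the integrant and
1,749 nt on the edited genome.

```r
plasmid <- assemble_in_silico(res, fx$vector)
plasmid
#> <pm_plasmid> circular, 4325 nt (vector 3000 + insert 1325)

sim <- predict_edited_genome(res, fx$genome, plasmid = plasmid)
sim$ver1_len; sim$ver2_len
#> [1] 1836
#> [1] 1749
```

The simulated circle closes at all three 20-bp junctions and carries the
edited insert; the simulated integrant yields the test-primer-1/2 product
(absent from wild type — the false-positive screen), and the resolved genome
differs from the input at exactly the requested base. `tidy(batch)` returns
the 7-per-task primer table, `glance(batch)` the run summary, and
`autoplot(batch)` plots every primer against the Tm/GC acceptance window.

File-based batches run the same way from a shell:

```sh
Rscript inst/cli/pmedit.R design --genome genome.fasta --vector vector.txt \
    --mutations mutations.csv --out results/
```

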