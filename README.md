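# mitoprofile

Profiling of human mitochondrial genome alignments from high-throughput
sequencing, as a scriptable R package with a command-line interface. Given a
BAM/SAM file mapped to a single mtDNA reference (rCRS-like FASTA),
mitoprofile computes quality-control summary statistics, assembles a
consensus sequence under three explicit base-calling rules, detects
heteroplasmic sites by minor allele frequency, assigns a haplogroup from
PhyloTree-style defining variants, estimates exogenous contamination,
profiles ancient-DNA deamination damage, calls and annotates
consensus-versus-reference variants, and renders everything into one static
HTML report with machine-readable TSV/JSON alongside. A bundled single-end
read simulator with known truth makes the whole pipeline testable offline.

It is aimed at population-genetics, forensic and ancient-DNA workflows where
the mitochondrial genome is analysed on its own and reproducibility matters
more than interactivity.

## The statistics at the core

All quantities are computed from a quality-filtered pileup (bases with phred
≥ 30 from reads with mapping quality ≥ 20 by default, duplicates and
secondary alignments excluded):

* **Consensus calling** per site under *majority* (most-read base; ties and
  empty columns give `N`), *best score* (highest phred regardless of depth;
  tied maxima give `N`), or *majority + best score* (majority first, count
  ties broken by phred).
* **Support ratio** per site: `P_support = (N_agree / N_depth) × 100`, the
  percentage of filtered bases agreeing with the consensus base.
* **Heteroplasmy**: `MAF = N_diff / N_con`, the ratio of bases discordant
  with the consensus to bases concordant with it; a site is flagged when
  some minor allele's MAF strictly exceeds the threshold (default 0.10)
  at sufficient depth (default ≥ 10).
* **Haplogroup assignment**: each haplogroup's cumulative defining variants
  (back-mutations `!` cancelling along the root-to-node path) are scored
  against the called bases; nodes are ranked by
  `(n_match − n_mismatch) / max(1, n_match + n_mismatch)`. Accuracy over a
  labelled set is `TP / (TP + FP)`.
* **Contamination indicator** over the `k` scorable defining sites of the
  assigned haplogroup:
  `P_mismatch = [Σ_i (N_mismatch,i / N_match,i) / k] × 100`.
* **Damage profile**: per-read-offset C→T rate anchored at the 5′ end and
  G→A at the 3′ end (reverse-strand reads complement-flipped into molecule
  coordinates), conditioned on reference-C/-G positions, plus the
  read-length distribution.

Derivations, default choices and their rationale are in the methods
vignette (`vignettes/mitoprofile-methods.Rmd`).

## Worked example

Simulate a sample from a known haplogroup with 10% exogenous reads, then
profile it:

```r
library(mitoprofile)

# synthetic 16.5 kb reference and a 16-haplogroup tree with known truth
set.seed(7)
ref  <- reference_genome(paste(sample(c("A","C","G","T"), 16569, TRUE),
                               collapse = ""), "synthMT")
tree <- random_haplotree(ref, n_nodes = 16, variants_per_node = 6, seed = 8)

# simulate a sample from haplogroup HG11 with 10% exogenous reads
hap <- make_haplotype(ref, cumulative_variants(tree, "HG11")$state)
sim <- simulate_reads(simulation_config(hap, depth = 80,
                                        contaminant = ref$sequence,
                                        contamination_fraction = 0.10,
                                        error_rate = 0.01, seed = 9), ref)

pu   <- build_pileup(sim$reads, ref)                # quality-filtered pileup
cons <- build_consensus(pu, "majority")             # consensus sequence
call <- assign_haplogroup(pu, tree)                 # haplogroup ranking
het  <- detect_heteroplasmy(pu, cons, maf_threshold = 0.10)

cat("reads:", nrow(sim$reads), " mean depth:", round(mean(pu$raw_depth), 1), "\n")
cat("best haplogroup:", call$best, "\n")
print(head(call$ranking, 3))
cat("P_mismatch:", round(as.numeric(p_mismatch(pu, tree, call$best)), 2), "%\n")
cat("flagged heteroplasmic sites:", sum(het$flagged), "\n")
```

which prints:

```
reads: 13255  mean depth: 80
best haplogroup: HG11
  haplogroup     score n_match n_mismatch n_nocall k_covered depth
1       HG11 1.0000000      12          0        0        12     2
2       HG02 1.0000000       6          0        0         6     1
3       HG15 0.3333333      12          6        0        18     3
P_mismatch: 10.09 %
flagged heteroplasmic sites: 5
```

The true haplogroup is recovered (its 12 cumulative defining variants all
match; the runner-up matches only the 6 shared ancestral ones and loses the
tie-break on matches). The 10% contaminant fraction surfaces twice, exactly
as it should: `P_mismatch` ≈ 10%, and the contaminant's alleles at
haplogroup-defining sites appear as borderline heteroplasmic calls with
MAF just over 0.10.

The same pipeline runs from the shell on files
(`BAM/SAM + FASTA [+ tree TSV + annotation CSV]`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli","mitoprofile",package="mitoprofile"))')
Rscript $CLI simulate   --ref ref.fa --out sim --depth 50 --seed 7
Rscript $CLI haplogroup --bam sim/simulated.sam --ref ref.fa --tree tree.tsv --out hg
Rscript $CLI run        --config run.yaml     # full pipeline + HTML report
```

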