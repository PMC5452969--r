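---
title: "Methods: consensus calling, haplogroup assignment and damage profiling in mitoprofile"
author: "mitoprofile authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calling, haplogroup assignment and damage profiling in mitoprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## Scope and data model

mitoprofile profiles alignments of high-throughput sequencing reads against a
single mitochondrial reference sequence (an rCRS-like FASTA of roughly
16.5 kb, though any single-record DNA FASTA is accepted). The unit every
analysis consumes is the *pileup*: for each 1-based reference position, the
count of each base A/C/G/T among filter-passing read bases, the best (maximum)
phred score seen per base, the number of reads whose CIGAR places a deletion
across the position, and the raw (pre-quality-filter) depth.

Coordinates are 1-based and fully closed throughout, matching mtDNA variant
nomenclature in which `C150T` means position 150. The mitochondrial genome is
circular, but BAM coordinates are linear; reads that would run past the
reference end are rejected rather than wrapped, mirroring standard practice
of mapping against the linearised reference. Analysis of origin-spanning
reads is out of scope.

### Filters

A base enters the pileup counts if and only if

* its phred score is **greater than or equal to** the base-quality threshold
  (default 30). Descriptions of such filters alternate between "higher than"
  and "at least"; this package pins the inclusive boundary so that the
  default of 30 admits Q30 bases, which is the common convention, and the
  test suite pins this boundary explicitly;
* its read passes the mapping-quality threshold (default 20), and is neither
  a flagged duplicate nor a secondary alignment (both exclusions can be
  switched off). No mapping-quality default is canonical for mtDNA pipelines,
  so 20 is this package's documented choice;
* it is a plain A/C/G/T. `N` is never counted; other IUPAC ambiguity codes
  are treated as `N` and reported once per pileup build.

Raw depth counts all aligned bases (and spanning deletions) of reads passing
the *read-level* filters, before the base-quality filter, so the difference
between raw and filtered depth is itself a quality signal.

## Consensus calling

Three site-calling rules are provided, selectable per run:

* **majority** — the base with the highest count wins; a tie for the maximum
  (with data present) yields `N`, as does an empty column.
* **bestscore** — the base with the single highest phred score among counted
  bases wins, regardless of depth; two or more bases sharing that maximum
  yield `N`.
* **majority + bestscore** — majority first; a count tie (with data) is
  re-decided among the tied bases by the highest phred score, and only a
  double tie stays `N`.

Deletions are not part of the original rule set but must be representable,
because haplogroup-defining variants include deletions. The package calls a
site `-` under majority rules when the spanning-deletion count strictly
exceeds every base count; `-` sites are dropped from the FASTA serialization
(and kept in the per-site table), and the best-score rule ignores deletions
entirely since they carry no phred score. This convention is this package's
own and is documented rather than inferred from any reference behaviour.

Per site, the support ratio

$$P_\mathrm{support} = \frac{N_\mathrm{agree}}{N_\mathrm{depth}} \times 100$$

is reported, where $N_\mathrm{agree}$ counts filter-passing bases agreeing
with the called base and $N_\mathrm{depth}$ is the filtered depth. Uniform
support near 100% indicates a clean assembly; a band of sites near, say, 70%
is the classic signature of a 30% exogenous read fraction.

## Heteroplasmy detection

For a site with consensus base $c$ and a candidate minor allele $a$, the
minor allele frequency is computed as the ratio of discordant to concordant
bases:

$$\mathrm{MAF} = \frac{N_\mathrm{diff}}{N_\mathrm{con}},$$

with $N_\mathrm{diff}$ the count of $a$ and $N_\mathrm{con}$ the count of
$c$. Note this ratio exceeds 1 when the minor allele outnumbers the
consensus; it is implemented exactly in this form, and the conventional
minor fraction $N_\mathrm{diff} / (N_\mathrm{diff} + N_\mathrm{con})$ is
reported in a separate, clearly labelled column, because the ratio form is
the one used as the detection threshold. Whether the denominator "should" be
concordant bases only or total depth cannot be settled from the available
description; reporting both resolves the ambiguity for downstream users.

A site is *flagged* when some minor allele's MAF strictly exceeds the
threshold (default 0.10), the consensus at the site is a called base, and
the filtered depth reaches `min_depth` (default 10). The depth floor is this
package's addition: without it a single discordant read at depth 2 would be
flagged. Detection at threshold $t$ with minor fraction $f$ and depth $d$
follows binomial sampling of the minor count, which is what the simulator's
two-haplotype mixtures reproduce.

## Variant calling and annotation

The consensus is realigned to the reference by a built-in global
(Needleman–Wunsch) aligner with fixed scoring — match $+1$, mismatch $-1$,
gap $-2$ (linear) — and deterministic tie-breaking: at every cell the
diagonal move is preferred, then the move consuming a consensus base, then
the move consuming a reference base. The traceback yields a monotonic
partial map between consensus and reference positions. Aligned pairs where
the consensus differs from the reference become substitution variants
(`C150T`); reference positions absent from the map become deletion variants
(`A249d`); `N` sites yield no variant; consensus insertions are reported
separately without a reference-position label. The aligner is implemented in
C++ for the 16.5 kb scale (the full dynamic program keeps one byte per cell,
roughly 274 MB transiently at mitochondrial size) and is verified in the
test suite against exhaustive enumeration on short sequences and against an
independent alignment implementation on longer ones.

Annotation databases are two-column CSV files (allele label, free-text
information), the layout used by customizable mtDNA annotation templates.
Joining is by exact label match; unmatched variants are kept with empty
annotation, multiple matches are all reported, and unparseable database rows
are skipped with a warning and a count.

## Haplogroup assignment

The haplogroup tree is a tab-delimited file — name, parent (empty for the
root), comma-separated defining-variant tokens — whose content is typically
derived from a PhyloTree build; conversion from PhyloTree's own export
format is the user's responsibility. Tokens cover substitutions (`A73G`),
back-mutations (`A5G!`), deletions (`A249d`) and insertions (`16182.1C`).
The *cumulative* variant state of a node replays the root-to-node path, a
later back-mutation cancelling the earlier variant at that position.
Insertions are parsed and carried but excluded from scoring — a pileup
column cannot host an insertion under this data model — and the number of
excluded tokens is reported so the information loss is visible.

Each node is scored against called bases (majority calls from the pileup by
default; a consensus object can be supplied instead — both substrates are
supported because either reading of "assignment from a BAM file" is
defensible). Per scorable cumulative variant: *match* when the call equals
the expected allele (deletion variants match a `-` call), *no-call* when the
site is `N`, *mismatch* otherwise. The ranking score is

$$s = \frac{n_\mathrm{match} - n_\mathrm{mismatch}}{\max(1,\; n_\mathrm{match} + n_\mathrm{mismatch})},$$

with ties broken by more matches, then deeper (more specific) node, then
name. **This scoring function is the largest single design choice in the
package** — no canonical definition of "most likely haplogroup" exists for
this kind of counting classifier — and it is therefore isolated behind one
function so an alternative (e.g. likelihood-based placement) can be
substituted without touching the rest of the pipeline.

Assignment accuracy over a labelled sample set is $TP/(TP+FP)$, where a true
positive is an exact name match.

### Contamination indicator

Over the $k$ scorable defining sites of the assigned haplogroup with at
least one supporting base,

$$P_\mathrm{mismatch} = \left[ \frac{1}{k} \sum_{i=1}^{k}
  \frac{N_{\mathrm{mismatch},i}}{N_{\mathrm{match},i}} \right] \times 100,$$

where $N_{\mathrm{match},i}$ counts pileup bases consistent with the
defining allele at site $i$ and $N_{\mathrm{mismatch},i}$ the remaining
filtered bases there. Sites with $N_\mathrm{match} = 0$ would make the ratio
infinite; they are excluded from $k$ and counted separately (the printed
formula divides by $N_\mathrm{match}$, so this exclusion is forced). With a
contaminant fraction $f$ and sequencing error $\varepsilon$, the per-site
ratio concentrates around $(f + \varepsilon')/(1 - f)$ at sites where the
contaminant carries the reference allele, so the indicator is convex in $f$
rather than linear — it is a monotone indicator, not an unbiased estimate of
the contaminated fraction.

## Ancient-DNA damage indicators

Post-mortem cytosine deamination appears as C→T substitutions concentrated
at the 5′ end of the original molecule (and G→A at the 3′ end, from the
complementary strand), decaying into the read. For offsets $o = 1..K$
(default $K = 25$, a typical window for this analysis), the 5′ rate at $o$
is the fraction of reference-C positions at molecule offset $o$ read as T;
symmetrically for 3′ G→A. Reads aligned to the reverse strand are
complement-flipped so offsets are in original-molecule coordinates — the
orientation symmetry (flipping every strand flag swaps the 5′/3′ statistics
with complemented substitution keys) is pinned in the tests. Rates condition
on reference-C (resp. -G) positions, the standard definition; offsets with
no eligible position are reported missing rather than zero. All 12
substitution rates are reported at both ends so the C→T/G→A excess can be
judged against the background error rate, and the read-length histogram
(fixed bin width 5) summarises fragmentation. Damage profiling defaults to a
milder base-quality cut (Q20) than consensus calling, exposed separately,
because damaged bases are signal here and over-filtering suppresses exactly
the pattern being measured. These are indicators only; no statistical
authentication model is fitted.

## The read simulator

Every stochastic claim in the package is validated against simulated reads
with known truth. The generator emulates an Illumina-style single-end
simulation: `round(depth × L / read_length)` reads, uniform start positions,
uniform strand, fixed read length (default 100), i.i.d. per-base errors at a
configurable rate (default 1%, uniform over the three alternatives), an
optional contaminant haplotype contributing each read with probability equal
to the contamination fraction (0–50%), and optional terminal deamination
applied *before* sequencing error: C→T at 5′ molecule offset $o$ with
probability $r_0 e^{-(o-1)/\lambda}$ and symmetrically G→A at the 3′ end.
Correct bases get Q37; error bases get a configurable quality (default also
Q37, so the quality filter does not silently remove injected errors — a
"low-quality-error" mode at e.g. Q15 exercises the filter path). Reads are
emitted pre-aligned at their true positions (mapping is upstream of this
toolkit's scope), and the truth object records per-read source, error and
damage events, and realized depth, sufficient to reproduce every read byte
from the configuration and seed.

The defaults are the package's standard operating point — 1% error,
single-end 100-base reads, depths spanning 1–1000×, contamination 0–30% —
and simulations in the tests and the acceptance script run at those values.

What the simulator does *not* reproduce: empirical quality-score profiles
(qualities are flat), indels and structural variants (haplotypes are
substitution-only, keeping truth coordinates aligned to the reference),
paired-end reads, mapping artefacts (reads are pre-aligned, so reference
bias and mismapping are absent), and library-specific damage chemistry
beyond the exponential terminal model. Passing tests therefore demonstrate
correctness of the *computations* under a clean generative model, not
robustness to every artefact of real sequencing data.

## Numerical and degenerate-input choices

* Zero-depth sites are `N` in every mode; the combined mode's tie-breaking
  applies only to genuine count ties with data.
* `P_support` and per-site MAF are undefined (reported missing / an error)
  at zero filtered depth or zero concordant bases respectively.
* The aligner's tie-breaking (diagonal, then up, then left) makes the
  position map deterministic; an all-`N` consensus is a degenerate but valid
  input (every pair scores as a mismatch), not an error.
* Accuracy is undefined on empty truth/prediction vectors (an error, not
  `NaN`).
* Read-length binning, section order in the report and output file names
  are fixed so repeat runs are byte-identical except for the HTML
  timestamp.

## Problem sizes used in the checks

The end-to-end checks run on a 16,569 bp synthetic reference with a 16-node
haplogroup tree carrying 6 defining substitutions per branch: 100 simulated
samples at 50× for the headline assignment accuracy, 40 samples per depth in
{1, 5, 10}× for the depth sweep, a contamination sweep at {0, 10, 20, 30}%
at 100×, damage recovery at 100× with $r_0 = 0.3$, $\lambda = 3$, and
two-haplotype heteroplasmy mixtures at depths 40 and 100. These sizes give
stable statistics (binomial standard errors well inside the asserted
tolerances) while keeping a full run in the low minutes on one CPU.

## Known limitations

* No indel-aware haplotype simulation, so deletion/insertion variant calling
  is exercised on constructed consensi rather than simulated reads.
* Haplogroup scoring treats defining sites as independent; no phylogenetic
  likelihood, and no re-basing of a tree onto a different reference
  coordinate frame (the tree file must match the supplied reference).
* The contamination indicator assumes the assigned haplogroup is correct;
  heavy contamination that flips the assignment also invalidates the
  indicator.
* The consensus never encodes mixed sites (no IUPAC ambiguity output);
  heteroplasmy is reported in its own table instead.
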