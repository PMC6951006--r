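---
title: "Methods: SINE insertion polymorphism analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SINE insertion polymorphism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinepop)
```

`sinepop` analyses a family of tRNA-derived short interspersed nuclear
elements (SINEs) segregating as presence/absence polymorphisms between the
migratory and freshwater-resident ecotypes of *Coilia nasus*. This vignette
documents the models, the parameters that matter, the synthetic-data design,
and the numerical decisions, so that results can be interpreted and the
implementation audited.

## The element model

A complete family member is modelled on a 208-bp consensus in three
contiguous regions: a 75-bp tRNA-related region carrying the RNA polymerase
III internal promoter (A box, consensus `TRGCNNARYNNG`; B box, `GWTCRANNC`),
a body region, and a 56-bp LINE-derived tail whose diagnostic motifs are
tandem TGTAA copies and/or a poly(A) tract. With a 75-bp tRNA region and a
56-bp tail, 77 bp remain; the stated body length of 75 bp leaves 2 nt
unaccounted, which we assign to the body, giving the fixed spans
`[0, 75)`, `[75, 152)`, `[152, 208)` (all coordinates in this package are
0-based, half-open).

`annotate_element()` aligns a candidate to the consensus with
Needleman–Wunsch (match +1, mismatch −1, gap −2; the source study reports no
scheme, so this is a package choice), projects the region boundaries through
the alignment, and reports percent identity as matches over alignment
columns, with `N` never counting as a match. Family membership uses the
conventional 76% conservation threshold applied to the body region. Body
indels of ≥ 3 bp are reported from the gap runs of the alignment.

Two alignment decisions deserve note:

* **Tie-breaking.** Among score-optimal alignments we return the one with
  the fewest gap columns, and among those the fewest gap runs (a
  three-state dynamic program tracks both). Under a linear gap penalty,
  score-equivalent alignments exist that interleave a planted contiguous
  insertion with chance matches; the lexicographic objective makes a planted
  41-bp body insertion come back as a single 41-bp `ins` call rather than a
  scatter of fragments, without changing any score.
* **Identity calibration.** For elements diverged by uniform substitutions,
  alignment identity tracks the planted substitution fraction to within
  0.02 across the family range (0.77–0.94). When divergence is concentrated
  in one block — as in our synthetic poly(A)-only and TGTAA-only tail
  classes, which replace a whole tail segment — a gapped alignment can
  legitimately re-register the block and report identity a few points above
  the substitution fraction. Identity recovery is therefore only a
  calibration target for substitution-only elements.

`classify_tail()` counts TGTAA copies as the longest tandem run of exact
copies and requires a downstream run of ≥ 5 A's for the poly(A) call;
`scan_ab_boxes()` scans the IUPAC box consensus with ≤ 2 mismatches,
restricting the A box to the first 40 nt and the B box downstream of it.
The two-mismatch gate is deliberately permissive — on random 75-mers chance
A-box hits are common — because the scan is a descriptive annotation, not a
classifier; the planted-box tests use backgrounds that cannot match.

`fold_hairpin()` is a maximum-pairing (Nussinov) fold with a minimum loop
of 3 nt and pairs A–T, G–C and (optionally) G–T scoring 1 each. It is a
combinatorial stand-in for thermodynamic folding and is used only to
exhibit the stem–loop character of the tail; the reported stem is the
longest run of consecutively nested pairs. Traceback always pairs when a
pairing choice attains the optimum and then takes the outermost partner.
Note that G–T wobble pairing is not symmetric under reverse complement
(G–T maps to A–C), so strand-symmetric folding requires `allow_gu = FALSE`;
that switch is also how the fold's strand-invariance property is tested.

`survey_transcripts()` mirrors the study's blastn screen of olfactory
transcriptome contigs: local (Smith–Waterman) alignment of the consensus
against each contig on both strands, a raw-score gate of 80, and a region
counted when ≥ 90% of its consensus span is covered by the hit; a contig
covering all three regions counts as a full-length transcript copy. The
survey scores with blastn-like +2/−3 (gap −5) rather than the annotation
scheme: under +1 scoring even a perfect 56-bp tail-only fragment could
never clear a gate of 80, while on the blastn scale (perfect tail = 112)
the gate separates real fragments from noise exactly as intended.

## Insertion and excision forensics

`call_tsd()` reports the longest k in 2–31 with
`filled[s−k, s) == filled[e, e+k)` — TSD copies flank the element and are
not counted inside it. Matching is exact and `N`-free. The call is certified
in tests by a brute-force scan over every k; on planted loci the call equals
the planted length whenever the flanks carry no longer chance duplication
(the generator records this flag).

`find_flank_duplications()` compares 100-nt windows at the two junctions of
the filled allele with the corresponding windows of the empty allele and
reports maximal segments (≥ 10 nt) that are repeated in the filled window
(≥ 2 occurrences) and occur more often there than in the empty window. The
repeat requirement matters: without it, any unique insertion-adjacent
segment trivially occurs "more often than in the empty allele". Empty-allele
windows are anchored such that removing the element plus one TSD copy gives
byte-identical windows, so clean insertions produce no calls.

`find_tandem_repeats()` enumerates maximal tandem arrays with a primitive
unit of 1–20 nt, ≥ 3 copies and ≥ 8 nt total, allowing a trailing partial
copy of at least half a unit; overlapping candidates collapse to the longest
array (ties: smallest unit, then leftmost). The thresholds admit every
repeat class seen in the study's flanks — from `(G)38` homopolymers to a
20-nt unit repeated 14 times — while excluding dinucleotide noise.
Offsets are signed: negative upstream of the 5' junction, positive
downstream of the 3' junction.

`call_footprint()` anchors an excised allele to its filled allele by exact
end-blocks: the longest shared prefix, then the longest shared suffix of
the remainders (so anchors cannot overlap); anchors under 30 nt raise an
"alleles not comparable" error. The fill is everything between the anchors
on the excised side; the microhomology is the longest exact suffix of the
fill equal to the bases immediately following it (window 25 nt); flank loss
is the filled-side gap minus the element and one TSD copy (clamped at 0);
and the fill's microsatellite is the largest tandem array covering at least
half the fill. When the copied junction bases happen to continue the
repeat's period, the detected array is genuinely longer than the planted
core; the generator records that extension so recovery is exact in both
directions.

## Population genetics

Genotypes are `II`/`IA`/`AA` (insertion homozygote, heterozygote, empty
homozygote) with explicit `missing`. Per cell,
`f_SINE = (2 n_II + n_IA) / 2n` and `Het = n_IA / n`.

The Hardy–Weinberg test is the conditional exact test: given the allele
counts, all heterozygote counts of the same parity are enumerated, each with
probability `n! / (n_II! n_IA! n_AA!) · 2^{n_IA} · n_I! n_A! / (2n)!`, and
the p-value sums the configurations no more probable than the observed one
(ties included at a 1e-12 relative tolerance). Monomorphic samples give
p = 1. The implementation is verified against an independent
polynomial-expansion enumeration for every genotype triple with n ≤ 25.
Exact conditional p-values are discrete and conservative at small n — at the
survey's n = 10 a Kolmogorov–Smirnov uniformity check would reject by
construction — so calibration is assessed at n = 500 diploids and f = 0.5,
where the null distribution is dense enough for the KS check to be
meaningful.

Genetic distances treat each locus as biallelic with frequency vectors
`(f, 1−f)`. The default is Nei's (1972) standard distance with identity
sums over loci and alleles; Nei's DA (1983) is available via `method = "da"`
and the choice is recorded in the matrix attributes. The ratio inside the
logarithm is clamped to ≤ 1, and completely disjoint allele sets (zero
between-population identity) are reported as a capped value of 10 with a
flag rather than infinity. Neighbor joining uses `ape::nj()` (Saitou–Nei
with the Studier–Keppler criterion); negative branch lengths are clamped to
zero with a flag. On the published frequencies the resident-lake
populations PY and DT join as neighbors, which is the topology check used
in acceptance.

AMOVA encodes individuals as per-locus insertion-dosage vectors (0/1/2), so
squared Euclidean distances drive the sums of squares, partitioned among
groups, among populations within groups, and within populations; variance
components follow the standard nested ANOVA expectations and Phi statistics
derive from the untruncated components (reported percentages truncate
negative components to zero, with a record). Permutation p-values permute
individuals across populations for Phi_ST, individuals within groups for
Phi_SC, and whole populations across groups for Phi_CT, with
`p = (1 + #{perm ≥ obs}) / (n_perm + 1)` so p ∈ (0, 1]. The default group
assignment places XS, CM and JJ in the migratory ecotype and PY and DT in
the resident one; TH (Taihu Lake) clusters with the migratory lineage on
frequencies but is lake-dwelling by habitat, so its assignment is an
explicit parameter of `default_ecotype_grouping()`.

The survey fixture `table1_fixture()` converts each published (f, Het) cell
into integer genotype counts for n = 10 diploids via
`het = round(10·Het)`, `n_II = round(10·f − het/2)`, `n_AA = 10 − n_II −
het`, validating that the counts reproduce the printed pair exactly and
erroring with the offending cell otherwise; the construction is unique for
all cells of the survey. One printed aggregate (the CM across-locus mean
heterozygosity) is inconsistent with its own column — it recomputes to 0.10
from the per-locus cells — and is excluded from the aggregate checks; all
30 per-locus cells reproduce exactly. The published per-locus ecotype table
is likewise carried as printed: its per-locus migratory frequencies are not
derivable from the population table under any simple pooling (the original
pooling is unreported), so only its across-locus Mean row, which is the
unweighted column mean of the printed rows, is checked.

## qPCR quantification

The standard curve is an ordinary least-squares fit of Ct on log10 template
copies; quantification inverts it (`copies = 10^((Ct − b)/a)`), replicates
are averaged on the Ct scale before inversion, and copies per genome
multiply by `genome_size_pg / input_mass_pg` with the *C. nasus* genome
size of 3.534 pg as default. Slopes outside the PCR-efficiency band
[−3.6, −3.1] warn but never fail, because the study's own curve (slope
−3.11) sits at the band edge. Input DNA mass is an explicit plate column
since the source study does not print it. Real plate measurements are not
reproducible at desk scale; the study's group means (3.5×10^5 resident vs
2.3×10^5 migratory copies per genome) parameterize a power simulation
(sd 0.3×10^5, n = 30 per group) instead.

## The synthetic-data generator

The generator's defaults are the study conditions: element identity drawn
uniformly from 0.77–0.94; TSD lengths on 2–31 nt with 80% of the mass
spread over 3–8 (weight 0.05 on length 2 and a geometric tail over 9–31 —
the study reports only the range and mode, so the exact weights are a
package choice); tail classes poly(A)/TGTAA/TGTAA-poly(A) at 25/25/50%;
150-nt flanks with A+T probability 0.566 to match the reported flank AT
content; one 3–31 bp body indel per element with probability 0.2; Ct noise
0.2 cycles; 6 populations of 10 diploids. Divergence is substitutions only,
uniform over positions but sparing the motif positions that define the
planted tail class, so the class remains readable at 77% identity; planted
identity is recorded as the realized substitution fraction. Excision
alleles are built as retained left flank + tandem fill + microhomology
copied from the retained 3' junction + retained right flank, so that with
zero fill, zero microhomology and no deletion the excised allele equals the
empty allele exactly.

Every planted feature is recoverable by exact substring inspection, and the
generator records per-locus cleanliness flags (is the planted TSD the
longest flank duplication? do the anchors extend by chance? does the copied
microhomology extend the repeat period?) computed by direct string
comparison, independent of the detectors. Recovery tests assert exact
equality on clean plants and certify every discrepancy against brute-force
oracles.

What the generator does not emulate: indel-rich or phylogenetically
structured divergence, nested or truncated insertions, read-level
sequencing error, linkage between loci, and real qPCR plate effects.
Passing recovery tests therefore demonstrates correctness of the detection
logic under the study's stated conditions, not robustness to every artifact
of real survey data.

## Problem sizes and determinism

The test suite plants 500 insertions and 200 excisions for forensic
recovery, sweeps every Hardy–Weinberg configuration with n ≤ 25 against the
enumeration oracle, checks alignment and folding against brute force at
≤ 12 nt and tandem calls at ≤ 60 nt, and calibrates null p-values with 200
replicates (99 permutations each for AMOVA). All randomness flows through
R's RNG seeded explicitly; `run_pipeline()` re-seeds from its configuration
and writes an md5-checksummed manifest, so identical seed and configuration
yield byte-identical artifacts.

## Limitations

Alignment scoring, the tandem-repeat thresholds and the TSD longest-match
convention are package choices where the source study is silent; all are
recorded above and in the function documentation. The hairpin model is
combinatorial, not thermodynamic. The exact HWE test is conservative at
n = 10. Real deposited sequences can be supplied as FASTA and run through
the same entry points, but nothing is downloaded and no RepeatMasker-style
library classification is attempted.
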