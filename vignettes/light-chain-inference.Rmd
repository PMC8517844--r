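---
title: "Inference of light-chain germline variation from naive BCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference of light-chain germline variation from naive BCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`iglight` infers germline variation of human immunoglobulin light-chain
(IGK/IGL) V and J genes from naive B-cell-receptor repertoire data: novel
single-nucleotide alleles, double- and single-chromosome gene deletions,
gene-anchored haplotypes, and alternatively spliced upstream variants.
This vignette explains the statistical procedures, the parameters that
matter, the synthetic-data generator the package is validated against,
and the numerical choices made where the design was genuinely open.

## Why light chains are the hard case

Light-chain inference inherits every difficulty of heavy-chain germline
inference and adds three of its own. First, the kappa locus carries a
large duplication: pairs of genes (e.g. `IGKV1-12` / `IGKV1D-12`) are
sequence-identical over the V-REGION, so an annotator cannot tell which
duplicate a transcript came from and per-gene usage statistics become
meaningless unless the duplicates are treated as one unit. Second,
several reference alleles in germline databases are truncated at their
5' or 3' ends, which makes aligners choose alleles by length rather than
identity. Third, light chains lack D segments, so the junction carries
little information and every inference must come from the V/J bodies and
their pairing.

## Reference preparation

`collapse_duplicates()` groups genes by the relation *"share at least one
identical allele sequence"*, closed transitively, and merges each group
into one gene whose name carries an `E` inserted after the family token
(`IGKV1-12` + `IGKV1D-12` → `IGKV1E-12`). Distinct sequences within a
group are renumbered consecutively from `01`, ordered by (original gene,
original allele), and provenance is kept in `collapsed_from`. Collapsing
never alters a sequence, and it is idempotent. The transitive closure is
a deliberate generalisation of pairwise merging: real loci can chain
(A shares with B, B shares with C), and the closure reduces to pairs when
chains are absent.

`extend_short_alleles()` brings every allele to its gene's maximal
length. Each short allele is end-anchored at the offset minimising
mismatches against the position-wise majority of the gene's full-length
alleles (ties to the smaller offset); missing terminal bases are filled
position-wise with the majority base over the gene's other alleles
covering the position. The database does not dictate a tie-break when
donors disagree, so the package uses a deterministic one: the base
contributed by the lowest-numbered covering allele. Extended spans are
recorded in `extended_5p_len`/`extended_3p_len`; they exist only to stop
length-driven misannotation, so they are (a) excluded from mismatch
counting during annotation and (b) suppressed from candidate reporting —
a variant "discovered" inside a synthetic consensus span would be an
artefact of the extension itself.

A consequence of masking is that Hamming distances are no longer
comparable across alleles compared over different numbers of positions: a
read one real error away from a full-length allele would tie with an
extended sibling whose masked span hides the disagreement. Annotation
ties at equal distance therefore break toward the allele compared over
the most positions (equivalently, the lowest mismatch *rate*); only true
ties — equal distance over equal compared length — are kept as ambiguous
multi-calls and counted fractionally (1/k) downstream.

## Novel alleles from mismatch frequencies

For each individual and allele, `build_profiles()` tallies the base
observed at every V-REGION position over all sequences assigned to that
allele, after two filters: individuals contribute at least 2,000
sequences, and sequences carry fewer than 3 mismatches to their assigned
germline (the repertoires are naive; residual mutation load beyond that
indicates antigen-experienced cells or artefacts). N bases never count
and never vote.

The *mismatch frequency* of a candidate polymorphism in one individual is
`count(alt)/depth` at the position. Its expected values follow from
zygosity: 1.00 for a homozygous carrier, about 0.50 for a balanced
heterozygote, and 1/k when k variants of one gene are expressed equally.
The acceptance cutoff of 0.25 is the k = 4 case: it admits equal
expression of up to four variants of a gene (two chromosomes, each
possibly carrying a duplicated pair), while anything recurring at lower
frequency across the cohort is indistinguishable from a recurrent
artefact.

Candidates are *generated* at half the cutoff (`candidate_floor` =
0.125). The floor is deliberately below the acceptance threshold so that
borderline positions and artefact stacks are emitted, classified, and
rejected **with a reason**, rather than silently missed — the rejected
table is a first-class output. An individual's frequency is only defined
where the profile depth reaches `min_candidate_depth` (default 10
sequences): a handful of stray reads cannot define a frequency, and
without this guard rare misassignment residue at trivial depth can
masquerade as a high-frequency variant.

### Separating polymorphisms from sequencing artefacts

MiSeq-style artefacts have two signatures: the substitution spectrum
(A>C is the most frequent error; errors in repeat motifs such as
`CCAC → CCCC` are enriched) and, more decisively, the *cohort pattern* of
per-individual mismatch frequencies. True polymorphisms are multimodal —
carriers cluster near 0.5 or 1.0, non-carriers near 0 — while artefacts
produce a "stack": everyone shows the same sub-cutoff frequency at the
same position.

`classify_pattern()` is a deterministic surrogate for that visual
judgement. With `S` the defined frequencies above a noise floor of 0.05,
sorted ascending:

* **multimodal** — someone reaches the 0.25 cutoff *and* the gap
  separating sub-cutoff from supra-cutoff members of `{0} ∪ S` is at
  least 0.15;
* **stack_like** — all of `S` sits below the cutoff within a span
  smaller than 0.15;
* **indeterminate** — anything else, including fewer than 3 defined
  frequencies.

The two constants (noise floor 0.05, gap 0.15) are configuration fields,
not magic numbers; the qualitative behaviour is insensitive to moderate
changes, and they exist because "stack-like" has no published
quantitative definition. Filtering then accepts candidates that pass the
cutoff and are not stack-like. Candidates that pass the cutoff but
classify as indeterminate are accepted: cutoff passage is the primary
evidence, and pattern classification only *removes* stack artefacts
(historically, validation of such borderline cases was a manual
decision). The A>C and repeat-motif flags annotate but never reject on
their own — flagged candidates have been validated as real germline
variants, so the flags are a reviewing aid, not a filter. When both
rejection grounds apply, the reported reason is `stack_like`, the more
informative one. Per gene, at most `max_novel_per_gene` (2) candidates
are retained, ranked by support; light-chain data at moderate depth does
not support more simultaneous novel inferences per gene, and the cap
bounds the damage of a systematically noisy gene.

Genotypes (`infer_genotype()`) include every allele — known or accepted
novel — whose expression share among the gene's sequences reaches the
cutoff, at most 4 per gene. A novel variant's share is measured by its
diagnostic alternate base within the base allele's profile.

## Deletions from relative usage

`relative_usage()` computes per-individual, per-gene usage fractions for
V and J independently (ambiguous calls split fractionally). Gene usage is
strongly conserved across individuals, so an individual whose usage of a
gene collapses toward zero is a candidate for a **double chromosome
deletion**. `deletion_test()` formalises this with a one-sided binomial
tail `Pr(count ≤ X | N, P)`: `X` is the individual's (floored) sequence
count for the gene, `N` their total, and `P` the lowest usage among
individuals above the segment floor who are not themselves deleted.
Floors are 0.001 for V and 0.005 for J — J genes are few, so each J gene's
baseline usage is higher. Genes whose cohort mean usage is below the
floor are reported `unknown`: no sensible `P` exists for them (such genes
may simply be pseudogenes).

The definition of `P` ("individuals without a deletion event") is
circular on the first pass, so the test iterates once: preliminary calls
are made with `P` from all above-floor individuals, then `P` is
recomputed excluding the preliminarily deleted and the test repeated. On
every simulation tested this converges in a single round, because
deletions push usage to (near) zero, far below any plausible `P`.
P-values are Benjamini–Hochberg adjusted across all tests in the run and
calls are made at adjusted p < 0.01. The deletion is a statement about
the *expressed repertoire*; without genomic validation a repertoire
deletion need not be a locus deletion.

## Haplotypes and single-chromosome deletions

A single-chromosome deletion leaves usage almost untouched, but it is
visible in *linkage*. In an individual heterozygous at an anchor J gene
(the kappa locus reliably offers one such gene), each transcript's V
allele is linked to the anchor allele it recombined with, revealing which
chromosome it sits on. Heterozygosity requires an anchor allele ratio of
at least 30:70; chromosome 1 is defined as the one carrying the
lexicographically lower anchor allele.

For each V allele with linked counts `k1`, `k2`, the Bayes factor
compares

* single-chromosome model: `k ~ Binomial(k1 + k2, 1 − ε)` or
  `Binomial(k1 + k2, ε)` with a uniform prior over which chromosome;
* both-chromosomes model: `k ~ Binomial(k1 + k2, 0.5)`.

`BF > 1000` assigns the allele to the likelier chromosome; `1/BF > 1000`
calls it present on both; anything else is unknown. The leak rate ε
(default 0.01) represents annotation noise — reads of one chromosome
miscalled to the other's anchor allele via sequencing errors at the
anchor's diagnostic positions. ε has no published value; the package
exposes it in configuration, and a property test verifies that
assignments are unchanged over ε ∈ [0.001, 0.05]. The computation is done
in log space so that extreme counts (BF beyond 10^300) do not overflow. A
chromosome carrying no allele of a gene, when every allele of that gene
is assigned to the other chromosome above threshold, is called
single-chromosome deleted.

`allele_bias()` supports the complementary expression question: grouping
individuals by genotype at a focal gene and, within heterozygotes,
breaking allele shares down by J partner. A germline-level expression
bias shows the same skewed share across every J gene, distinguishing it
from recombination artefacts tied to a particular pairing.

## Upstream sequences and alternative splicing

Upstream sequences (5'UTR + L-PART1 + L-PART2) are extracted as the
portion of each read before the V-REGION, grouped by individual and
unambiguous allele call. All coordinates are anchored at the 3'
(V-proximal) end, because that is the one boundary every read shares.
Length classes below 5% relative frequency are removed (incomplete 5'
ends), survivors are trimmed to the shortest surviving class, and each
group is clustered by single linkage at identity 0.999 over at least half
the shorter sequence. At upstream lengths of 60–100 nt an identity of
0.999 means "identical over the overlap", which is the intent: each
sequencing-error variant falls into its own cluster and is then removed
by the cluster filters — a cluster survives only with frequency ≥ 0.01
**and** ≥ 5 sequences. This is the stricter reading of the published
filter (discard when either bound fails); the two bounds are independent
configuration knobs. Cluster consensus keeps the majority base where its
frequency reaches 0.6 and writes N otherwise; N bases never vote.
Per-individual consensus variants are collapsed across the cohort by
exact identity, and each cohort variant reports the number of individuals
and the fraction of the allele's sequences it represents (the fraction is
per-allele over the cohort, the conservative denominator).

`classify_splice()` compares each cohort variant against the gene's
genomic model. A variant is *canonical* if it equals the spliced
exon + L-PART2 junction (3'-anchored, N treated as wildcard), and
*intron_retained* if it matches the model with a prefix of the intron
inserted at the donor site; the smallest matching prefix length is
reported as `retained_len`. Retention is matched only as a donor-side
intron *prefix* — acceptor-side or internal retention is out of scope.
For retained variants the transcript is translated from the leader ATG
and the first in-frame stop codon is reported (`ptc_codon_index`); a
frame-preserving retention may have none. Variants matching neither model
are reported `unclassified` with the first mismatching position — in
simulated data these are recurrent upstream sequencing artefacts, and on
real data they would include genuine upstream polymorphisms, which this
classifier deliberately does not interpret.

## The synthetic-data generator

`simulate_study()` is first-class, tested code, not a fixture. Its
defaults define the package's reference study conditions: 20 individuals
× 5,000 transcripts over 10 V genes (~296 nt) and 5 J genes (38 nt);
5 planted novel SNPs carried by 40% of individuals (heterozygous carriers
express the variant at share 0.5, 30% of carriers are homozygous);
3 positionally fixed error hotspots at per-read rate 0.15; 2 double and
2 single chromosome deletions; one duplicated gene pair and two truncated
reference alleles; intron retention in the 2 lowest-usage genes at
probability 0.12 with a 7-base retained prefix; an anchor J gene
heterozygous in exactly 25% of individuals. The substitution error model
uses a per-base rate of 0.001 with a 3× multiplier on the A→C channel and
an extra 0.002 where the substituted base would equal both neighbours
(repeat-motif errors). These rates are typical of MiSeq 2×300 amplicon
data after pre-processing; the hotspot rate of 0.15 places artefact
stacks between the candidate floor (0.125) and the acceptance cutoff
(0.25), which is exactly the regime in which pattern classification, not
the cutoff, must do the work.

Design choices worth knowing:

* **Hotspots sit on SNP-free genes.** Hotspot positions are drawn once
  per run on genes without planted SNPs, so the per-gene candidate cap
  ranks true variants and artefacts on different genes and truth remains
  separable. With 10 genes and 5 + 3 + 2 + 2 planted roles the roles
  cannot all be disjoint; double-deletion genes may reuse SNP genes, in
  which case SNP carriers are drawn from non-deleted individuals.
* **Single-deletion carriers are anchor-heterozygous.** A single
  deletion is only observable through anchored linkage, so the generator
  forces those individuals into the heterozygous set — mirroring how such
  events are only discoverable in anchor-informative individuals.
* **Chromosome-consistent transcripts.** Each transcript picks one
  chromosome and takes both its V and J allele from it; this is what
  makes linkage informative. The expression-bias gene instead biases the
  *chromosome choice* (2:1 toward the chromosome carrying allele 01 in
  heterozygotes), producing the consistent cross-J allele bias the
  bias analysis recovers.
* **Engineered splice frame.** Leader exons are built from non-stop
  codons with a fixed junction phase, and introns start `GTAAGTA`, so a
  7-base retention reads `…TGT AAG TAA` — an in-frame TAA — while the
  canonical frame is stop-free. Truth tables record the stop's codon
  index.
* **Junctions are a fixed 6-mer linker.** Light chains lack D segments
  and none of the implemented analyses uses junction diversity; somatic
  hypermutation is modelled only as the residual load the <3-mismatch
  filter removes, since the cohort is naive.

What the generator does **not** emulate: V(D)J junction diversity and
N-nucleotides, clonal expansion, isotypes, indels, primer and amplicon
coverage biases, or PCR chimeras. Passing tests therefore demonstrate the
statistical machinery — they do not certify performance on real reads,
where the substitution-only annotator in particular is a simplification
(a documented stand-in for a full aligner).

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; user-facing variant labels
  are 1-based on the ungapped reference allele (`T31C` counts from
  position 1 of the V-REGION).
* Mismatch frequency at zero (or sub-`min_candidate_depth`) depth is
  `NA`, never 0 — absence of evidence is not evidence of germline
  identity.
* Binomial tails use `stats::pbinom`, which agrees with an explicit
  summation oracle to 10⁻¹² up to N = 10,000 (tested); Bayes factors are
  computed in log space.
* All candidate and cluster orderings have deterministic tie-breaks
  (support then position; size then lexicographic consensus), so every
  pipeline stage is reproducible run-to-run and
  permutation-invariant in its inputs.
* Reads shorter than the shortest reference V are flagged unannotated and
  excluded; empty upstream groups are dropped with a notice; a gene whose
  every individual sits below the usage floor is `unknown`, not an error.

## Problem sizes used by the test-suite

The packaged tests validate parameter recovery on the full reference
conditions (20 × 5,000 sequences; every planted SNP recovered with no
artefact false positives, all deletions called, retention recovered with
the exact retained length and PTC) and calibration on 20 null replicates
of 50 individuals × 2,100 sequences (deleted-call rate at most 0.02 at
significance 0.01). The null replicates run on generator truth
annotations with substitution noise disabled — relative usage is
invariant to substitution errors, and the property under test is the
binomial test's calibration, not the annotator. Unit tests use small
constructed instances whose expected values are computed by hand or by
independent brute-force oracles in the test code.

## Known limitations

* The annotator is substitution-only; indel alleles and heavily mutated
  repertoires need a full aligner upstream, after which all downstream
  stages apply unchanged to the resulting AIRR table.
* Deletion calls are repertoire-level statements; a gene absent from
  expression need not be absent from the genome.
* The multimodal/stack rule is one defensible formalisation of a visual
  judgement; its constants are configurable and should be revisited for
  cohorts much smaller or larger than ~100 individuals.
* Upstream variant counts are conservative: the cluster filters remove
  rare true variants along with noise, and lowly expressed genes yield
  few upstream sequences, so their variants carry low confidence.
* `cohort_fraction` for upstream variants uses the allele's total
  upstream sequences as denominator; per-individual averaging would give
  different (also defensible) numbers.
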