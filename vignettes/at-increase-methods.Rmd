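---
title: "Methods: base-composition parity and [AT]-increase in allopolyploid subgenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-composition parity and [AT]-increase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical machinery behind `atshift`, the
choices that were genuinely open when the package was designed, and what the
synthetic-data checks do — and do not — establish about real data.

## The quantities

**[AT] value.** For sequence, the fraction of counted bases that are A or T,
with `N` reported but excluded from the denominator. For polymorphic sites,
a dosage-weighted analogue per accession: at each non-missing bi-allelic
SNP an accession contributes weight 1 to its homozygous base, or 0.5 to the
reference and 0.5 to the alternate base when heterozygous; missing calls
contribute nothing and shrink the denominator. Weights conserve mass — the
four base sums add up to the number of non-missing sites — which the test
suite asserts as an invariant, along with invariance under ref/alt label
swaps (dosage `d -> 1 - d`).

**PR2 deviation.** `dAT = [A] - [T]`, `dCG = [C] - [G]`, signed, over the
four unambiguous bases of a single strand. Under a strand-symmetric mutation
process both vanish; an i.i.d. simulated genome at 5 Mb keeps both below
0.005 with large margin (binomial bound).

**Shuffling test.** To compare the [AT] of two base pools, each side is
bootstrapped: `n_iter` multinomial draws of `sample_size` bases from the
pool's base composition, [AT] computed per replicate, and the two replicate
sets compared by a two-sample t-test. The resampling unit was an open
choice — the procedure that inspired it says only "random shuffling" — and
we chose a multinomial bootstrap with replacement, seedable and
config-capped in size (a 3.6-Gb pool is resampled at a configurable
`sample_size`, not in full). The equal-variance (pooled) t-test is the
default, matching an "independent-sample t test"; Welch is a flag. When both
replicate sets are degenerate (zero variance), the p-value is defined as 1
for equal means and 0 otherwise.

## Group comparisons: Duncan's multiple range test

Groups are ranked by mean; a span of `p` ranked means is declared
non-significant when its range falls below
`qtukey(1 - alpha_p, p, df) * sqrt(MSE / n_h)` with the protection level
`alpha_p = 1 - (1 - alpha)^(p - 1)`, and a non-significant span protects all
of its sub-spans. Unequal group sizes use the harmonic mean of the pair.
Letters are maximal non-significant runs. Ties in group means are broken by
group name, so letter assignment is deterministic. With `MSE = 0`, any
nonzero range is significant.

Two structural facts are worth recording because they affect acceptance
checks elsewhere:

- By construction, Duncan's familywise error for three equal groups under
  the null is `1 - (1 - alpha)^2 = 9.75%` at `alpha = 0.05`: the widest span
  is tested at `alpha_3`, so three null groups share a single letter in
  ~90.25% of datasets, not 95%. A procedure that reached 95% here would be
  Student–Newman–Keuls (constant per-span alpha), not Duncan.
- The replicate unit matters. Per-accession [AT] values computed on a
  *common* site set share that set's sampling noise across accessions, so a
  between-subgenome Duncan test over accessions treats a chance site-draw
  difference as real group separation. For subgenome-level contrasts the
  package's checks use chromosomal-window [AT]-differences as replicates —
  the same unit the window-track figures use — which supplies a genuine
  between-window error term.

## Sliding windows and region strata

Windows default to a 2-Mb span sliding by 1 Mb; a window's group value is
the mean of per-accession [AT] values over the sites inside it (the
per-accession rule applied locally — whether to pool alleles instead was an
open question; the per-accession mean is consistent with the violin-plot
convention). Windows or strata with fewer than `min_sites = 10` sites are
flagged missing rather than reported (the source analysis likewise skipped
a 6-SNP sweep); trailing partial windows are kept if they clear the
threshold. Window differences are reported on both scales because published
figures use both: `delta` (absolute difference of [AT] fractions — the scale
of the 0 and 0.1 boundaries) and `delta_rel` (relative change).

## Functional annotation

The classifier assigns exactly one of seven classes per SNP. Inside CDS the
ref and alt codons are translated (strand-aware, standard nuclear code):
same amino acid → synonymous, different → missense; start-codon changes,
stop gain/loss and splice-region hits (first/last 2 bp of an intron) fold
into `other_genic`, keeping the seven-set scheme. Then UTR, intron,
gene-proximal (within 5 kb of a gene — the distance the reference annotation
tool uses by default; configurable) and intergenic. Across multiple
transcripts the most severe effect wins, with severity
`missense > synonymous > other_genic > utr > intronic` (fixed here; the
source is silent). Transcripts whose CDS length is not divisible by three,
or whose first phase is nonzero, are skipped with a warning. Equal-size
subsampling (`subsample_equal`) removes set-size confounding when comparing
[AT] between annotation sets.

## Mutation spectrum

Bi-allelic SNPs are typed by their unordered base pair (6 types) and by the
tri-nucleotide motif 5'-XNY-3' built from the reference-strand flanking
bases (96 motifs). Sites at contig edges or with an `N` flank are excluded
from motif denominators but kept for type-level statistics (an open
question; exclusion chosen). High-frequency tiers use a strict `>` against
`factor × 1/96`. `revcomp_motif()` is an involution; its fixed points exist
only for A/T and C/G types with reverse-complement-palindromic flanks, which
the suite asserts by enumeration.

## Private variants and derived rates

A site is private to the focal group when it is polymorphic there and every
non-missing reference-panel call is the same homozygous allele
(heterozygous or conflicting reference calls disqualify — strict fixity;
the source says only "not variable"), with reference missingness ≤ 0.2
among the progenitor accessions that actually carry the site's subgenome.
The derived rate is per-accession: derived-allele dosage summed over
qualifying sites divided by the accession's non-missing qualifying sites,
then averaged within groups (the exact averaging in the source is
unstated; this labeling is explicit).

One property deserves emphasis: private-site rate estimates are
*ascertainment-biased upward* when the focal sample is small, because a
private site requires at least one sampled focal carrier, truncating the
low-frequency tail of the site-frequency distribution. At 30 focal
accessions the bias is about +0.01 on a true mean of 0.15 in our generator;
at 90 focal accessions it is below 0.002. Recovery checks therefore
condition recall on planted mutations that actually segregate in the
sampled cohort — unsampled variation is unrecallable by any method.

## The [AT] value as a genome phenotype

- **LD pruning**: within each 50-SNP window, the later member of any pair
  with r² > 0.3 is dropped, and the window slides by 50 — deterministic and
  idempotent on its own output.
- **Kinship**: frequency-standardized cross-products of mean-imputed,
  centered dosages averaged over markers (VanRaden form on the
  allele-fraction scale).
- **LMM scan**: `y = mu + x*beta + g + e`, `g ~ N(0, sg2*K)`,
  `e ~ N(0, se2*I)`. K is eigendecomposed once; the variance ratio
  `delta = se2/sg2` is estimated by REML under the null on a log-spaced grid
  (61 points over 1e-5..1e5) with local refinement by `optimize`, then
  reused for every marker (the single-variance-ratio fast path of the
  reference program). Markers are tested by a Wald t-test in the rotated
  model with `df = n - 2`; missing dosages are mean-imputed per site;
  markers with singular designs are skipped. With `K = I` the weights are
  constant and the scan reduces *exactly* to OLS marker regression, which
  the suite asserts to 1e-8. Negative kinship eigenvalues beyond -1e-8
  trigger a warning and are clipped to zero.
- **Thresholds**: significance at −log10 p ≥ 6 as printed in the source
  (not recomputed from the marker count); markers within 5 Mb merge into
  one locus (the grouping distance is not stated in the source). Candidate
  intervals span all same-chromosome SNPs with r² > 0.6 to the peak. PC
  sign is arbitrary, so the PC1 correlation reports `|r|` (a signed value
  with a fixed orientation rule is also returned).
- **Expression filter**: TPM strictly greater than 1 in every listed
  tissue; genes missing from the table count as unexpressed, with a
  warning.

## The synthetic-data generator

`simulate_population()` is a two-stratum site-frequency generator, not a
coalescent: the statistics this pipeline measures are site-wise, so
haplotype structure beyond window-level LD is unnecessary and the
generator runs in seconds.

- **References**: i.i.d. bases at GC = 0.46 per chromosome (six 2-Mb
  chromosomes, 1A/2A/1B/2B/1D/2D, by default). Gene models (20 genes/Mb)
  are written into the sequence: ATG start, sense codons, stop, UTRs,
  introns, both strands, ≥10 kb intergenic spacing, so the annotation
  classifier can be validated against construction truth.
- **Groups**: the six canonical groups at the published panel sizes
  (20 wild emmer, 5 durum, 5 *Ae. tauschii*, 15 + 14 landraces,
  34 varieties); wild emmer and durum carry A+B, *Ae. tauschii* carries D,
  the hexaploid groups carry all three. Genotypes are drawn under partial
  selfing (inbreeding F = 0.95, so heterozygotes are rare but present) with
  2% missing calls; the draw preserves the allele frequency exactly in
  expectation.
- **Standing variation** (850 SNPs/Mb): shared wild/domesticated
  polymorphism, symmetric baseline spectrum, frequencies Beta(0.8, 0.8)
  rescaled to [0.1, 0.9] (shared ancestral polymorphism bounded away from
  fixation), lineage drift (Beta concentration 30), per-group jitter (60),
  and a bottleneck that fixes 10% of standing variants in the domesticated
  lineage.
- **New variation** (400 SNPs/Mb × subgenome multiplier, default
  D = 1.5): present only in the hexaploid groups. Positions are sampled
  proportionally to donor mutability and flank context; the derived allele
  is drawn from baseline type weights times a GC→AT bias (3) and a ×5
  hotspot multiplier for C→T at the five high-frequency C/T contexts
  (G→A at their reverse complements). The baseline type weights
  (A/G = C/T = 0.25, A/C = G/T = 0.12, A/T = 0.09, C/G = 0.08) are set
  *below* the observed wheat type frequencies deliberately: observed
  frequencies already include hotspot enrichment, and with the hotspots
  applied the realized A/G and C/T frequencies land near the observed
  ~35%. The rate multiplier scales both the new-variant count and the mean
  derived-allele frequency (default base 0.15) — a faster clock yields
  more, and on average older, private mutations — so both the window
  [AT]-gap and the private-variant derived rate respond monotonically to
  it, which the suite checks across multipliers.
- **Sweeps** (3 per chromosome, 100 kb, 30 extra SNPs each): clustered,
  strongly AT-biased swept variants at high domesticated frequency
  (mean 0.6), elevating [AT] inside sweep intervals.
- **Truth ledger**: every emitted VCF record has a ledger row (stratum,
  donor/derived, motif, planted frequencies); the hotspot motif set and any
  causal-marker plan ride along as attributes. An optional causal plan
  makes the [AT] phenotype heritable by letting standing-marker dosages
  scale each accession's new-variant carriage probability.

**What the generator does not emulate**: realistic recombination maps and
haplotype blocks, gene conversion and homoeologous exchange, demographic
detail beyond a one-step bottleneck, alignment/calling artifacts, and the
real wheat annotation's class proportions (intergenic fractions near 93%
require real intergenic space). Passing the synthetic checks therefore
demonstrates that the *statistics are implemented correctly and recover
planted signals under the stated model* — not that the biological
conclusions transfer to any particular real dataset.

## Problem sizes and numerical choices in the checks

The default cohort (93 accessions, ~16k SNPs over 12 Mb) simulates in about
two seconds, so the recovery sweeps run 50 replicate cohorts each. The
private-variant recovery cohort uses 30 accessions per group and ~5,000
planted new mutations per subgenome at derived fractions 0.15/0.15/0.20;
LMM calibration uses 100 null cohorts of 60 accessions × 500 markers and a
planted marker explaining 30% of variance (the remaining variance split
45% kinship-structured, 25% i.i.d. — the regime in which a mixed-model
power statement is meaningful). Oracle-equivalence checks (base counts,
composition, windows, motifs, filtering, Duncan letters) run ≥50 random
instances against independent brute-force implementations. The whole suite
is sized for a single CPU.
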