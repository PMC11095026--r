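---
title: "Modeling reduced metagenome sequencing: digestion, size selection, and ratio-based quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reduced metagenome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsim)
```

# The problem

Reduced metagenome sequencing (RMS) applies ddRADseq-style library
preparation to a mixed community: restriction enzymes fragment every
genome at their recognition sites, a size-selection step keeps fragments
in a narrow length window, and the survivors are sequenced as paired-end
short reads. Two properties make the resulting data awkward for standard
profiling tools. First, each genome yields its *own* irregular
fragment-length distribution, determined by where its recognition sites
happen to fall. Second, size selection and sequencing impose a shared,
length-dependent acceptance on all fragments. The read count a taxon
receives is therefore a convolution of its abundance, its digest profile,
and the selection envelope — total mapped reads are *not* proportional to
abundance.

`rmsim` models the forward process (genomes + abundances + enzymes →
reads) and provides two inverse estimators: enzyme cut efficiency from
observed fragment-count ratios, and relative taxonomic abundance by fixed
length taxonomic ratios (FLTR).

# Digestion model

Cut sites are located by an overlap-tolerant scan: every offset at which
the IUPAC-degenerate recognition sequence matches contributes a cut,
including overlapping occurrences (e.g. `GCGC` matches `GCGCGC` at
offsets 0 and 2). Non-palindromic motifs are additionally scanned as
their reverse complement. An `N` in the genome never satisfies a motif
position: a site interrupted by assembly ambiguity is conservatively
treated as absent rather than risking phantom fragments.

Digestion is partial. With per-site cut efficiency $c \in (0, 1]$ — the
probability that an enzyme actually cleaves a given site during the
reaction — a candidate fragment requires both of its boundary sites cut
and all $i$ sites strictly inside it uncut:

$$\Pr(\text{fragment}) = \begin{cases}
1 & c = 1,\ i = 0\\
c^2 (1-c)^i & \text{otherwise.}
\end{cases}$$

Summing probabilities by length gives the expected per-copy digest
distribution $D_g(x)$ for genome $g$.

Modeling choices worth stating explicitly:

* **Coordinates** are 0-based half-open everywhere; a cut at position $k$
  falls between bases $k-1$ and $k$. Only top-strand cut geometry is
  tracked — the few-bp sticky-end overhang does not affect read-level
  quantification, and single-coordinate cuts keep every downstream
  operation exactly testable.
* **Enumeration bounds.** Candidate fragments are only enumerated inside
  a length window (default: the size-selection mean $\pm 6\sigma$) and up
  to `max_internal = 5` internal sites. Deeper partials survive with
  probability at most $c^2(1-c)^6$ and are negligible at any realistic
  $c$; the window bound mirrors the fact that fragments far outside the
  envelope can never be selected.
* **Terminal fragments** (contig start/end to the first/last cut) are
  excluded: they lack one enzyme-generated end and cannot receive both
  adapters. Contigs of multi-contig assemblies are digested independently
  as linear molecules.
* **One global $c$** is shared by all enzymes in the panel, matching the
  single user-set efficiency of the modeled protocol. The probability
  model is stated for palindromic motifs; we apply the same formula to
  non-palindromic motifs as a documented extension (per-strand site
  occupancy is not modeled separately).
* **Type IIB (isolength) enzymes** (e.g. BcgI, `CGANNNNNNTGC` with
  12 bp flanks) excise the recognition site plus fixed flanks, so all
  fragments share one length; each excision needs its two flanking cuts,
  giving survival $c^2$ with $i = 0$. Overlapping excisions are emitted
  independently — per-site independence, no collision resolution.

# Size selection and read allocation

Per-genome digests are scaled by **genome-copy abundance** (the abundance
table is copy proportions, not target read fractions) and pooled into
$D(x)$. Physical size selection is modeled as the intersection of $D$
with a Gaussian envelope anchored to it:

$$S(x) = \min\!\big(D(x),\ k\,\varphi(x;\mu,\sigma)\big), \qquad
k = \frac{D(a)}{\varphi(a;\mu,\sigma)}$$

with anchor $a = \operatorname{round}(\mu - \sigma)$ by default (falling
back to the nearest supported length). The pointwise minimum is the only
reading of "intersection" that both respects the envelope shape and never
inflates a length beyond what the digest supplies; anchoring one standard
deviation below the mean pins the envelope to the rising flank of the
digest, where selection equipment is calibrated in the narrow-selection
regime. The anchor is a parameter because the protocol itself does not
fix it. A custom length-weight table (JSON, `{"length": weight}`) can
replace $\varphi$ — typically the observed distribution of a real run,
re-exported by `extractLengthDistribution()`.

The read budget $n$ is distributed over fragments with probability
proportional to $w_f \cdot S(x_f)/D(x_f)$, where $w_f = p_f \cdot
a_{g(f)}$ is the abundance-scaled survival weight. "Dividing the input
read number amongst the size-selected distribution" is implemented as
proportional allocation normalized to exactly $n$: equal-per-fragment
division would erase the abundance signal that quantification is meant to
recover. Two rounding modes exist — seeded multinomial (stochastic
default) and largest-remainder (deterministic, used where tests need
exact counts). Both conserve $\sum \text{reads} = n$ exactly; ties in
largest-remainder rounding go to the earliest fragment in input order.
Gaussian densities are evaluated at integer lengths without continuity
correction — only density *ratios* within the support matter, and these
are insensitive to the correction at $\sigma \gtrsim 10$ bp.

# Read synthesis and the error model

Read 1 is the first `read_length` bases of (oriented insert + R1
adapter); read 2 of (reverse-complemented insert + R2 adapter). Inserts
shorter than the read length thus show authentic adapter read-through;
any residual shortfall is padded with `A`, chosen to be deterministic and
visibly artificial. For double-digest fragments read 1 starts at the
forward-enzyme end (adapter asymmetry of ddRAD chemistry); same-enzyme
fragments orient uniformly at random. Base qualities are sampled
uniformly from a donor FASTQ's quality strings (a synthetic donor
generator is included); each base is then substituted with probability
$10^{-Q/10}$, uniformly among the three other bases. Substitution is the
whole error model — no indels, chimeras, or tile effects. FASTQ headers
carry the source fragment (`genome:contig:start:end:orientation:serial`),
so downstream evaluation never depends on an aligner.

# Cut-efficiency estimation

Under the survival model, a fully digested fragment ($i=0$) occurs
$c^2$-proportionally and the partial fragment extending one cut past
either end ($i=1$) occurs $c^2(1-c)$-proportionally, so their count ratio
is $r = 1/(1-c)$ and

$$c = \frac{r - 1}{r}, \qquad 1 < r < \infty,$$

with $c = 1$ declared when no encompassing fragment is observed at all
(complete digestion). Pairs are restricted to inner fragments of
100–450 bp — the window least distorted by size selection — and to inner
counts of at least 5 reads (ratio stability); both are parameters. Many
pairs are aggregated by the **median** ratio before applying the formula:
the protocol description leaves the statistic open, and the median is
robust to the low-count outer fragments that dominate the ratio noise
(mean aggregation is available). Pairs whose outer count is zero are
treated as absent — evidence toward complete digestion — rather than as
infinite ratios.

# FLTR quantification

Fragments are first *recreated* from read pairs (provenance headers, or
SAM alignments where proper pairing and a MAPQ > 0 filter against
multi-mapping are enforced). Both endpoints must coincide exactly with
expected cut positions, and any fragment spanning an expected cut site is
discarded: partial fragments distort per-locus depth unpredictably and
are rare in practice.

For taxon $t$ and length $L$, the depth $d(t, L)$ is the total read count
of $t$'s kept fragments of length $L$ divided by the number of $t$'s
*distinct expected* fully digested fragments of that length — expected
fragments with zero reads stay in the denominator. This per-distinct-
fragment mean is the reading under which the between-taxon ratio at a
fixed length is proportional to abundance even when taxa differ in
fragment multiplicity; a per-length-total denominator would not be.

Within each length, ratios $d(t_i, L)/d(t_j, L)$ are computed for all
taxon pairs present, then averaged (unweighted) over lengths into the
ratio matrix $R$. Each column $j$ with a defined reference entry
$R[k, j]$ is divided by it, where $k$ is the taxon with the most defined
relationships (ties to earliest input order); the row average of the
scaled matrix, normalized to sum to one, is the abundance estimate. This
column-scaling reading of "scaled to the taxon with the greatest number
of relationships" makes recovery provably exact: whenever depths factor
as $d(t, L) = a_t\, s(L)$ for an arbitrary shared length bias $s$, every
scaled entry in row $i$ equals $a_i / a_k$. Unweighted averaging keeps
that exactness; a depth-weighted variant is deliberately not the default.

Taxa whose scaled row has no defined entry — i.e. taxa not reachable from
the reference within the direct-plus-one-hop relationships the scaled
matrix encodes — are reported as *unquantified* rather than imputed
through longer ratio paths; the remaining estimates are renormalized.
Mean- and median-depth baselines (per-taxon summaries over distinct
expected fragments) are computed alongside for comparison; they are
exactly the estimators that a shared length bias misleads.

# Synthetic data

All test inputs are generated in code. Genomes are i.i.d. base strings
at a target GC content; optionally, concrete motif instances are planted
at fixed spacings and all accidental occurrences of the planted motifs
are scrubbed by point mutation, so expected cut positions and fragment
lengths are known in closed form. Communities draw uniform or log-normal
(default $\sigma_{\log} = 1$, a realistic several-fold spread)
genome-copy abundances. Donor quality files use per-position Gaussian
Phred scores clamped to $[0, 41]$.

What the generator deliberately does *not* emulate: real genomic
composition (k-mer structure, GC skew along the chromosome, repeats),
shared sequence between related taxa (every synthetic genome is unique,
so multi-mapping ambiguity is absent outside SAM mode), PCR amplification
bias (discussed in the field but given no quantitative model here), and
allelic dropout from site-destroying mutations. Passing tests therefore
demonstrate correctness of the *model implementation* and the estimators'
behavior under the model's own assumptions — not performance on real
communities, where reference error, conserved fragments, and
amplification bias add distortions the simulation does not contain.

# Test and benchmark scales

The oracle-equivalence checks run 50 random genomes of 1–5 kb against a
brute-force per-offset scanner and all-pairs fragment enumerator. Error
calibration uses $10^6$ bases per quality level against the binomial
3-sigma band. Cut-efficiency recovery uses ~200-cut chains: exact on
noise-free model counts at $c \in \{0.5, 0.8, 0.95\}$, within $\pm 0.03$
on Poisson-sampled counts with $\geq 200$ pairs. The end-to-end check
simulates 10 genomes of 100 kb with EcoRI+MseI at $c = 0.9$,
$\mu = 150$, $\sigma = 50$ and $2 \times 10^5$ read pairs, then requires
Pearson $\geq 0.95$ between FLTR estimates and the true log-normal
abundances. These sizes were chosen as the smallest scales at which each
property is sharply distinguishable from noise.

# Known limitations

* Circular chromosomes are digested as linear (the two terminal pieces
  are dropped rather than joined).
* Methylation sensitivity, nicking, and star activity are out of scope.
* FLTR assumes the length bias is shared across taxa at each length
  (no strong per-taxon GC × length interaction) and quantifies only taxa
  connected to the reference taxon through co-occurring lengths.
* The SAM path trusts the aligner's proper-pair flags; it deduplicates
  nothing beyond the MAPQ-0 filter.
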