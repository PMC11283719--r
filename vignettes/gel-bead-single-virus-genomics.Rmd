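---
title: "Models and methods behind virosag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind virosag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virosag)
```

`virosag` simulates a gel-bead single-virus genomics experiment and
implements the downstream analysis that turns per-bead sequencing data into
viral single-amplified genomes (vSAGs) and their comparative genomics. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic data does and does not capture.

## The platform model

A viral suspension is mixed 1:1 with molten agarose and emulsified into
~30 µm beads, so each bead receives a Poisson-distributed number of
particles. After in-bead lysis and multiple displacement amplification
(MDA), beads with amplified DNA fluoresce, are sorted, and are sequenced
individually. The package models this chain stage by stage.

**Encapsulation.** Per-bead particle counts are Poisson(λ); particle
identities are i.i.d. draws from the community's relative abundances
(`encapsulate()`). The observable is the positive rate
p = 1 − e^(−λ), inverted by `estimate_mean_loading()`. Concentration
follows as λ/V_bead × dilution factor, with V_bead = (π/6)d³ (d = 30 µm
default, i.e. 1.41e−8 mL) and a default dilution factor of 2 for the 1:1
agarose mix. The platform's operating rule — dilute when p exceeds 20%,
strictly — is `dilution_decision()`, which also reports the implied
co-encapsulation risk P(k ≥ 2 | k ≥ 1) = 1 − λe^(−λ)/(1 − e^(−λ)).

**Amplification bias.** MDA coverage is famously uneven. Per-base depth is
modelled as a lognormal random field: lognormal(0, σ) values at knots every
2 kb, linearly interpolated (correlation length ~2 kb), scaled by a mean
depth, with 1 kb windows zeroed independently at a dropout probability.
σ = 0 with zero dropout gives perfectly uniform depth (Gini 0); the default
σ ≈ 1–1.2 with 5% dropout produces Gini values in the 0.3–0.6 range and
breadths around 90%, the regime reported for phi29 amplification of viral
genomes. ssDNA genomes take a yield multiplier (default 1; the chemistry is
not modelled further). A bead is "positive" when total amplified yield
exceeds a threshold, default 0 — any amplification detected. The
fluorescence chemistry itself is not modelled; the threshold is the free
parameter that stands in for it.

**Assembly surrogate.** Real per-bead assembly is out of scope; what the
decision logic downstream needs is that each bead yields fragmented contigs
whose breakpoints follow amplification dropout. `fragment_to_contigs()`
emits the maximal intervals with depth above a floor, at least 1 kb long,
with ground-truth provenance recorded (and hidden from analysis). Contig
totals can therefore never exceed the loaded genome length, and higher
dropout monotonically fragments the recovery — both are tested properties.

## The synthetic community

`generate_community()` draws genome lengths from a lognormal (default
median 40 kb, log-sd 0.6, truncated to 1–300 kb, matching the size range of
environmental dsDNA phages), assigns relative abundances by a discrete
power law p_i ∝ i^(−slope) over rank (slope 1.5 by default), and marks a
fraction ssDNA. The true abundance distribution of river-water viromes is
unknown; the power law is a stand-in and is exposed as a parameter.

Genes are planted from a shared pool of orthologous groups (OGs). Every OG
owns a canonical ORF; each genome carries a copy that is (i) synonymously
shuffled at 60% of codons and (ii) non-synonymously mutated at 5% of
codons. The split matters: synonymous shuffling decays *nucleotide*
identity between genomes that share an OG (unrelated species do not share
near-identical nucleotide genes, and the ANI machinery must not be confused
by them) while the *protein* family stays recognisable for clustering. OGs
are drawn without replacement within a genome, so genomes carry no
near-identical paralogs. Genes are placed with exponential inter-gene gaps
calibrated to one gene per kb, tile ≈85–90% of the genome, and are real
ORFs (ATG…stop, no internal stops), so the ORF caller can be scored against
them. AMG status and the auxiliary score (1–5; 1–3 means confident) are
properties of the OG; roughly 10% of pool OGs are AMGs.

**Strains.** `spawn_strains()` derives near-identical strains: point
substitutions only *outside* core genes (so conserved markers like the
terminase large subunit remain identical across strains, as observed within
a viral species), plus insertion of a strain-specific subset of flexible
gene cassettes — MTase subtypes by default — at inter-gene positions
flanked by core genes. At the default snv rate of 0.005 all strain pairs
stay above 99% ANI, comfortably one species under the ANI ≥ 95 / AF ≥ 85
criterion. The host background genome is 1 Mb-scale random sequence with a
GC offset of 0.15 from the viral mean; below ~0.10 the tetranucleotide
signatures of host and virus are no longer separable, which is why the
default sits above that.

## vSAG construction

Per bead: contigs are scored for virality (fraction of length covered by
viral genes — ground truth in simulation, a pluggable scorer on real data;
keep at score ≥ 0.3), then binned by single-linkage clustering of
d(i,j) = w_tnf·‖tnf_i − tnf_j‖₂ + w_ab·|log(a_i/a_j)|, with w_tnf = 1,
w_ab = 0.5 and a cut height of 0.3 calibrated on simulated fixtures: contigs
of one genome differ by ≲0.1 (TNF noise at 1–10 kb, identical pooled
abundance), while a 5-fold abundance ratio alone contributes 0.8. Bins
under 10 kb are discarded. Bins are concatenated with 100-bp poly-N linkers
(any N-run ≥ 10 decodes as a linker); completeness is
100·min(1, ungapped length / expected length), the expected length being
the true source-genome length in simulation or a user-supplied length class
on real data — a deliberate surrogate for marker-based completeness, which
would require reference HMMs. Tiers follow the high ≥ 90% / medium ≥ 50%
convention. The bin with the highest completeness (> 0%, strictly) becomes
the vSAG; ties break to the larger bin, then lexicographic id; all other
bins are recorded as excluded. Beads under 5 000 read pairs are reported
separately as small-data.

## Clustering layers

**ANI/AF.** `compute_ani_af()` cuts the query into 1 kb fragments, seeds
each on the subject (both strands) by exact 15-mers at four offsets, ranks
candidate placements by seed votes, and scores the best placement by direct
positional comparison; only when direct identity falls below 98% does it
fall back to a local alignment (match 1, mismatch −2, gap open 10, extend
1) around the best candidate. The stiff mismatch penalty stops alignments
from extending across non-homologous stretches (e.g. a cassette present in
one strain only); the vote ranking stops fragments from latching onto a
shared gene at the wrong locus. ANI is the weighted mean identity of
aligned fragments; AF divides aligned length by the *shorter* sequence, the
convention that lets a partial genome cluster with its full-length species
representative. Fragments below 50% identity are discarded as spurious.
All-vs-all tables use a 13-mer Jaccard prefilter (≥ 0.005);
`cluster_votus_greedy()` computes ANI lazily against current centroids
after sorting by completeness then length — the deterministic greedy
ordering makes results invariant to input shuffling.

**PCs.** Proteins come from a six-frame ORF scan (start codons ATG/GTG/TTG,
≥ 60 aa, longest-first greedy selection tolerating ≤ 45 bp overlaps —
gene starts commonly overlap neighbours by a few codons, and strictly
disjoint selection measurably loses true genes to the few-codon upstream
extensions of their neighbours). The similarity graph uses amino-acid 4-mer
Jaccard with an edge threshold of 0.3: under the generator's divergence
model, within-family Jaccard concentrates around 0.5 (minimum ~0.35) and
between-family values stay below ~0.02, so 0.5 would sit exactly on the
within-family median and fragment true families, while 0.3 separates the
two distributions cleanly. Markov clustering (expansion 2, inflation 2,
pruning 1e−5, ≤ 100 iterations, convergence at 1e−8) runs per connected
component. Self-loops are set to each node's strongest incident edge
weight, not 1: with −log10-p edge weights of order 10, unit loops make
two-node cliques collapse into singletons under inflation.

**VCs.** Genome pairs sharing at least one PC get an edge weighted by
−log10 of the hypergeometric upper-tail probability of sharing that many
PCs given their repertoires and the PC universe; edges below weight 1
(p > 0.1) are dropped, genomes with fewer than two PCs are outliers, and
MCL on the weighted graph yields disjoint VCs (an overlapping-cluster
variant would count shared PCs differently — a declared simplification).
Representatives are the members with the highest completeness, ties to the
longer genome.

## Annotation statistics

Taxonomy voting requires strictly more than 30% of proteins to have a
reference hit and assigns each rank top-down when strictly more than 50% of
hit proteins agree, stopping at the first rank without a majority. Marker
taxonomy keeps hits with score ≥ 40 (inclusive) and E ≤ 1e−5 and truncates
to the longest common lineage prefix. The AMG-vs-VC-sharing test builds the
2×2 table {multi-VC, single-VC} × {AMG, not} and computes the two-sided
Fisher p by exact enumeration of the hypergeometric support (probabilities
≤ the observed one, with a 1e−7 relative guard against ties lost to
floating point); degenerate margins return p = 1 with a flag, and odds
ratios take the Haldane +0.5 correction when a cell is zero. Recruitment
curves filter alignments at identity ≥ 50, query coverage strictly over 80,
E ≤ 1e−5, then smooth recruited identities with a Gaussian kernel of
bandwidth 0.5 × their SD (0.1 when the SD is 0), normalised so the curve
integrates to 100%.

Within a vOTU, the OG matrix marks an OG core iff present in every member;
everything else is flexible. Insertion detection reports maximal runs of
flexible-OG genes bounded by core OGs (a flank must additionally be present
in at least half the members); a member missing a flank yields a partial
event. One consequence worth stating: a flexible cassette that by chance
lands in *every* member is operationally core — no member exists to reveal
the insertion — so such cases are undetectable in principle, and recall
statements exclude them.

## What the simulation does and does not show

The generator reproduces the statistical structure the analysis relies on:
Poisson loading, uneven MDA coverage with dropout, per-bead fragmentation,
compositional (TNF) and abundance signals for binning, shared protein
families, species-level strain groups with core/flexible architecture, and
host-DNA background. It does **not** model real phage synteny, codon usage,
chimera formation, primer artifacts, sequencing-quality profiles, assembly
errors, or homology-search sensitivity; OGs are label-based ground truth,
not evolved protein families, and real-data mode therefore consumes
external tools' tabular outputs (mapping counts, annotation hits) rather
than re-implementing search. Passing tests show the *decision logic* is
correct under the stated statistical assumptions — not that any upstream
aligner or assembler is.

Problem sizes in the test-suite and acceptance script — communities of
4–30 genomes, 60–500 beads, 10^5 beads for the Poisson round trip, 20-seed
replicates for property checks — were chosen as the smallest sizes at which
the checked statistics are stable; all randomness flows from explicit
seeds, and identical seeds reproduce byte-identical outputs.

## Known limitations

* Completeness is length-based; circular permutations or large repeats
  would confuse it, and real CheckV-style marker completeness behaves
  differently on highly incomplete bins.
* The binning distance is a two-term simplification; it ignores coverage
  covariance across samples that real binners exploit.
* vOTU clustering is greedy; borderline pairs (ANI ≈ 95) can split
  depending on centroid order, which the deterministic sort makes
  reproducible but not order-free in the mathematical sense.
* Chimeric vSAGs from co-encapsulated beads that binning fails to separate
  can bridge two species into one vOTU — the same failure mode the real
  platform dilutes to avoid.
* Concentration estimates inherit the bead-volume and dilution-factor
  constants; conversions to pfu/µg would need packaging-efficiency inputs
  that are exposed as parameters rather than assumed.
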