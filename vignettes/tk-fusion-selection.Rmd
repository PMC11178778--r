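---
title: "How oncogenic kinase fusions are selected: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How oncogenic kinase fusions are selected: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkfusions)
```

## The problem

Tyrosine-kinase (TK) fusions such as EML4-ALK arise when a chromosomal
translocation joins the 5' portion of a partner gene to the intact
kinase domain of a TK gene. Clinically observed fusions are strikingly
stereotyped — a recurrent kinase intron, a short list of partners, a
preferred partner exon — yet genome-wide junction sequencing shows
that double-strand breaks rejoin all over the genome. `tkfusions`
implements the computational side of an experimental design that
explains the gap: junctions are cloned from a fixed bait DSB in a
kinase intron (high-throughput genome-wide translocation sequencing,
HTGTS), both *before* any selective pressure and *after* functional
selection in which only cells driven by an oncogenic fusion survive.
Comparing the two landscapes, and annotating each junction with the
determinants of fusion productivity, shows which rearrangements the
selection keeps and why.

The package provides five analysis stages, each usable on its own:

1. **Junction calling** (`call_junctions`) — the filter cascade that
   turns raw alignment records into clean junctions.
2. **Hotspot detection** (`call_islands`, `refine_hotspots`,
   `merge_by_gene`) — island clustering against a Poisson background
   with local-enrichment refinement.
3. **Strand-bias scoring** (`strand_bias`) — a binary-entropy
   statistic of the plus-strand junction fraction.
4. **Fusion annotation** (`classify_fusions`) — orientation, reading
   frame, partner transcription and protein stability.
5. **Landscape summaries** (`partner_frequency`, `partner_sharing`,
   `exon_usage`, `hotspot_partner_overlap`) — the COSMIC-style
   tallies used to describe fusion recurrence.

A synthetic-data module (`simulate_genome`,
`simulate_pre_selection`, `apply_selection`, `emit_alignment_table`,
`simulate_cosmic_table`) generates all inputs with known ground
truth; the `analysis/` scripts in the repository run the stages end
to end on it.

## Junction calling

Raw records carry BLAT-style alignment statistics. The score is
`matches − mismatches − gap_opens`; the cascade applies, in a fixed
order, filters whose thresholds are the standard HTGTS choices:

| filter | rule | default |
|---|---|---|
| primer anchor | read must begin with bait primer + 5 bases | flag |
| score | drop `score < min_score` | 30 |
| ambiguity | drop multi-aligned reads with best−second `< 4` | 4 |
| gap | drop alignments with a gap `>= 10` nt | 10 nt |
| PCR repeats | same junction, read starts `< 3` bp apart collapse | 3 bp |
| ligation artifacts | junction at a HaeIII blunt-cut position | exact |

Boundary semantics are strict as stated: score 30 is kept, score
difference 4 is kept, a 9-nt gap is kept, read starts exactly 3 bp
apart are distinct molecules. The junction position is the genomic
base matching the 5'-most aligned base of the read: `aln_start` on
the plus strand, `aln_end − 1` on the minus strand. This convention
also fixes which genomic side of the breakpoint is retained in the
rearranged allele (right for plus, left for minus), which is what
orientation classification consumes. Whether the minus-strand 5' end
maps to the higher coordinate is a convention, not a fact about the
assay; it is isolated in `call_junction` and tested for internal
consistency (emission followed by calling round-trips exactly).

PCR-repeat collapsing clusters records greedily in ascending
`read_start` order; a record joins the open cluster while it is
within 3 bp of the cluster anchor. The *anchor* (smallest
`read_start`; ties broken by `read_id`) survives. Keeping the anchor
rather than an arbitrary member makes the operation idempotent —
surviving read starts are always at least the window apart, so a
second pass changes nothing — which we consider a requirement for a
deduplication step. HaeIII-artifact removal is exact-position by
default; `filter_params(haeiii_window = w)` relaxes it to ±w bp for
noisy position assignment.

## Hotspot detection

Candidate hotspots are called per chromosome with a SICER-style
island model at the standard human parameters: window 500 bp, gap
2000 bp, e-value 10, redundancy 1 (at most one junction per exact
position and strand), effective genome fraction 0.74. The background
is Poisson with per-window mean

$$\lambda_w = \frac{N \cdot \text{window}}{\text{EGF} \cdot G},$$

where `N` is the junction count and `G` the genome length. A window
is *eligible* when its count `k` satisfies
`P(X >= k; lambda_w) < 0.2` (the SICER default eligibility level);
eligible windows at most `gap` apart chain into islands, trimmed to
eligible ends, and each island scores
`sum(-ln P(X = count; lambda_w))` over its eligible windows. The
retention threshold is calibrated by Monte Carlo rather than by
SICER's asymptotic score distribution: we simulate 20 Poisson
background genomes at `lambda_w`, form islands identically, and keep
observed islands scoring strictly above the smallest score at which
the mean number of background islands does not exceed the e-value.
This is reproducible, seedable, and testable without an external
binary. The recorded `fdr` parameter applies only to a
control-library mode the pipeline does not use; the e-value path is
operative.

Refinement applies three elimination rules: candidates within ±2 Mb
of the bait DSB (bait-proximal rejoining, not genuine hotspots),
candidates with fewer than 5 junctions, and candidates overlapping
the off-target blacklist are discarded; each survivor of length `L`
with count `c` is then tested against its local background, measured
over flanks of 5×`L` on each side, clipped to the chromosome and
excluding other candidate spans (so one hotspot does not contaminate
another's background):

$$\lambda_{local} = \max\!\left(\frac{\text{flank count} \cdot L}
{\text{usable flank length}},\; \lambda_{bg} \cdot L\right),
\qquad p = P(X \ge c;\ \lambda_{local}).$$

Two choices here were genuinely open and we settled them by
measuring the operating characteristics on null simulations (uniform
background, N = 2000 junctions on 10 Mb, 200 seeds):

* **The background floor on `lambda_local`.** Candidates are
  score-selected maxima of the genome-wide scan, so their flanks are
  biased low by selection; the raw flank estimate fabricates
  enrichment for diffuse chains of junctions and produced a refined
  false hotspot in over 90% of null genomes. Flooring the local rate
  at the genome-wide background — the same guard peak callers such
  as MACS2 apply — removes that failure mode without touching true
  clusters, whose flank estimate exceeds the floor anyway.
* **The Bonferroni multiplicity.** Adjusting `p` only over the
  handful of surviving candidates ignores that the scan examined
  every window; we adjust by the number of windows scanned
  (`sum(ceiling(chrom_len / window))`). With both choices the null
  family-wise error rate is below 5% at the `adjusted P <= 0.01`
  significance level, while planted clusters of 10 junctions within
  500 bp are recovered with sensitivity 1.0.

A candidate with no usable flank (fully enclosed by other
candidates, or at a chromosome end of a tiny contig) is tested
against the floor alone. Refined hotspots in the same gene — gene
assignment is by largest overlap — merge into one spanning interval
with summed counts; merging happens after testing, and the merged
record keeps its members' smallest adjusted p-value. Junction counts
for the minimum-count rule are taken after redundancy capping,
consistent with redundancy 1.

## Strand bias

For a hotspot with plus-strand fraction `P`, the score is the binary
entropy

$$S = -P \log_2 P - (1-P)\log_2(1-P), \qquad 0\log_2 0 := 0,$$

so `S = 1` means no strand bias and `S = 0` a fully one-sided
hotspot. Junction strand encodes which gene orientation the
rearrangement fused to the bait, so functional selection — which
only keeps the orientation that puts the partner promoter upstream
of the kinase domain — drives `S` down within partner genes, while
pre-selection hotspots sit near 1.

```{r strand-bias}
strand_bias_score(c(0.5, 0.75, 1))
```

## Fusion annotation

A junction is classified productive exactly when all determinants
hold:

* **Orientation** — the retained prey side carries the partner's 5'
  portion: left for a plus-strand partner, right for minus.
* **Location** — the breakpoint is intronic. Breakpoints inside
  exons are atypical events observed clinically as weak drivers;
  they are non-productive by default, and
  `selection_params(allow_exonic = TRUE)` waives both the location
  and the (mid-exon-undefined) frame requirement for them.
* **Frame** — the partner's donor end-phase equals the kinase's
  acceptor start-phase at the bait intron, phases being cumulative
  coding length mod 3. Intron and exon numbering is transcript order
  on the coding strand (intron 19 separates exons 19 and 20), so a
  bait in kinase intron 19 retains exon 20 onward.
* **Transcription** — partner expression at or above
  `min_expression` (FPKM-like units; default 1, i.e. any nonzero
  expression in the bundled fixtures). A junction in a silent gene is
  detectable as DNA but yields no fusion transcript.
* **Stability** — a score in [0, 1] per (partner, retained kinase
  exon), thresholded at 0.5 by default. Stability is an *input*: the
  determinant is established experimentally (proteasome-inhibitor
  rescue of unstable fusion proteins), and no sequence-based
  predictor is warranted, so the package looks scores up (default
  1.0 when absent) rather than inventing biology.

A dimerization-domain requirement on the partner is available
(`require_dimerization`) but off by default; the association is
correlative. When several genes overlap a junction, the gene with the
largest overlap is used. `clone_frequency(n_clones, n_cells)` converts
resistant-clone counts to clones per million plated cells.

## The synthetic-data generator

`simulate_genome()` builds the standard study genome: 2 × 10 Mb, an
ALK-like minus-strand kinase of 22 exons on chr2 with the bait DSB in
intron 19 (acceptor phase 1 at exon 20), and a chr1 partner panel
that spans the determinant space — expressed in-frame partners on
both strands (PTNA, PTNB, PTNE), a silent in-frame partner (PTNC, the
partner whose fusions appear only once its transcription is switched
on), and a phase-incompatible partner (PTND). HaeIII cut positions
(~30 per Mb) and one blacklist interval complete the model.

`simulate_pre_selection()` draws junction positions from the mixture
the pre-selection assay exhibits: a bait-proximal component (default
30% of background, symmetric triangular decay over ±2 Mb — the assay
shows enhanced clustering there but no specific law, and a triangular
kernel is the simplest peaked symmetric choice), a per-gene component
with rate ∝ expression^coupling (default coupling 1; its weight,
`gene_fraction`, defaults to 30% of the non-bait background, chosen
so that gene-body enrichment is visible without dominating), and
uniform background; strand is 50/50 except where a
planted hotspot prescribes otherwise, and the retained prey side
follows deterministically from strand by the junction-caller's
convention, so emission and calling round-trip. Planted hotspots are
added on top of `n_junctions` with truth labels. The default library
size (2000) is the desk-scale stand-in for the genome-scale assay,
sized so that island calling, refinement and the selection contrast
all operate in their intended regimes on a 20 Mb toy genome.

`emit_alignment_table()` inverts the junction caller for clean
records and injects each artifact class at configurable rates (PCR
duplicates 0.2, low-score 0.1, gapped 0.05, multi-mappers 0.05,
HaeIII ligations 0.05, primer failures 0.05 — roughly the proportions
a real library loses at each stage). Injected read ids sort after all
clean ids so that deduplication provably retains the original
molecule.

`apply_selection()` keeps the productive subset, optionally thinned
by `survival_noise` (stochastic clone loss; there is no quantitative
survival model to estimate it from, so it is a free parameter,
default 0).

What the generator deliberately does **not** emulate: base-level
reads (no sequencing errors, no FASTQ — alignment records are
simulated directly), transcript isoforms (one transcript per gene
defines exon numbering), chromatin or replication-timing covariates
of breakage, and any quantitative clone-survival kinetics. Passing
tests therefore demonstrate that the *statistical machinery* behaves
as designed under the assumed generative structure, not that real
libraries satisfy those assumptions.

## Landscape summaries

`percent()` rounds half-up at the printed precision (81.25% → 81%,
2.597% → 2.6%), matching how such fractions are reported.
`partner_sharing()` counts a partner as shared when it fuses with at
least two distinct kinase *genes* (tissues do not multiply-count),
and the shared fraction is over distinct partners.
`exon_usage()` and `partner_frequency()` are exact tallies;
round-tripping a generated fusion table through them reproduces the
generating specification identically, which the suite asserts.

## Numerical notes and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; BED output
  likewise; GTF import converts from 1-based inclusive.
* An empty junction set yields an empty island table; an empty
  hotspot has no defined strand bias (error, by design).
* Poisson tails use the stable upper-tail form
  (`ppois(c - 1, lower.tail = FALSE)`); the suite checks them against
  direct pmf summation to 1e-10 relative error.
* The Monte-Carlo e-value calibration consumes the `seed` argument of
  `call_islands`; identical seeds give byte-identical results, and
  all generator functions are likewise seeded.
* Island scores have atoms (many one-junction windows share a score);
  the calibrated threshold is applied strictly (`>`), so a whole atom
  is never retained on a tie that would overshoot the e-value.

## Problem sizes

The test suite and the analysis scripts run at desk scale, chosen so
the full suite completes in about a minute: 10–20 Mb genomes,
libraries of 1000–2200 junctions, 200-seed null calibrations, and
50-seed sensitivity sweeps. All thresholds above are independent of
these sizes.

## Known limitations

* The island model is a faithful simplification of SICER (fixed
  eligibility level, Monte-Carlo e-value calibration); broad-domain
  features and the control-library FDR mode are out of scope.
* Stability and expression are inputs, not predictions; the package
  ranks and gates fusions but cannot nominate unstable fusions from
  sequence.
* Exon numbering follows a single canonical transcript per gene;
  fusion tables built on other transcript choices must be renumbered
  before import.
* `clone_frequency` is a unit conversion, not an estimator; no
  plating-efficiency correction is applied.
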