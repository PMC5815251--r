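---
title: "preyweb: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{preyweb: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Generalist predators such as spiders (Araneae) connect above- and
below-ground food webs, but their prey spectra are hard to observe
directly. Gut-content DNA metabarcoding amplifies a short marker — here
the nuclear ITS2 spacer flanked by the conserved 5.8S and 28S rRNA genes —
from whole-predator DNA extracts and sequences it at depth. Two obstacles
shape the method:

* predator DNA vastly outnumbers digested prey DNA, so amplification must
  be biased toward the prey clade (Hexapoda: insects and springtails)
  with clade-discriminative primers and predator-specific *blocking
  primers* carrying a non-extendable C3 spacer at their 3′ end;
* the marker occurs in many intragenomic copies, so one predator species
  contributes several ITS2 variants that must not be mistaken for
  distinct taxa.

`preyweb` implements the full desk side of this workflow: primer design
from paired clade alignments, strict quality control of indexed forward
reads, greedy 97% OTU clustering, lowest-common-ancestor (LCA) taxonomic
assignment, predator-by-prey interaction matrices with per-PCR-setting
summaries, and a ground-truthed amplicon simulator that makes the whole
chain testable without any external data.

# Primer design

Both clades are summarised as per-column profiles of their multiple
alignments (`build_profile()`): base frequencies over non-gap residues
(ambiguity codes spread fractional weight over their base sets), a gap
fraction, and an IUPAC consensus containing every base at frequency ≥ 0.2
(a column is a gap when half or more of the sequences are gapped). The
0.2 / 0.5 thresholds are configuration knobs; their defaults were chosen
so that consensus calls on small curated alignments match what a person
designing primers by eye would write down.

`find_discriminative_windows()` enumerates **all** windows of length
17–25 nt in both orientations, keeps those whose target-clade consensus
is gap-free, at most 2-fold degenerate and conserved at ≥ 0.9 mean
coverage, and scores each candidate against the excluded clade's
consensus with `match_primer()` (set-membership matching; a site `N`
matches nothing by default, because an uncertain reference should not
count as support). Ranking is lexicographic and total: more 3′-terminal
mismatches first (the last `k = 3` positions — "at or around the 3′ end"
is deliberately a small region, and `k` is configurable), then an
insertion/deletion signal at the 3′ terminus, total mismatches, target
conservation, and finally window coordinates so that enumeration order
can never matter. Candidates that match the excluded consensus perfectly
are discarded — they cannot discriminate.

`design_blocking_primers()` inverts the roles: a blocking candidate must
equal the excluded (predator) consensus across a window overlapping the
indel anchor, must mismatch the target consensus within its 3′-terminal
positions (a target gap there counts), and is emitted with a C3-spacer
annotation. Sub-clade primers (e.g. for Lepidoptera) are obtained by
re-running the same operations on sub-clade alignments rather than by
special-case code.

# Read processing

The QC dialect is strict and order-fixed, and every read falls into
exactly one class:

1. **Index quality** — discard if *any* of the 16 index bases is below
   Q30. A mean-quality reading would be laxer; the any-base reading is
   the conservative interpretation and is the default.
2. **Index mismatch** — exact pairing of the 8-mer index pair against the
   sample sheet; zero mismatches tolerated by default.
3. **3′ trimming** — peel bases off the 3′ end until the terminal five
   bases are all ≥ Q30. An alternative reading ("cut at the first clean
   window from the 5′ side") exists; the 3′-peeling semantics are the
   declared choice and are idempotent. Reads shorter than the window are
   left to the length filter rather than adding a discard class.
4. **Length** — reject below 170 bp (ITS2 amplicons of this marker are
   longer; shorter reads are primer dimers or junk).
5. **Quality fraction** — reject when ≥ 10% of remaining bases are below
   Q30 (exactly 10% rejects).

After filtering, the variable 3–6-base pad and the amplification primer
are located (IUPAC-aware, one mismatch allowed) and removed; reads
without a recognisable primer are dropped and counted separately. This
step is not part of the five classes above because it is a property of
the fusion-primer construct, not of read quality. Only forward reads are
processed; reverse reads of this chemistry are too low-quality to add
information.

# Sequence identity and clustering

Identity between two sequences is defined through a global
Needleman–Wunsch alignment with match +1, mismatch −1 and linear gap −2,
terminal gaps scored like internal ones. The identity is computed on the
alignment columns *excluding the terminal gap runs*: matching columns
divided by remaining columns, internal gaps counting as non-matching
columns. Two consequences matter:

* a 3′-trimmed read that is an exact prefix of a longer centroid has
  identity 1 — trimming depth cannot split OTUs;
* unrelated sequences cannot reach high identity through a tiny
  coincidental overlap, because the alignment must span both sequences.

On score ties the traceback prefers gap steps over diagonal steps, which
coalesces co-optimal gaps into the (excluded) terminal runs instead of
scattering them inward; this makes the reported identity deterministic
and as large as any co-optimal alignment allows. Equal-length sequences
differing by substitutions get the intuitive value (6 substitutions in
200 → 194/200 = 0.97, which is **inside** the 97% cutoff; 7 → 0.965,
outside).

`greedy_cluster()` processes dereplicated sequences in (abundance
descending, sequence ascending) order; each joins the best existing
centroid at ≥ 97% identity (ties to the earliest centroid) or founds a
new OTU. Because the input is abundance-sorted, each centroid is its
OTU's most abundant member, and the whole procedure is independent of
read-file ordering. Clustering is done once on the pooled data across
samples and settings; per-setting tables are row selections afterwards.

For speed the implementation retrieves candidate centroids through an
inverted 8-mer index and skips alignments that provably cannot reach the
cutoff: an alignment with `d` non-matching columns destroys at most `8 d`
of the overlap's distinct 8-mers, so identity ≥ 0.97 over an overlap of
length `L` forces ≥ ~0.75 (L−7) shared 8-mers; candidates below 0.7 (L−7)
(margin for within-sequence 8-mer collisions) are skipped, as are
candidates whose shared-8-mer identity upper bound cannot beat the
incumbent best hit (on a tie the earlier centroid wins anyway). These
bounds make the screens exact accelerations, not approximations; the
test suite verifies equality with a brute-force implementation.

Denoising is approximated by the combination of abundance-ordered
clustering and the minimum-abundance OTU filter (`filter_min_abundance()`:
OTUs of ten or fewer total reads removed; eleven survives). Chimera
detection is deliberately absent: in this marker system reference-based
chimera removal also discards genuine sequences, so foreign OTUs are
instead removed by the clade-retention step below.

# Taxonomy

`assign_taxonomy()` computes the identity of each OTU centroid to every
reference (same identity definition as clustering). If the best identity
is below 0.8 the OTU stays unassigned. Otherwise all references within
`epsilon = 0.01` of the best identity vote, and the lineage is truncated
at the deepest rank on which all voters agree (LCA). This fixed identity
band is a declared approximation of query-centric adaptive
neighbourhood selection: it keeps the neighbour set a pure function of
the identities, making assignment order-independent and monotone (adding
a neighbour can only shorten the lineage).

Clade retention maps lineages onto the two target clades through a
configurable table — `Insecta`, `Collembola`, `Protura` and `Diplura`
imply Hexapoda, since reference lineages rarely carry "Hexapoda" as an
explicit rank — and discards everything else, including unassigned OTUs
(likely chimeras or contaminants).

# Food webs and summaries

An interaction matrix cell counts the samples in which an Araneae entity
(OTU, or the sample's species label in `by_species` mode) co-occurred
with a Hexapoda OTU. The cross-setting union deduplicates by *physical
specimen*: the same spider detected under several PCR settings supports
an edge once. This is why the sample sheet carries a `specimen` column
(defaulting to `sample_id` when each specimen was sequenced once).

`setting_summary()` mirrors the conventional per-setting summary row.
Two definitional details are fixed by reproducing all printed values of
such tables exactly:

* mean Hexapoda reads are averaged over *Hexapoda-positive* samples,
  while mean Araneae reads are averaged over all samples with reads;
* the "percentage of Hexapoda reads" is Hexapoda reads relative to
  **Araneae** reads (×100), not to their sum — only this ratio reproduces
  the reference rows used as arithmetic fixtures in the acceptance tests.

Percentages are rounded half-up (sample percentages to 1 decimal, the
read percentage to 2), means to the nearest integer; zero denominators
yield `NA`, never NaN arithmetic. Raw counts are used throughout — no
rarefaction subsampling enters any matrix. Rarefaction curves are
reported separately via the closed form
`E(S_n) = Σ_i (1 − C(N−N_i, n)/C(N, n))`, evaluated with log-gamma.

# The simulator: a stated world

`simulate_truth()` + `generate_reads()` emulate the structure of a real
spider gut-content run:

* 15 predator species with 2–3 intragenomic ITS2 variants each; variants
  are built by substituting exactly 1% of positions from a common base
  sequence, so pairwise variant divergence is ≤ 2% and co-clustering at
  97% holds *by construction*;
* 50 prey taxa with mutually unrelated templates (verified < 97%), each
  carrying a full reference lineage (≈ 70% insects across six orders,
  ≈ 30% springtails);
* a diet matrix at connectance 0.15 (every predator gets at least one
  edge), and per-specimen consumed-prey sets drawn at meal probability
  0.35;
* 50 specimens, each sequenced under four PCR settings (no blocking,
  blocking primer A, B, and A+B) — 200 sample libraries of 5,000 reads;
* a predator template weight of 0.99, which puts the Hexapoda read
  percentage in the ~1% regime that real runs of this design report;
  blocking multiplies the predator weight by (1 − β), with β = 0.5 for
  all blocking settings by default (a single multiplicative suppression
  factor is the simplest mechanism with the observed effect direction;
  no thermodynamics are modelled);
* per-base substitution error 0.005; Phred qualities from a flat mean-36
  profile decaying linearly after position 180 (sd 4), index reads at
  mean 37/sd 3 — so index-quality and index-mismatch rejections occur at
  realistic rates because the indexes themselves are sequenced with
  errors;
* 1% chimeras joining two pool templates at a uniform breakpoint, and
  two negative-control libraries per setting carrying a Poisson(5) trace
  of predator contamination.

All randomness flows from the single mandatory seed in `sim_params()`.

What the simulator does **not** emulate: PCR-cycle amplification bias,
index hopping, length variation of the marker between taxa, DNA
degradation differences between fresh and digested prey, and database
incompleteness (every simulated taxon has a perfect reference). A green
end-to-end test therefore establishes that the pipeline's logic recovers
a known web from reads with realistic error and dominance structure — it
does not establish field-level sensitivity, which in real runs is
limited by template quality rather than by the desk-side pipeline.

# Numerical and degenerate-input choices

* All alignment bands are sized from the decision threshold they serve
  and are therefore exact for identities at or above it.
* 0-based half-open coordinates everywhere internally; 1-based only in
  human-readable reports.
* Ties: clustering ties go to the earliest centroid; ranking ties in
  primer design fall through to window coordinates; traceback ties
  prefer terminal gaps (see above).
* Empty inputs return empty, typed results (empty candidate tables,
  empty OTU tables); genuinely contradictory inputs (unequal alignment
  lengths, duplicate index pairs, unknown sample ids, anchors outside
  the alignment) raise errors naming the contract they violate.
* Reads shorter than the trim window, samples that end up empty, and
  all-zero summary tables are all representable and tested.

# Known limitations

* The greedy clusterer is exact but single-threaded; ~350k unique
  sequences cluster in about a minute, which is adequate for the tested
  scale but not for multi-run studies.
* The LCA neighbour band is a fixed ε; a query with one very close and
  many moderately close references keeps only the close ones, but no
  adaptive k selection is attempted.
* `by_species` mode trusts the sample sheet's morphology labels; it does
  not reconcile them against Araneae OTUs (both modes are provided so
  the comparison can be made externally).
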