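---
title: "Methods behind the carbonic anhydrase gene-family census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the carbonic anhydrase gene-family census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cacensus` chains eight stages — synthetic data generation, format IO,
quality filtering, identity clustering, profile construction and
scanning, taxonomic census, environmental abundance, and phylogenetic
diversity — into one reproducible census of carbonic anhydrase (CA)
gene-family diversity. This vignette explains each stage's model, the
parameters that matter, the numerical conventions, and what the
synthetic ground truth does and does not establish about real data.

## The synthetic study generator

Real CA surveys draw on tens of thousands of genomes and thousands of
metagenome datasets that cannot be bundled with a package. The
generator (`sim_config()`, `simulate_ca_study()`) instead emulates the
*structure* of such a survey at desk scale, with every latent variable
recorded as ground truth:

- **Genomes.** Four organism groups (Bacteria, Archaea, Fungi, Algae).
  Each genome is CA-capable with probability 1 − `zero_ca_fraction`
  for its group; capable genomes draw per-class copy counts from
  Poisson distributions with the group-by-class means in `copy_rate`.
  The two-part draw is a zero-inflated Poisson: it reproduces both the
  sizeable fraction of genomes without CA and the overdispersion of
  copy counts. Default group sizes (120/24/40/16) are down-sampled
  from survey proportions while keeping every group large enough to
  exercise; default zero-CA fractions (0.31/0.52/0.015/0.69) mirror
  survey presence percentages, and the default rate matrix makes fungi
  and algae CA-rich (γ especially), archaea γ-dominated with a zero α
  rate, and bacteria mostly single-copy.
- **Taxonomies.** Lineages are drawn from a nested pool in which each
  rank partitions the one above; taxon names are path-encoded so that
  agreement at a deep rank implies agreement above it. A
  `missing_rank_fraction` (default 0.05) blanks cells to exercise the
  missing-data policy.
- **Sequences.** Each class has a base sequence; ancestors are the base
  mutated at `between_divergence` (default 0.80) of non-motif
  positions, and each genome copy is its ancestor mutated at
  `within_divergence` (default 0.10). Mutation is substitution-only
  (uniform over the 19 alternatives), which keeps pairwise identity
  analytically predictable: two descendants agree at a fraction of
  roughly (1 − d)² + d²/19 of positions. Class-specific metal-binding
  residues (His triads for α and γ, a Cys-His-Cys triad for β, at
  configurable positions) are never mutated. An optional `indels` mode
  adds short indels to exercise alignment code at the cost of that
  predictability.
- **Conservation control.** Each ancestor receives a taxonomic
  restriction depth drawn from `conservation_depth_weights`; an
  ancestor restricted at, say, Phylum only acquires members inside one
  phylum, so its realized cluster LCR is at least that deep. The first
  ancestor per class stays unrestricted so that every genome always
  has an eligible ancestor. The default weights produce a declining,
  survey-like conservation gradient; because restriction is a lower
  bound on depth (small clusters can be deeper by chance), the realized
  gradient is at least as conserved as the weights suggest.
- **Metagenomes.** Each of the seven environment categories gets
  `n_datasets_per_environment` datasets of `orfs_per_dataset` ORFs:
  true CA ORFs (sampled descendants, a `truncate_fraction` of them
  truncated) plus residue-shuffled decoys. Shuffling preserves
  composition exactly, so only position-specific signal — not amino
  acid frequency — can separate decoys from true CA in the scanning
  stage. Ancestors can be made environment-exclusive
  (`env_exclusive_fraction`, or an explicit map) for specificity tests.

Every operation reseeds deterministically from `seed`, so a fixed
configuration yields byte-identical outputs, files included.

What passing tests on this generator shows: that each stage computes
its defined quantity correctly, that the stages compose, and that the
scanning stage separates position-specific signal from composition at
the stated thresholds. What it does not show: robustness to real
protein evolution (rate heterogeneity, domain shuffling, long indels),
to annotation noise in real databases, or to taxonomies with synonymy
and rank conflicts. The generator's uniform substitution model is a
deliberate simplification, not a claim about evolution.

## Filtering

Length filtering keeps sequences with `min_len ≤ length ≤ max_len`
residues, inclusive on both ends; defaults 100–1000 aa bracket
plausible single-domain CA sizes and are configuration, not biology.
Alignment-stage filtering removes rows whose non-gap residue count is
*strictly* below 75% of the alignment length (a row at exactly the
bound is kept) and rows failing the metal-binding check, which requires
an allowed residue (not a gap) at every required alignment column.
Motif columns depend on the reference alignment in use, so they ship as
data (`default_motifs()`), not code. Both filters are idempotent and
commute.

## Clustering

Identity is matches ÷ alignment length of an optimal global alignment
under a configurable match/mismatch/linear-gap scheme (defaults
1/−1/−1); gap columns count against identity. Among equal-score
alignments the implementation reports a canonical one (diagonal
preferred, then gap-in-second, then gap-in-first); the test suite
checks the score against exhaustive enumeration of *all* alignments and
accepts any optimal alignment's identity. Clustering is greedy,
CD-HIT-style: sort by length descending then id ascending, join the
first representative at or above the threshold, else found a new
cluster. This is deterministic and order-invariant by construction, but
representatives of different clusters are not guaranteed to be mutually
below the threshold — a known property of greedy clustering, shared
with the standard tools. An optional 3-mer screen skips alignments
against representatives sharing no 3-mer; it is off by default and the
suite verifies it does not change results at the identity levels this
pipeline clusters at.

## Profiles and scanning

Clusters with at least three members are aligned center-star around the
representative (pairwise global alignments merged under "once a gap,
always a gap"), which is deterministic and adequate for sets already
above the clustering threshold; columns with more than 90% gaps are
trimmed. Match states are columns with gap fraction below 0.5;
emissions are residue counts plus a pseudocount (default 0.5),
normalized over the 20-letter alphabet, scored as log₂ odds against a
uniform background — i.e. in bits, the scale on which the 50-bit
retention threshold is defined. Transition costs are fixed log₂
probabilities (M→M 0.9, M→I = M→D 0.05, I→M = D→M 0.6, I→I = D→D 0.4);
insert states emit at background (0 bits); entry into and exit from any
match state is free (local alignment). Out-of-alphabet residues score 0
bits rather than erroring. Viterbi scoring is exact dynamic
programming, verified against brute-force path enumeration on small
profiles.

Hit assignment keeps, per ORF, only its maximum-scoring profile, and
only at score ≥ 50 (inclusive); ties break by profile id ascending. The
alternative reading — keep only the best ORF per profile and dataset —
is available as `hit_policy = "best_orf_per_profile"`, because
downstream abundance tables depend on which convention is used; the
default prevents one ORF from being counted under several profiles.

## Taxonomic census

The lowest common rank walks Superkingdom → Genus and keeps the deepest
rank at which all members with a non-missing value agree. Missing
values (blank, `unclassified`, `incertae sedis` — normalized at read
time) are non-informative: they neither anchor nor break agreement.
This matches the observation that uncertain ranks should have little
effect on assignment; the alternative (missing breaks agreement) would
force large mixed-annotation clusters to artificially shallow ranks.
Conservation at rank *r* counts clusters whose LCR is at *r* or deeper,
divided by all clusters considered — a cumulative definition that is
monotone non-increasing by construction. Percentages are computed as
100·n/total rounded to one decimal (zero decimals only in table-style
summaries); copy-number statistics are computed over genomes carrying
at least one copy of the relevant class, with sample (n−1) SD, reported
as 0 and flagged when only one carrier exists. The rank ladder
deliberately omits a Kingdom rank, which not all Superkingdoms possess.

## Environmental distribution

Hits are counted per environment × profile and rolled up to classes or
LCR-derived groups; all rollups conserve totals. The abundance
transform is log₁₀((H/f)/T + 10⁻⁵) with H the cell's hits, f the
environment's share of distinct studies, and T the number of genomes in
the taxonomic group. Base 10 and "T counts genomes" are the package's
documented choices where conventions differ; the additive constant
pins empty cells at exactly −5. Specificity tables select the top-N
profiles per environment by raw hits (ties by id), take the union, and
group the selected profiles by their full environment-membership sets
(≥ 1 raw hit), the construction behind upset-style intersection plots.
Scaling is applied per (environment × group) cell.

## Phylogenetic diversity

Support-based collapsing contracts every internal edge whose child
support is strictly below the threshold (default 95 on a percent scale;
fractional supports are rescaled at read time) and adds the contracted
edge's length to each child, preserving root-to-tip distances — the
package's explicit convention, since polytomy construction is otherwise
underdetermined. Nodes without a support value are kept by default.
Long terminal branches are flagged above median + k·MAD (default
k = 5); only the outcome of long-branch exclusion is standard, so the
rule is configuration. Subset PD uses the crown convention (the edge
above the subset's connecting node is excluded; `include_root = TRUE`
reverses this). The PD-contribution test removes the focal tips,
measures the PD lost, and compares against uniformly drawn equal-size
tip sets, with the add-one p-value correction so p is never zero —
at 999 randomizations the smallest attainable p is 1/1000. The uniform
null is the package's choice of randomization scheme. Note that the
default generator does not plant excess diversity on fungal branches,
so the pipeline's fungal PD test on synthetic data is expected to be
non-significant; the planted-outlier tests establish that the test
detects real excess.

## Pipeline and problem sizes

`run_ca_pipeline()` connects the stages exclusively through documented
files in the output directory and writes a manifest of MD5 checksums;
rerunning an identical configuration reproduces identical checksums.
The guide tree over cluster representatives is neighbor-joining on
1 − identity distances — a deliberate, fast stand-in for full
phylogenetic inference, which is out of scope. The test suite runs the
generator at its defaults (200 genomes, ≈ 700 proteins, 21 datasets)
for end-to-end checks and smaller per-module configurations elsewhere;
oracle comparisons use exhaustive enumeration at sizes where
enumeration is exact (alignments of ≤ 8–14 residues, profiles of ≤ 5
match states, clusters of ≤ 12 sequences, all tip subsets of a 6-genome
toy taxonomy). These sizes are the package's choices for keeping
exhaustive verification exact and fast.

## Known limitations

- Greedy clustering depends on the ordering rule; it reproduces the
  *kind* of clustering used in large surveys, not any tool bit-exactly.
- Profile scores share HMMER's bit-score scale and architecture in
  spirit, but are not HMMER-comparable numbers; the 50-bit threshold
  is meaningful relative to this package's models.
- Center-star alignment is optimal per pair, not globally; for highly
  divergent clusters a progressive aligner would differ.
- The NJ guide tree and the uniform-null randomization are pragmatic
  defaults, not substitutes for model-based phylogenetics.
- Environment categories are a fixed seven-way scheme; mapping real
  ecosystem ontologies onto it is the caller's responsibility.
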