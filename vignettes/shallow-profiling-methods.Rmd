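---
title: "Methods: homology-based profiling of shallow shotgun metagenomes"
author: "metashallow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based profiling of shallow shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metashallow)
```

# The problem

Shallow shotgun metagenomics profiles a microbial community from a modest
number of reads — on the order of 100,000 — instead of the full output of a
sequencing run. At that depth, species-level accuracy depends less on raw
statistical power than on (i) the quality of the reference database the
reads are compared against, and (ii) the decision rule that turns local
alignment hits into taxonomic assignments. `metashallow` implements both
sides, together with the machinery needed to *measure* profiling accuracy on
synthetic communities with known composition.

The package deliberately contains everything needed to exercise the method
offline: simulators generate genomes and reads with ground-truth manifests,
a built-in aligner produces hits, and the benchmark module scores the
recovered profiles. External aligners can be plugged in through the tabular
(BLAST `outfmt 6`) hit format, but nothing in the test suite requires one.

# Reference database curation

Public genome collections contain mislabelled and redundant genomes, and
contaminating host sequence. Curation therefore runs in four steps
(`curate_reference_db()`), all parameterized by `curation_params()`:

1. **Taxonomic revision by ANI.** For every non-reference genome, the
   closest reference genome is the ANI record with the highest ANI; ties
   break by the larger `min(query_cov, subject_cov)` and then by accession,
   purely for determinism. If ANI exceeds 94% *and both* coverages exceed
   70%, the genome adopts the reference's species; 94–95% ANI over a
   sufficient fraction of the genome is the accepted genome-based species
   boundary, and the 70% coverage floor accommodates draft assemblies and
   horizontally acquired regions. When the gate fails but the closest
   reference shares the declared genus, the declared taxonomy is retained —
   the species likely has no reference genome yet. Otherwise the genome is
   flagged `unresolved` and kept with its declared labels. A failed
   *coverage* gate never reclassifies, even at high ANI: we treat partial
   evidence conservatively.
2. **Dereplication.** Genomes with ANI above 99% to *their own species'*
   reference genome add nothing but compute time and are dropped. The
   comparison is only against the species reference, never all-vs-all, so a
   diverse species keeps its distinct strains.
3. **Contig length floors.** Reference contigs shorter than 1 kbp (viral),
   5 kbp (prokaryotic) or 12 kbp (eukaryotic) are removed; short deposited
   contigs are enriched in vector, low-complexity and chimeric sequence.
   Floors are inclusive: a contig exactly at the floor survives.
4. **Host decontamination.** Assemblies of host-associated microbes often
   carry stretches of host DNA. A contig is removed when a hit against a
   configured host genome reaches 90% identity over at least 50% of the
   contig. These two thresholds are the package's own quantification of
   "high identity to a host" and are exposed in `curation_params()`;
   anything materially weaker starts deleting genuinely shared sequence.

The length filter runs before host decontamination; the order is visible in
the code and the change log, and on sane inputs the two commute except for
the wasted work of aligning doomed short contigs.

A per-species **size table** (arithmetic mean of retained genome lengths —
the mean, not the median, so that a species' table entry moves smoothly as
genomes are added) supports abundance normalization below.

# Read classification

Reads pass a quality filter — mean Phred at least 25 and length at least
150 bp, with both mates of a pair dropped if either fails — and optional
host depletion, then at most `sample_size` reads (default 100,000) are
drawn uniformly, pairs kept together. "Quality of at least 25" is read as
*mean* read quality rather than per-base trimming: the filter is a
whole-read retain/remove decision, and the cutoff is a parameter.

Hits for each read are gated at E-value ≤ 1e−5 and query coverage ≥ 95%,
and capped at the 100 highest bit scores. The decision rule is then:

* best identity **> 94%** (strictly): species level. A single best species
  is reported directly. Equal best hits to multiple species go to the
  **least common ancestor** of those species — unless all tied hits are
  viral, where LCA is disabled by default (`viral_lca_disabled`) and the
  highest-bit-score hit wins: public viral genomes share so much sequence
  that LCA would collapse most viral reads to useless ranks. A tie mixing
  viral and non-viral references falls through to ordinary LCA, since the
  viral shortcut exists to compensate for redundancy *within* viral
  databases, not across kingdoms.
* best identity in **[20%, 94%]**: the read is assigned to the best hit's
  genus as `"undefined species"` — novel species without reference genomes
  are expected in real samples, and the low genus floor lets them surface
  at genus level. Identity exactly 94 is genus-level: the species rule is a
  strict inequality.
* below 20%: unclassified.

Ties are defined on *percent identity* within `identity_tie_epsilon`
(default 0: exact equality), not on bit score; the epsilon is exposed
because upstream tools are vague about what "equal best hits" means
numerically. Mates of a pair are classified independently and counted as
two reads.

Counts aggregate into species-level tables (genus-level `"undefined
species"` assignments and higher-rank LCA assignments keep their own rows)
with `relative = 100 · count / classified`. **Genome-size normalization**
divides each species' count by its mean genome size from the size table and
renormalizes: longer genomes shed proportionally more fragments into the
sequencer, so raw read fractions overstate large-genome species. Taxa with
no size-table entry fall back to the database-wide mean size (with a
warning for unlisted species): a genus-level bin has no defined genome
size, and the neutral fallback neither promotes nor demotes it.

# Contig classification

Assembled contigs longer than 5 kbp (strictly) are classified with the same
rule set, with one deliberate change: the 95% query-coverage gate is not
applied — a 100-kbp contig rarely aligns end-to-end against a draft
reference — and hits must instead span at least 1 kbp. A contig is scored
by its surviving best-hit set as a whole, not by majority vote over
segments; with curated references the two agree except on chimeric contigs,
which segment voting would mask rather than expose. Pools of contigs
sharing a taxon are annotated by a minimal six-frame ORF caller (maximal
ATG-to-stop, ≥300 nt, stop codon included) and written as standard GenBank
flat files, one LOCUS per contig, with the taxon lineage as ORGANISM. The
ORF caller is a deliberate simplification: the contract is the GenBank
structure for browser-based inspection, not annotation quality.

# Functional profiling

Reads are searched against labelled reference sequences
(`seq_id|family|pathways` FASTA headers, carbohydrate-active-enzyme style
family codes). Gates are configured separately from the taxonomic ones —
E ≤ 1e−5 but coverage only ≥ 50%, since a read may span a domain boundary.
Each read credits the family of its single best hit (bit score, ties by
lexicographic family order), and every pathway listed on that reference;
pathway counts are therefore deliberately non-exclusive. Counting only the
best hit (rather than all passing hits) keeps family counts read-additive:
totals plus unassigned always equal the input reads. The built-in backend
searches nucleotide space; translated search can be supplied externally
through the same tabular format.

# Simulators: what they emulate and what they do not

`simulate_illumina()` draws fragments uniformly over genome positions and
strands (insert 400 ± 40 bp), emits 150-bp mates from opposite fragment
ends, and substitutes each base independently with probability 0.02 — the
standard WGSIM-style base error rate for artificial Illumina data. Indels,
quality-dependent errors and PCR duplicates are deliberately absent:
short-read errors are substitution-dominated, and the truth is carried by
the manifest, so quality strings are constant Q30. `simulate_nanopore()`
emits fixed-length 8-kbp reads with a 0.003 error rate split evenly among
substitutions, insertions and deletions, reflecting the indel-dominated
error profile of long reads; homopolymer bias is not modelled. Fixed length
(rather than a length distribution) keeps per-read error budgets exactly
comparable; the length is a parameter.

Per-species abundances are specified in reads and honoured *exactly* (even
counts are required in paired mode), so manifests and expected profiles are
deterministic; every random draw sits under the spec's single seed and runs
are byte-identical at a fixed seed.

Because simulated genomes are i.i.d. random sequences, cross-species hits
essentially never occur at these genome sizes. Passing the recovery tests
therefore demonstrates the correctness of the pipeline's bookkeeping and
thresholds — not robustness to genuinely homologous genomes, conserved
regions, or real error profiles, which require real references.

# Benchmarks

The **DExA index** (deviation from expected abundance) is half the L1
distance between observed and expected relative-abundance profiles on the
percent scale over the union of species:
`DExA = Σ|obs − exp| / 2`. The halving reconciles "sum of absolute
deviations" with a 0–100% range: identical profiles score 0%, profiles
with disjoint species sets score 100%. Observed profiles are renormalized
over classified reads (unclassified mass is reported separately); genus
bins keep their own labels and count as non-matching species — the
strictest reading.

**Confusion under ablation** removes chosen species from the database and
tracks: in-database reads recovered at their true species (TP) versus
anything else (FP); ablated-species reads left unclassified or at genus
level (TN) versus confidently assigned to a concrete species (FN). Note the
FN/FP labelling follows profiler-benchmarking usage — an FN is an ablated
read *mis-assigned with confidence* — which inverts the textbook
convention; both labellings are returned (`alt_FP`, `alt_FN`). Rates
condition on the in-database and ablated read totals respectively.

**Depth titration** subsamples a read set at a ladder of depths (seeded),
profiles each, and reports DExA per depth.

# Numerical and design choices

* **Built-in aligners.** `local_align()` is an exact Smith–Waterman
  (match +1, mismatch −1, gap −2, linear) searching both strands, with a
  deterministic tie policy (smallest query end, then subject end; traceback
  prefers diagonal over up over left). It is the oracle and small-instance
  backend. `align_reads()` is a k-mer seeded (k = 15), ungapped-extension
  aligner over a full subject index, suitable for substitution-dominated
  short reads and exact long queries; indels shift the diagonal and are not
  chased, so indel-rich long reads should use an external gapped backend.
  Spurious single-seed hits extend into low-identity, negative-score
  alignments and are removed by the E-value gate.
* **Synthetic E-values.** Both built-in aligners report a monotone
  Karlin–Altschul-style transform of the raw score
  (`bits = (1.33·S − ln 0.621) / ln 2`, `E = m·n·2^−bits`). These are
  calibrated for *thresholding and ordering only*; production runs consume
  backend E-values verbatim.
* **Boundary conventions.** Species identity strictly `> 94`; genus
  `≥ 20`; read length `≥ 150` (so 149-bp reads fail); contig
  classification strictly `> 5000`; contig floors inclusive `≥`; ANI
  reclassification strictly `> 94` and coverages strictly `> 70`;
  dereplication strictly `> 99`.
* **Degenerate inputs.** Empty hit sets classify as unclassified; genomes
  with no ANI records are retained and flagged; genomes losing all contigs
  to the length floor are dropped; empty contig pools write no GenBank file
  but log a message; profiles of zero classified reads are empty with the
  unclassified count preserved.
* **Problem sizes.** The bundled tests run entirely on synthetic data:
  recovery uses 5 species (0.5–2 Mb genomes, GC 0.35–0.60) with abundances
  40/25/20/10/5% over 20,000 read pairs at error 0.02 — genome sizes and
  depth chosen so every species receives thousands of read pairs while a
  full run stays interactive on one core; error-rate checks use ≥ 10^5
  simulated bases; the even-design checks generate 100,000 reads over 10
  and over 1,000 species.

# Known limitations

* The seeded aligner is ungapped; genuine long-read classification needs an
  external backend (any tool emitting `outfmt 6`).
* The taxonomy lifted from database labels spans
  root–superkingdom–genus–species; intermediate ranks appear only when a
  full node table is supplied, and genus names must be unique across
  kingdoms in the lifted form.
* ANI values are consumed, never computed; the simulators fabricate
  consistent ANI tables for testing.
* The ORF caller has no translation table options or start-codon variants;
  it exists to exercise the GenBank contract.
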