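---
title: "Profiling accumulated low-stringency alignments to find present and fossil coding regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling accumulated low-stringency alignments to find present and fossil coding regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anablastr)
```

## The idea

Translations of coding DNA accumulate many *weak* protein-database
alignments, because coding sequence — however diverged — tends to retain
short footprints of the ancestral proteins it descends from.
Translations of non-coding DNA produce weak alignments only by chance,
and chance hits do not pile up at the same positions. The package turns
this asymmetry into a per-position statistic: translate a genomic region
in all six frames with stop codons masked, align each framed translation
against a clustered protein database under deliberately permissive
thresholds, and count, at every residue position, how many *distinct
database clusters* contribute an alignment covering that position.
Contiguous positions whose count clears an empirically calibrated cutoff
are called as peaks. Because stop codons are masked rather than used as
boundaries, the statistic is blind to ORF structure and therefore sees
pseudogenes, frameshifted relics and other gene fossils just as well as
intact genes.

## Pipeline and assumptions

The scan operates on *inter-exon* regions: every gap between two
consecutive annotated exons, after merging exon intervals across genes
and strands. The substrate assumption is that the annotation's exons are
trustworthy; everything between them is fair game. Gaps inside a single
transcript's exon span are labelled introns, the rest intergenic;
chromosome termini are excluded by default (`include_termini = TRUE`
adds them) because a terminus is bounded by only one exon.

Six-frame translation uses the standard genetic code (the method targets
nuclear DNA). Each stop codon becomes exactly one `X`, preserving length
in codon units, and codons containing ambiguous bases also become `X`;
the X column of the substitution matrix scores them, so they cannot
nucleate alignments. Frames 1–3 read the forward strand at offsets
0–2, frames 4–6 the reverse complement likewise, each strand 5'→3',
which makes every residue position map to exactly one genomic codon —
the mapping `protein_to_genomic()`/`genomic_to_protein()` is exact and
invertible, and peaks are reported in genome coordinates through it.

## Parameters that matter

* **Substitution matrix — BLOSUM90** (default). A hard matrix favours
  short, high-identity alignments, the right shape for detecting small
  conserved footprints rather than long diffuse homology.
* **Bit-score threshold — 30.** The retention floor for hits. Raw scores
  are normalised to bits with the scheme's gapped Karlin–Altschul
  parameters (`bits = (λ·raw − ln K)/ln 2`); for BLOSUM90 with gap
  open 10 / extend 1 the published values λ = 0.290, K = 0.075 are the
  defaults. At ~28 the profile drowns in chance hits; at ~40 only genes
  findable by conventional search remain. Both λ/K and the gap costs are
  configuration, not constants, since no single choice is canonical.
* **E-value cap — 200,000.** Deliberately astronomical; its only role is
  to admit hits far below conventional significance while bounding
  degenerate cases. `E = m·n·2^(−bits)` with `m·n` defaulting to query
  length × total database residues.
* **Per-query cap — 10,000 hits**, best by bit score, for bounded memory
  on promiscuous queries.
* **SEG masking — window 12, locut 2.2, hicut 2.5 bits.** Low-complexity
  query stretches would otherwise accumulate spurious cross-cluster
  hits. Masking applies to the query only, mirroring standard search
  engines.
* **Peak cutoff — 70** in the reference genome-scale setting, but the
  meaningful definition is empirical: `calibrate_cutoff()` runs shuffled
  copies of the regions through the identical pipeline and returns one
  more than the chosen quantile (default: maximum) of the per-region
  maximum heights. On small synthetic databases the calibrated cutoff is
  correspondingly small; the cutoff scales with the database, not with
  the genome.

The database is assumed to hold **one representative per cluster**
(UniRef50-style). The distinct-cluster count then approximates "number
of independent protein lineages supporting this position". The
spec-level alternative — counting raw alignments — is available as
`distinct_clusters = FALSE`, but de-duplication is the default reading:
it is what bounds counts by database size and what makes redundant HSPs
harmless.

## The alignment engine

Internal searches use an affine-gap Smith–Waterman in compiled code (the
first residue of a gap costs `gap_open + gap_extend`, matching common
search engines — `pairwiseAlignment()` with the same parameters is used
as an independent cross-check in the test suite, and an exhaustive
dynamic-programming oracle plus a path-enumeration oracle verify raw
scores exactly on small inputs). Suboptimal alignments per
query–subject pair are recovered by masking the query residues used by
each alignment and re-running, bounded by `max_hsps_per_subject`
(default 16). This guarantees query-disjoint HSPs, which is exactly the
object the per-position profile consumes; subject-side overlap is
permitted and harmless because counting is per cluster. For large
databases the search can instead be run in an external engine and
re-imported from 12-column tabular output with `parse_external_hits()`,
which applies the identical filters and ordering.

## What the synthetic data emulates — and what it does not

`generate_protein_db()` builds families of records sharing exact
conserved blocks (default: 2 blocks of 18 residues) embedded in random
flanks, with blocks appearing in the same order at roughly conserved
relative positions — the minimal structure that produces the
many-distinct-clusters signal over a related query. Defaults are 200
clusters in 20 families of 10. `generate_genome_with_implants()` plants
back-translated (optionally mutated) database proteins into i.i.d.
background DNA at GC 0.36 (a yeast-like composition), each implant in
its own inter-exon region between dummy single-exon genes. Event kinds
cover intact genes, stop-riddled pseudogenes, +1-frameshifted
pseudogenes (insertions at evenly spaced codon boundaries, so conserved
signal falls on both sides of each shift), C-terminal subtractions
(first 65% retained) and internal foreign fragments (central 50%).
Synonymous codons are drawn uniformly; codon bias is deliberately not
modelled because the search operates on protein sequence.

Passing tests on this material demonstrate the machinery: exact profile
arithmetic, correct frame/strand attribution, calibration behaviour, and
recovery of diverged (20% substituted) implants against a null of
shuffled sequence. They do *not* demonstrate performance on real
genomes: real intergenic DNA is not i.i.d., real protein families share
diffuse similarity beyond block motifs, real databases are four orders
of magnitude larger (which is what pushes the calibrated cutoff up to
tens of accumulated sequences), and repeat content is richer than SEG's
window model. Claims about a particular genome require the external
search route against a real clustered database.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open in every user-facing table and in
  BED/bedGraph output; GFF3 input/output converts at the boundary.
  1-based interval arithmetic is delegated to IRanges internally.
* Regions shorter than 3 nt translate to empty frames with a warning;
  zero-length inter-exon gaps are skipped; duplicate FASTA identifiers
  and exons outside chromosome bounds are fatal.
* `≥ cutoff` is the default significance inequality, with
  `strict = TRUE` switching to `>`; the two differ only exactly at the
  cutoff. `merge_gap` (default 0) bridges sub-threshold gaps when
  merging runs; `min_length` (default 1) drops short runs. No smoothing
  is applied anywhere.
* Calibration uses the type-1 (order statistic) quantile so the returned
  cutoff is always an observed height plus one; it is therefore
  non-decreasing in the quantile level.
* Raising the cutoff shrinks peak coverage and never extends a peak, but
  can *split* one peak into several — a run property worth knowing when
  comparing peak counts across cutoffs.
* Hit ordering is fully deterministic (bit score desc, subject ID,
  query start), shuffles are seeded, and a scan writes byte-identical
  outputs for identical configuration and seed.
* SEG masking is idempotent by construction: masked residues stay
  masked and windows containing them are not re-evaluated.

## Problem sizes in the shipped tests

The suite exercises the full pipeline at desk scale: a 200-cluster
database, 11 implanted regions (~0.7 kb each), 50 shuffled control
regions for calibration and null behaviour, 500 randomised profile
recounts, 250+ alignment-oracle pairs (length ≤ 12) and 1,000 coordinate
round-trips. These sizes keep the default test run to a few minutes on
one CPU while still covering every event kind on both strands.

## Known limitations

* The built-in engine is exact but quadratic; genome × UniRef-scale
  searches belong in an external heuristic engine, re-imported through
  the tabular parser.
* No p-value model for peak heights is provided — significance is
  empirical by design, inherited from the shuffle calibration.
* Transcript structure beyond exon intervals is ignored (no UTR
  inference, no trans-splicing); pseudogene/transposon annotations are
  not treated specially, so their exons (if annotated as `exon`) shape
  the region set.
* Reverse-strand biology aside, the reversed-sequence control
  (`reverse_region()`) is a character reversal, not a reverse
  complement; it models "same composition, no coding meaning".
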