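---
title: "TaxoSpectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TaxoSpectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TaxoSpectra)
```

## The problem

Untargeted metabolomics produces tandem mass spectra (MS/MS) whose molecular
origin is usually unknown. When a reference collection of MS/MS runs acquired
from *microbial monocultures* is available, a match between an unknown
spectrum and a monoculture run ties the molecule to a taxon: monocultures make
the attribution unambiguous in a way mixed-community data cannot. TaxoSpectra
is a self-contained engine for exactly this workflow: it indexes a local
repository of monoculture MS/MS spectra, searches query spectra against it,
and aggregates the matches onto an NCBI-style taxonomic tree so the result is
read as "which organisms have produced this spectrum, and in what fraction of
their samples".

Everything is local and hermetic: the repository is a set of MGF files plus a
ten-column metadata table (file path, qualified file name, dataset accession,
taxon name, alternative taxon name, NCBI id, id-assignment provenance, ReDU
availability, blank flag, QC flag) and a parent-pointer lineage table. No
network lookups are performed.

## Scoring: the modified cosine

Two spectra are compared with the modified cosine score. A peak pair $(i, j)$
is *eligible* when the fragments agree directly,
$|m_i - m_j| \le \tau_f$, or after shifting the second spectrum's fragment by
the precursor mass difference $\Delta = p_a - p_b$,
$|m_i - (m_j + \Delta)| \le \tau_f$. The shift term is what lets a modified
molecule (one precursor heavier by a substituent) still match the fragments
that carry the modification. Intensities are square-root transformed and
L2-normalized per spectrum, each eligible pair is weighted by the product of
the two normalized intensities, and the score is the total weight of the best
one-to-one assignment of pairs (each peak used at most once). It therefore
lies in $[0, 1]$ and equals 1 for identical spectra.

Design choices worth stating:

* **Exact assignment.** The maximum-weight one-to-one selection is solved
  exactly with a Hungarian-algorithm solver on the (sparse, typically tiny)
  candidate-pair matrix, zero-padded so leaving a peak unmatched costs
  nothing. Exactness buys determinism and symmetry
  ($|s(a,b) - s(b,a)| < 10^{-9}$); the test suite cross-checks it against an
  independent exhaustive subset-DP enumeration on small spectra.
* **Square-root intensities by default.** The dominant practice in the
  repository-search ecosystem; `intensityTransform = "none"` is available and
  tested, and the choice is an explicit `SearchConfig` knob.
* **Matched-ion count.** Direct and shifted pairs both count toward the
  reported number of matching fragment ions (one number is reported, as one
  number is thresholded).
* **Inclusive thresholds.** "Minimum cosine 0.7, minimum 3 matched ions" are
  inclusive ($\ge$), so a match exactly at a boundary is accepted.

Default parameters are the conventional repository-search operating point:
precursor and fragment tolerances of 0.05 Th (absolute, not ppm), minimum
cosine 0.7, minimum matched ions 3, analogue search off. In analogue mode the
precursor window widens to 130 Th so related molecules can match through
shifted fragments.

## Candidate retrieval

References are indexed by precursor m/z (sorted vector; retrieval by two
binary searches, inclusive at both window bounds) and only candidates inside
the precursor window are scored. The index is content-fingerprinted so a
search can detect an index/metadata mismatch. We deliberately key the index
on precursor m/z alone: under an absolute-tolerance window, precursor
intensity plays no role in candidate eligibility.

## Taxonomic aggregation

The repository's taxonomy is held as a flat parent-pointer node table.
Counter semantics:

* Every biological file attaches at its resolved taxon node and contributes
  +1 to `n_files` along its full lineage; a match contributes +1 to
  `n_matched` the same way (upstream propagation). A file with several
  matching scans counts once in node counters — per-scan detail lives in the
  dataset-matches table.
* Files whose NCBI id is absent from the lineage table are rescued by name
  (alternative name first, then the reported name), mirroring the common
  curation of an unknown strain to its species; files that cannot be resolved
  at all go to an `Unclassified` pseudo-node with a warning, never silently.
* Blanks and QCs attach to dedicated pseudo-children of the root with
  reserved negative ids (−1, −2; −3 for unclassified) so they can never
  collide with NCBI ids and never inflate any taxon's counters — including
  the root's, whose `n_matched / n_files` is the biological-files proportion.
* Because real metadata can attach files at internal taxa (the fallback
  above), each node carries an own-attachment counter next to its subtree
  totals; conservation is `total = own + sum(children)` at every node, and
  the suite verifies it after random aggregation/filter sequences.

Filtering collapses the tree to a maximum rank (subtree totals stay on the
surviving ancestor, so proportions are preserved) and prunes nodes below a
minimum match count while keeping ancestors of retained nodes, so the
exported tree stays connected. Exports: nested JSON (the authoritative
format, round-trip tested), Newick with counters in comment blocks, and a
dependency-free static HTML rendering of collapsible lists.

## Cohort subtraction and domain partitioning

To mine candidate microbial spectra from a colonized-versus-germ-free animal
comparison, `subtractCohort()` removes colonized-cohort spectra that (a)
share a feature id with the germ-free cohort, then (b) have at least one
germ-free spectrum with cosine **strictly** greater than 0.7 at a precursor
delta within ±0.02 Th. The strict inequality matters: a pair exactly at 0.7
is retained, and the suite pins this with a spectrum pair engineered to score
exactly 7/10 (transformed intensities (7, 5, 5, 1) have L2 norm exactly 10).
Retention is monotone in the cosine threshold by construction.

Searched queries are then partitioned by the producer domain of their matched
files, derived from the lineage: any host-cell-line match (recognized as a
*Homo sapiens* / Metazoa lineage) takes precedence, then bacteria-only /
fungi-only / both / unmatched; files with an underivable domain are counted
in an explicit ambiguous bin rather than dropped.

## The synthetic repository generator

Tests and the acceptance script run against a deterministic generator
(`fixtureSpec()` / `makeRepository()` / `makeQueries()` / `makeCohorts()`)
whose seed fully determines every artefact. It emulates the structural
features the engine depends on:

* a taxonomy with bacteria and fungi under halving rank ladders (phylum to
  species) plus *Homo sapiens* for host cell lines;
* per-taxon "producer" fragment patterns — 8–40 peaks drawn on a 0.01 Th grid
  in 80–1500 Th with log-normal intensities, precursors in 150–1200 Th —
  chosen as realistic sparsity for tolerance-based matching;
* blank/QC files carrying shared contaminant patterns, a host-shared
  bacterial pattern (to exercise host-match precedence), one species emitted
  without an NCBI id (to exercise the name fallback), and analogue-shifted
  query variants whose shifted precursor is guaranteed clear of every
  reference precursor, so they match only in analogue mode;
* query noise of 0.005 Th m/z jitter and 10% intensity coefficient of
  variation — an optimistic but plausible high-resolution replicate noise
  level. Negative-control queries are placed beyond every reference
  precursor window by construction, so their zero-match expectation is a
  property of the design, not luck.

What the generator does **not** emulate: chromatography, isotope envelopes,
adducts, co-isolation chimeras, instrument-specific noise, or the long-tail
intensity structure of real repositories. Passing tests therefore demonstrate
the correctness of the machinery (scoring, retrieval, aggregation,
bookkeeping) under controlled conditions, not real-world recall; on real
data, recall depends on acquisition variability the generator deliberately
leaves out.

## Numerical and degenerate-input choices

* Peaks closer than $10^{-5}$ Th are merged (intensity sum at the
  intensity-weighted mean m/z) at construction, preventing double-counting in
  the assignment; whether hosted tools deduplicate is unstated, so this is a
  documented local choice.
* Scores are clipped at 1 after summation to absorb last-ulp overshoot;
  self-similarity is asserted to $10^{-9}$.
* Zero-weight candidate pairs never count as matched ions, so degenerate
  zero-intensity peaks cannot inflate ion counts.
* Spectra without a precursor are representable and flagged unsearchable;
  readers never drop them silently. Empty files, empty libraries, and empty
  match sets all produce empty-but-valid results.
* Charge is carried but unused: all tolerances operate in m/z space.
* Scan numbers follow the source file verbatim so USIs round-trip.

## Validation problem sizes

The shipped suite validates the scorer against exhaustive enumeration on
1,000 random small-spectrum pairs (≤8 peaks), index retrieval against a
linear scan on 1,000 queries × 5,000 references in both windowing modes,
count conservation over 100 random match subsets on a 40-taxon repository,
and planted-taxon recovery with 200 positive and 50 negative queries against
a 50-taxon repository at the default operating point — sizes chosen so the
whole suite stays interactive on a laptop while every code path is exercised
at meaningful multiplicity. `scripts/acceptance.R` recomputes the same
quantities from scratch against the installed package.

## Known limitations

* Absolute (Th) tolerances only; no ppm mode.
* No mzML/mzXML parsing — convert upstream to MGF.
* One taxonomy source (supplied lineage table); no GTDB/SILVA mapping.
* The analogue search considers a single precursor-difference shift per
  pair, the standard modified-cosine construction; neutral-loss-only and
  entropy-based scores are out of scope.
* Upstream feature extraction (clustering/molecular networking) is assumed
  done; cohort inputs are consensus spectra.
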