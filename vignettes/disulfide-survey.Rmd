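---
title: "Estimating proteome-scale disulfide abundance by sequence-structure mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating proteome-scale disulfide abundance by sequence-structure mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysmapr)
```

## The model

Thermophilic archaea — above all the Crenarchaea — stabilise many cytosolic
proteins with disulfide bonds, in sharp contrast to the reducing cytosol of
bacteria and eukaryotes. Direct structural evidence exists for only a
handful of organisms, so proteome-wide estimates must be inferred from
sequence. `cysmapr` implements the sequence-to-structure mapping estimator
of that inference, plus the two companion analyses used to sanity-check it.

The central assumption is geometric: if two cysteines of a query protein
form a disulfide, then when the query is overlaid onto the structure of a
homologous protein, those two positions must end up close in space. The
estimator therefore:

1. filters the proteome (below);
2. finds, for each protein, the best homologous chain in a
   structure-sequence library, accepting a hit only when `E < 1e-4`;
3. realigns query and chain sequence by full dynamic programming — search
   coordinates are not trusted near indels;
4. places each eligible cysteine at the C-alpha of its aligned residue (the
   aligned residue need *not* be a cysteine: the question is where the
   query's cysteine would sit if the query folded like the homolog);
5. counts a mapped cysteine as a **hit** when another mapped cysteine of the
   same chain lies strictly closer than 8 Å, C-alpha to C-alpha — and counts
   it once, regardless of partner multiplicity;
6. pools over the proteome: `f = total hits / total mapped cysteines (m)`.

`f` is a *pooled ratio*, not a mean of per-protein fractions: proteins with
many mapped cysteines carry proportionally more weight, and proteins with a
single mapped cysteine (which can never be a hit) dilute the estimate
rather than contributing a hard zero. Per-protein fractions are reported
for diagnostics only. Because alignment errors and genuine structural
divergence can only push paired cysteines apart, not conjure proximity, the
estimator is biased *downward*; the parameter-recovery tests confirm the
signed bias is ≤ 0 on matched protein sets.

The control `f′` asks the same question of deposited structures directly:
cysteines appearing in `SSBOND` records over cysteines observed in `ATOM`
records. `LINK`-record cysteines (typically metal- or ligand-coordinating)
are excluded from both sides, and any entry binding Zn or Fe is dropped
wholesale, since metal sites would masquerade as disulfide-competent
cysteine clusters. Near-duplicate chains (≥ 95 % identity, with ≥ 80 %
coverage of the shorter chain) collapse to the first-seen representative so
heavily re-deposited proteins count once; the identity threshold and the
metal list are arguments, because reasonable surveys could include Ni or Cu.

The parity analysis is the cheap cross-check: in a proteome where most
cysteines are paired, proteins with an even cysteine count are
over-represented. `parity_table()` tabulates proteins by raw cysteine count
within a 150–200 residue window (mid-sized proteins show the effect most
clearly; the window is configurable), and `parity_bias()` reduces the table
to `(even≥2 − odd≥3)/(even≥2 + odd≥3)` with an exact binomial p-value at
null probability ½. The scalar and its test are an extension of the visual
analysis — report output labels them as such.

## Filters and their order

* **Minimum cysteines** (`min_cys = 2`, raw count): a protein with fewer
  than two cysteines cannot carry an intramolecular disulfide.
* **Secretion filter**: secreted and periplasmic proteins form disulfides
  in any organism, so they are removed before anything else is counted.
  The built-in predictor is a deliberate, documented three-rule heuristic
  (basic residue in the first 7; a 10-residue window starting in residues
  2–25 with ≥ 8 hydrophobics; a −3/−1 small-residue cleavage site in
  residues 15–40) — a stand-in for trained tools, not a reimplementation of
  one. For faithful reproduction of a published filtering step, supply
  externally computed calls via `mode = "exclusion_list"`.
* **Clustering mask** (`cluster_spacing = 5`): cysteines within 5 residues
  of each other in sequence — both members of the close pair — are masked
  from *mapping eligibility*, as a proxy for metal-binding motifs such as
  CXXC. The mask never removes a protein, and a protein whose eligible set
  drops below two simply contributes zero mapped cysteines.

"Within 5 residues" is read conservatively as separation ≤ 5; the boundary
case (separation exactly 5 masks, 6 does not) is pinned by tests and the
threshold is an argument. The documented order is min-cys → secretion →
clustering; the parity analysis runs after the secretion filter but uses
raw counts (whole-protein totals are what the even/odd argument is about),
while the clustering mask applies only to structure mapping.

## Alignment choices

The realignment step is a Gotoh affine-gap dynamic program (Rcpp) under
BLOSUM62, gap open 11, gap extend 1, with a gap of length L costing
`open + L·extend`. End gaps are free by default ("overlap" mode): deposited
chains are frequently fragments, and charging terminal gaps would drag the
aligned core around. `type = "global"` gives the strict end-to-end variant.
The original survey did not state its matrix, penalties, or end-gap
treatment; these defaults are this package's documented choices, not
inferred values. Traceback ties break deterministically (diagonal, then
gap-in-target, then gap-in-query; endpoints scanned last row then last
column, first maximum kept), so reruns are byte-identical. Scores are
integer-valued sums compared with a 1e-9 tolerance in the C++ kernel.
Letters outside the matrix alphabet score as `X`; selenocysteine `U` is
never counted as cysteine (the survey counts cysteines proper — a
documented, togglable decision).

The internal homology search scores each library chain by local
Smith–Waterman (delegated to `Biostrings::pairwiseAlignment`) and converts
scores to E-values with fixed Karlin–Altschul constants (λ = 0.267,
K = 0.041; gapped BLOSUM62 11/1 convention). This is a self-contained
stand-in for an external BLAST run: it is calibrated to reproduce
accept/reject behaviour at the `1e-4` gate on synthetic data, not BLAST's
exact numbers. Pre-computed hits in the 12-column blast-tabular dialect are
accepted as an alternative input path, which is how a production survey
against the real PDB would be run. Hits sort by ascending E-value, ties by
descending score then lexicographic target id; exactly one structure — the
best hit — is used per protein.

Only intra-chain distances enter the hit count. Intermolecular disulfides
are real (they are one favoured explanation for odd cysteine counts) but
invisible to this criterion; `annotate_odd_case()` flags mapped non-hit
cysteines as metal-proximal (CA within 8 Å of a metal atom), surface
candidates (< 12 neighbouring CAs within 10 Å) or buried.

## The synthetic-data generator

`generate_proteome()` builds the study conditions every test runs under.
Each protein derives from a generated structure: a persistent 3-D C-alpha
walk with 3.8 Å steps and soft self-avoidance (non-adjacent CAs re-sampled
below 3.5 Å, bounded retries). Planted disulfide pairs close onto a
sphere-shell intersection so their CA separation falls in 4.0–6.5 Å —
inside the 8 Å criterion with margin — while planted free cysteines must
end ≥ 10 Å from every other cysteine, outside it. Both windows are
arguments so the boundary can be probed. Queries are the structure
sequences with substitutions at the divergence rate (planted cysteines are
preserved unless the cysteine-loss option is used, and substitutions never
*create* cysteines); a fraction of proteins get a signal-peptide prefix
satisfying the heuristic, a CXXC motif with a Zn atom and LINK records, or
one extra unpaired cysteine. The realized pooled `true_f` — recomputed from
the actual plantings of non-secreted proteins — is recorded and is the
authoritative truth value; `true_f = 1` with a nonzero odd-cysteine
fraction is rejected as infeasible.

Defaults: 100 proteins of 120–180 residues, divergence 0.1, secreted
fraction 0.1, metal-motif fraction 0.1, odd-cysteine fraction 0.05. For the
sequence-only parity generator the independent-cysteine rate defaults to
0.03 (~5 cysteines per 150–200 aa protein). That rate is chosen for the
statistic, not for realism alone: the bias truncates at even ≥ 2 / odd ≥ 3,
and for Poisson-like counts with mean ≈ 3 that truncation alone pushes the
expected "bias" to ≈ +0.12 even under independence; at mean ≈ 5 the
truncation term falls to ≈ 0.03, so the null behaves like a null. This is
a small-count limitation of the parity statistic worth remembering when
applying it to cysteine-poor real proteomes.

What the generator does *not* emulate: real protein folds (CA walks have no
secondary structure or compact core), homology search against unrelated
superfamilies (every query has exactly one true source), insertions and
deletions between query and structure (divergence is substitution-only),
partial-coverage fragment structures, and inter-chain contacts. Passing
tests therefore demonstrate the correctness of the machinery — filters,
search gating, realignment, placement, counting, pooling — under controlled
truth, not survey accuracy on any real proteome, which depends on database
coverage and genuine structural divergence.

## Validation scales

The suite validates the alignment kernel against exhaustive enumeration of
all alignments (200 random pairs up to length 7, overlap and global modes),
proximity counting against O(n²) scans (500 random point sets up to 12
points), f′ against hand-kept bookkeeping on 20 planted fixtures (exact),
parameter recovery on 200-protein bundles at planted fractions 0, 0.3, 0.6
and 0.9 with 10 % divergence (within 0.10, and exactly 0 and 1 at zero
divergence), and the parity null over 200 replicates of 300-protein
proteomes (mean |bias| < 0.1). `scripts/acceptance.R` re-runs these
computations from scratch under a caller-supplied seed.

## Known limitations

* `f` underestimates true disulfide abundance by construction (coverage,
  divergence, intermolecular bonds); the original survey makes the same
  point, and the f′ control exists precisely to calibrate this.
* The heuristic secretion filter trades accuracy for self-containment; its
  measured recall on planted motifs is high but its false-positive rate on
  arbitrary sequences is a few percent, which slightly perturbs which
  proteins enter the pool (never systematically toward higher f).
* E-values from the internal search are not BLAST E-values; use tabular
  input when comparability matters.
* PDB parsing covers the fixed-column records the pipeline needs
  (ATOM/HETATM/SSBOND/LINK/HEADER, first altloc, insertion codes carried);
  mmCIF is out of scope.
* Strain deduplication defines the parent as the first-listed proteome, as
  the choice of parent is otherwise underdetermined; pass an explicit
  ordering for a different convention. The ±10 % rule compares mapped
  protein counts only, with the comparison tolerance as an argument.
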