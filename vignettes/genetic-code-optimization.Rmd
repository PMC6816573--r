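---
title: "Methods: genetic-code optimization as a traveling salesman problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic-code optimization as a traveling salesman problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopcode)
```

This vignette records the model, the parameter conventions, and the
numerical and design decisions behind `hopcode`, including the places where
the package deliberately departs from face-value readings of the source
material it reimplements.

## The model in brief

A genetic code is a total map from 64 codons to 21 labels (20 amino acids
plus stop). The package treats the *layout* of a code as a cyclic tour of
the 21 labels through an index space, threaded onto codons by a fixed
codon wheel. Error minimization then becomes tour-length minimization:
codes whose wheel-adjacent labels are physio-chemically similar make
single-nucleotide mutations cheap.

Three ingredients are fixed by construction and tested exhaustively:

* **Index table.** Each of the four indices (polarity, hydrophobicity,
  volume, isoelectric point) is z-scored over the 20 amino acids with the
  sample standard deviation (denominator $n-1$). This denominator is not a
  matter of taste: it is pinned by requiring the recomputed values to agree
  with the published normalized table at 4 significant figures, which the
  population convention fails for every cell. Three published cells are
  inconsistent with their own raw values (Leu polarity, and the signs of
  Trp and Tyr hydrophobicity); `index_table_discrepancies()` flags them, the
  recomputed z-scores are operative, and the published variants remain
  available via `aa_index_table("printed")`. The stop signal never enters
  the normalization; its coordinates are fixed outlier pseudo-values.
* **Codon wheel.** A reflected base-4 Gray code over the codon positions
  ordered (3rd fastest, 1st, 2nd slowest), bases cycling in the order given
  by the wheel variant (default `AGCTTCGA`). Every adjacent pair, including
  the wrap-around, differs at one base, and the step census is always
  48/12/4 by position (3rd/1st/2nd). Addresses rank the reference code's
  synonymous classes by first encounter along the wheel. A worked example
  in the source material labels the final codon ATA with address 21, which
  no consistent ranking reproduces (Ile's class is first met at ATT; the
  standard code forms 25 contiguous runs on the wheel, not 21). The package
  uses strict first-encounter ranking of the 21 classes, with the stop
  class taking a rank like any other. The choice affects only which wheel
  segment carries which rank — not the block structure, and therefore not
  any error statistic.
* **Tour-to-code mapping.** `code_from_path()` assigns the label at tour
  position $k$ to all codons with address $k$. Because addresses coincide
  with synonymous classes, every generated code preserves the standard
  block-size multiset, and a uniformly random tour is *exactly* a uniform
  permutation of labels among blocks — the permutation null and the mapping
  are two views of one scheme, which the test suite checks distributionally.

## The error statistic and its degeneracy ambiguity

The mutational error of a code is a transition-weighted mean of
$|X_i - X_j|$ over stop-free single-base codon pairs, with transitions
(A↔G, C↔T) weighted $w = 5$ and transversions 1, the denominator being the
total weight. The double sum over codon pairs admits two readings that
differ in how codon degeneracy enters:

* `collapse = "codon"`: every codon pair counts. Repeated exchanges —
  e.g. the four CUx→GUx pairs all exchanging Leu for Val at position 1 —
  enter four times. With $w = 1$ this is the plain mean over the standard
  code's 263 pairs.
* `collapse = "type"` (default): pairs are first collapsed to distinct
  substitution types (amino-acid pair × position × transition/transversion),
  so each distinct exchange enters once.

Both are implemented; the collapsed form is the default because it is the
form under which the permutation analysis reproduces the published
significance pattern of the standard code across all four indices — most
sharply for the isoelectric point, where the codon-pair form places the
standard code *below* the null mean (one-sided $p \approx 0.3$) while the
collapsed form places it slightly above ($z \approx +0.35$,
$p \approx 0.65$), matching the published non-significance. Under the
collapsed statistic the standard code sits near $-2.9$ null standard
deviations for polarity, $-2.2$ for hydrophobicity, $-1.8$ for volume. The
published polarity p-value (0.010) corresponds to a milder $z \approx -2.3$
than either reading produces; this residual disagreement is documented
rather than fitted away, and the package's computed proportions stand.

Per-category summaries (position × ti/tv) are always reported at codon-pair
level, since the category census (263 pairs partitioned into six classes)
is itself a quantity of interest.

The permutation null draws uniform bijections of the 21 labels onto the 21
synonymous blocks, so the stop block moves and the stop-free pair count $n$
is recomputed per draw (258–279 depending on where stop lands). Empirical
p-values are one-sided lower-tail proportions with no multiple-testing
correction across indices (none is applied in the analysis being
reproduced); a one-sample t-test of the null sample against the observed
error is reported as a secondary statistic only.

## The solver

The mean field on neuron $(X, i)$ couples an occupancy penalty (weight
`d_p`) with distance terms to the cyclically adjacent tour positions;
activities are renormalized per city by a Boltzmann (softmax) rule at
temperature `T`. Numerical conventions:

* **Asynchronous updates.** One city row is recomputed at a time, in random
  order within a sweep. Synchronous full-matrix updates oscillate
  indefinitely at working temperatures (a familiar failure mode of
  parallel softmax dynamics) and are retained only behind
  `update = "sync"` for study.
* **Distance normalization.** Input distance matrices are divided by their
  maximum entry by default, so the canonical `d_p = 0.7`, `T = 0.1` operate
  on a common scale regardless of how many indices enter the distance.
  After normalization the 21-city single-index instances yield valid tours
  at high rates; denser or smaller instances may need a stronger penalty
  (the small-instance tests use `d_p = 2`).
* **Annealing.** `temp` is the working temperature. With
  `anneal_from = 0.5` the temperature cools geometrically (factor `cool =
  0.98` per sweep) to the floor; annealed runs converge essentially always
  and find near-optimal tours, while fixed-temperature runs yield a mix of
  valid and invalid decodings. Ensembles anneal by default.
* **Convergence and decoding.** Convergence is a maximum activity change
  below `tol = 1e-6` in a sweep (cap 10000 sweeps). Tours are decoded by
  per-position argmax over cities, ties broken by lowest index; a decoding
  that misses or repeats a city is an *invalid verdict*, not an exception,
  and invalid tours are discarded rather than repaired. Softmax rows are
  computed with a log-sum-exp guard, so extreme `-E/T` ratios cannot
  overflow.
* **Initialization.** Activities start at $0.5 \pm 0.1$ uniform. The
  softmax makes rows stochastic from the first update onward.

`tsp_brute_force()` provides the exact optimum by exhaustive enumeration
($n \le 9$), used as the independent yardstick: across random small
instances, the best of 100 annealed restarts matches the exhaustive optimum
(the tests require ≥90% of instances within 5%; in practice all instances
hit the optimum exactly).

## Index geometry conventions

Whether the stop pseudo-entry joins the PCA and correlation is a genuine
free choice. The package includes it by default: with stop included the
polarity–hydrophobicity correlation is $-0.807$, matching the published
$-0.81$ at two decimals (without it, $-0.78$). PCA is computed on the
correlation matrix (`scale. = TRUE`). Under this convention the first two
components explain about 47.4% and 38.4% of variance against published
values of 48.73% and 37.96%; no convention tested (with/without stop,
covariance/correlation, computed/published table) reproduces those figures
exactly, the closest being the published-typo table with stop (48.5/38.4).
The acceptance test therefore asserts the correlation at printed precision
and the variance fractions within 1.5 percentage points.

## Ensembles, reported fractions, and a known shortfall

`run_ensemble()` solves the tour repeatedly, maps valid tours to codes,
scores all four indices, and normalizes against a single shared
block-permutation null per index (default 1000 draws). The
fraction-beating-SGC is computed per restart batch (default 100) and
averaged. Everything derives from one seed: the same configuration and seed
reproduce the ensemble byte-for-byte.

One published quantity is *not* reproduced and deserves a frank account:
the claim that on average ~89% of polarity-optimized codes beat the
standard code on polarity. The tour-to-code mapping has a free cyclic
phase: a tour can enter the wheel at any of 21 rotations (and 2
directions), and the solver has no way to prefer one, since all phases have
equal tour length. Enumerating the phases of even the *globally optimal*
polarity tour shows only about two-thirds of them beat the standard code —
the standard code is simply too polarity-optimized, under either form of
the statistic, for a phase-blind mapping to beat it nine times in ten.
Measured ensembles land near 30–45% depending on annealing. The package
reports the honestly computed fraction. The companion quantity — the best
code's optimality ratio, $\{\Delta(\mathrm{Mean}) - \Delta(\mathrm{SGC})\}
/ \{\Delta(\mathrm{Mean}) - \Delta(\mathrm{Code})\} \times 100$, where
100% means matching the standard code and smaller is better — is
reproduced comfortably: annealed ensembles of a few hundred restarts
typically reach 55–70%, beating the published best of 48% in the
smaller-is-better sense.

## Synthetic fixtures and what the tests show

`generate_fixture()` supplies the deterministic synthetic inputs used by
the test suite: small symmetric random distance matrices for the solver
oracle, block-permuted codes, and toy index tables with known correlation
structure. These probe the machinery, not biology: random uniform distances
have no metric embedding or cluster structure, and toy tables have no
physio-chemical meaning, so passing tests certify the algorithms (exact
field evaluation, row-stochasticity, block preservation, oracle optimality)
rather than any claim about real amino-acid data — those claims rest on the
bundled index table and the permutation analyses above.

Problem sizes used by the checks: permutation tests run 1000 draws in the
acceptance script (3000 in the test suite, which tightens the Monte-Carlo
error of the estimate while keeping the published-precision comparison
band); ensembles use 150 restarts in the tests and 300 in the acceptance
script; the solver oracle uses instances of 5–7 cities with 100 restarts.

## Known limitations

* The solver is a local optimizer; single restarts can and do return tours
  worse than the standard code's layout. All headline numbers are ensemble
  or best-of-restart quantities.
* The three inconsistent table cells and the exact PCA variance fractions
  cannot be reconciled with their published values from the shipped raw
  data; the package flags rather than patches them.
* The 89%-beating fraction is structurally unattainable under a
  phase-blind tour-to-code mapping (see above); results for that quantity
  should be read accordingly.
* Only the four bundled indices are supported; alternative index sets and
  any phylogenetic machinery are out of scope.
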