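---
title: "Designing fluorescent molecules by tree search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing fluorescent molecules by tree search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluortree)
```

## The design problem

A simple fluorophore absorbs at wavelength $a_w$ with oscillator strength
(OS) $a_i$, relaxes to the minimum of its first excited singlet state, and
emits at $f_w$ with OS $f_i$. Designing molecules whose quadruple
$(a_w, a_i, f_w, f_i)$ sits in a target region is hard because fluorescence
correlates only weakly with simple structural descriptors; the approach
implemented here is therefore generative: a Monte Carlo tree search (MCTS)
writes SMILES strings token by token, a photophysics evaluator scores each
completed molecule, and a reward function turns the quadruple into a single
number the search maximizes.

The expensive part of a real deployment — TD-DFT calculations at both the
S$_0$ and S$_1$ minima — is isolated behind a one-function evaluator
contract. The package ships a deterministic closed-form surrogate for
development and testing, plus the two halves of a quantum-chemistry
adapter: an input-deck writer and a TD-DFT log parser. Executing a QC
engine is deliberately out of scope.

## The reward

$$R = W_{aw} e^{-\frac{(a_w - T_{aw})^2}{2\sigma_a^2}}
  + W_{ai}\,\tanh\!\big[(\log_{10}(a_i+\epsilon) - \log_{10} T_{ai})^2\big]
  + W_{fw} e^{-\frac{(f_w - T_{fw})^2}{2\sigma_f^2}}
  + W_{fi}\,\tanh\!\big[(\log_{10}(f_i+\epsilon) - \log_{10} T_{fi})^2\big]$$

Defaults (all tunable through `reward_params()`):

| parameter | default | unit | role |
|---|---|---|---|
| $T_{aw}$, $T_{fw}$ | 700, 1200 | nm | wavelength targets (near-infrared window) |
| $T_{ai}$, $T_{fi}$ | 0.01, 0.01 | — | OS thresholds |
| $W_{aw}, W_{ai}, W_{fw}, W_{fi}$ | 0.4, 0.1, 0.4, 0.1 | — | weights (sum to 1, so $R \in [0,1]$) |
| $\sigma_a$, $\sigma_f$ | 150, 150 | nm | Gaussian widths |
| $\epsilon$ | $10^{-8}$ | — | floor inside the logarithm |

Two readings of the OS term are provided because the squared form has a
counterintuitive property: it rewards oscillator strengths far *below* the
threshold exactly as much as far above it (the square erases the sign of
the log-ratio). `os_variant = "literal_squared"` (the default) keeps the
squared form; `"signed_monotone"` uses
$\max(0, \tanh(\log_{10}(x+\epsilon) - \log_{10}T))$, which is zero at or
below threshold and increases monotonically above it. Every test and
reported number states which variant it uses; the default is used unless
said otherwise. Profiles whose evaluation failed score exactly 0 — this
keeps the reward bounded and teaches the tree to avoid regions that
produce unevaluable strings.

## The search

Each tree node holds a token prefix, cumulative reward $R_i$, completed
visits $v_i$, virtual visits $w_i$ and a prior $P_i$. Selection descends by

$$S_i = \frac{R_i}{v_i + w_i}
  + C\, P_i \frac{\sqrt{v_p + w_p}}{1 + v_i + w_i}, \qquad C = 4,$$

with three numerical conventions, chosen once and fixed:

* **Unvisited nodes** ($v_i + w_i = 0$): the exploitation term is defined
  as 0 rather than infinite, so first visits are driven by the prior and
  no division by zero occurs. This meshes with the virtual-loss
  bookkeeping, which must be able to decrement to zero.
* **Square root**: the exploration numerator is $\sqrt{v_p + w_p}$, the
  standard PUCT form.
* **Ties** break toward the lowest vocabulary index, making single-worker
  runs bit-reproducible.

Virtual loss adds 1 to $w$ on every node of a selection path the moment
the path is chosen, and removes it at backpropagation. With
`n_workers > 1` the coordinator selects that many paths before evaluating
any of them, so the in-flight paths repel each other exactly as they would
across genuinely parallel workers. The coordinator remains the only writer
of the tree; evaluation is the only batched stage. This in-process batching
satisfies the same contract as a multi-process deployment while keeping
`n_workers = 1` runs deterministic under a fixed seed, which is what the
correctness tests need.

Rollouts sample a completion of the leaf's prefix from the prior. Invalid
strings (syntax, valence, element constraint) and unterminated samples
backpropagate reward 0 — they consume a visit, so the tree learns to avoid
them, but they do not consume budget: `budget` counts oracle evaluations
of valid, previously unseen molecules. Duplicates (same canonical SMILES
through a different token sequence) are served from the evaluation cache
and never receive a second generation index, so the run ledger is
deduplicated by construction. Because small grammars can be exhausted
before `budget` is met, `max_rollouts` and `stall_limit` (rollouts without
a new unique molecule) bound every run.

## The prior

The prior is a contract — a conditional next-token distribution plus a
sampler — not a specific architecture; search correctness is independent
of prior quality, which the search-versus-enumeration test demonstrates
with a deliberately crude prior. Two implementations ship:

* an interpolated **n-gram back-off** model (default order 4, add-$\alpha$
  smoothing with $\alpha = 0.2$ down to a uniform base), deterministic and
  trained in one counting pass — the fast choice for tests and small runs;
* a single-layer **Elman recurrent network** over one-hot token embeddings
  (hidden width 24, full backpropagation through time, Adagrad with
  learning rate 0.5, gradient clipping at $\pm 5$), written directly in R.
  At the vocabulary sizes of H/C/N/O SMILES (15–30 tokens) it trains on
  desk-scale corpora in seconds and its held-out likelihood improves
  monotonically over early epochs, which the suite asserts.

The tokenizer keeps bracket atoms (`[nH]`), `Cl`/`Br` and `%NN` ring
closures as single tokens so arbitrary corpora load, even though the
default element filter restricts generated molecules to H, C, N, O — the
composition of the corpus this generator targets. Begin/end sentinels are
never emitted inside a sequence; the begin token's probability is clamped
to zero and the distribution renormalized.

## Molecules and descriptors

SMILES handling is delegated to OpenBabel (via ChemmineOB/ChemmineR) for
canonicalization, kekulization and ring perception, with two defensive
layers written in-package because OpenBabel *repairs* rather than rejects
some malformed input: a syntax screen (balanced branches and ring-bond
digits, no dangling bonds) runs before OpenBabel, and a valence check (sum
of explicit bond orders against standard valences, charge-adjusted) plus
an atom-count cross-check run after it. A string that any layer rejects is
an invalid rollout, never a silently fixed one.

Two descriptors feed the surrogate and the run analysis:

* **Aromatic ring count** — the number of rings in a smallest ring basis
  (SSSR) whose bonds are all aromatic. Candidate rings and per-ring
  aromaticity come from ChemmineR; the basis is selected greedily by GF(2)
  independence over edge space, smallest rings first, and its size is
  fixed by the cyclomatic number, so fused-system envelopes (e.g. the
  10-membered perimeter of naphthalene) are never counted.
* **Conjugation length** — the maximum number of double bonds along any
  simple path whose bond orders strictly alternate single/double, counted
  on the kekulized graph; a lone double bond counts as 1, triple bonds do
  not participate. Aggregating by the *longest chain* (rather than a
  global sum) is a design choice: "length" reads as a path extent, and it
  gives kekulized benzene the intuitive value 3. Kekulization is made
  deterministic by always deriving structure from the canonical SMILES,
  so every writing of a molecule yields the same kekulé assignment and
  the descriptor is well-defined per molecule. Both descriptors are
  checked against independent exhaustive-path and cyclomatic-number
  oracles in the suite, and for invariance across randomized atom
  orderings.

## The evaluators

`make_oracle()` wraps any function from a molecule to a profile.
`oracle_evaluate()` adds two guarantees the search relies on: results are
cached by canonical SMILES (a duplicate is never re-evaluated — the suite
checks the underlying evaluator runs once), and every failure becomes an
`evaluation_failed` profile rather than an exception.

The **surrogate** is a fixed closed form over the descriptors
($L$ = conjugation length, $A$ = ring count, $N$ = nitrogen count):
$a_w = 150 + 55L + 15A$ nm, $a_i = 1 - e^{-0.15(L+1)}$,
$f_w = a_w + 40 + 10N$ nm, $f_i = a_i e^{-0.1A}$. It reproduces the
qualitative structure–property trends that matter for testing — absorption
red-shifts strictly with conjugation at fixed ring count, emission always
lies red of absorption — and it is exactly linear in $L$ at fixed $A$,
which turns the correlation analysis into a parameter-recovery check. What
it does **not** emulate: the scatter of real TD-DFT results around any
structural trend, evaluation failures, charge-transfer effects, or
Stokes shifts beyond $40 + 10N$ nm — under the default filter the 100 nm
shift criterion is therefore rarely if ever met by surrogate profiles.
Consequently a green suite shows the machinery is correct, not that the
surrogate's chemistry is realistic.

The **QC adapter** writes Gaussian-style input decks (route section with
the level of theory, `td=(nstates=10)`, and `root=1` for the excited-state
optimization stage; charge/multiplicity; Cartesian block) and parses
excited-state announcement lines from TD-DFT logs. Defaults follow the
protocol this generator targets: B3LYP/3-21G*, the lowest 10 states at
each of the S$_0$ and S$_1$ minima. When geometry optimization repeats the
TD block, only the final block is returned. Wavelengths are recomputed
from parsed energies with $hc = 1239.84193$ eV·nm, so printed roundings in
a log (energies to 2 decimals) can move a wavelength by up to ~1 nm
relative to a printed value; comparisons honor that. S$_1$ properties are
read from excited state 1 of both runs; state reordering along the
optimization is out of scope. Deck coordinates use one deterministic
planar sketch embedding per canonical SMILES — sufficient for byte-stable
decks and round-trip testing; a real deployment plugs a 3D embedder into
the same slot.

## Filtering and analysis

The screening criteria — absorption OS $> 0.1$; fluorescence wavelength
$> 400$ nm with OS $> 0.01$; shift $> 100$ nm — are strict inequalities by
default. "Greater than" is read literally; a `strict = FALSE` switch makes
every comparison inclusive, so boundary profiles are decided by an
explicit flag, never silently. Percentages are reported with 2-decimal
half-up rounding. The median generation index of a selected subset uses
the lower median for even counts. The scatter summaries are reduced to a
binned data structure (wavelength × OS × descriptor counts per band);
`autoplot()`/`plot_photophysics()` render it but the tabular form is the
contract.

## Problem sizes and reproducibility

The suite and the acceptance script are sized for a single CPU: the
bundled corpus has 201 unique H/C/N/O molecules (training corpora of 500
strings are resampled from it where a larger corpus is wanted); the
search-versus-enumeration check uses the `{C, O, =}` grammar at up to six
tokens, whose unique valid molecules can be enumerated exhaustively, with
single-worker budget 300 over ten seeds and one four-worker run; the live
acceptance run uses budget 300 on the bundled corpus. Every stochastic
step — prior initialization and shuffling, rollout sampling, profile
draws — flows from a single integer seed, and single-worker searches are
bit-reproducible.

## Known limitations

* The OS reward's squared default rewards very weak transitions far below
  threshold; use `"signed_monotone"` when that matters.
* Aromaticity follows the OpenBabel/ChemmineR model; systems where
  chemists disagree about aromatic perception (some fused heterocycles)
  follow that model's verdict.
* The conjugation descriptor is path-based; cross-conjugated systems
  score by their longest branch only.
* The parallel coordinator emulates concurrency in-process; wall-clock
  scaling across machines is not part of the contract.
* Stereochemistry, conformer ensembles and 3D embedding quality are out
  of scope throughout.
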