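---
title: "Weighted entropic associative memory: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted entropic associative memory: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weam)
```

## The model

An associative memory register (AMR) is an $n \times m$ table whose columns
are arguments (features) and whose rows are discrete values. The register
stores a weighted relation $r$: cell $(i, j)$ holds a non-negative integer
weight $w_{ij}$, and the pair $(a_i, v_j)$ belongs to $r$ exactly when
$w_{ij} > 0$. Remembered objects are *feature functions* — total assignments
of one value to each argument — and many functions are overlapped on the
same table, which makes the representation declarative but distributed.

Registration ($\lambda$) is additive: each cell addressed by the cue is
incremented by one, so frequently used cells accumulate weight. Column $i$,
normalized by its total weight $W_i = \sum_j w_{ij}$, is a probability
distribution $\Psi_i$ with $p_{ij} = w_{ij} / W_i$, and its Shannon entropy
is
$$e_i = -\sum_j p_{ij} \log_2 p_{ij}, \qquad 0 \log_2 0 = 0 .$$
The entropy of the register is the mean column entropy
$e = \frac{1}{n}\sum_i e_i$; it measures the indeterminacy of the stored
relation. Empty columns are fully determined and contribute zero. The
unweighted (binary) variant replaces $p_{ij}$ by a uniform distribution on
the $k_i$ marked cells, giving $\frac{1}{n}\sum_i \log_2 k_i$; the weighted
entropy never exceeds it.

The table holds every function formed by picking one marked cell per
column, so the total count is $|F_T| = \prod_i \max(k_i, 1)$, which equals
$2^{en}$ exactly when the non-zero weights within each column are equal.
With $|F_R|$ functions registered explicitly, the productivity of the
representation is $|F_P| = |F_T| - |F_R|$ latent functions that emerge from
the overlap. (At maximal entropy the count is $m^n$; `amr_count_functions()`
returns it as a double, exact below $2^{53}$, together with $\log_2 |F_T|$
computed in log space for larger tables. No arbitrary-precision integer
package is assumed.)

## Recognition and retrieval

Recognition ($\eta$) is a material-implication test relaxed by $\xi$, plus
a cue-strength test. Let $\omega_i = W_i / k_i$ be the mean non-zero weight
of column $i$ ($\omega_i = 0$ for an empty column, so the thresholds remain
computable on sparse registers), and
$\Omega = \frac{1}{n}\sum_i \omega_i$. A defined argument $i$ with cue
value $j$ *passes* iff
$$w_{ij} > 0 \quad\text{and}\quad w_{ij} \ge \iota\, \omega_i .$$
The explicit $w_{ij} > 0$ clause matters: read literally, $w \ge \iota
\omega_i$ would accept empty cells at $\iota = 0$, contradicting both the
definition of the relation ($w \ne 0$ iff the pair is stored) and the
observed behaviour of the permissive scenario, which does reject unseen
cues. Undefined arguments of a partial cue pass vacuously. The cue is
accepted iff at most $\xi$ arguments fail **and** its strength
$\rho = \frac{1}{n} \sum_i w_{i,\mathrm{cue}(i)}$ satisfies
$\rho \ge \kappa\, \Omega$. We keep the $1/n$ denominator of $\rho$ even
for partial cues (undefined arguments contribute zero); the alternative —
averaging over defined arguments only — would make partial cues look
stronger than total ones. The summands of $\rho$ are the raw weights,
not gated by the per-argument test: the per-argument test and the strength
test are deliberately independent filters.

Retrieval ($\beta$) is constructive. If the cue is rejected the result is
undefined. Otherwise each output value is drawn from
$\Phi_i \propto \Psi_i \odot \zeta_i$, where $\zeta_i$ is a normal
distribution centred on the cue's value with standard deviation $\sigma$,
discretized by **integrating** the density over the unit bins
$[j - \tfrac12, j + \tfrac12)$ rather than sampling it at bin centres —
numerically stabler and exact under refinement. $\sigma$ is measured in
row units by default; a configuration switch
(`recognition_params(sigma_units = "fraction")`) interprets it as a
fraction of $m$ instead. With $\sigma = 0$, $\zeta_i$ degenerates to a
point mass and retrieval returns a photographic copy of the cue. Undefined
cue arguments, and arguments admitted by $\xi$ whose $\Phi_i$ has no mass,
fall back to sampling $\Psi_i$ alone; an empty column stays undefined (the
system-level wrapper then completes it photographically before
dequantization). All sampling flows through an explicit seed and the
caller's RNG state is restored afterwards.

### The recognition parameters

| parameter | role | unit | default |
|---|---|---|---|
| $\iota$ | minimum cell weight relative to $\omega_i$; sensitivity | ratio | 0 |
| $\kappa$ | minimum cue strength relative to $\Omega$ | ratio | 0 |
| $\xi$ | arguments allowed to fail the implication | count | 0 |
| $\sigma$ | retrieval noise around the cue | rows | 0.5 |

Six named scenarios (`scenario_params("I")` … `"VI"`) span the
permissive-to-selective range: I $(0,0,0,0.5)$, II $(0.3,0,0,0.5)$,
III $(0,1.5,0,0.5)$, IV $(0,0,0,0.1)$, V $(0.3,1.5,0,0.1)$,
VI $(0.3,1.5,1,0.1)$. Raising $\iota$ or $\kappa$ shrinks the accepted-cue
set; raising $\xi$ grows it (property-tested).

## The ensemble and its decision

A `memory_system` keeps one labelled register per class (22 Mexbet phones
by default), a shared min–max quantizer, and one shared parameter set (the
per-register override is left as configuration, matching the open question
of whether per-class parameters would help). Registration is supervised;
recognition presents the cue to every register and picks, among accepting
registers, the one minimizing $e \cdot (1/\rho)$ — low indeterminacy
(prior) and strong cue support (likelihood). Entropies are taken at
recognition time, i.e. the state the registers are in when the cue
arrives. A responder with $\rho = 0$ (possible only through
$\xi$-relaxation) scores $+\infty$; exact ties break to the
lexicographically smallest label, a choice the model leaves open.

Quantization is linear min–max per dimension with boundary clipping, fitted
bounds widened by a small epsilon on constant dimensions; dequantization
returns bin centres, so the round-trip error is at most half a bin and
levels are recovered exactly. Whether normalization should be per dimension
or global is unspecified in the model; per dimension is chosen because
encoder-output coordinates have no common scale.

## Evaluation conventions

Phone strings use the Mexbet-22 inventory; tokenization is greedy
longest-match so the multi-character symbols `tS`, `n~`, `r(` win over
their prefixes. Edit distance is the unit-cost token-level Levenshtein
distance (token-level, not character-level: it reproduces the reference
length of 27 for the worked-example transcription, character-level does
not). The phoneme error rate is the model's own normalization
$$\mathrm{FER} = \frac{I + D + S}{I + D + S + L} = \frac{d}{d + L},$$
*not* the conventional $d / L$; it lies in $[0, 1)$. A classifier that
emits eight frames per phone therefore scores $7L / 8L = 0.875$ regardless
of the reference.

Precision/recall/accuracy follow the standard definitions with one
convention: a register that rejects everything has no false positives
(precision 1) and misses all positives (recall 0). At the system level
there are no true negatives, so accuracy coincides with recall.

Bigram simplification scans a raw phone sequence left to right; with $a$
the last accepted phone and $c$ the next raw phone, candidate $b$ survives
iff
$$p(b \mid a, c) = w\, p(b \mid a) + (1 - w)\,\frac{p(c \mid b) p(b)}{p(c)}
> p(b), \qquad w = 0.5 .$$
The boundary rules — first token accepted unconditionally, last token
scored by $p(b \mid a)$ alone — are this package's choice; the procedure's
description does not fix them, and the packaged worked-example
*simplified* strings are shipped as printed rather than regenerated, so
this choice is off the acceptance path. Probabilities are maximum
likelihood with an epsilon guard on denominators only; no smoothing.

## The learning loop

`run_stages()` implements the incremental protocol. Stage 0 optionally
cuts classes above the median count (the protocol's initial balancing step),
partitions the pool 70/20/10 into Train/Rem/Test, fits the quantizer and a
surrogate classifier (nearest centroid, standing in for the neural
classifier behind the same interface) on Train, fills the registers from
Rem, and evaluates on Test. Each stage then:

1. **Active phase** — novel frame streams are cut into 8-frame windows at a
   10 ms hop (window vectors are the frame means; streams shorter than the
   window yield one centre-padded window). Windows rejected by every
   register are discarded; accepted windows act as retrieval cues, and the
   (cue, retrieved) pair enters the pool under the decision label iff both
   members belong to the same class — by default as judged by the
   classifier on both members (`check = "classifier"`); comparing the
   cue's classifier label with the memory's decision label is available as
   `check = "decision"`.
2. **Balancing** — collection targets come from `balance_quotas()`: classes
   at or below the median may grow to 10% above it; classes above the
   median may still add up to one tenth of the largest class's count. The
   median cut itself is applied once, at stage 0: re-cutting every stage
   would discard collected data.
3. **Passive phase** — the enriched pool is re-partitioned and everything
   is refitted and the registers rebuilt (default), or the existing
   registers are extended with the new units' Rem share
   (`rebuild = FALSE`).

Because Test$_s$ is re-drawn from the enriched pool each stage — and the
enriched pool contains window means and retrieved units, a harder and
shifting distribution — stagewise Test$_s$ metrics are not directly
comparable. A fixed probe set (`config$probe`) gives comparable
trajectories, and the loop's claims (imbalance strictly reduced, recall
not reduced) are assessed end-to-end, stage 5 against stage 0, which is
also how the protocol's headline claim — a small end-to-end recall
improvement — is framed.

## What the synthetic generator emulates — and what it does not

`generator_config()` emulates class-conditional encoder outputs: one
cluster per phone class in 32-D, frame streams at a 10 ms hop, 8-frame
windows, and phone durations from a normal with mean 69.9 ms and
s.d. 28.9 ms truncated at one frame. (Note the truncation raises the mean
frame count to about 7.13, not 69.9/10 = 6.99; the tests assert the
truncated-normal value.)

Each cluster is a Gaussian core plus a small broad-outlier component
(`outlier_frac = 0.02`, s.d. `outlier_spread = 2`). The heavy tail is not
cosmetic. The $\kappa$ test compares the cue's mean hit weight $\rho$
against the mean non-zero column weight $\Omega$; in a register whose
columns each concentrate on a single cell, $\rho = \Omega$ for *every*
cue, so $\kappa \ge 1$ rejects everything. Columns must hold rarely-used
cells — which deflate $\omega_i$ without attracting cues — for the
selective scenarios to operate, and real encoder outputs provide exactly
that through their heavy tails. Conversely $\iota$ with $\xi = 0$ rejects
any cue that lands on such a cell, so for a *smooth unimodal* cluster,
whose minority-cell hit rate equals the minority mass, the two thresholds
of scenario V conflict and recall is bounded well below 1 at any spread —
which is why this scenario's recall on real speech sits well below 1. The parameter-recovery tests therefore state a world with a very
tight core (separation/spread = 100) and the 2% outlier tail, where
scenario V reaches precision 1.0 and recall 0.96–0.98, and about a
thousand remembered units per class, the scale at which column tails are
reliably populated. Classes remembered at much smaller scale (below
roughly a hundred units) fall out of the $\kappa = 1.5$ operating regime
and stop accepting even their own cues — which in the learning loop means
they cannot self-collect; the loop's stated world keeps every class above
that scale.

A green test on this generator establishes that the machinery — storage,
recognition thresholds, the entropy-weighted decision, windowing,
balancing, staging — behaves as specified in a regime comparable to the
real one. It does not establish acoustic realism: there are no MFCCs, no
coarticulation beyond window mixing at phone boundaries, no
speaker/channel effects, and corpus-level figures obtained with trained neural encoders on real
speech are not reproduced here.

## Numerical choices and degenerate inputs

* $0 \log 0 = 0$ throughout; entropies are clamped at 0 against negative
  round-off.
* Weights are unbounded non-negative integers; the codomain bound of the
  weight function is not enforced.
* An all-rejected decision returns the label `"rejected"` rather than an
  error; empty streams yield empty window sets; an empty stage is a no-op
  reported as such.
* `quantizer_fit()` requires two vectors; constant dimensions are widened
  by `max(|lo|, 1) * 1e-6`.
* Seeds: every sampling function takes an explicit integer seed, uses it
  locally, and restores the caller's RNG state; derived seeds stay below
  $2^{31}$.
* Serialization is JSON headers plus CSV weight matrices; round-trips are
  bit-exact on the integer weights. Configuration files are JSON (no YAML
  parser is assumed).

## Known limitations

Hetero-associative addressing, weight decay/forgetting, continuous-valued
weights and multi-class single-register storage are out of scope. The CLI
covers the experiment workflows, not a speech pipeline: there is no audio
I/O. `F_T` loses integer exactness above $2^{53}$ (use `log2_F_T`).
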