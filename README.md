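# weam — weighted entropic associative memory

`weam` implements a declarative-but-distributed model of associative
memory and its application to phonetic representation and learning. It is
aimed at researchers in computational cognitive modelling who want a
runnable, testable implementation of weighted memory registers — and at
anyone who needs its evaluation toolkit for phone strings over the
Mexbet-22 Mexican Spanish alphabet.

## The model in brief

An associative memory register (AMR) is an *n* × *m* table of non-negative
integer weights: columns are arguments (features), rows are discrete
values, and a stored object is a function assigning one value per argument.
Three operations act on a register with respect to a cue:

* **λ-register** — additive storage: every cell addressed by the cue is
  incremented by one.
* **η-recognition** — a material-implication test relaxed by ξ, with two
  weight thresholds: per argument, the hit cell must satisfy
  *w* ≥ ι·ω<sub>i</sub> (ω<sub>i</sub> = mean non-zero weight of the
  column); overall, the cue strength ρ = (1/n) Σ w<sub>i,cue(i)</sub> must
  reach κ·Ω.
* **β-retrieval** — constructive reconstruction: each output value is drawn
  from Φ<sub>i</sub> ∝ Ψ<sub>i</sub> ⊙ ζ<sub>i</sub>, the column's weight
  distribution modulated by a normal of width σ centred on the cue. σ = 0
  returns a photographic copy.

Each column, normalized, is a probability distribution Ψ<sub>i</sub>; the
register's entropy e = (1/n) Σ<sub>i</sub> H(Ψ<sub>i</sub>) measures its
indeterminacy, and the table holds |F<sub>T</sub>| = 2<sup>en</sup>
functions (when column weights are equal) of which all but the registered
ones are emergent. An ensemble of labelled registers recognizes a cue by
presenting it to all registers and choosing the responder minimizing
e·(1/ρ) — a Bayesian decision with the entropy as prior and the cue
strength as likelihood.

On top of this the package provides min–max quantization between real
feature vectors and discrete cues, the size/fill capacity sweep, phone
string evaluation (greedy Mexbet-22 tokenizer, token Levenshtein, the
phoneme error rate FER = d/(d+L), bigram-based string simplification), a
five-stage self-training loop with corpus balancing, a synthetic
class-conditional data generator, JSON/CSV persistence and a CLI. See the
methods vignette (`vignettes/weam-methods.Rmd`) for the full account.

## Worked example

The package ships the strings of a reference worked example — the phonetic
transcription of one utterance ("Este es el resultado de ese trabajo") and
the raw outputs of a memory-based and a network-only recognizer:

```r
library(weam)
s   <- table5_strings()
ref <- phone_tokenize(s$transcription)   # 27 tokens
phone_levenshtein(phone_tokenize(s$network), ref)
#> [1] 199
phone_levenshtein(phone_tokenize(s$memory), ref)
#> [1] 153
fer(phone_tokenize(s$memory), ref)       # d/(d+L) = 153/180
#> [1] 0.85
fer(phone_tokenize(s$network), ref)      # 199/226
#> [1] 0.8805
```

The memory's string is 46 edits closer to the truth than the bare
network's — the memory rejects speech segments outright instead of forcing
them to the nearest phone. `table5_distances()` recomputes the whole
reference table (lengths 27/225/178/41/37; distances 199, 153, 51, 20, 18,
14).

Registers themselves:

```r
a <- weighted_amr(4, 4, label = "a")
for (lv in list(c(0,1,2,3), c(0,1,2,2), c(0,1,2,3)))
  a <- amr_register(a, feature_function(lv, 4))
a
#> <weighted_amr 'a': 4 args x 4 levels, total weight 12, e = 0.2296>
amr_count_functions(a, registered = 2)[c("F_T", "F_P")]
#> $F_T
#> [1] 2
#> $F_P
#> [1] 0
r <- amr_recognize(a, feature_function(c(0,1,2,3), 4),
                   recognition_params(iota = 0.3, kappa = 1))
c(r$accepted, r$rho, r$omega_bar)
#> [1] 1.000 2.750 2.625
```

The fourth column has seen two values, so the register's entropy is
positive and it holds both combinations as retrievable functions; the cue
is accepted because every hit cell clears ι·ω and its strength ρ = 2.75
clears κ·Ω = 2.625.

## Command line

```sh
Rscript -e 'weam::weam_cli()' synth --out corpus --classes 22 --utterances 50 --seed 1
Rscript -e 'weam::weam_cli()' build --data corpus/rem_units.csv --out state --m 8 --scenario V
Rscript -e 'weam::weam_cli()' register --state state --data corpus/rem_units.csv
Rscript -e 'weam::weam_cli()' recognize --state state --data corpus/test_units.csv --out dec.csv
Rscript -e 'weam::weam_cli()' eval --table5
```

Subcommands: `synth`, `build`, `register`, `recognize`, `retrieve`,
`sweep`, `learn`, `eval`; flags are `--key value`, with `--config
file.json` supplying defaults.
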