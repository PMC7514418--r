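---
title: "Competitive prediction for reference-free DNA compression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive prediction for reference-free DNA compression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdna)
```

## The model

`cpdna` codes a DNA sequence $x_1 x_2 \cdots x_n$ over $\Theta = \{A,C,G,T\}$
one base at a time. At each position two *classes* of models produce a
predictive distribution over the four bases, a binary selector picks one
class, and the selected distribution drives an arithmetic (range) coder.
Because every model is updated only with already-coded symbols, the
decompressor can rebuild the identical pipeline from the container header and
invert the process exactly.

### Class 1: weighted context models

An order-$k$ context model keeps counts $n(s \mid c)$ of which base followed
each $k$-mer context $c$ and predicts

$$P(s \mid c) = \frac{n(s \mid c) + \alpha}{\sum_{s'} n(s' \mid c) + 4\alpha},$$

so $\alpha$ interpolates between the frequency estimate ($\alpha \to 0$) and
the uniform law ($\alpha \to \infty$). Counters are 8-bit; when one would
pass 255 all four counters of that context are halved, which bounds memory
and gives old evidence a slow implicit decay. Shallow orders use a dense
$4^{k+1}$-counter table; deep orders ($k \ge 12$ in the presets) use a
bounded cache-hash — $2^{b}$ buckets of at most `max_collisions` entries with
the oldest entry evicted first — because deep-context tables are
astronomically sparse.

Two extensions target biology-specific structure:

* **Inverted repeats.** Genomes carry segments that recur as their
  reverse complement. Every coded window $x_{i-k..i}$ therefore also trains
  the *image* event: context $\mathrm{RC}(x_{i-k+1..i})$, symbol
  $\overline{x_{i-k}}$. A model in mode `"both"` predicts from the forward
  context, which hits these image counts while traversing the complementary
  copy of an earlier region; mode `"ir_only"` predicts through the
  reverse-complement query itself. The forward event always trains — the
  mechanism only works because a reverse-complement query can meet
  forward-trained counts and vice versa.
* **Substitution-tolerant context models (STCM).** Point mutations break
  deep contexts for $k$ positions each. An STCM shares its host model's
  counter store (single writer: the host) but predicts from a private
  *edited* context: when its own top prediction misses, that top symbol is
  written into the edited context instead of the true one, up to a budget of
  `max_subs` substitutions; when the budget is spent it resynchronizes on
  the true history. A ring of the last $l$ hit/fail outcomes gates the model:
  more than $t$ fails switch its *output* to uniform until performance
  recovers. The gate always tracks the underlying context prediction — if it
  tracked the uniform fallback, the off state would be absorbing (the argmax
  of a uniform distribution is constant), which we verified empirically
  before fixing the rule.

All context-model experts (models plus attached STCMs) are blended softly:

$$P(x_i) = \sum_m w_{m,i}\, P_m(x_i), \qquad
  w_{m,i} \propto w_{m,i-1}^{\gamma_m}\, P_m(x_{i-1}),$$

with per-expert forgetting factors $\gamma_m \in [0,1)$ and weights floored
at $10^{-12}$ before normalisation so no expert dies irrecoverably. Small
$\gamma$ makes weights track the last few outcomes; $\gamma$ near 1 freezes
them.

### Class 2: weighted stochastic repeat models

A repeat model is a *copy expert*: a pointer into the already-coded sequence
predicting "the next base is the base at my pointer" with probability
$q = (h + a_h)/(h + f + a_h + a_m)$ after $h$ hits and $f$ fails, the other
three bases sharing $1-q$ evenly. A $k$-mer index over the coded prefix
stores, per $k$-mer, up to 16 positions of the base following each
occurrence (FIFO). When the current $k$-mer has stored positions and fewer
than `rpn` instances are live, a new instance spawns at a position chosen
*uniformly at random* by a seeded portable generator — both codec sides draw
identical values, so no position index is ever transmitted; that is what
makes the repeats "stochastic". With inverted repeats enabled the
reverse-complement of the current $k$-mer is looked up as well and the
spawned instance walks *backward*, emitting complemented predictions.
Instances die when $q$ falls below `deactivate_below` or the pointer leaves
the coded region; the slot frees on the following step. Instance weights use
the same forgetting update with a deliberately small shared $\gamma_r$
(0.2 in the presets): copy experts go from perfect to useless at a repeat
boundary, so the mixture must re-weight within a few bases.

### Competitive selection

A binary context model of order $k_c$ watches the sequence
$Z_1 Z_2 \cdots$ of past *winners* — which class assigned the higher
probability to each realised base (ties to the context class). Before coding
base $i$ it estimates $P(Z_i = 1 \mid \text{last } k_c \text{ winners})$ with
the same $\alpha$-estimator on two counters per context and forwards only
the selected class's mixture to the coder; no cross-class blending takes
place. After decoding, the winner is recomputed from the true base, so both
sides maintain identical $Z$ histories. The selector's order matters:
short sequences give the binary model little training data (low orders win),
long sequences reward longer winner patterns — hence the preset orders grow
from 4 at level 1 to 16 at level 12 and above.

## Coding and the container

Model probabilities are doubles, but the coder sees integers only: each
selected distribution is quantized to frequencies summing to exactly
$2^{16}$ by largest-remainder rounding, ties broken in symbol code order,
every frequency floored at 1 (funded by the largest entry). A byte-wise
carry-propagating range coder (32-bit range, 64-bit low register, LZMA-style
renormalisation) then codes the base. This keeps the bitstream bit-exact
across platforms whose floating point behaves identically for a fixed
operation order, and adds a measured overhead of a few dozen bits per
stream plus a per-symbol quantization loss bounded in the tests at
$10^{-3}$ bits in expectation.

The container is `magic CPD1 | version | length | seed | full model
configuration | CRC32`, followed by the payload. All real-valued parameters
travel as integer rationals or permille, so the decoder reconstructs exactly
the configuration the encoder used, including the RNG seed for the
stochastic spawns. Tampered headers fail the CRC; truncated payloads are
detected by decoder overrun.

### The per-step contract

Decoder synchronization depends on a fixed update order, which the engine
pins down as: predict both classes → select → quantize → code → update
mixture weights (with pre-quantization probabilities) → update context-model
counters (forward, then inverted-repeat event) → update STCM states → update
repeat instances → append the base to the packed history → attempt spawns →
add the new $k$-mer position to the index → renormalise repeat weights →
record the winner. Spawning *before* indexing the current $k$-mer keeps the
draw causal: an instance can never point at the base about to be coded.
New instances enter with weight $1/n_{\text{active}}$ and the active set is
renormalised.

## Presets

Levels 1–15 trade resources for compression. Context-model orders grow from
$\{1,3\}$ at level 1 to thirteen models up to order 20 at level 15; repeat
groups grow from one ($k$-mer 11, 8 instances) to three ($k$-mers 12/16/20,
32 instances each). Parameter bands follow what works for DNA: shallow
models forget fast ($\gamma \le 0.8$), deep models remember
($\gamma \approx 0.95$) and smooth less ($\alpha$ down to $1/64$), and the
order-6 model — empirically special, plausibly through the periodicity of
coding DNA — sits at $\gamma = 0.80$ in the $[0.75, 0.85]$ band from level 3
up. The deepest model carries an STCM from level 5 (the two deepest from
level 9). Model count, maximum order, cache sizes, instance bounds and
selector order are all non-decreasing in the level; the preset table is this
package's own and makes no claim of matching any other implementation's
levels model-for-model.

## The synthetic-data generator

`gen_dna()` emulates the structures the model classes exist for: uniform
i.i.d. background (the incompressible floor), tandem arrays
(`unit^copies`), dispersed copies on random background, $S\,\Vert\,
\mathrm{RC}(S)$ inverted constructs, and any of these with i.i.d.
substitution noise — all driven by the same portable xorshift64* generator
as the codec, so every fixture is reproducible from a seed alone. It does
*not* emulate GC skew, isochores, microsatellite slippage, indels, or
N-runs; passing tests therefore demonstrate correctness of the mechanisms
and their value on the structure each targets, not end-to-end performance
on real genomes. Fixture sizes in the test-suite were chosen to give each
property room to express itself at desk scale: 100 kb for rate properties
(floors, tandem, inverted, mutated), 20 kb for selector behaviour, up to
2 kb for the 200-sequence × 15-preset losslessness sweep.

## Numerical choices and degenerate inputs

* Contexts are zero-padded at the start of the sequence (implicit leading
  `A`s); inverted-repeat events and queries first fire at position $k$.
* STCM argmax ties resolve to the lowest symbol code; class-selection ties
  resolve to the context class.
* Weight updates use the exact pre-quantization probabilities.
* Empty sequences are a compile-time error for the compressor; single-base
  sequences are valid streams. An empty model class yields a uniform class
  distribution, and the selector degrades gracefully.
* Non-ACGT input characters are deleted (and counted) at read time, not
  substituted: the tool is lossless with respect to the filtered ACGT
  stream only, and the filter report makes the deletion visible.

## Known limitations

* One sequence per container; multi-record FASTA inputs are concatenated
  and record boundaries are not restored.
* No indel tolerance: the STCM handles substitutions only, and repeat
  instances cannot re-anchor after an insertion or deletion.
* Compression of truly random data pays the selector's small overhead
  (measured in the tests as under 0.02 bits/base above the 2-bit floor).
* The decompressor trusts the header's model parameters; it detects
  corruption (CRC, overrun) but cannot recover from it.
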