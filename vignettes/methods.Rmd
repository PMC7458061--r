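---
title: "Methods: document-level CID extraction with a graph-convolutional classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: document-level CID extraction with a graph-convolutional classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and
its assumptions, the knobs that matter, what the synthetic world does and
does not establish, and the places where the design was genuinely open and
a choice had to be made.

## The task and its decomposition

Chemical-induced disease (CID) extraction is document-level binary
classification over *concept pairs*: for an abstract with chemical and
disease mentions normalised to MeSH identifiers, decide for each
(chemical, disease) pair whether the document asserts the relation. The
pipeline decomposes into candidate construction (which mention pair
represents a concept pair, and at which level), representation (tokens to
vectors), and classification.

**Candidate construction.** Each concept pair yields at most one
instance per document. Pairs co-occurring in a sentence become
*intrasentence* instances, represented by the co-sentential mention pair
with the smallest token distance (measured between span midpoints). All
remaining pairs become *intersentence* instances, represented by the
mention pair with the smallest sentence distance (ties: token distance,
then earliest chemical mention, then earliest disease mention), and pairs
whose nearest mentions are more than `max_sentence_distance` (default 3)
sentences apart are dropped. The distance filter is applied at training
*and* prediction time — it is part of instance construction, so gold pairs
it removes are honestly counted as false negatives by `evaluate()`.
Token distance between span midpoints is our reading of "nearest"
(the metric is not fixed by the task); the tie-breaks exist purely to make
construction deterministic and testable.

**The document graph.** Nodes are all tokens of the abstract. Edges:
every dependency arc within a sentence; one edge between the dependency
roots of each adjacent sentence pair; one self-loop per token. For the
graph convolution the typed, directed edge list collapses to a binary,
symmetric adjacency with unit diagonal — all edge types share one weight
matrix. Since each sentence parse is a tree and consecutive roots are
linked, the graph is connected and every degree is at least 1, so the
degree normalisation below never divides by zero. Punctuation tokens are
kept as nodes to preserve index alignment with the token sequence.

## The classifier

Per-token input `w_i = [w_ctx,i ; w_pos,i ; w_dc,i ; w_dd,i]`:

* `w_ctx,i` — a contextual embedder's output (interface: token sequence in,
  one vector per token out). At desk scale this is a deterministic hash
  embedder: a unit-norm pseudo-random vector per surface form plus damped
  (0.3×) contributions from the left and right neighbour surfaces. It is
  *weakly* context-sensitive — enough to exercise the interface contract,
  not a language model.
* `w_pos,i` — a fixed Gaussian embedding of the UPOS tag (`<UNK>` row for
  unseen tags).
* `w_dc,i`, `w_dd,i` — one distance embedding per target entity, sharing
  the table: the signed distance to the nearest token of the chemical
  (resp. disease) span, 0 inside the span, clipped to ±`clip`. A single
  "position" feature would be ill-defined for a *pair*wise task, hence two.
  Embedding tables are fixed (seeded) rather than trained: the trainable
  encoder sits above them, and fixed tables make features precomputable
  and runs exactly reproducible.

The window is the whole document, truncated symmetrically around the two
mention spans to `max_len` tokens when necessary (both spans are always
retained; the adjacency is restricted to the window, with degrees
recomputed on the restriction).

**Encoder.** A BiLSTM with the standard gate equations (logistic gates,
tanh cell candidate, `h_t = o_t ⊙ tanh(c_t)`); the backward pass runs on
the reversed sequence and per-token outputs are concatenated.

**Attention branch.** Self-attention over the BiLSTM states `H`:
scaled dot-product `softmax(HH'/√d)H`; *general* scores `h_i' W h_j`;
*additive* scores `v' tanh(W₁h_i + W₂h_j + s)` (we read the extra `s`
parameter as a shared bias inside the nonlinearity); *multihead* applies
scaled dot-product per head on learned projections `Q, K, V`, concatenates
the heads and re-projects with `W_o` — per-head width `d/h`, the standard
transformer convention, adopted because the source formulation leaves the
output dimension ambiguous.

**Graph branch.** `L` graph convolutions
`H^(l) = ReLU(D⁻¹ A H^(l-1) W^(l) + b^(l))` over the window-restricted
adjacency, taking the (dropout-masked) BiLSTM output as `H^(0)`. `L` is
not fixed by the method description; the default is 2 — one hop reaches a
mention's syntactic neighbourhood, two hops cross an adjacent-sentence
root edge, and the locality tests pin down exactly this radius.

**Pooling and output.** Columnwise max over all window tokens of the GCN
output gives `h_sent`; over the chemical and disease spans, `h_c` and
`h_d` (max-pooling chosen for the entity vectors too — the source's entity
formula is unreadable, and max matches the stated sentence pooling); over
the attention output, `h_att`. `h_final = [h_sent; h_c; h_d; h_att]`
feeds a two-layer rectified perceptron and a softmax (the perceptron
nonlinearity is unstated in the source; the rectifier matches the GCN
activation). Decision threshold 0.5 = argmax.

**Ablations.** `attention_kind = "none"` drops `h_att`;
`use_gcn = FALSE` drops the graph convolutions but still pools `h_sent`,
`h_c`, `h_d` from the BiLSTM output. We deliberately did *not* reduce the
no-GCN model to the attention vector alone: without entity pooling it
could not represent which pair is being classified, and the comparison
would credit the GCN for trivially missing machinery rather than for graph
propagation.

## Tunable parameters

| parameter | paper profile | test profile | meaning |
|---|---|---|---|
| `dim_ctx` | 1024 | 32 | contextual embedder width |
| `dim_pos`, `dim_dist` | 100 | 8 | POS / distance embedding widths |
| `clip` | 50 | 10 | distance clip radius (tokens) |
| `lstm_dim` | 250/direction | 16 | BiLSTM output width 500 / 32 |
| `gcn_dim`, `mlp_dim` | 500 | 32 | GCN and perceptron widths |
| `gcn_layers` | 2 | 2 | propagation radius (hops) |
| `n_heads` | 5 | 2 | attention heads (must divide BiLSTM width) |
| `dropout` | 0.5 | 0.2 | on BiLSTM output and each GCN layer, training only |
| `learning_rate` | 0.001 | 0.002 | Adam step size |
| `batch_size` | 32 | 8 | minibatch size |

The paper profile mirrors the full-scale experimental settings (widths
500, 5 heads, dropout 0.5, Adam 0.001 with minibatch 32; "BiLSTM width
500" is read as the concatenated output). The test profile is sized for
CPU-minutes: with ~600 instances a batch of 32 would give too few
gradient steps in 20 epochs, so it uses batch 8 with a mildly larger
step, and lighter dropout because 32-unit layers under 0.5 dropout are
mostly noise. These desk-scale settings were fixed when the profile was
designed, not tuned against the acceptance thresholds.

Training is full-batch-seeded and single-threaded: given (configuration,
seed, input) every run is bit-reproducible, which the tests assert.

## The synthetic world

`generate_corpus()` emulates the *shape* of a CDR-style corpus: 3–6
sentence abstracts of 6–10-token sentences over a closed ~200-type
lexicon, random single-rooted dependency trees (random recursive
attachment), 1 chemical and 2 disease concepts per document with
MeSH-formatted ids, mentions placed on tree leaves, and a target positive
rate of 0.35 — a candidate-level class balance typical of document-level
CID corpora. `inter_fraction = 0.4` of disease concepts are realised only
cross-sentence, within 3 sentences, matching the instance-construction
filter.

Labels come from a planted rule. Under `dependency_path` (default), a
pair is positive iff a trigger token sits on the unique document-graph
path between its mention pair. Positives get the trigger as close to the
disease mention as possible while avoiding negative pairs' paths;
negatives get an off-path decoy in the disease's sentence. Every instance
contributes exactly one trigger, so per-document trigger counts carry no
label information and a bag-of-words learner is blind by construction —
only adjacency in the graph separates the classes. Labels are drawn once
per document and the structure is rejection-sampled until the rule
realises them exactly, keeping the positive rate an unbiased
Bernoulli(`p_positive`) sample. The `lexical` rule (trigger linearly
adjacent to the chemical mention) is the easy control; with several
diseases per chemical its labels correlate across pairs, so rate targets
are only guaranteed for `dependency_path`.

What a green end-to-end test establishes: the full differentiation and
optimisation path works, the graph branch carries information that the
lexical surface does not, and the ±GCN comparison moves in the direction
reported for the real task. What it does **not** establish: performance
on real biomedical language (no synonymy, anaphora, hypernymy, parse
errors, or realistic length), nor the value of a pretrained contextual
model, which the hash embedder deliberately does not emulate.

## Numerical and degenerate-input choices

* Softmax rows are max-shifted before exponentiation; the cross-entropy
  clips probabilities at 1e-12.
* Max-pooling ties route gradients to the first maximising row.
* LSTM forget-gate biases start at 1, all other biases at 0; weights are
  Glorot-scaled Gaussians from the configuration seed.
* Empty mention spans, heads not dividing the width, `L < 1`, dropout
  outside [0,1) and a training set without positives are errors, not
  warnings.
* Mentions crossing sentence boundaries are kept and assigned to their
  first token's sentence (dropping them would silently change recall
  denominators); mentions matching no token are errors.
* Duplicate gold-relation lines are deduplicated on read with a logged
  warning; unnormalised (`-1`) mentions are dropped; composite concept
  fields are expanded into one mention per concept.

## Known limitations

* The neural core is dense base-R linear algebra: appropriate and fast at
  desk scale, but the paper profile (widths 500, contextual dim 1024) on a
  real corpus would want a compiled backend.
* The contextual embedder interface accepts precomputed per-token vectors
  (`precomputed_embedder()`) as the bridge to real pretrained models, but
  no pretrained model ships with the package.
* Sentence segmentation and parsing are consumed, not produced: real data
  must arrive as PubTator + CoNLL-U from an external parser.
* Evaluation conventions (distance-filtered gold pairs as inter-level
  false negatives) are documented choices; published corpus-level numbers
  may use different denominators, so scores are not directly comparable
  across toolkits.
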