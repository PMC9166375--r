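---
title: "Document subgraphs and the shared-weight CNN: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Document subgraphs and the shared-weight CNN: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docgraphRE)
```

## The problem

Chemical-induced disease (CID) relations in biomedical abstracts are
annotated at the *document* level: a chemical concept and a disease concept
are related somewhere in the abstract, with no pointer to the sentence that
expresses the relation. Roughly a third of such relations are
*inter-sentence* — the two concepts are never mentioned together inside any
single sentence — so classifiers built on single-sentence dependency paths
cannot even represent them. docgraphRE implements a graph-based pipeline
for this setting: merge the dependency trees of the title and a sliding
window of consecutive sentences into a *document subgraph*, connect the
trees with labeled virtual edges, mine multiple dependency paths between
entity mention heads, and classify each concept pair with a shared-weight
convolutional network (swCNN) over its top-k paths.

## Document subgraphs

For every window of `w` consecutive abstract sentences (the title is part
of every window) the subgraph contains:

* the directed, labeled dependency arcs of each sentence (all labels kept);
* a **TITLE** edge between the title root and the first window sentence's
  root;
* **NEXT-SENT** edges between the roots of consecutive window sentences;
* optional **COREF-sent / COREF-to-title / COREF-from-title** edges from a
  precomputed coreference-link table, and **KB-CTD** edges between the head
  tokens of chemical/disease mention pairs whose concept pair appears in a
  knowledge-base table (rows with relation code `M` by default).

Virtual edges are undirected and labeled by their names; each family can
be toggled independently (`edge_config()`) so ablation grids are runnable.
Duplicate virtual edges collapse, because graphs are sets. Windows never
slide over the title, and a document with fewer sentences than `w` yields
one whole-document window rather than none — otherwise short abstracts
would emit no candidate pairs at all. Coreference or knowledge-base edges
whose endpoints fall outside the current window are skipped (an endpoint
outside the *document* is an error); nothing in the method requires
truncating them instead.

The assumption behind the window bound is that related entities are close:
pairs farther apart than five consecutive sentences are ignored, and the
package enforces `1 <= w <= 5`.

## Path mining

Between the head tokens of a chemical and a disease mention (the head is
the mention token whose syntactic head lies outside the mention; ties or
none fall back to the rightmost token), `find_paths()` enumerates simple
paths breadth-first, never revisiting a node. Two thresholds bound the
search: `md = 15` nodes per path and `kmax = 150` collected paths. Virtual
edges are traversed exactly like syntactic arcs; every edge records its
traversal direction (with or against the stored arc orientation).

Candidate generation applies three remedies against abstract-level label
noise:

1. **Minimal span.** A mention-pair co-occurrence is dropped when another
   co-occurrence of the same concept pair overlaps it with a strictly
   contained sentence span — if the relation is expressed at all, it is
   most likely expressed where the mentions are closest.
2. **Instance merging.** All paths of all mention pairs and all windows of
   one (document, chemical, disease) key are pooled into a single
   instance; repeated paths are removed. The deduplication key is the
   lexical pattern along the path (surface form, POS tag, edge label,
   traversal direction), not node identity, so the same pair recurring at
   different positions with identical patterns also collapses — the harm
   being addressed is pattern-frequency distortion, and that distortion is
   lexical. Pre-deduplication multiplicities are kept.
3. **Top-k selection.** Either the `k` shortest paths (default, `k = 3`)
   or the `k` most repeated ones; all tie-breaks are fixed (node count,
   then node coordinates) so runs are reproducible. The search itself is
   collected in breadth-first order with lexicographic neighbour
   expansion for the same reason.

Concept pairs that never co-occur in any window produce no instance; they
are excluded from training and predicted NONE at test time, where they
count against recall.

## Path representation

Each path element is embedded and transformed:

* a dependency unit is `d = tanh([type ⊕ direction] W_d + b_d)`, with a
  72-row syntactic label table and a separate 6-row virtual-label table
  (keeping the syntactic table at exactly 72 rows), each 150-dimensional,
  and a 2x150 direction table. Labels outside the inventory use the
  generic `dep` row, so parser drift does not grow the table;
* a token is `t = tanh([word ⊕ POS (⊕ char ⊕ aux)] W_t + b_t)`: frozen
  pretrained 300-dim word vectors (out-of-vocabulary surfaces use the mean
  vector), a 57x50 POS table (56 OntoNotes tags plus one reserved unknown
  row — which also reconciles the 56-tag inventory with the 57-row
  table), optionally an 85x50 character table feeding a 50-unit-per-
  direction biLSTM and a fixed 45-dim auxiliary lexical vector. Both
  optional blocks default to on at full scale;
* each token is augmented with attentive information from its children
  *on the original sentence tree* (not the subgraph), so a token is
  encoded identically on every path through it. The child context
  concatenates the child's word and POS vectors, the type row of its
  incoming dependency label, the parent's word vector and a signed
  token-distance multiple of a 32-dim base distance embedding — 832
  dimensions at full scale. A single-unit scorer gives
  `alpha_s = sigmoid(cbar W_e + b_e)`; a heuristic gate
  `alpha_h = sigmoid(beta d^2)` with `beta = -0.03` discounts distant
  children; 100 ReLU kernel filters of size 832 are max-pooled over the
  gated child contexts. Leaf tokens get a zero augmentation vector (the
  neutral ReLU output; a maximum over no children is undefined);
* the final token vector is `x = tanh([t ⊕ a] W_x + b_x)`, 595-dim at
  full scale.

Two points here were genuinely open. First, the attention gates could
rescale either the bare child features or the full concatenated context;
the kernel-filter width (832) forces the latter, so the gated vector is
the full context. Second, the intermediate and final token dimensions are
not pinned down by the published accounting, which lists no parameters
for the three tanh transforms; both default to the same `token_out` and
the total parameter count is therefore reported but not treated as a
contract. `count_parameters()` reproduces every component that *is*
unambiguous: 10800, 300, 4250, 40400, 2850, 32, 833 and 83300.

## The shared-weight CNN

The `k` encoded paths of an instance share one set of convolution
filters: for region sizes `r` in {1, 2, 3} dependency units, windows of
`r` tokens and `r-1` dependency vectors advance token-to-token, and each
of the 128 filters per region keeps a single maximum over *all* paths and
*all* positions (filter-wise pooling). Pooling is per region size, with
the three blocks concatenated to a 384-dim feature vector — the
per-filter maximum makes the features invariant to path order and to
padding. Paths shorter than a region size simply contribute nothing to
it; an instance whose paths are all shorter leaves that block at zero.
A softmax layer (with bias) maps the features to the two classes.

The loss is class-weighted cross-entropy (3:1 for CID:NONE, countering
the negative-pair excess that window-based candidate generation creates)
plus `lambda ||theta||^2` over the weight arrays (biases excluded, the
usual convention). The log is floored at 1e-12. Training uses Adam
(step 1e-3), Glorot-uniform initialization, mini-batches of 128, dropout
0.5 after the embedding and CNN layers, zero-mean Gaussian input noise
with scale 0.001 (a noise *mean* of 0.001 would be a constant bias, so
the stated value is read as the scale), per-column max-norm capping at
3.0, and early stopping on development F1. All randomness —
initialization, shuffling, dropout, noise — derives from one seed, and
the whole forward/backward pass is hand-written in matrix algebra, so two
runs with the same seed are bit-identical.

Early stopping deserves a note: the patience default is 15 epochs
without a new best development F1. With mini-batches of 128 on a corpus
of a few thousand instances there are only ~10 updates per epoch, and
development F1 plateaus or fluctuates for the first several epochs while
the attention and convolution stacks warm up; a 5-epoch patience
reproducibly halted training while the loss was still falling steeply.
The value remains configurable.

Word vectors stay frozen (they are a pretrained input), and the
character biLSTM runs forward-only with fixed weights, acting as a
stable subword hashing function; gradients flow through every other
parameter group, which a finite-difference check verifies to 1e-4.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` builds PubTator documents with matching CoNLL-U
parses from a small library of fixed dependency templates. Every title
contains a chemical mention. A positive document plants exactly one CID
pair with a trigger verb ("induced"-class) on the dependency route
between the mention heads, in one of three constructions:

* **intra**: `chem TRIG disease` inside one sentence (70% of positives
  by default, mirroring the ~30% inter-sentence share in real
  abstract-level corpora);
* **title-routed inter**: the chemical appears only in the title, a
  trigger bridge sentence sits at S1 and the disease at S2, so the only
  trigger-bearing route uses the TITLE edge into the bridge and a
  NEXT-SENT hop — a route that exists only for `w >= 2`;
* **consecutive-sentence inter**: a trigger-rooted chemical sentence
  followed by the disease sentence, routed over NEXT-SENT and not
  covered at all at `w = 1`.

Negative documents deliberately mirror the positive surface statistics
without triggers: same-sentence chemical-disease co-occurrences under a
neutral verb, disease-only sentences, control-substance titles
("placebo"-class words form their own embedding cluster), and
active-chemical titles *without* relations. The word vectors are
class-structured (class mean plus noise), emulating the cluster geometry
of real pretrained embeddings. Together these force the classifier to
learn the conjunctive evidence pattern — chemical near trigger *and*
trigger near disease — rather than any single-token shortcut, and they
make the two window-width effects measurable by construction: at
`w = 1`, no trigger-bearing path exists for any inter pair, and with
TITLE edges disabled, title-routed pairs lose their only path.

What the generator does **not** emulate: real biomedical syntax (parses
come from a handful of short templates), lexical ambiguity, annotation
noise, discontinuous or nested mentions, coreference chains, or the
~1:3 to 1:4 positive:negative imbalance growth with window width seen in
real corpora. A pass on these fixtures demonstrates that the pipeline is
wired correctly and that the model can exploit graph-routed evidence; it
says nothing about F1 on real corpora, whose headline numbers require
external data and multi-hour training runs and are out of scope here.

## Problem sizes and runtimes

The test suite and the acceptance script use a 500-document corpus
(70/15/15 train/dev/test split), the compact configuration
(`compact_encoder_config()`: 20-dim word vectors, 16 filters per region,
character and auxiliary features off) and at most 50 training epochs —
sizes chosen so the full synthetic-recovery experiment, including the
`w = 1` and no-TITLE conditions, completes in a couple of minutes on one
CPU. The full-scale `encoder_config()` is exercised structurally
(dimensions, bounds, parameter accounting) rather than trained.

## Numerical and degenerate-input choices

* Tie-breaks everywhere are deterministic: path ordering by node count
  then coordinates; top-k by the same ordering; frequency ties by length
  then ordering; filter-wise pooling takes the first argmax.
* `source == target` in the path search is a degenerate-pair error;
  mentions overlapping no token, or crossing sentence boundaries, are
  alignment errors (nested mentions are handled by token overlap).
* Offsets are 0-based half-open over `title + single separator +
  abstract`. Sentence boundaries trust parse token spans when present,
  otherwise a deterministic splitter (sentence-final punctuation followed
  by whitespace and an uppercase letter or digit).
* Empty inputs round-trip: zero documents produce empty streams, and
  readers of empty streams return empty lists.
* Non-finite training loss aborts with a diagnostic rather than
  continuing silently.

## Known limitations

* The intra/inter locus split is computed at the concept level (a pair is
  intra if *any* sentence mentions both concepts), which is one of two
  defensible readings of mention- versus concept-level splitting.
* The worked-example pair counts reported for real corpora (e.g. "42
  valid pairs" for one abstract) are not encoded as contracts; their
  derivation is not reproducible from the stated rules alone.
* Distant-supervision documents are ingested through the same pipeline
  with weight 1 and no concept filtering; the CLI and `run_experiment()`
  accept them, but no reweighting is implemented.
* The breadth-first frontier is bounded only by `md`, `kmax` and the
  no-revisit rule; on adversarially dense graphs (far denser than merged
  dependency trees) the partial-path frontier can still grow large before
  `kmax` paths complete.
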