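---
title: "Reference-free deconvolution of linked-read barcodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free deconvolution of linked-read barcodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkdecon)
library(data.table)
```

## The problem

Linked-read protocols (10x Chromium, TELL-Seq, LoopSeq, ...) partition long
DNA fragments (tens to hundreds of kb) into droplets, shear them, and
sequence short reads that all carry the droplet's barcode. The barcode is
long-range information on the cheap — but the barcode pool is finite, so
every barcode is reused for several unrelated fragments (typically ~2-20).
The set of reads with one barcode (a *read cloud*) is therefore a mixture
of fragments. *Barcode deconvolution* is the task of splitting each cloud
into groups of reads that came from a single fragment, yielding *enhanced
barcodes* `<barcode>-<group>` that downstream tools (assemblers,
scaffolders, phasers, taxonomic classifiers) can treat as fragment
identifiers.

`linkdecon` solves this without a reference genome. The only signal used is
sequencing redundancy: the genome is covered by many fragments, so the
reads of a fragment overlap reads from many *other* barcodes, and two reads
of the *same* fragment tend to overlap the *same* set of other barcodes,
while two reads from different fragments of one cloud share almost none.

## Expected shared barcodes

The package ships the closed-form model behind that claim
(`expected_common_same_fragment()`, `expected_common_far_fragments()`).
With fragments of length $L$ drawn uniformly, a fraction $p$ of each
fragment covered by reads, read coverage $c$ (hence fragment coverage
$c/p$), $n$ fragments per barcode and $N_{tot}$ barcodes:

* two reads of one fragment, $l < L$ apart, are jointly covered by
  $p_1 = \frac{L-l}{L}\left(\frac{c}{p} - 1\right)$ other fragments on
  average;
* two reads of different, far-apart fragments of one barcode share
  $p_2 = \left(\frac{c}{p}\right)^2 \frac{n-1}{n N_{tot} - c/p}$
  fragments on average.

Both get multiplied by $P^2$, the squared probability that a read of a
common fragment actually overlaps a given read; $P$ has no closed form
here, defaults to 1, and cancels from every ratio, which is why the
package exposes it only as an optional scale factor. In real experiments
$N_{tot} \gtrsim 10^6$ while $c/p \lesssim 10^3$, so $p_1 \gg p_2$ — the
shared-barcode count separates same-fragment from cross-fragment read
pairs by orders of magnitude. A useful rule of thumb derived from the two
formulas: the mean separation ratio is roughly $\frac{2}{3}\,G/((n-1)\bar
L)$ for genome size $G$ and mean fragment length $\bar L$, which is what
limits how far the conditions can be scaled down (see *Known
limitations*).

## The pipeline

### Sparse k-mer index

All overlap detection is alignment-free. Every read pair's mates are
scanned for canonical k-mers (k = 20 by default; the canonical form is the
lexicographic minimum of a k-mer and its reverse complement, and both
mates pool into one per-pair k-mer set). Indexing every k-mer would be
wasteful, so only a fraction $d$ (default 1/8) is kept: a k-mer qualifies
at level $m$ when its lexicographic rank fraction (its base-4 value over
$4^k$, computed on the canonical form so selection is strand-invariant) is
below $m\,d$. Every stretch of $w$ bases (default 50) escalates the level
until it holds at least one selected k-mer. The escalation is evaluated
over *sliding* stretches: a k-mer is selected iff its rank is below the
highest level demanded by any stretch covering it. Three properties follow
by construction, and are enforced in the test suite:

* every $w$-base stretch of every read contains an indexed k-mer, even in
  extreme-composition regions;
* the minimum-rank k-mer of any $w$-stretch is always selected, so two
  error-free reads with an exact overlap of at least $w$ bases share at
  least one indexed k-mer;
* a read and its reverse complement index the same canonical set.

An earlier draft used disjoint left-to-right windows with per-window
escalation; that variant is subtly weaker (a stretch straddling two
windows can be left without an indexed k-mer, and the selection changes
under reverse complement because the window frame flips), so the sliding
formulation was adopted. k-mers containing `N` are never selected; reads
shorter than $w$ escalate over the whole read as a single stretch.

The index maps each indexed canonical k-mer to the list of pairs carrying
it. Two pairs sharing at least `min_shared` (default 3) distinct indexed
k-mers are flagged *similar* — no alignment, no positional check.

### Repeat de-indexing

Repeats break the "overlap means same locus" assumption: a k-mer from a
repeated element occurs in reads from all copies and creates hubs of false
links. `prune_repeats()` de-indexes every k-mer whose occurrence count is
at least `repeat_factor` (default 2) times the average occurrence count.
The average that matters is the *occurrence-weighted* mean count
$\sum c_i^2 / \sum c_i$ — the typical count of the k-mers a read actually
carries, which tracks the sequencing coverage. With it, a threshold of
twice the average removes exactly the k-mers present at twice the typical
copy-depth or more, i.e. repeats, and leaves ordinary single-copy k-mers
alone. The plain per-k-mer mean list length is also available
(`average = "kmer"`) but is not the default for a structural reason: on
realistic data the k-mer population is numerically dominated by singleton
k-mers created by sequencing errors (at 1% error, a 300 bp pair
contributes ~3 novel k-mer types per indexed fraction), which drags that
mean far below the count of ordinary k-mers; doubling it still lands below
typical coverage, so essentially every informative k-mer would be
de-indexed and deconvolution would collapse. The occurrence-weighted mean
is insensitive to the singleton swarm. After pruning some pairs may have
no indexed k-mers left; they surface as group 0 downstream.

### Per-cloud read graph

Each barcode (*anchor*) is processed independently. For every pair of the
anchor cloud, the barcodes of its similar reads form a link set (the
anchor's own barcode is excluded by default — it is shared by construction
and carries no signal that discriminates between the anchor's fragments;
`self_barcode = "include"` restores it). The bipartite structure is then
collapsed: two anchor pairs are joined by an edge whose weight is the
number of barcodes their link sets share. By the model above,
same-fragment edges are heavy and cross-fragment edges light.

### Chinese-whispers clustering

The read graph is clustered with weighted Chinese whispers
(`chinese_whispers()`): every node starts as its own cluster; nodes are
visited in a fresh seeded-random order each pass and adopt the label with
the largest total incident edge weight among their neighbours (the node's
own current label does not vote; ties break uniformly at random). The
algorithm is parameter-free, agnostic about the number of clusters, and
converges quickly on the small, dense graphs that clouds produce; passes
stop when nothing changes or after `max_iter` (default 100, a safety cap
against the rare oscillation). Clusters are renumbered 1..G by first
appearance in read input order so output is stable and diff-friendly.
Reads with no edge at all — too noisy to overlap anything, or fully
de-indexed in repeat regions — get the reserved group 0, "not
deconvolved". A plain threshold-and-connected-components alternative was
deliberately not used: residual false links at any threshold chain
clusters together, which is exactly what the weighted local majority
tolerates.

Determinism is a contract: each cloud's clustering seed is derived from
the global seed and the barcode string (`derive_seed()`), so the result is
a pure function of (data, seed), independent of cloud processing order,
batching (`chunk_pairs`) and the `workers` partitioning.

## The simulator

`simulate_linked_reads()` generates the data the method is designed for,
with ground truth: a (optionally pseudo-diploid, `make_pseudo_diploid()`)
genome; fragments of uniform length in `[frag_len_min, frag_len_max]`
with uniform starts, enough for the target read coverage
(count = $\lceil cG / (p\bar L)\rceil$); within each fragment,
$\mathrm{round}(pL_f/(2\,\mathrm{read\_len}))$ read pairs at uniform
starts with a fixed insert of `2 * read_len` (mate 2 reverse-complemented
from the bases following mate 1); i.i.d. substitution errors at
`error_rate`; barcodes (count = fragments / `fragments_per_barcode`)
assigned to fragments uniformly at random. The defaults encode the
conditions used throughout the tests: 70-130 kb fragments, p = 0.15,
150 bp pairs at 1% error, coverage 50, 4 fragments per barcode, 1%
haplotype divergence.

Deliberate simplifications, documented rather than hidden: read starts are
uniform without overlap enforcement and the insert size is fixed (the
protocol constrains only the covered fraction); errors are substitutions
only; qualities are constant `'I'` (the algorithm never reads them);
fragments clipped at sequence ends are kept and flagged, preserving start
uniformity at a small cost in realized coverage; there are no barcode
sequencing errors and no PCR duplicates; none of the empirical
droplet-loading or coverage biases of real instruments are reproduced. A
green test suite on this generator therefore shows the algorithm is
correct under the stated model, not that it is robust to every artifact of
real linked-read data.

## Evaluation metrics

With the simulator's truth as reference (`reference_from_truth()`: one
reference cloud per fragment), `entropy_report()` scores a deconvolution
in both directions with natural-log entropies: per reference cloud, the
entropy of its reads' distribution over deconvolved clouds
(*over-deconvolution*: splitting a fragment); per deconvolved cloud, the
entropy of its composition over reference clouds (*under-deconvolution*:
mixing fragments). Both are zero iff perfect; an even two-way split scores
$\ln 2 \approx 0.693$. The natural log is pinned by that value: with base
2 the same split would read 1.0, with base 10, 0.30. Raw barcodes (every
cloud = one "deconvolved" cloud, `raw_deconvolution()`) are
under-deconvolved but not over-deconvolved, which is the baseline the
pipeline must improve. Group-0 reads are excluded by default (only
deconvolved reads are scored; `include_group0 = TRUE` restores them), each
cloud contributes one unweighted value, and histograms use 0.1-wide bins.

## Taxonomic rank promotion

All reads of a fragment come from one organism, so a cloud (ideally an
enhanced-barcode cloud) can *promote* vaguely classified reads: if the
cloud-mates' taxa strictly below a read's taxon all lie on a single
root-to-leaf chain, the read moves to the deepest of them (or their LCA
with `target = "lca"`); if the mates disagree across branches — typical
when a raw barcode mixes fragments of related organisms — nothing happens.
Deconvolution reduces exactly those conflicts, which is the point of
running it before classification. Unassigned reads adopt the cloud
consensus under the same no-conflict rule; this is optional
(`promote_unassigned`) because it is the most aggressive variant of the
idea. Promotion is monotone by construction (a read only ever moves down
its own chain), and splitting a cloud can remove supporting mates but can
never create a conflict that was not already there.

## Numerical and implementation choices

* k-mers are base-4 codes in doubles; $4^{20} < 2^{53}$ keeps all
  arithmetic exact, and the codes are computed for all reads at once with
  a 20-tap FIR filter over the concatenated base stream (reads joined by
  an `N` separator, which poisons boundary-crossing k-mers). `k` is
  capped at 26 for exactness.
* The selection threshold comparison adds 0.5 in integer code space to
  absorb the floating-point boundary where a stretch minimum sits exactly
  on a level multiple; a k-mer whose rank equals $m\,d$ exactly may thus
  be selected one level early, consistently everywhere.
* The occurrence index is two CSR arrays (k-mer to pairs, pair to k-mers);
  similarity queries are batched data.table joins, and per-cloud work is
  batched so memory stays bounded regardless of dataset size.
* Chinese-whispers tie-breaks and visit orders come from an RNG seeded per
  cloud; the caller's RNG state is saved and restored around every
  stochastic step, so library calls never perturb user code.
* Degenerate inputs: clouds of one pair get group 0 (no edges are
  possible — this follows the tag-0 rule literally and slightly depresses
  the deconvolved fraction when clouds are tiny); empty link sets,
  unbarcoded reads and empty datasets flow through without special cases.

## Problem sizes used in the tests

The test-suite replications run at desk scale, chosen once: the main
end-to-end run uses a 200 kb random pseudo-diploid genome with fragments
scaled to 7-13 kb (all other protocol parameters as above), giving ~65 000
read pairs, ~13 300 fragments and ~3 300 barcodes. The planted-partition
benchmark uses a haploid 400 kb genome with 2-3 kb fragments and p = 0.75,
error-free — chosen so the same-fragment/cross-fragment separation ratio
(~35) sits in the method's intended operating regime while each fragment
still yields ~6 read pairs.

## Known limitations

* Scaling the genome down while keeping coverage fixed shrinks the barcode
  pool quadratically relative to fragment coverage: at the 200 kb scale
  the separation ratio is only ~9 (vs. $\gtrsim 30$ at megabase scale and
  $\sim 10^3$ in real experiments), and ~50% of multi-fragment clouds
  contain two fragments whose genomic footprints overlap. Reads of such
  fragments are statistically indistinguishable from barcode-overlap
  information alone, so a tail of mixed clouds at that scale is inherent
  to the conditions, not a property of the estimator; the entropy tests
  quantify it.
* Enhanced clouds can be over-split, typically into the two ends of a
  fragment whose middle is thinly covered; the resulting clouds are still
  locally coherent, and show up as an over-deconvolution mode near
  $\ln 2$.
* Large segmental duplications defeat repeat de-indexing by construction:
  fragments of one barcode lying in different copies cannot be separated.
* The implementation is single-process; `workers` fixes the partitioning
  contract (identical results for any value) rather than spawning threads.
* Rank promotion trusts the input classification; a misclassified mate on
  the right chain will promote its cloud confidently and wrongly.
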