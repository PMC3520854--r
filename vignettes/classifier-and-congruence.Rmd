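---
title: "Word-based naive Bayesian rRNA classification and training-set congruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-based naive Bayesian rRNA classification and training-set congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxnbc)
```

## The problem

Short 16S rRNA amplicon reads from poorly characterized environments —
insect guts are the motivating case — are routinely assigned to taxa with
a word-based naive Bayesian classifier (NBC) trained on a general-purpose
reference database. When the community contains deep, environment-specific
lineages that the reference databases cover thinly, three things happen:
many reads cannot be classified confidently, different databases assign
the same read to different taxa, and bootstrap confidence drops. The
remedy examined here is to build a small environment-specific reference
database with a bespoke taxonomy and *augment* each general-purpose
training set with it. `taxnbc` implements the classifier, the
database-construction rules, the multi-training-set congruence analytics,
and a seeded simulator that reproduces the whole design on synthetic
data, so every step can be tested end to end without external downloads.

## The classifier

A training set is a pair of files: reference sequences and a
tab-separated taxonomy assigning each reference an ordered six-rank
lineage (Domain, Phylum, Class, Order, Family, Genus). Sequences are
decomposed into overlapping words (k-mers) of length $w = 8$; windows
containing an ambiguity code are skipped.

With $N$ training sequences of which $n(w)$ contain word $w$ at least
once, the word prior is

$$ P(w) = \frac{n(w) + 0.5}{N + 1}, $$

and for a genus $G$ with $M$ sequences of which $m(w)$ contain $w$,

$$ P(w \mid G) = \frac{m(w) + P(w)}{M + 1}. $$

A query read with distinct word set $V$ is assigned the genus maximizing
$\sum_{w \in V} \log P(w \mid G)$. The pseudo-counts keep every
conditional probability strictly positive, so scores are always finite,
even for genera sharing no word with the read. Word *presence*, not
multiplicity, enters both training and scoring — the convention of the
classical rRNA NBC formulation this package follows. Exact score ties
are broken toward the lexicographically smallest genus identifier, which
makes every result deterministic.

Confidence is estimated by bootstrap: each of 100 trials samples
$\max(1, \lfloor |V|/8 \rfloor)$ words from $V$ uniformly with
replacement and records the winning genus of the subsample. The reported
genus is the one winning the most trials; the confidence at a rank is
100 times the fraction of trials whose winner's lineage passes through
the reported taxon at that rank. Because a trial that supports a genus
also supports every ancestor of that genus, confidence is non-decreasing
from Genus up to Domain by construction. The bootstrap seed is a
required, recorded parameter; identical seeds give bit-identical output.

Reporting uses a 60% confidence threshold: scanning from Domain to
Genus, the first rank whose confidence falls below the cutoff — and
every deeper rank — is relabelled `unclassified`. Confidence exactly
equal to the cutoff passes. A read below the cutoff even at Domain is
unclassified overall.

Reads are assumed primer-oriented (directional amplicons); no
reverse-complement scan is performed.

## Building a custom database

Candidate full-length sequences pass through four stages
(`build_custom_db()`):

1. **Length filter** — ungapped length at least 1250 bp (inclusive),
   keeping only near-full-length candidates.
2. **Dereplication at 99% identity** — greedy centroid clustering,
   processing sequences longest-first (ties by id); a sequence joins the
   first representative at or above the threshold, otherwise founds a
   new cluster. Longest-first favors full-length representatives and is
   deterministic.
3. **Nearest cultured hit** — each representative is compared against a
   set of cultured references by global alignment (match +1, mismatch
   −1, gap −2; identity = matching columns / columns after trimming
   terminal gaps). This replaces an online database search with an
   in-package computation using the same decision variable.
4. **Placement rule** — if the best cultured hit is *more than* 95%
   identical, the candidate adopts the hit's lineage down to genus.
   Otherwise it is placed in the class supplied by the user's
   phylogenetic framework and the ranks below Class are marked *incertae
   sedis*; a clade name, when known (e.g. "firm-4"), occupies the Family
   rank, and a previously published genus name can be retained at Genus.
   The 95% boundary is strict: exactly 0.95 goes to the class-level
   rule.

Clade membership is an input (a small TSV), not something the package
infers: in practice it comes from a phylogeny built and inspected with
external tools, a judgment this package deliberately does not
algorithmize. Every placement is recorded in a provenance table (hit,
identity, basis).

Incertae-sedis marks are stored as per-rank flags and serialized into
taxonomy files by suffixing the label with `_incertae_sedis`, so files
round-trip exactly. Lineages shorter than six ranks on input are padded
downward with flagged placeholders repeating the deepest named label;
more than six unprefixed ranks is an error (rank-prefixed
Greengenes-style lineages are reduced to the six canonical ranks). How
to reconcile databases that use suborders or subclasses is genuinely
underdetermined; normalizing everything to six ranks is this package's
choice, and it is applied uniformly to every set being compared.

`augment()` concatenates a base set with a custom set; an id collision
is a hard error, because silently overriding a reference would corrupt
the attribution of classification differences between sets.

## Congruence evaluation

`classify_all()` classifies every query against every training set
(per-set seeds derived deterministically from the master seed and the
set name) and the analytics are all recomputable from the resulting
table:

* **Rank congruence** — at a rank, a query is *congruent* when all sets
  report the same non-`unclassified` label; *mutually different* when
  all pairwise labels differ, with `unclassified` counting as a label of
  its own; *partial* otherwise. The three categories partition the
  queries. Whether shared unclassifiedness should count as agreement is
  undefined in general; here it never counts as congruence, and two
  `unclassified` labels are not "different" — both choices are explicit
  and tested.
* **Pairwise agreement** — counts of queries with identical
  non-`unclassified` labels for each pair of sets.
* **Unclassified counts** — per set, both the overall count (Domain
  unclassified) and per-rank counts. In a single-domain world the
  Domain-level count is structurally zero — every bootstrap trial's
  winner shares the domain — so the informative counts are at the deeper
  ranks; the augmentation analysis below uses the Family rank,
  matching the rank at which the congruence and bootstrap effects are
  measured.
* **Mean family bootstrap** — per set, queries grouped by the family
  label *that set* assigned (not a reference truth), averaging the
  family-rank confidence: the per-set family summary behind heat-map
  style figures.
* **OTU tallies** — exact dereplication of reads, 97%-identity OTU
  clustering (the same greedy engine as the 99% dereplication, so the
  two stages cannot diverge), and per-family unique/OTU counts.

## The simulator

`scenario_config()` fixes all generation parameters; every output is a
pure function of the configuration. The defaults define the package's
reference study conditions:

| parameter | default | meaning |
|---|---|---|
| taxonomy shape | 4 phyla × 2 families × 2 genera | 16 genera in 8 families |
| refs per genus | 5 | reference sequences per genus |
| reference length | 1300 bp | near-full-length rRNA |
| divergence | 0.02 / 0.08 / 0.15 / 0.25 | per-branch substituted fraction at genus / genera / families / phyla |
| read window | positions 20–340 | 5′ hypervariable-like subwindow |
| read length | 250 bp | directional amplicon read |
| read error rate | 0.005 per base | substitution errors |
| reads | 500 | query set size |

A single root sequence is drawn uniformly over ACGT and mutated down the
hierarchy; each divergence value is the per-branch probability that a
site is substituted (replacement uniform over the three alternatives).
Reads pick a genus, then a reference, excise the window, truncate to the
read length and apply independent per-base errors. Evolution is
substitution-only — no indels, no chimeras, no homopolymer error model —
which keeps identities and window excision exactly computable; the
divergence defaults produce the strict identity ordering within genus >
within family > within phylum that real rRNA taxonomies show at these
ranks.

Because substitutions fall uniformly, the simulator has no conserved
sites. Real 16S genes alternate conserved and hypervariable regions, so
real novel reads share many words with *every* reference and produce
broader bootstrap scatter than synthetic reads at the same divergence.
Passing the recovery and augmentation checks here demonstrates the
machinery is correct under controlled conditions, not that any
particular real community will show effects of the same magnitude.

### The holdout scenario

`make_holdout_scenario()` reproduces the augmentation design: the
references of the holdout genera (default: both genera of one family in
each of two phyla — two complete families, so held-out reads are novel
clades with no family-level relatives in any base set, like the deep
environment-specific clades that motivate a custom database) form the
custom set. Three base sets are built from the remaining references by
jackknifing *genus coverage*: each base set drops all references of a
distinct random third of the non-holdout genera. Coverage jackknifing —
rather than thinning references uniformly — is what makes the base sets
behave like independently curated databases of different breadth: a read
whose genus a set lacks must be forced onto that set's nearest
remaining relatives, which is precisely the mechanism behind confident
misclassification and sub-threshold bootstrap scatter. Each base set
also applies a recorded, invertible *label dialect* (a per-set renaming
of Phylum through Family; Domain stays `Bacteria`, as real databases
agree there), emulating the incompatible taxonomic frameworks of
independently maintained references. Half of the reads derive from
holdout genera.

At these conditions, classifying the 500 reads against the three base
sets and again after augmenting each with the custom set, the package's
acceptance checks require: fewer Family-rank unclassified reads in every
set, a strictly larger all-sets-congruent count at Family, and a
strictly higher mean family-rank bootstrap over holdout-derived reads in
every set.

## Numerical and implementation choices

* Words are encoded as base-4 integers into a dense $4^w$ count vector
  per genus, which keeps training and scoring fully vectorized;
  $w$ is limited to 1–10 ($w = 8$ default).
* Confidence comparisons in the threshold use plain `<`; the cutoff is
  in percent, on the same scale the confidences are reported.
* Alignment identity uses `Biostrings::pairwiseAlignment` (global,
  match +1, mismatch −1, gap −2) with terminal gap columns trimmed.
  Tests check it against an independent dynamic-programming
  implementation on substitution-diverged pairs, where the optimal
  alignment is unambiguous; near-equal-scoring alternative alignments
  can differ in identity at higher divergence, which is why clustering
  guarantees are only claimed for well-separated inputs (margins of
  several percentage points around the threshold). Near the threshold,
  greedy centroid clustering is order-dependent and only determinism is
  guaranteed.
* All randomness (simulation, bootstrap, jackknife) flows from explicit
  integer seeds through isolated RNG scopes, so library calls elsewhere
  cannot perturb results; derived seeds are 31-bit hashes of the parent
  seed and a string tag (set name, read id).

## Problem sizes

The test-suite and acceptance computations use the reference conditions
above: 100 random toy instances (word size 4, reads 30–60 bp) for the
brute-force oracle comparison, the 500-read default scenario for
recovery, and the 500-read holdout scenario (3 base sets before and
after augmentation, 3,000 bootstrap classifications) for the
augmentation analysis. These sizes were chosen to exercise every code
path at full depth while remaining comfortable on a single CPU.

## Limitations

* The simulator does not model indels, chimeras, platform-specific
  error profiles, conserved-site structure or realistic abundance
  distributions.
* The classifier does not scan reverse complements and has no
  alignment-based or phylogenetic-placement fallback.
* Clade membership for the class-level placement rule must be supplied;
  the package does not infer trees.
* Congruence treats taxonomy labels as opaque strings; synonymy between
  frameworks must be resolved upstream (or via the recorded dialect map
  in simulations).
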