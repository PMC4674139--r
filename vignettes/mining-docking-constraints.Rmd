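---
title: "Mining literature-derived constraints for protein-protein docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining literature-derived constraints for protein-protein docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockmine)
```

## The problem

Rigid-body docking of two proteins produces thousands of candidate
matches, and picking the near-native ones is the hard part. For many
interactions, however, the biomedical literature already names residues
involved in binding. `dockmine` implements a pipeline that turns
published abstracts into residue-level docking constraints:

1. **Retrieval** — boolean PubMed-style queries are assembled from the
   protein pair's names. An *AND-query* demands both interactors in an
   abstract; an *OR-query* accepts either, retrieving far more text at
   the price of more noise.
2. **Extraction** — residue mentions (`Ser 4`, `alanine23`, `S4A`) are
   pulled from the abstracts with a regular-expression grammar.
3. **Structural filtering** — a mention survives only if its residue
   name and number match a *surface* residue of the target structure
   (relative solvent exposure of at least 25%); an identified residue
   is *correct* when it lies at the crystallographic interface (any
   heavy atom within 6 Å of the partner).
4. **Relevance filtering (optional)** — a bag-of-words SVM removes
   abstracts written in a non-interaction context.
5. **Constraints and rescoring** — surviving residues are ranked by a
   capped confidence score and used to re-sort the docking scan output.

Per complex, mining quality is summarized by the fraction of correct
residues among all identified ones,
$$P = \frac{\sum_i N_i^{\mathrm{int}}}{\sum_i (N_i^{\mathrm{int}} + N_i^{\mathrm{non}})},$$
accumulated over the $N$ abstracts that contained residues
(`ptm()`). At dataset level, `dataset_metrics()` reports coverage
($L_{\mathrm{tot}}/n$), success ($L_{\mathrm{int}}/n$) and accuracy
($L_{\mathrm{int}}/L_{\mathrm{tot}}$), rounded half-up to one decimal.

## Query construction

`normalize_name()` trims trailing whitespace, percent-encodes
everything outside the RFC 3986 unreserved set (space becomes `%20`),
and expands hyphens. For each hyphen the full set of
{keep, remove, replace-by-space} combinations is generated, so a name
with two hyphens yields up to $3^2 = 9$ variants:

```{r}
normalize_name("IL-15R-alpha")
```

Two design points were genuinely open:

* **Variant superset.** For multi-hyphen names we generate the complete
  cartesian product over hyphens rather than a curated subset. Extra
  variants can only add retrieval recall; a variant that matches
  nothing costs nothing. Encoding is idempotent — re-normalizing any
  emitted variant reproduces members of the same set — which keeps
  query construction stable under repeated processing.
* **Name-length rules.** Names shorter than 3 characters are too
  ambiguous to query and are dropped; exactly-3-character names are
  AND-restricted with the keyword `protein` at query-assembly time.

Proteolytically processed entries ("cleaved into chains") are resolved
by `resolve_cleaved_names()` with three scenarios keyed on exact
matching of the structure entry's name: match to the recommended name
(use recommended plus all chain names), match to exactly one chain
name (use recommended plus that chain), or no match (use recommended
plus the structure name). "Exact" means Levenshtein distance zero after
case-folding and whitespace collapsing — a string-distance routine is
used, but only the distance-0 decision is needed for all three
scenarios. Generic-word protein names (e.g. `act`) are AND-combined
with caller-supplied controlled-vocabulary (MeSH) terms; the vocabulary
is configuration, not hard-coded, because the appropriate heading
depends on the corpus. Gene names, organism names, E.C. numbers and
CD-antigen tags are deliberately excluded from queries.

## Corpora

The canonical on-disk format is a small JSON schema (`read_corpus()`,
`write_corpus_json()`); MEDLINE/PubMed XML is supported read-only.
Records carry a `retrieved_by` tag set (`AND`, `OR-1`, `OR-2`). The two
halves of an OR-query are submitted separately so an abstract's tags
record which interactor it mentions; an abstract matched by both halves
keeps both tags, since the format does not privilege either interactor.
Every abstract retrieved by an AND-query is by construction also
retrievable by the OR-query, so AND tags are unioned onto the same
records. Date filtering is at day resolution and *conservative*:
records with an unknown date fail any active window, because a record
that cannot prove it predates the structure paper must not leak into a
blind-prediction benchmark. Live E-utilities retrieval is an injectable
adapter (`fetch_pubmed()`); calling it without a transport is an
explicit "offline" error rather than a silently empty corpus, and no
test depends on the network.

## The mention grammar

Residue numbers are `[1-9][0-9]*` — a leading zero invalidates a
match. Three-letter codes match in exactly three case styles (`Ser`,
`ser`, `SER`) and full names in two (`Serine`, `serine`); other mixed
casings (`aLa`) are rejected as noise. Name and number may be joined by
nothing, one space, a hyphen, or the number may be parenthesized with
no interior spaces (`His(57)` yes, `His( 57 )` no). Every match must
sit on word boundaries on both sides, so fragments of database
accessions such as `XGLY2003` never fire; the printed pattern grammar
leaves boundary context unstated, and boundaries are the conservative
reading.

Mutation shorthands (`S4A`, `Ser4Ala`, `Ser-4Ala`) are matched **only**
when the abstract contains a mutagenesis keyword (`mutation`,
`mutagenesis`, `mutagen`, `mutant`, `substitution`; whole-word,
case-insensitive). A matched mutation emits *both* the original and the
substituted residue, since an abstract about an S4A mutant carries
information about position 4 regardless of which residue sits there.
Bare one-letter mentions outside mutation context are out of scope:
disambiguating them needs sentence-level parsing.

## Structural filtering

Structures are read from PDB files (first model, `ATOM` records,
hydrogens and waters dropped, highest-occupancy alternate conformers
kept). Solvent-accessible surface area is computed with a
Shrake–Rupley-style rolling-probe sphere sampling: probe radius 1.4 Å,
960 quasi-uniform lattice points per atom, element-based van der Waals
radii. Relative exposure divides the per-residue area by the
theoretical maximum area for that residue type (Tien et al. 2013
table); residues at or above 25% are surface. The sampling density and
max-area reference are configuration with sensible defaults — any
standard SASA implementation preserves the intent of the 25% rule, and
the test suite pins the implementation against an independent
latitude–longitude grid quadrature (areas within 5%, surface sets
within one residue on toy structures).

Interfaces use the inclusive 6 Å heavy-atom cutoff. Surface and
interface sets are computed independently — neither is derived from the
other, and nothing forces interface residues to be surface residues of
the isolated chain.

Mined numbers follow the reference (database) sequence, which often
disagrees with structure numbering. `map_numbering()` aligns the
reference sequence against the chain sequence globally (identity-scored
substitution matrix; match +2, mismatch −1, gap open 4, extend 1) and
maps aligned positions; it refuses below 90% identity over the shorter
sequence, because a low-identity "mapping" would manufacture residue
matches from noise. Mentions are plain integers, so they match only
residues with a blank insertion code; with mapping disabled the raw
structure numbering is used (both modes are legitimate analyses).

`identify_residues()` applies the retrieval-mode rule: AND-retrieved
abstracts are checked against both interactors, OR-retrieved ones only
against the interactor the abstract mentions, which bounds the rate of
accidental name/number coincidences.

## Relevance filtering

Training labels come from the identified-residue counts of an abstract:
positive when `n_int − n_non > 4` or (`n_non = 0` and `n_int > 0`),
negative in the mirrored cases, otherwise unused. The rules are
exhaustive and exclusive; abstracts with no identified residues at all
are unused — they carry no evidence either way.

Tokenization lower-cases, strips stop words (a compact configurable
list), removes caller-supplied protein and amino-acid names (they were
part of the query and would leak the label), and applies the Porter
suffix-stripping algorithm, implemented in the package and verified
against the algorithm's published worked examples. A configurable
exception map collapses spelling families that plain suffix stripping
leaves apart; it ships with the `inclu-` and `muta-` families and is
user-extensible, as the appropriate list is corpus-dependent.

Per-class stem frequencies are normalized token counts,
$f_k(m) = \frac{1}{L_k}\sum_i J_i(m)$; feature vectors use the raw
per-abstract counts $J_i(m)$ (the presence/absence variant reportedly
performs in the same range and is not implemented). Stems pass
selection when $|f_{pos}(m) - f_{neg}(m)| > 0.02$ and
$f_{pos}(m) + f_{neg}(m) > 0.2$, and are ordered by the contrast
$\delta(m) = (f_{pos} - f_{neg})/(f_{pos} + f_{neg})$. The bundled
`inst/extdata/feature_sets/` files carry the published manual sets
(MF60–MF10) and the published full automated set (AF143, in decreasing
$\delta$ order); the $\delta$ values themselves are corpus-dependent
and not reproducible offline, so truncated automated subsets are
recomputed from whatever corpus is at hand via `truncate_features()`.

The classifier is a soft-margin SVM (libsvm via `e1071`), feature
vectors unscaled, with linear, polynomial
$(\alpha x_i \cdot x_j + c_0)^d$ ($\alpha = 1$, $c_0 = 0$) and RBF
$\exp(-\gamma|x_i - x_j|^2)$ kernels. Classification follows the sign
of the decision value; scores within a margin (default half-width 0.05)
are "unclassified" and excluded from metric evaluation. The 80/20
train/validation split is per class, seeded and deterministic; with 450
positive and 855 negative abstracts it yields 360/684 training and a
261-abstract validation set.

Metrics are the standard precision, recall, accuracy and the Matthews
correlation coefficient with the **signed** numerator,
$MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$.
Some presentations print the numerator with a plus sign; only the
signed form reproduces the ~0.25 values implied by the published
confusion matrices, so the signed form is used. Metrics with a zero
denominator are reported as undefined (`NA`), never silently as zero.

## Constraints and rescoring

Each identified residue gets the confidence
$f(R) = \min(10, \sum_{i=1}^{N_R} a_i)$ over its distinct source
abstracts, $a_i = 2$ for AND-retrieved and $1$ for OR-only abstracts;
the cap balances single-mention constraints against residues
over-represented in the literature. The cap is applied to the score
only — the raw count of AND contributions is kept separately, because
the tie rule needs it: when more residues than the per-interactor
budget (default 5) share the cutoff confidence, residues with more
AND-derived contributions win, and remaining ties are removed by a
seeded random draw.

For validation, `reference_constraints()` extracts the
crystallographic interface, ranks all cross-interface residue pairs by
Cα–Cα distance and returns the top three with maximal confidence;
exactly tied distances are broken lexicographically by chain and
residue number (the choice is arbitrary but must be stable).

`rescore()` scores every docking match by the summed confidence of
constraint residues at the *model* interface, operationalized with the
same 6 Å heavy-atom rule used for real interfaces (the model-interface
cutoff is otherwise unspecified, and reusing the interface definition
keeps one geometric notion throughout). The sort is stable and
descending, so equal scores preserve scan order and an empty constraint
set leaves the ranking untouched. Match quality is the ligand interface
Cα RMSD (i-RMSD): the unbound ligand is least-squares superimposed onto
the bound ligand within the complex, and the RMSD runs over the
interface residues of the bound reference, matched by residue number
(unmatched residues are skipped and counted). The ligand is the smaller
protein. Success criteria are inclusive: *strict* = some match with
i-RMSD ≤ 5 Å in the top 10, *relaxed* = i-RMSD ≤ 8 Å in the top 100.

## What the synthetic fixtures do and do not show

The package generates all its test data:

* `generate_mention_corpus()` plants residue mentions in
  grammar-conformant surface forms inside templated filler sentences,
  recording the expected extraction as ground truth. It exercises every
  admitted style/case combination and the mutation-context contrast.
* `generate_svm_corpus()` draws abstract tokens from an
  interaction-flavored vs. a clinical/genetics-flavored vocabulary with
  a tunable separation; at full separation a linear SVM must recover
  the labels almost perfectly (validation MCC > 0.9).
* `generate_complex()` builds two facing synthetic chains whose contact
  patch sits at a closest heavy-atom distance of 5.5 Å while every
  non-patch pair is beyond 6 Å, so the interface truth is exact by
  construction; residues use the 19 standard types with a side-chain
  atom. It also emits jittered/rigidly perturbed unbound copies and a
  pose list with one near-native pose and far-away decoys. Poses and
  i-RMSD references are expressed in the bound-receptor frame: the
  unbound receptor differs only by coordinate jitter, which emulates a
  conformational difference without leaving the frame the pose list is
  defined in.

Default problem sizes — chains of 20–30 residues, corpora of tens to a
couple hundred abstracts, pose lists of ~20 matches — are chosen so the
complete suite exercises every code path in seconds; the geometry and
statistics of the methods do not change with size. Passing tests
demonstrate that the machinery is implemented correctly: full recall on
planted mentions, agreement with brute-force geometric oracles,
parameter recovery on separable text. They deliberately do **not**
demonstrate performance on real literature or real structures —
abstracts here are templated token bags, not English prose; toy chains
have no packing, secondary structure or burial gradients; and retrieval
noise, numbering chaos and nomenclature drift of real corpora are all
absent. Corpus-scale retrieval counts and benchmark success-rate gains
are therefore outside what this package can or tries to reproduce
offline.

## Known limitations

* One-letter residue mentions outside mutation context are not mined.
* mmCIF input and NMR multi-model handling (beyond taking the first
  model) are unsupported.
* The docking scan itself is out of scope; the package consumes a
  ranked pose list and re-sorts it.
* The automated feature sets beyond AF143's stem list (their $\delta$
  values, and hence AF138/AF24 as fixed artifacts) are corpus-dependent
  and must be recomputed on the user's corpus.
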