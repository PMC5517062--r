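---
title: "Mining in vivo bioassay descriptions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining in vivo bioassay descriptions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vivominer)
```

## The problem

Whole-animal (in vivo) drug-screening assays are summarized in curated
bioactivity databases by one-sentence, curator-written descriptions such as

> *Inhibition of carrageenan-induced paw oedema in Sprague-Dawley rat at
> 5.16 mg/kg, sc after 3 hrs*

Each description packs the animal model (genetic strain, induced disease
model, or transgenic line), the phenotypic readout, and dosing details into
roughly twenty words. No structured fields carry that information, so
comparing or clustering tens of thousands of such assays requires text
mining. vivominer implements a complete pipeline for this corpus type:
normalization and shallow parsing, dictionary- and rule-based named entity
recognition (NER), a word-embedding semantic space, random-forest
classification of assays by the ATC class of their reference drugs, and a
bipartite drug/animal-model network.

## Preprocessing and the chunking grammar

Descriptions are first normalized: binomial species names become common
names ("Rattus norvegicus" → "rat") and whole-token administration
acronyms are expanded ("sc" → "subcutaneous", "qd" → "daily") from an
editable twenty-entry table (`vm_acronym_map()`). Every normalization is
recorded in an offset map so spans can be translated between raw and
normalized coordinates in both directions (`map_span()`); this is what lets
gold annotations made on raw text score predictions made on normalized
text.

Tokens are tagged with Penn-Treebank-style parts of speech. The reference
backend for this corpus is an external biomedical tagger distributed as a
native binary, which a source package cannot bundle; the tagger is
therefore a pluggable function (`tag_tokens(tagger = )`) and the bundled
default is a deterministic lexicon-plus-suffix tagger with small editable
protein/cell-line lexicons standing in for the backend's biological NER
flags. The bundled tagger is crude by design — closed-class words from a
lexicon, `-ed`/`-ing`/`-ly`/adjectival suffix rules, chemical-noun
exceptions — but it is reproducible, dependency-free, and sufficient for
the grammar below; results on real corpora will improve with the external
backend plugged in.

Custom tags overlay the POS layer (`apply_custom_tags()`):

* `IND`/`IND_B` on twenty-four procedure triggers (*induced*, *infected*,
  *xenografted*, *fed*, *operated*, *(pre)treated*, *stimulated*, ...);
  the `IND_B` subset contains triggers that can legitimately begin a
  phrase (*fasted*, *trained*, *deprived*, *exposed*). Only a third of the
  full keyword list is printed in the method's public description; the
  shipped list completes it with documented extrapolations and is editable
  via `vm_keyword_config()`.
* `TRANSG`/`EXPR`/`KNOCK` on transgenesis keywords (*transgenic*,
  *overexpressing*, *knockout*, ...).
* `SP` on species words, `PROT`/`CELL` from the tagging backend.

Base noun phrases are the maximal, non-overlapping, leftmost-longest
matches of

```
NP: {<JJ|NN.*>* <PROT|CELL|NN.*>+}
```

over grammar symbols in which a token's custom tag takes precedence over
its POS tag. Two consequences matter. Determiners and numbers can never
enter a phrase unless the backend flagged them as part of a protein or
cell-line name ("Concanavalin **A**"). And because procedure triggers
carry `IND` rather than a noun tag, phrases split automatically at
triggers, separating experimental stimulus from phenotypic outcome:
"concanavalin A induced hepatic cell necrosis" yields *concanavalin A* and
*hepatic cell necrosis*. Hyphenated stimuli are split at the hyphen during
tokenization precisely so this rule fires on "carrageenan-induced".

The implementation is verified against two independent oracles in the test
suite: the literal grammar regular expression applied by R's regex engine,
exhaustively over every tag sequence of length ≤ 8 on the behaviourally
distinct alphabet, and a brute-force leftmost-longest enumeration over all
substrings for lengths ≤ 5.

## Dictionaries and named entity recognition

**Genetic strains.** A strain dictionary is compiled per species from a
listing table of basic strains with their type, synonyms and substrains
(`compile_strain_dictionary()`). All lookups use alphanumeric match keys —
lower-cased with every non-alphanumeric character removed — so punctuation
variants collide ("ob-ob mouse" = "ob/ob mouse"). Substrain designations
fold onto their parent if and only if the prefix before "/" is a known
inbred basic strain ("AKR/NCr" → "AKR"); unknown prefixes are left intact
to protect hybrid names like "B6D2F1" and intrinsic slashes like "ob/ob".
Matching is longest-first on token sequences, tolerates interleaved
sex/age modifiers ("C56BL/6J **male** mouse"), and normalizes to
"<preferred name> <species>".

**Phenotypes.** A dictionary built from OBO ontologies
(`load_phenotype_dictionary()`): labels plus exact synonyms of
non-obsolete terms, synonyms folding onto the label. Exact-only synonyms
are the default — broad/related synonyms of clinical ontologies are noisy —
with `synonym_scope = "all"` to widen. Terms shorter than 3 characters and
a curated blocklist of generic English words are excluded; this trades
recall for precision, which is the documented behaviour of dictionary NER
on this corpus. Matches consisting solely of measurement words (*level*,
*production*, ...) directly after a protein token are suppressed as
molecular biomarkers ("IL4 production") rather than phenotypes; the
suffix set is a visible argument because the underlying distinction is
described only by example in the source method.

**Induced and transgenic models.** No controlled vocabulary exists, so
extraction is rule-based (`extract_rule_entities()`). The core pattern
`{<NP|FW|POS>* <IND>+}` captures noun-phrase runs ending in procedure
triggers ("Freund's complete adjuvant induced", "Staphylococcus aureus
infected"); the transgenic family uses the same shape over
`TRANSG|EXPR|KNOCK` ("APOA1 transgenic"); and head-noun phrases ending in
*test*, *assay*, *model*, *paradigm* or *task* are captured without a
trigger ("glucose tolerance test"). Only the core pattern is printed in
the method's public description; the companion patterns reconstruct the
documented eight-pattern set and each is unit-tested against the published
example strings.

**Evaluation.** `evaluate_ner()` scores per-class and micro-averaged
precision/recall/F1 under *exact* (identical class and span) and *partial*
matching. The source method cites an external strict/relaxed scheme
without reprinting it; this package defines partial as *same class, any
character overlap*, and uses the identical machinery for inter-annotator
agreement between two annotation sets. Exact F1 ≤ partial F1 holds by
construction and is asserted over randomized prediction/gold pairs.

## The embedding semantic space

Token streams for embedding training (`tokens_for_embedding()`) emit
multi-word noun phrases as single underscore-joined tokens, replace strain
mentions with their normalized names ("c57bl_mouse"), and drop numbers,
measurement units and a fixed snapshot of a standard English stopword
list, all lower-cased.

`train_embeddings()` is a single-threaded CBOW/skip-gram implementation
with negative sampling, written for this package because the R environment
offers no established word-embedding package. It follows the reference
algorithm (dynamic window, unigram table with power 0.75, linear learning
rate decay) and is bit-reproducible for a fixed seed. Defaults are the
published corpus settings: **250 dimensions, window 5, minimum count 30**.
Three parameters the source leaves unstated are fixed here as: CBOW
architecture (the training tool's default at publication time; skip-gram
is available and passes the same planted-structure tests), 5 epochs, and
no frequency subsampling (`sample = 0`) so that small corpora keep all
planted tokens deterministically.

Queries: `nearest_terms()` (cosine, query excluded), `analogy_query()`
(rank by cosine to `vec(a) − vec(b) + vec(c)`, query tokens excluded; with
`a == b` the ranking provably reduces to the nearest neighbours of `c`),
`assay_vector()` (unit-normalized mean of in-vocabulary token vectors; an
all-out-of-vocabulary description returns a flagged zero vector and is
excluded from classification).

`similarity_matrix()` builds the model-by-phenotype cosine matrix,
Z-scores each row, and clusters rows and columns with average linkage on
Euclidean distances. Whether the column dendrogram should be computed on
the raw or the Z-scored orientation is ambiguous in the source figure;
both are returned (`col_hclust`, `col_hclust_raw`). `project_assays_2d()`
reduces assay vectors to 20 principal components (or the matrix rank) and
then applies t-SNE; the perplexity default is 30 (unstated in the source),
automatically reduced for small samples, and recorded with the seed in the
output attributes.

Exact reproduction of published cosine values is out of reach — they are
stochastic and corpus-version dependent — so the tests verify rank-order
properties: planted synonyms rank first, planted disease→readout pairings
answer analogy queries, and planted synonym pairs beat random pairs under
a 1,000-shuffle permutation test.

## Classification by reference-drug ATC class

Many assays include approved drugs as positive controls; their WHO ATC
codes label the assay. Four problems are predefined (`class_problem()`):
cidal vs non-cidal, nervous-system vs other, the five most common
therapeutic groups (N03, N05, L01, A10, and the C01/M01/M02/S01
anti-inflammatory combination carried by indomethacin — handled by the
code-set map, not drug-specific rules), and six nervous-system subclasses.
"Approved" means development phase 4. The cidal code set beyond the four
published prefixes ships as the editable default {L01, J01, J02, J04,
J05, P01, P02, P03}. An assay is labeled only when the level-2 prefixes of
all its approved drugs map to exactly one class (the unambiguity rule);
exclusions are reported with reason codes.

Cross-validation (`cross_validate_rf()`) uses 10 folds under two splits:
plain assay-wise, and document-wise, in which all assays curated from one
publication share a fold. Same-document assays are frequently
near-duplicates differing only in dose or timing, so the assay split leaks
and overestimates accuracy; the synthetic corpus reproduces this effect
directionally (document-split accuracy ≤ assay-split accuracy).

The forest is 200 trees with Gini splits, `sqrt(p)` features per split,
and balanced class weights `n/(K·n_c)`, matching the published settings;
it is implemented in compiled code within the package because no
random-forest package is available in the target environment. Two
conventions the source leaves open are fixed and labeled: reported
accuracy is pooled over held-out predictions (the mean over folds is also
emitted), and the out-of-bag estimate comes from one fit on the full
labeled set. Feature vectors are frozen before cross-validation (the
embedding is trained once on the full corpus, as the source implies);
note this means fold-external token statistics inform the features — a
strict per-fold retraining mode would be leakage-free but deviates from
the published procedure.

Per-class phrase enrichment (`enriched_phrases()`) uses the one-sided
Fisher exact test on presence/absence 2×2 tables, computed from the
hypergeometric distribution and verified in the tests against exhaustive
combinatorial enumeration for all tables with margins ≤ 50, including the
forced p = 1/C(6,3) = 0.05 case.

## The drug–model network

`build_network()` links an approved drug to an animal model when they
co-occur in at least five **distinct assays** (the alternative — counting
assay-compound pairs — is rejected because the construction is stated per
assay). General-purpose strains (outbred stocks screened across all
indications: Wistar rat, Sprague Dawley rat, Swiss mouse, ...) are
excluded via an editable list seeded from the published outbred markings,
and synonymous model names are consolidated through a merge map
("maximum electric shock" → "maximal electroshock"). Isolated nodes are
dropped, matching the published node-count construction. Bipartiteness is
verified structurally; raising the threshold is monotone (never adds
nodes or edges). Exports: GraphML (primary), GML (logical attributes
written as 0/1 since GML lacks booleans), and TSV edge lists.

## The synthetic corpus generator

`generate_corpus()` emits the full artifact set — assay, compound and link
tables, BRAT-compatible gold annotations, and a ledger of every planted
truth — from a seeded configuration. Its stated world:

* **Templates.** Descriptions of 10–30 words of the form
  "*<effect> of <stimulus>-induced <phenotype> in <strain> <species> at
  <dose> mg/kg, <route> after <time> hrs*" and one reordered variant.
  Doses are log-uniform in 0.1–100 mg/kg and never part of gold spans.
* **Documents.** Assays of one document (default 3–6) share class,
  template and planted entities, differing in dose/route/timing — the
  near-duplicate structure that motivates document splits.
* **Vocabularies** are seeded from entity names common in rodent
  pharmacology (maximal electroshock, carrageenan, streptozotocin, P388
  leukemia; SHR, ZDF, ob/ob, Sprague Dawley; phenytoin, indomethacin,
  metformin with their real ATC codes) so fixtures read realistically.
  `vocab_overlap` interpolates between fully class-separable vocabularies
  (0) and identical pooled vocabularies including the strain pools (1).
* **Noise knobs**, all default 0 so the default world is clean: strain
  synonym/substrain surfaces ("ob-ob mouse", "Black 6 mouse" — gold
  normalization stays canonical), route acronyms ("sc", undone by
  normalization), planted interchangeable synonyms for the embedding
  tests, and a transgenic-document rate.

What a green synthetic run establishes — and what it does not: the
generator emulates the *structural* properties of curated assay data
(entity layout, near-duplicate documents, class-vocabulary separation),
not the real corpus's vocabulary breadth, curator idiosyncrasies, or
tagger errors. Pipeline closure (exact F1 = 1.0 at zero noise) validates
span bookkeeping and matching semantics end to end; it does not predict
benchmark F-scores on the real gold set, which depend on dictionary
coverage and the external tagger.

Two test-harness choices are documented here because the published corpus
is ~100× larger than the synthetic one: end-to-end tests train embeddings
at 50 dimensions / minimum count 5 / 60 epochs (a small corpus supports
fewer dimensions and needs more iterations than the 250/30/5 large-corpus
defaults), and the identical-vocabulary null run uses 200 documents
because content is drawn once per document, so document-level sampling
noise — the only residual signal under identical vocabularies — shrinks
with document count.

## Numerical and degenerate-input conventions

* Word counts for corpus statistics strip punctuation, then split on
  whitespace; whether counting happens before or after acronym expansion
  is exposed as `expand_acronyms` (default: before, i.e. raw text).
* Ranked outputs break ties deterministically: mention frequencies by
  name, enrichment by in-class frequency then name, cosine rankings by
  token.
* Empty corpora yield all-zero statistics, empty mention tables and empty
  graphs, never errors; out-of-vocabulary queries and spans outside their
  description are explicit errors naming the offender.
* All randomness (fold assignment, corpus generation, training, t-SNE)
  derives from explicit integer seeds; fold assignment uses a small
  package-internal generator so it cannot disturb the global RNG state.

## Known limitations

* The bundled fallback tagger approximates, not replicates, the external
  biomedical tagger; published benchmark F-scores are only meaningful
  with the original backend and the full strain listings.
* Experimental-model synonyms are not normalized at extraction time (only
  the network build consolidates them), mirroring the source method.
* The rule patterns are tuned to this corpus's curator conventions and
  will need re-evaluation on free text from other sources.
* The embedding implementation is single-threaded; corpora of 10^5
  descriptions train in minutes, but it is not a general-purpose
  replacement for optimized libraries.
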