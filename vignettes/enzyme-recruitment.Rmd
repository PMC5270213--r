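---
title: "Comparing enzyme repertoires of primary and secondary metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing enzyme repertoires of primary and secondary metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrecruit)
```

## The scientific question

Bacterial metabolism is conventionally split into primary metabolism (PM) —
the reactions every cell needs to grow and divide — and secondary metabolism
(SM), the biosynthesis of specialized products such as antibiotics and
siderophores, typically encoded in biosynthetic gene clusters (BGCs). The
standing hypothesis is that SM enzymes arise by duplication and divergence of
PM enzymes. smrecruit implements a comparative, annotation-driven way to
probe that hypothesis at scale: it contrasts two carefully delimited enzyme
sets — a PM side from genomes known to be free of BGCs, and an SM side from
expert-curated BGCs — using the Enzyme Commission (EC) classification as the
common functional language, and homology hit tables as the evolutionary
evidence.

Everything in the package operates on plain tables: enzyme catalogs
(TSV), BLAST-style tabular hit lists, genome gene-order tables and pathway
maps. Live database access and running an aligner are deliberately out of
scope; the package consumes their file outputs, which keeps every analysis
deterministic and reproducible offline.

## The EC number as grouping key

An EC number `c.s.d.n` encodes reaction class (1–6: oxidoreductases,
transferases, hydrolases, lyases, isomerases, ligases), subclass,
subdivision, and a substrate-level serial number. Enzymes sharing the first
three digits (the *subdivision*) share reaction chemistry, which makes the
hierarchy a natural set of grouping keys: `ec_key()` truncates a parsed EC
to any of the four levels, and every statistic in the package is computed
"at a level".

Two policies matter in practice:

* **Wildcards.** Partial annotations such as `1.-.-.-` are accepted, but only
  as a contiguous right suffix. A record wildcarded above the analysis level
  is *excluded from that level's denominator* rather than guessed — so
  `2.1.1.-` counts in class-, subclass- and subdivision-level spectra and is
  invisible to full-EC statistics. The alternative (imputation) would
  silently manufacture functions.
* **Preliminary serials** (`1.14.13.n5`) are rejected by default; a flag
  strips the `n` for catalogs that use them. Rejection is the auditable
  default because provisional numbers are renumbered over time.

The class digit is capped at 6 by default, the universe all summary
statistics here assume; `max_class = 7` admits translocases for reuse of the
parser outside that setting.

## Catalogs and the inclusion filters

A catalog row is one protein: gene id, collection (genome or BGC), species,
EC annotation, protein length, product text. `apply_inclusion_filters()`
keeps exactly the records with one EC number: no-EC records say nothing
about function, and multi-EC records are functionally ambiguous. The filter
log records both removal counts so that real catalogs can be audited against
their sources. Filtering is idempotent, and happens after loading — never at
parse time — so the audit numbers refer to the catalog as supplied.

`leave_one_out()` produces the control splits: one genome's enzymes against
the remaining PM side, or one BGC's enzymes against the remaining SM side.
These within-side comparisons baseline how much functional change homology
alone would show without any PM-to-SM transition.

## Spectra, overrepresentation, shared functions

`ec_frequencies()` counts records per key and normalizes to percent.
Frequencies are record-based: an EC represented by thirty enzymes weighs
thirty times as much as a singleton, which is what "how much of this
repertoire is transferase chemistry" should mean. A distinct-EC weighting is
available as a sensitivity check.

`overrep_ratios()` divides SM by PM frequencies per key. Keys missing on the
PM side have no finite ratio and are flagged `absent_in_pm`; keys missing on
the SM side get ratio 0. The default flag threshold of 20 highlights the
rare, strongly SM-biased chemistries. `shared_exclusive_functions()`
partitions the key union into shared / SM-only / PM-only — the shared count
over the SM inventory is the lower bound on recruitment reported by
`recruitment_fraction()`.

`frequency_correlation()` returns the squared Pearson correlation of two
spectra. Whether keys absent from one side should enter as zeros is genuinely
ambiguous; both pairings are implemented, with union-plus-zero-fill as the
default because a function absent from one side *is* information about
dissimilarity of the spectra. Fewer than three pairs or a zero-variance side
is an error, not an NA, so degenerate inputs cannot leak into downstream
summaries.

## Homology screening

Hits arrive in the standard 12-column tabular format (optionally extended
with query/subject lengths; otherwise lengths resolve from the catalogs).
`filter_hits()` applies three rules:

* **E-value ≤ 1e-20**, boundary inclusive. This stringent default minimizes
  false homology; 1e-10 is the conventional relaxed control, and cutoff
  relaxation is guaranteed monotone (a kept hit can never disappear).
* **Length rule:** the subject may differ from the *query's* length by at
  most 30 % (inclusive). This guards against multi-domain proteins matching
  on a single shared domain. The query is the denominator because the SM
  enzyme is the anchor of each comparison.
* **Self-hits** (identical gene ids) are dropped.

Duplicate (query, subject) rows — multi-HSP alignments — collapse to the
minimum-E-value row *before* filtering, so the unit of counting is the
homolog pair, not the alignment segment. Per-hit rejection reasons are kept.

`function_hit_map()` joins kept hits with both catalogs and yields, at a
chosen level, one row per hit carrying the SM query's key and the PM
subject's key. Hits whose endpoints lack a usable (single, level-complete)
EC drop out of that level's view, mirroring the requirement that both
partners of a counted pair have an assigned function.

## Classifying functional flexibility

For each SM key with at least one homolog, `classify_functions()` compares
every PM hit key with the SM key:

* `ALL_SAME` — every homolog keeps the function: a monofunctional family;
* `MIXED` — some do, some do not: a multifunctional family;
* `ALL_DIFF` — none does: the function most likely changed after
  recruitment.

The three categories partition the classified keys, so their counts always
sum to the number of SM keys with hits. `summarize_classification()` turns
counts into percent fractions; its `n_total` argument substitutes a larger
denominator (e.g. *all* SM subdivisions, including those without homologs)
when a fraction is to be quoted against the full inventory — in that case
the three fractions deliberately do not sum to 100, the remainder being the
unclassified keys.

`functional_conservation()` computes `fc`, the *hit-weighted* fraction of a
group's homolog hits that keep the group's key. Hit weighting (rather than
key weighting) is canonical here because `fc` describes the evidence mass:
a subdivision with forty conserving hits and one changing hit should score
close to 1. The key-weighted alternative is recoverable from the
classification table.

## The functional-change network

`build_change_graph()` turns a function hit map into a directed graph:
nodes are grouping keys annotated with hit counts, `fc`, and a flag for keys
absent from the PM side; each hit whose PM key differs from its SM key
contributes to one directed edge PM-key → SM-key. Same-function hits feed
node `fc` only, never an edge, which yields two exact identities that are
property-tested and enforced by construction: per node, incoming edge weight
equals `n_hits − n_same`; globally, edge weights plus same-function hits
equal the total kept hits.

Edges carry the mean E-value of their hits. The default mean is geometric
(mean of log10 E-values, exponentiated): E-values span dozens of orders of
magnitude, and an arithmetic mean would be dominated by the weakest hit.
The arithmetic mean is available as an option. Mean E-values are binned for
display; the default bin edges 1e-20 / 1e-50 / 1e-100 follow the decades
commonly used to color such networks and are configurable — they are
presentation metadata, recorded in the export, not part of the statistics.

Exports: GraphML (lossless, attribute-typed, round-trips through
`read_change_graph()`), SIF with interaction type `changes_to`, and a plain
edge TSV. Node and edge order is lexicographic so exports are byte-stable.

## Genomic neighborhoods

For the most direct PM/SM comparisons — homolog pairs living in the same
genome — the package reproduces per-BGC report pages.
`extract_neighborhood()` cuts a ±k gene-order window (default ±10) around a
putative PM homolog; windows are gene-indexed, not base-pair-indexed, and
truncate at replicon ends unless the replicon is declared circular. The ±10
and ±2 defaults bracket bacterial operon statistics: typical operons run
three to four genes, and almost all are shorter than ten, so the inner
window approximates "same operon" and the outer window "same genomic
context".

`assign_labels()` flags each window gene:

* **P** (possible PM contribution): the gene carries a complete EC that
  occurs in the PM reference set. Wildcarded ECs never earn a P.
* **S** (possible SM contribution): the gene is mapped to the species'
  secondary-metabolite biosynthesis pathway. This is pathway-membership
  based (an EC-set route is also available) because pathway mapping is how
  the label is defined in the source annotations — and it is the only
  reading that reproduces the reference tallies, where a gene annotated
  only as `2.1.1.-` still carries an S through its pathway membership.

The anchor gene is included in the window and in all tallies; this inclusive
convention is what reproduces both transcribed reference neighborhoods
(13 P / 2 S around *pabB*, 17 P / 16 S around *trpE*) exactly.
`summarize_pathways()` counts, per pathway, member genes in the outer and
inner windows (`n_outer/n_inner` rows, sorted by outer count), and
`render_report()` assembles deterministic, timestamp-free HTML pages with
one block per homolog and a hyperlink per gene.

## The synthetic-data generator

`simulate_bundle()` emits a complete input bundle — both catalogs, a
12-column hit table, genome gene-order tables with operon-like co-pathway
runs and an embedded BGC span, and a pathway map — together with the planted
truth. It emulates the features the pipeline is sensitive to:

* homolog families with controlled functional makeup (the default design
  plants six monofunctional, three multifunctional and two fully-changed
  families, one of the latter mirroring the isochorismate-synthase
  constellation: SM 5.4.4.2 with PM homologs 2.6.1.85 and 4.1.3.27);
* within-family hit E-values drawn log-uniformly in [1e-40, 1e-21] — at or
  below the acceptance cutoff — and member lengths jittered ±10 % around a
  family base length, which keeps every family pair inside the 30 % rule;
* decoy hits with E-values in [1e-18, 1e-11] (visible only under the 1e-10
  control) and decoys violating the length rule at passing E-values;
* no-EC and multi-EC records injected at 5 % each, which the filter log must
  recover exactly;
* background enzymes drawn from per-class weights approximating a PM class
  spectrum (transferases ≈ 35 %, oxidoreductases ≈ 19 %, …).

Defaults are sized to the study design: 15 PM collections and 20 BGCs, with
65 background genes per genome, i.e. about a thousand PM records per bundle.
E-values are sampled log-uniformly because that is the scale on which both
the cutoffs and the display bins operate.

What the generator does **not** emulate: sequence-level realism (hits are
planted, not aligned), phylogenetic correlation between genomes, and the
long-tailed EC frequency profiles of real annotation databases. Passing the
synthetic suites therefore demonstrates that the bookkeeping — filtering,
grouping, counting, graph construction, labeling — is exact; it does not
validate annotation quality of any real input.

`oracle_expected_outputs()` recomputes every expected result by brute-force
enumeration over the planted structure using plain base-R string handling,
sharing no code with the pipeline. The test suite requires exact agreement
between the two routes on classification, conservation rates,
shared/exclusive sets, change-graph edges and neighborhood tallies, across
several seeds.

## Orchestration and reproducibility

`run_spectrum()`, `run_flexibility()` and `run_neighborhoods()` (and
`run_pipeline()` over all three) execute the stages from a `run_config()` —
optionally read from YAML — and write sorted TSV/JSON/GraphML/HTML outputs
plus a per-stage manifest (configuration echo, MD5 of every input, package
version, record counts). Floating-point table output is fixed at six
significant digits; all orderings are deterministic; reruns on identical
inputs are byte-identical. A thin command-line wrapper with subcommands
lives in `inst/scripts/smrecruit-pipeline.R`.

## Numerical and degenerate-input choices

* Percentages are carried at full precision everywhere; rounding is left to
  display.
* Empty catalogs yield empty frequency tables; an empty filtered hit set is
  a warning, not an error, and propagates empty outputs.
* Tie-break for multi-HSP collapse: lowest E-value, then highest bit score,
  then input order after a stable sort — so permuting input rows cannot
  change any result.
* `fc` is undefined (row omitted) for groups without hits; ratios against a
  zero PM frequency are flagged rather than infinite.

## Known limitations

* The PM/SM dichotomy is operational, not biological: the PM side is a
  conservative proxy (BGC-free genomes), the SM side a curated subset, so
  shared-function counts are lower bounds by design.
* Homology is inferred from a single stringent BLAST-style threshold;
  orthology/paralogy is deliberately not resolved — with pervasive
  horizontal transfer of BGCs the distinction is not reliably decidable.
* Neighborhood windows are an operon proxy; the package presents labeled
  evidence per candidate homolog and never issues an automated PM-versus-SM
  verdict.

## A worked micro-example

```{r}
design <- tibble::tibble(
  gene_id = paste0("q", 1:2), collection_id = "BGC1", species_tax = "t",
  ec = "5.4.4.2", length = 450, product = "isochorismate synthase"
)
sm <- apply_inclusion_filters(as_enzyme_catalog(design, "sm"))
pm <- apply_inclusion_filters(as_enzyme_catalog(
  tibble::tibble(
    gene_id = paste0("s", 1:2), collection_id = "G1", species_tax = "t",
    ec = c("2.6.1.85", "4.1.3.27"), length = c(470, 460),
    product = c("ADC synthase", "anthranilate synthase")
  ), "pm"
))
hits <- tibble::tibble(
  query_id = c("q1", "q1"), subject_id = c("s1", "s2"),
  evalue = c(5e-26, 3e-21), bitscore = 0, qlen = 450, slen = c(470, 460)
)
map <- function_hit_map(filter_hits(hits), sm, pm, "subdivision")
classify_functions(map)
tidy(build_change_graph(map))
```

The isochorismate-synthase-like query is classified `ALL_DIFF` — both of its
homologs catalyze different chemistry — and the change graph carries the two
corresponding edges into subdivision 5.4.4.
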