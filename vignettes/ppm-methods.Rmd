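---
title: "Profile and pattern matching for reliable enzyme-function identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile and pattern matching for reliable enzyme-function identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmatch)
```

## The problem

Single amplified genomes (SAGs) of uncultured extremophiles are a rich
source of novel enzymes, but their annotations are unusually unreliable:
assemblies are fragmentary, many genes are incomplete, and low homology to
characterized proteins means that a third or more of the coding sequences
have no similarity support at all. For an experimentalist planning
expression and characterization campaigns, a false positive annotation is
expensive — so the selection step must be heavily biased against false
positives, even at the cost of many false negatives.

`ppmatch` implements a profile-and-pattern matching (PPM) strategy built
on that premise. Two *orthogonal* descriptor systems are used jointly:

* **profiles** — Gene Ontology terms attached to a gene by its annotation
  pipeline, treated as literal IDs (no GO-graph propagation), and
* **patterns** — PROSITE consensus patterns, short amino-acid signatures
  of active sites and binding motifs.

A gene that carries several independent descriptors of the targeted
function is far less likely to be a false positive than one supported by
a single electronic annotation. The pipeline therefore filters an
annotated gene collection through independent profile and pattern
filters, removes likely gene fragments, groups the surviving
non-redundant genes by their *exact* descriptor combination, and calls a
gene **reliable** when its combination contains at least two descriptors.

## From proteins of interest to filter lists

The search target is a list of Enzyme Commission (E.C.) numbers — one per
protein-of-interest (POI) family, wildcards permitted in the serial field
only (`1.1.1.*`). `parse_ec_list()` enforces that constraint at parse
time; broader wildcards are rejected because the first three fields define
the catalytic chemistry the search is about.

Translation proceeds in `expand_and_filter()` and
`translate_descriptors()`:

1. wildcards expand against the mapping tables' concrete E.C. numbers;
2. duplicates are removed preserving first occurrence (reproducible
   ordered output);
3. entries whose status is *preliminary* (an `n`-prefixed serial in the
   enzyme table), *transferred* or *deleted* (their standard description
   phrases) are set aside;
4. the surviving numbers map to the deduplicated union of GO terms and
   PROSITE IDs; patterns known to be unspecific (by default `PS00198`,
   `PS00455`, `PS00143`) are dropped from the pattern list with a log of
   the removal; and
5. supplemental descriptors cover non-enzymatic POIs (e.g. aquaporin),
   which have no E.C. number at all.

The mapping tables are consumed in the public flat-file dialects
(`ID`/`DE` enzyme releases, `ec2go` lines, PROSITE `ID`/`AC`/`DE`/`PA`
entries) so that the pipeline runs from plain text without any live
database queries. `simulate_poi_study()` generates a complete synthetic
study in those dialects whose per-group totals replay the published
stepwise conversion (2576 input numbers, 433 non-redundant, 264 active,
171 GO terms, 49 consensus patterns).

## The pattern engine

PROSITE consensus patterns are parsed into element lists (`x`, fixed
residue, `[...]` any-of, `{...}` none-of, with `(n)`/`(n,m)` repeats and
`<`/`>` anchors). The matcher reports **every** distinct span for which
some assignment of per-element repeat lengths matches contiguously — not
first-only, not leftmost-longest. Presence/absence is what the PPM
filters consume, and complete reporting makes the matcher exactly
comparable to a brute-force oracle that enumerates all repeat
assignments; the test suite holds the two equal over thousands of random
(pattern, sequence) pairs.

Numerical and edge-case choices:

* Coordinates are 1-based inclusive (PROSITE convention).
* Ambiguity codes `X`, `B`, `Z` and unknown letters satisfy only the
  wildcard `x`; they never satisfy fixed, any-of or none-of elements.
  This is deliberately conservative — an uncertain residue should never
  *create* a motif hit.
* Repetition is permitted on any element kind (`[ED](2)`).
* The rare `[...>]` C-terminal-or-residue idiom is rejected with an
  explicit unsupported-syntax error rather than silently mis-read.

## Gene collections and the fragment filter

Annotated genes arrive as a TSV with a fixed header
(`gene_id`, `genome_id`, `taxon`, `nt_length`, `complete`, `product`,
`go_terms`, `prosite_ids`), optionally joined with a protein FASTA for
scan-mode pattern matching. Two conventions matter:

* when `nt_length` is absent it is derived as `3 * aa_length + 3`
  (codons plus stop), because the filter threshold is stated in
  nucleotides while protein tables may lack CDS lengths;
* an absent `complete` flag defaults to `FALSE` — again the
  anti-false-positive default.

`gene_fragment_filter()` keeps genes that are at least 300 nucleotides
long **and** annotated complete; 300 nt is the minimal length commonly
required for a functional product, and the boundary is kept inclusive
(`>= 300` survives). The filter is idempotent and commutes with the
descriptor filters; `ppm()` runs descriptor filters first by default
(matching the reference workflow's reported counts) and exposes
`fragment_first = TRUE` for the swapped order.

## Sets, ranking, condensation

After deduplication each gene carries its full sorted combination of
matched descriptors. Genes sharing one exact combination form a PPM set;
classes partition the sets — *profile* (GO only), *pattern* (PROSITE
only), *profile-and-pattern* (both, and such genes belong only here).
Sets are ranked by descriptor count, then member count, then
lexicographic combination; the secondary tie-breaks are this package's
convention (the reference method specifies only ranking by the amount of
descriptor combinations). IDs `Pro i` / `Pat i` / `PP i` are assigned per
class in rank order.

Condensation of sets into enzyme families was a manual curation step in
the original workflow, so `condense_meta_sets()` takes the family map as
an explicit input and never guesses: unmapped sets pass through as
singleton meta-sets. On the worked example the 12 multi-descriptor sets
condense into 9 enzyme families.

## Deriving new consensus patterns

Families without existing descriptors (the motivating case is the
gamma-class carbonic anhydrases) can still be screened by deriving a
relaxed pattern from an archetype's functional residues and a set of
candidate homologs:

* at each functional position, the union of residues observed across
  archetype and candidates becomes a fixed element or an any-of class
  (archetype residue first);
* a position showing more than `breadth` distinct residues (default 4)
  is judged uninformative and degrades to `x`, merging into the adjacent
  spacer — the default is a deliberate curation knob, not an estimate,
  and each degradation is reported;
* spacers record observed non-gap lengths per sequence, rendered `x(n)`
  or `x(n,m)`; gaps in candidates shorten spacers exactly as the
  alignment dictates.

The derived pattern is verified against every input sequence through the
package's own matcher, and derived spacer ranges are minimal: narrowing
any `x(n,m)` excludes at least one input. Role tags (metal binding,
catalytic, structural) do not alter the algorithm; they are carried into
the report so a curator can judge which substitutions may affect
function. `gamma_ca_fixture()` encodes the curated variation pattern of
the motivating study — a spacer shortened from 11 to 10 residues in all
candidates, N→C and Q→K at hydrogen-bonding positions, E→D at the final
catalytic position, conserved Arg/Asp and histidines — and derives
`R-x-D-x(10,11)-[NC]-x-[QK]-x(5)-H-x(2)-[ED]` and `H-x(3)-H`, both
matching all seven inputs.

```{r derive}
fx <- gamma_ca_fixture()
dp <- derive_patterns(fx$alignment, fx$archetype_id, fx$positions,
                      fx$segments, fx$candidate_ids)
vapply(dp, function(d) format(d$pattern), "")
```

## Phylogenetic clustering and representative selection

Within a set, members are typically isoenzymes; one representative per
phylogenetic cluster is enough for expression work. The package uses the
classical protein-distance pipeline: **complete deletion** (every column
with a gap or missing symbol in any sequence is removed globally),
p-distance, **Poisson correction** `d = -ln(1 - p)` in substitutions per
site, and **neighbor joining** (via `ape::nj`, with negative branch
lengths clamped to zero and the deficit logged). A pair with `p = 1` is
an error, not a clamped value — the correction is undefined there.

Clusters are extracted by cutting branches longer than a threshold
(default 0.1 substitutions per site, the magnitude at which closely
related within-family groups separate; the original analysis clustered by
visual inspection, so the cut rule is this package's operationalization
and the threshold is configurable). Representatives follow a three-rule
cascade mirroring manual practice: unique containment (one member's
aligned residues cover all others), then highest external similarity
score (e.g. a BLASTp result supplied as a table — the package runs no
BLAST itself), then most functional side chains
(C, D, E, H, K, N, Q, R, S, T, W, Y), with a lexicographic final
tie-break.

## What the simulators emulate — and what they do not

All fixtures are generated in code, deterministically under a seed:

* `simulate_annotated_genes()` builds a collection whose surviving genes
  carry exactly the worked example's 23 descriptor combinations (234
  genes), plus 168 fragmentary profile-hit genes and 539 fragmentary
  pattern-hit genes — the counts the fragment filter removed in the
  reference run — and a descriptor-free background. Warehouse-style hit
  totals that count one row per query result rather than per
  gene–descriptor pair are *not* reproducible in this representation;
  the generator reproduces the removal deltas and every non-redundant
  endpoint (106 profile genes, 142 pattern genes, 117 reliable genes).
* `simulate_planted_proteins()` guarantees exact scan ground truth by
  rejection-sampling background sequences against the matcher itself.
* `simulate_cluster_alignment()` mutates cluster ancestors from a common
  root; it produces ungapped alignments with uniform rates, so it tests
  the clustering contract, not realistic protein evolution (no indels,
  no rate heterogeneity, no MDA amplification bias or assembly
  artifacts).

Passing tests on these fixtures show that the algorithms honour their
contracts, not that any particular real SAG collection would yield the
same counts.

## Problem sizes and reproduction

The test suite and the acceptance script run the translation study at
its full published size (2576 E.C. numbers), the PPM replay at 1091
genes, the matcher-vs-oracle comparison at 1000 random pairs (patterns
up to 6 elements, sequences up to 40 residues), neighbor joining at 100
random 4–8 leaf additive instances with a 1e-9 path-length tolerance,
and the clustering fixture at 14 leaves in 4 planted clusters. These
sizes were chosen as the smallest at which every contract is exercised
meaningfully; `scripts/acceptance.R` recomputes all headline quantities
from scratch and writes them as JSON.

## Known limitations

* Annotation-mode filtering trusts the input GO/PROSITE assignments; it
  cannot recover annotations the upstream pipeline missed (scan mode
  recomputes pattern hits, but profiles have no scan equivalent here).
* GO terms are matched as literal IDs; a profile list that uses parent
  terms will not match genes annotated with children.
* PROSITE profiles (weight matrices) and miniprofiles are out of scope;
  only consensus patterns are supported.
* The meta-set step automates bookkeeping, not curation: family labels
  must be supplied.
* The branch-cut clustering rule is a reproducible stand-in for what was
  originally a visual decision; different thresholds can split or merge
  borderline clusters.
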