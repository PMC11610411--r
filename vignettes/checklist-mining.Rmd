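---
title: "Mining and analysing plant checklists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and analysing plant checklists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floramine)
```

## The problem

Expert-curated plant checklists — accepted names, their synonyms, and
per-species distributions — are served by portals such as Kew's Plants
of the World Online as one webpage per taxon rather than as a bulk
download. `floramine` treats that page tree as a data source: a crawler
walks family → genus → species pages, parsers extract a structured
record from each page, and an analytics layer turns the records into
the outputs botanists actually use (checklist spreadsheets, richness
maps, discovery curves, nomenclatural-change graphics).

This vignette is the package's own account of the models and the design
choices behind them.

## The data model

A **name record** is one published name: genus, epithet, authorship,
the protologue citation, the publication year parsed from that
citation, a status (accepted, homotypic synonym or heterotypic
synonym), a stable identifier and a page locator. A **species record**
bundles one accepted name with its synonyms, its distribution and its
family. Invariants are enforced by `validate_species()`, which returns
named violations rather than throwing: structural checking of scraped
data is itself an analytic result.

Three choices deserve justification:

* **The year window is [1753, current year].** Botanical nomenclature
  starts with *Species Plantarum* (1753); a parsed year outside the
  window is necessarily a citation defect and maps to *unknown* instead
  of contaminating discovery curves.
* **Name identity is the (genus, epithet, authorship) triple**,
  authorship case-sensitive, because homonyms differ only by author.
  Hybrid markers ("×") are display-only and stripped for comparisons.
* **Statuses outside the model** (POWO also shows "unplaced" and
  "artificial hybrid" names) are rejected with a named violation rather
  than silently coerced into a synonym class they do not belong to.
  Infraspecific names are likewise out of the species-level model; all
  package outputs are species-level.

Year parsing prefers the first parenthesized four-digit year in the
window — the dominant modern citation style, `"Sp. Pl.: 1042 (1753)"` —
and falls back to the last bare four-digit token for older styles such
as `"Fl. Bras. 2(2): 44. 1877"`. The last (not first) bare token is
used because page/volume numbers precede the year in those citations.
Unparseable input yields *unknown*, never an error.

The **basionym year** of a species is
`min({accepted year} ∪ {homotypic synonym years})`, ignoring unknowns.
The basionym shares the accepted name's type, hence is found among the
homotypic synonyms; heterotypic synonyms are based on other types and
never participate. This is the "actual discovery date" basis of the
dual accumulation curves.

## The crawler

Pages are addressed by a `taxon_uri` regardless of whether they come
from a live base URL or a local directory, so tests and live runs share
one code path. Three mechanisms matter:

* **Rate limiting.** After every `requests_per_pause`-th request the
  crawler sleeps `pause_seconds`; the defaults are a 300-second pause
  after every 500th request, a deliberately conservative politeness
  setting for a public server. The counter is cumulative and the pause
  fires on the modulus (`count %% 500 == 0`); with a per-crawl counter
  this is equivalent to resetting after each pause. The clock is an
  injected dependency (`mock_clock()`), so the schedule is testable in
  milliseconds.
* **Retries.** Transient fetch failures are retried up to three times
  with doubling backoff (1, 2, 4 s). Retries count toward the
  rate-limit counter — a retry is still a server hit. A fourth failure
  is recorded in the crawl's `failures` list and the page is skipped;
  failures are data, never silent.
* **Checkpoints.** After every completed taxon the full crawl state
  (completed and pending queues, parsed records, genus summaries,
  failures, request count) is serialized as line-oriented JSON with an
  MD5 integrity footer, written to a temporary file and renamed into
  place. Restarting with an existing checkpoint re-fetches nothing that
  is complete and continues from the pending queue; a corrupt
  checkpoint (truncation, modification, bad JSON) refuses to load and
  names the defect. Persisting parsed records in the checkpoint makes a
  resumed crawl return the complete record set, not just the tail.

Parser selectors are centralized in a per-dialect table keyed by the
`checklist-dialect` meta tag each page carries. Real portal markup
changes over time; an unknown dialect is an explicit error, not
best-effort scraping.

## Geography

Portal distributions use TDWG's World Geographical Scheme for Recording
Plant Distributions at level 3 ("botanical countries"), which only
sometimes coincide with political countries. The bundled mapping table
(`inst/extdata/wgsrpd3_mapping.csv`) is a hand-compiled subset of the
published level-3 scheme (Brummitt 2001, *World Geographical Scheme for
Recording Plant Distributions*, ed. 2) covering about a hundred units,
including multi-country units (Borneo, New Guinea, Korea) and
subdivided countries (Brazil, Mexico, China, Australia); a fuller table
in the same three-column format (`botanical_country, political_country,
alias`) can be dropped in. Country names follow the mapping file
verbatim — no ISO normalization and no geopolitical adjudication of
disputed territories; the optional alias column covers spelling
variants such as "Burma".

`convert_regions()` is a union homomorphism: the countries of a set of
botanical countries are the union of each unit's countries, so
conversion can never shrink information. Lookup is insensitive to case,
surrounding whitespace and diacritics; names that fail lookup land in
`unresolved_regions` with a warning. An empty input is flagged
*unknown*, mirroring the rule that a species page without a
distribution section is assigned unknown rather than dropped.

## Queries

* `family_species_count()` counts **distinct accepted species**;
  synonyms never count.
* `megadiverse_genera()` uses a strict `>` 500 cutoff by default,
  matching Frodin's phrase "more than 500 species"; users wanting
  at-least semantics can pass `threshold - 1`.
* `top_genera()` defaults to `n = 10` (a package choice, stated
  prominently here and in the help) and includes **all genera tied
  with the n-th count** — alphabetical truncation would misrepresent
  richness ranks, so the result may exceed `n`.
* Country constraints match species natively occurring in **any** of
  the listed countries (the all-of reading is rarely wanted and can be
  composed from single-country queries); introduced ranges participate
  only when `include_introduced` is set, because richness maps
  conventionally show native distributions.
* CSV exports use a fixed, documented column order with `"|"`-joined
  multi-value cells and print `"unknown"` for unknown-distribution
  species; the dialect is stable under write → read → write.

## Richness and discovery analytics

Richness is **distinct-species incidence**: a species with three
regions adds one to each of the three counts. This makes the incidence
identity `Σ_regions counts = Σ_species |regions(species)|` an exact
invariant, checked at both geographic levels on every test run.
Unknown-distribution species appear in `unknown_count`, never on the
map.

Accumulation series count species whose basis year is at most each
observed year. The two bases (accepted date, basionym date) bracket the
description history: the basionym curve is pointwise ≥ the accepted
curve because each species' basionym year is ≤ its accepted year. The
end point plus the unknown-year tally always equals the total species
count. Curve axes start at 1753 regardless of the earliest datum so
cross-taxon panels align.

The nomenclatural-change graphic pairs each accepted name's year with
its synonyms' years and statuses. The exact density statistic behind a
violin rendering is a presentation choice; the **sidecar CSV of
(accepted year, synonym year, status, synonym count) is the normative
output**, and both renderers always write their plotted tables next to
the images so graphical claims are testable without pixel comparisons.

Map geometries are read from GeoJSON feature collections whose features
carry a `region_name` property; the package flattens polygon rings
itself and draws them with `ggplot2::geom_polygon`, a deliberately
lightweight geometry layer — choropleths need ring outlines and a fill
scale, not a full simple-features stack. The bundled
`toy_countries.geojson` / `toy_botanical.geojson` are schematic
synthetic rectangles for examples and tests, not real boundaries;
real-world maps should be drawn against proper country or WGSRPD
polygons with the same `region_name` join key.

## The synthetic flora

The generator emulates exactly what the miner reads: nested
family/genus/species pages with authorship, protologue citations
(years embedded and re-parsed), homotypic/heterotypic synonym sections,
and native/introduced region lists, with unknown-distribution species
rendered as pages lacking the distribution section entirely. Its
defaults are the package's study conditions, chosen once as a plausible
modest tropical family set: 3 families, 2–6 genera per family, 1–20
species per genus, 0–4 synonyms per species with a 40% homotypic
fraction, publication years uniform on 1753–2022, a 5% chance of an
unknown distribution and a 15% chance of an introduced range, ranges
drawn from the bundled WGSRPD subset.

Two structural rules are built in rather than sampled: homotypic
synonym years never exceed the accepted year (a basionym precedes its
recombination — this is what makes the basionym-curve dominance a
theorem rather than a tendency), and (genus, epithet) pairs are unique
within a flora so round-trip comparisons are collision-free. The seed
is the only randomness source; there is no wall-clock or ordering
nondeterminism.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: real portals' evolving markup (only
the versioned `v1` dialect is rendered), infraspecific and unplaced
names, orthographic variants and encoding noise in authorship strings,
non-uniform description-year dynamics (real discovery curves have
world-war troughs and monographic bursts), spatially autocorrelated
ranges, and HTTP-level behaviour (timeouts, redirects, rate-limit
responses). The parsers' error paths for mangled markup are exercised
with hand-built pages instead.

## Problem sizes and runtime choices

The test suite keeps simulations small enough to iterate comfortably:
round-trip fidelity runs over 20 seeded floras of roughly 50–500
species each; resumption is swept over every interruption point of the
7-page demonstration site; oracle-equivalence and invariant checks use
floras of a few dozen species across several seeds, each compared
against independent brute-force double-loop re-implementations written
in the tests themselves. The rate-limiter acceptance check drives 1000+
requests against a mocked clock, so the 300-second pauses cost no real
time. The full suite runs in well under a minute on one CPU.

## Known limitations

* Remote mining is implemented over plain `url()` connections without
  HTTP niceties (no conditional requests, no custom user agent
  configuration); serious live use should run behind the checkpointed
  crawler with conservative rate limits.
* The bundled region mapping is a subset; analyses of floras outside
  its coverage will report unresolved regions until a fuller WGSRPD
  table is supplied.
* Country filtering is native-range, any-of semantics; "endemic to"
  queries (occurs in X and nowhere else) are not built in, though they
  are a two-line composition over `species_table()`.
* The miner takes portal content at face value: no fuzzy name matching
  or orthographic correction is attempted (that is the niche of
  dedicated name-resolution tools).
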