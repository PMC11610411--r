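# floramine

Mining and analysing plant checklists from POWO-style taxon pages.

Global plant-diversity databases such as Kew's Plants of the World Online
(POWO) publish the World Checklist of Vascular Plants as one webpage per
taxon: a family page listing genera, a genus page listing accepted
species, and a species page carrying authorship, the protologue
citation, homotypic/heterotypic synonym lists and native/introduced
distributions in TDWG level-3 "botanical countries". `floramine` is for
taxonomists, biogeographers and conservation scientists who want those
pages as tidy checklists and as downstream analytics:

* a **resumable, rate-limited crawler** with page parsers that turn a
  taxon-page tree (a live base URL or a local directory) into species
  records; interrupted runs restart from a checkpointed queue and never
  re-fetch a completed page;
* **botanical-country → political-country conversion** (e.g. Borneo →
  Brunei + Indonesia + Malaysia), so every checklist carries
  distributions at both levels;
* **checklist queries**: species counts per family, genus-level lists,
  species-level lists with country-constrained filtering, focused
  per-species distribution lookups, megadiverse genera (strictly more
  than 500 species by default, after Frodin's review of large plant
  genera) and the top-*n* species-rich genera with ties included;
* **species-richness choropleths** at either geographic level, and
  **species-discovery accumulation curves** under two date bases — the
  accepted name's publication year, and the basionym year
  `min({accepted year} ∪ {homotypic synonym years})`, which dates the
  actual discovery and discards later purely nomenclatural
  recombinations — plus per-species nomenclatural-change tables and
  violin graphics;
* a **seeded synthetic-flora generator** that renders ground-truth
  checklists as a static POWO-style HTML site, so the entire
  crawl → parse → analyse pipeline is testable offline and every parsed
  field can be compared against known truth.

## Worked example

The package ships a four-species demonstration flora (two genera of one
family) that exercises every rule of the data model. Render it as a
static site, mine the site back, and analyse the result:

```r
library(floramine)

fl   <- demo_flora()
site <- file.path(tempdir(), "demo-site")
fl   <- render_site(fl, site)       # 7 pages: 1 family + 2 genera + 4 species
res  <- mine_site(site)             # crawl + parse
cl   <- as_checklist(res)           # annotate with political countries
cl
#> <checklist> 4 accepted species, 2 genera, 1 family/families

family_species_count(cl, "Demoaceae")
#> [1] 4

richness_table(cl, "country")
#> <richness_table> level=country, 4 region(s), 4 species (1 unknown)
#>    Brunei Indonesia  Malaysia      Peru 
#>         2         2         2         2
```

Two species are native to Borneo, which spans three political
countries, so Brunei, Indonesia and Malaysia each count 2; one species
has no published distribution and is reported in the unknown tally
rather than silently dropped.

```r
accumulation_series(cl, "accepted_date")$points
#>   year cumulative
#> 1 1753          1
#> 2 1820          2
#> 3 1850          3
#> 4 1900          4
accumulation_series(cl, "basionym_date")$points
#>   year cumulative
#> 1 1753          1
#> 2 1801          2
#> 3 1820          3
#> 4 1900          4
```

*Alpha duo* (accepted 1850) has a homotypic synonym from 1801 — its
basionym — so the basionym-basis curve reaches 2 species half a century
before the accepted-name curve does. Focused lookups report misses
explicitly:

```r
sd <- species_distribution(cl, c("Alpha duo", "Nonexistens absum"))
sd$records[[1]]$country_distribution$native_countries
#> [1] "Peru"
sd$misses
#> [1] "Nonexistens absum"
```

`render_richness_map()` and `render_discovery_graph()` write
publication-style PNG figures (viridis/ColorBrewer palettes, chosen for
color-vision-deficiency safety) together with plot-data CSV sidecars so
the plotted values are testable without image diffing. A thin command
line lives at `inst/cli/floramine.R`
(`Rscript floramine.R species --site-dir SITE --country Peru --out DIR`
and friends).

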