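Package: floramine
Title: Mining and Analysing Plant Checklists from POWO-Style Taxon Pages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for turning Plants of the World Online (POWO)-style
    taxon webpages into tidy taxonomic checklists and downstream
    biodiversity analytics. Includes a resumable, rate-limited crawler
    with page parsers; conversion of TDWG level-3 botanical-country
    distributions to political countries; query functions for family,
    genus and species checklists (species counts, megadiverse and
    top-ranked genera, per-species distributions); species-richness
    choropleth maps; and species-discovery accumulation curves with
    nomenclatural-change analytics. A seeded synthetic-flora generator
    renders ground-truth checklists as a static POWO-style site so the
    whole crawl-parse-analyse pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    ggplot2,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
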