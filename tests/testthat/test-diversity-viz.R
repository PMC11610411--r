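test_that("richness tables count distinct species per region", {
  cl <- as_checklist(demo_flora())
  bot <- richness_table(cl, "botanical_country")
  expect_identical(bot$counts[["Borneo"]], 2L)
  expect_identical(bot$counts[["Peru"]], 2L)
  expect_identical(bot$unknown_count, 1L)
  ctry <- richness_table(cl, "country")
  expect_identical(
    ctry$counts[c("Brunei", "Indonesia", "Malaysia", "Peru")],
    c(Brunei = 2L, Indonesia = 2L, Malaysia = 2L, Peru = 2L))
  # introduced ranges only count when requested
  intr <- richness_table(cl, "country", use_introduced = TRUE)
  expect_identical(intr$counts[["Madagascar"]], 1L)
  expect_false("Madagascar" %in% names(ctry$counts))
})

test_that("richness matches the species-by-region double loop", {
  m <- load_mapping()
  for (seed in c(81, 82, 83)) {
    fl <- generate_flora(small_spec(seed))
    cl <- as_checklist(fl, mapping = m)
    for (level in c("country", "botanical_country")) {
      got <- richness_table(cl, level)
      want <- oracle_richness(fl$species, level, m)
      expect_identical(got$unknown_count, want$unknown)
      expect_identical(length(got$counts), length(want$counts))
      for (r in names(want$counts)) {
        expect_identical(got$counts[[r]], want$counts[[r]], info = r)
      }
      # incidence identity: sum of counts equals sum over species of
      # its distinct region count
      per_species <- vapply(cl$species, function(sp) {
        regs <- if (level == "botanical_country") {
          sp$distribution$native_botanical
        } else {
          sp$country_distribution$native_countries
        }
        length(unique(regs))
      }, integer(1))
      expect_identical(sum(got$counts), sum(per_species))
    }
  }
})

test_that("accumulation series are cumulative, conserved and ordered", {
  cl <- as_checklist(demo_flora())
  acc <- accumulation_series(cl, "accepted_date")
  expect_identical(acc$points$year, c(1753L, 1820L, 1850L, 1900L))
  expect_identical(acc$points$cumulative, 1:4)
  # basionym basis shifts Alpha duo from 1850 back to 1801
  bas <- accumulation_series(cl, "basionym_date")
  expect_identical(bas$points$year, c(1753L, 1801L, 1820L, 1900L))
  expect_identical(bas$points$cumulative, 1:4)

  # species with unknown years are excluded but conserved in the tally
  with_unknown <- c(demo_flora()$species,
                    list(quick_species("Zeta", "ignota", year = 1900L)))
  with_unknown[[5]]$accepted$year <- NA_integer_
  s <- accumulation_series(with_unknown, "accepted_date")
  expect_identical(s$n_unknown_year, 1L)
  expect_identical(utils::tail(s$points$cumulative, 1) + s$n_unknown_year,
                   length(with_unknown))

  for (seed in c(91, 92)) {
    fl <- generate_flora(small_spec(seed))
    for (basis in c("accepted_date", "basionym_date")) {
      got <- accumulation_series(fl$species, basis)
      years <- vapply(fl$species, function(sp) {
        if (basis == "accepted_date") sp$accepted$year
        else basionym_year(sp)
      }, integer(1))
      expect_identical(got$points, oracle_accumulation(years))
      expect_true(all(diff(got$points$cumulative) > 0))
      expect_identical(utils::tail(got$points$cumulative, 1L) +
                         got$n_unknown_year, length(fl$species))
    }
  }
})

test_that("the basionym curve dominates the accepted curve pointwise", {
  cum_at <- function(series, y) {
    pts <- series$points
    below <- pts$cumulative[pts$year <= y]
    if (length(below)) utils::tail(below, 1) else 0L
  }
  for (seed in c(101, 102)) {
    fl <- generate_flora(small_spec(seed))
    acc <- accumulation_series(fl$species, "accepted_date")
    bas <- accumulation_series(fl$species, "basionym_date")
    for (y in sort(unique(c(acc$points$year, bas$points$year)))) {
      expect_gte(cum_at(bas, y), cum_at(acc, y))
    }
  }
})

test_that("nomenclatural change tables pair accepted and synonym years", {
  fl <- demo_flora()
  ct <- nomenclatural_change_table(fl$species)
  duo <- ct[ct$binomial == "Alpha duo", ]
  expect_identical(nrow(duo), 2L)
  expect_identical(duo$accepted_year, c(1850L, 1850L))
  expect_identical(duo$synonym_year[duo$synonym_status == "homotypic"],
                   1801L)
  # species without synonyms keep a single row with empty synonym fields
  unus <- ct[ct$binomial == "Alpha unus", ]
  expect_identical(nrow(unus), 1L)
  expect_true(is.na(unus$synonym))
  # total synonym rows equal the flora-wide synonym count
  fl2 <- generate_flora(small_spec(111))
  ct2 <- nomenclatural_change_table(fl2$species, group_column = "genus")
  expect_identical(sum(!is.na(ct2$synonym_status)),
                   sum(vapply(fl2$species,
                              function(s) length(s$synonyms),
                              integer(1))))
  expect_true(all(ct2$group %in%
                    vapply(fl2$species,
                           function(s) s$accepted$genus, "")))
  expect_error(nomenclatural_change_table(fl$species, "habitat"),
               "habitat")
})

test_that("richness maps render with sidecar data and unmatched reports", {
  cl <- as_checklist(demo_flora())
  geo <- system.file("extdata", "toy_countries.geojson",
                     package = "floramine")
  out <- file.path(tempfile(), "map.png")
  rt <- richness_table(cl, "country")
  r <- render_richness_map(rt, geo, "rocket", out)
  expect_true(file.exists(r$files))
  expect_length(r$unmatched, 0L)
  side <- utils::read.csv(sub("\\.png$", ".csv", out))
  expect_equal(side$richness[side$region_name == "Peru"], 2)

  # a counted region absent from the geometries is reported by name
  rt2 <- rt
  rt2$counts <- c(rt2$counts, Atlantis = 3L)
  r2 <- render_richness_map(rt2, geo, "viridis",
                            file.path(tempfile(), "m2.png"))
  expect_identical(r2$unmatched, "Atlantis")

  # grouping by family writes one file per family
  fl <- generate_flora(flora_spec(n_families = 2,
                                  genera_per_family = c(1, 2),
                                  species_per_genus = c(2, 3),
                                  seed = 5))
  grouped <- richness_table(as_checklist(fl), "country",
                            group_by = "family")
  expect_length(grouped, 2L)
  r3 <- render_richness_map(grouped, geo, "mako",
                            file.path(tempfile(), "fam.png"))
  expect_length(r3$files, 2L)
  expect_true(all(file.exists(r3$files)))
})

test_that("discovery graphics write curves, violins and sidecars", {
  fl <- demo_flora()
  acc <- accumulation_series(fl$species, "accepted_date")
  bas <- accumulation_series(fl$species, "basionym_date")
  ct <- nomenclatural_change_table(fl$species, group_column = "genus")
  prefix <- file.path(tempfile(), "disc")
  r <- render_discovery_graph(acc, bas, ct, prefix)
  expect_length(r$files, 2L)
  expect_true(all(file.exists(r$files)))
  curves <- utils::read.csv(paste0(prefix, "_curves.csv"))
  expect_setequal(unique(curves$basis), c("accepted", "basionym"))
  # renderers are pure functions of their inputs: plotted data are the
  # series themselves
  expect_identical(curves$cumulative[curves$basis == "accepted"],
                   acc$points$cumulative)
  changes <- utils::read.csv(paste0(prefix, "_changes.csv"))
  expect_identical(nrow(changes), nrow(ct))

  # a single-species flora renders degenerate but valid plots
  single <- list(quick_species("Unica", "sola", year = 1800L))
  r2 <- render_discovery_graph(
    accumulation_series(single, "accepted_date"),
    accumulation_series(single, "basionym_date"),
    nomenclatural_change_table(single),
    file.path(tempfile(), "one"))
  expect_true(all(file.exists(r2$files)))
})
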