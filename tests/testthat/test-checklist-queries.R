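demo_checklist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- as_checklist(demo_flora())
    cache
  }
})

test_that("family species counts ignore synonyms and name lookup errors", {
  cl <- demo_checklist()
  expect_identical(family_species_count(cl, "Demoaceae"), 4L)
  expect_error(family_species_count(cl, "Nullaceae"), "Nullaceae")
  # randomized floras match the brute-force distinct-binomial count
  for (seed in c(41, 42)) {
    fl <- generate_flora(small_spec(seed))
    cl2 <- as_checklist(fl)
    for (fam in fl$family_names) {
      expect_identical(family_species_count(cl2, fam),
                       oracle_family_count(fl$species, fam))
    }
  }
})

test_that("genus lists carry counts and honour country constraints", {
  cl <- demo_checklist()
  gl <- genus_list(cl)
  expect_identical(vapply(gl, function(g) g$genus, ""),
                   c("Alpha", "Beta"))
  expect_identical(vapply(gl, function(g) g$species_count, integer(1)),
                   c(3L, 1L))
  # native occurrence in Peru: A. duo and B. quattuor only
  peru <- genus_list(cl, query_filter(families = "Demoaceae",
                                      countries = "Peru"))
  expect_identical(vapply(peru, function(g) g$genus, ""),
                   c("Alpha", "Beta"))
  expect_identical(vapply(peru, function(g) g$species_count, integer(1)),
                   c(1L, 1L))
  # a mapped country absent from the flora yields an empty list
  none <- genus_list(cl, query_filter(families = "Demoaceae",
                                      countries = "Japan"))
  expect_length(none, 0L)
  expect_error(
    genus_list(cl, query_filter(families = "Demoaceae",
                                countries = "Narnia")),
    "Narnia")
})

test_that("species lists filter by taxa and native country occurrence", {
  cl <- demo_checklist()
  alpha <- species_list(cl, query_filter(genera = "Alpha"))
  expect_length(alpha, 3L)
  # Brunei is reached via Borneo: A. unus and B. quattuor
  brunei <- species_list(cl, query_filter(families = "Demoaceae",
                                          countries = "Brunei"))
  expect_setequal(
    vapply(brunei, function(s) paste(s$accepted$genus,
                                     s$accepted$epithet), ""),
    c("Alpha unus", "Beta quattuor"))
  # unknown-distribution species are included unconstrained, flagged
  all_sp <- species_list(cl, query_filter(families = "Demoaceae"))
  expect_length(all_sp, 4L)
  expect_identical(sum(vapply(all_sp,
                              function(s) s$distribution$is_unknown,
                              logical(1))), 1L)
})

test_that("country-constrained lists equal the brute-force filter", {
  m <- load_mapping()
  for (seed in c(51, 52)) {
    fl <- generate_flora(small_spec(seed))
    cl <- as_checklist(fl, mapping = m)
    for (ctry in c("Brazil", "Indonesia", "Australia")) {
      got <- species_list(cl, query_filter(families = fl$family_names,
                                           countries = ctry))
      want <- oracle_country_filter(fl$species, ctry, m)
      expect_setequal(
        vapply(got, function(s) s$accepted$record_id, ""),
        vapply(want, function(s) s$accepted$record_id, ""))
    }
  }
})

test_that("designated-species lookups report misses explicitly", {
  cl <- demo_checklist()
  one <- species_distribution(cl, "Alpha duo")
  expect_length(one$records, 1L)
  expect_identical(one$records[[1]]$country_distribution$native_countries,
                   "Peru")
  expect_length(one$misses, 0L)

  mixed <- species_distribution(cl, c("Alpha duo", "Nonexistens absum"))
  expect_length(mixed$records, 1L)
  expect_identical(mixed$misses, "Nonexistens absum")

  # equivalent to filtering the full species list to the same binomials
  via_list <- species_list(cl, query_filter(species = "Alpha duo"))
  expect_identical(
    ground_truth_table(mixed$records),
    ground_truth_table(via_list))
})

test_that("megadiverse selection is strictly greater-than the threshold", {
  species <- c(quick_genus("Biggus", 501), quick_genus("Borderus", 500),
               quick_genus("Parvus", 12))
  cl <- as_checklist(species)
  # the no-threshold default applies the >500 cutoff
  mega <- megadiverse_genera(cl)
  expect_identical(vapply(mega, function(g) g$genus, ""), "Biggus")
  expect_length(megadiverse_genera(cl, threshold = 11), 3L)
  # threshold 0 keeps every genus with at least one species
  expect_length(megadiverse_genera(cl, threshold = 0), 3L)
  expect_error(megadiverse_genera(cl, threshold = -1), "threshold")
})

test_that("top genera include all ties at the n-th rank", {
  species <- c(quick_genus("Amplus", 5), quick_genus("Binus", 3),
               quick_genus("Cedrus", 3), quick_genus("Dexus", 1))
  cl <- as_checklist(species)
  top2 <- top_genera(cl, n = 2)
  expect_identical(vapply(top2, function(g) g$genus, ""),
                   c("Amplus", "Binus", "Cedrus"))
  expect_length(top_genera(cl, n = 10), 4L)
  expect_identical(vapply(top_genera(demo_checklist(), n = 1),
                          function(g) g$genus, ""), "Alpha")
  expect_error(top_genera(cl, n = 0), "n must be")
})

test_that("threshold and top-n selections are monotone", {
  fl <- generate_flora(small_spec(61))
  cl <- as_checklist(fl)
  genus_names <- function(gl) vapply(gl, function(g) g$genus, "")
  for (t in 1:6) {
    expect_true(all(genus_names(megadiverse_genera(cl, threshold = t))
                    %in%
                    genus_names(megadiverse_genera(cl,
                                                   threshold = t - 1))))
  }
  for (n in 1:5) {
    expect_true(all(genus_names(top_genera(cl, n = n)) %in%
                    genus_names(top_genera(cl, n = n + 1))))
  }
})

test_that("CSV exports use the documented schema and a stable dialect", {
  cl <- demo_checklist()
  out <- tempfile()
  p <- export_csv(species_list(cl, query_filter(families = "Demoaceae")),
                  out, "species")
  tab <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_identical(names(tab),
                   c("family", "genus", "species", "authorship",
                     "protologue", "year", "native_botanical",
                     "native_countries", "introduced_botanical",
                     "introduced_countries", "record_id", "uri"))
  expect_identical(nrow(tab), 4L)
  # multi-value cells are pipe-joined; unknown species print "unknown"
  quattuor <- tab[tab$species == "quattuor", ]
  expect_identical(quattuor$native_botanical, "Borneo|Peru")
  expect_identical(quattuor$native_countries,
                   "Brunei|Indonesia|Malaysia|Peru")
  expect_identical(tab[tab$species == "tres", "native_countries"],
                   "unknown")

  # empty result -> header-only file
  p0 <- export_csv(list(), out, "empty")
  expect_length(readLines(p0), 1L)

  # write -> read -> write is byte-identical
  p2 <- file.path(out, "species2.csv")
  utils::write.csv(utils::read.csv(p, stringsAsFactors = FALSE,
                                   check.names = FALSE),
                   p2, row.names = FALSE, fileEncoding = "UTF-8")
  expect_identical(readLines(p), readLines(p2))
})

test_that("family counts equal species-list lengths on random floras", {
  for (seed in c(71, 72)) {
    fl <- generate_flora(small_spec(seed))
    cl <- as_checklist(fl)
    for (fam in fl$family_names) {
      expect_identical(
        family_species_count(cl, fam),
        length(species_list(cl, query_filter(families = fam))))
    }
  }
})
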