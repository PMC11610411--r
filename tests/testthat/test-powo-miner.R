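demo_site <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "floramine-demo-site")
      unlink(d, recursive = TRUE)
      render_site(demo_flora(), d)
      cache <<- d
    }
    cache
  }
})

test_that("total pause time follows the modulus schedule", {
  d <- demo_site()
  page <- file.path("species", "sp-000001.html")
  for (cfg in list(c(rpp = 2, n = 5), c(rpp = 3, n = 9),
                   c(rpp = 7, n = 20))) {
    clock <- mock_clock()
    fetcher <- page_fetcher(local_site(d),
                            rate_limit_policy(cfg[["rpp"]], 10),
                            clock)
    for (i in seq_len(cfg[["n"]])) fetcher$fetch(page)
    expect_identical(clock$elapsed,
                     floor(cfg[["n"]] / cfg[["rpp"]]) * 10,
                     info = paste(cfg, collapse = "/"))
  }
  # policy of 2 over 5 fetches pauses exactly after fetches 2 and 4
  clock <- mock_clock()
  fetcher <- page_fetcher(local_site(d), rate_limit_policy(2, 60), clock)
  for (i in 1:5) fetcher$fetch(page)
  expect_identical(clock$log, c(60, 60))
})

test_that("parsers recover the demo fixture pages exactly", {
  d <- demo_site()
  read_page <- function(p) paste(readLines(file.path(d, p)),
                                 collapse = "\n")
  fp <- parse_family_page(read_page("family/fam-000001.html"))
  expect_identical(fp$family, "Demoaceae")
  expect_length(fp$genera, 2L)
  expect_identical(vapply(fp$genera, function(u) u$rank, ""),
                   c("genus", "genus"))

  gp <- parse_genus_page(read_page("genus/gen-000001.html"))
  expect_identical(gp$summary$genus, "Alpha")
  expect_identical(gp$summary$species_count, 3L)
  expect_identical(gp$family, "Demoaceae")

  sp <- parse_species_page(read_page("species/sp-000004.html"),
                           uri = "species/sp-000004.html")
  expect_identical(sp$accepted$epithet, "quattuor")
  expect_setequal(sp$distribution$native_botanical, c("Borneo", "Peru"))
  expect_identical(sp$distribution$introduced_botanical, "Madagascar")
  expect_identical(sp$accepted$year, 1900L)

  # page without a distribution section -> unknown, never an error
  tres <- parse_species_page(read_page("species/sp-000003.html"))
  expect_true(tres$distribution$is_unknown)

  duo <- parse_species_page(read_page("species/sp-000002.html"))
  expect_identical(
    vapply(duo$synonyms, function(s) s$status, ""),
    c("homotypic_synonym", "heterotypic_synonym"))
  expect_identical(duo$synonyms[[1]]$year, 1801L)
})

test_that("malformed markup raises parse errors naming the selector", {
  shell <- function(body) paste0(
    "<html><head><meta name=\"checklist-dialect\" content=\"v1\"/>",
    "</head><body>", body, "</body></html>")
  expect_error(parse_family_page(shell("<p>nothing</p>")),
               "taxon-name")
  expect_error(
    parse_family_page(shell(
      "<h1 class='taxon-name' data-rank='family'>F</h1>")),
    "genus-list")
  expect_error(
    parse_species_page(shell("<p>no heading</p>")), "heading")
  # rank mismatch is detected
  expect_error(
    parse_genus_page(shell(
      "<h1 class='taxon-name' data-rank='species'>x</h1>")),
    "genus")
  # unknown or missing dialect refuses to guess
  expect_error(parse_family_page("<html><body></body></html>"),
               "dialect")
  expect_error(
    parse_family_page(paste0(
      "<html><head><meta name=\"checklist-dialect\" content=\"v9\"/>",
      "</head><body></body></html>")),
    "v9")
  # a family with zero genera is data, not an error
  fp <- parse_family_page(shell(paste0(
    "<h1 class='taxon-name' data-rank='family'>Emptyaceae</h1>",
    "<ul class='genus-list'></ul>")))
  expect_length(fp$genera, 0L)
})

test_that("transient fetch failures are retried with doubling backoff", {
  calls <- 0L
  flaky <- structure(
    list(kind = "local", root = ".",
         read = function(uri) {
           calls <<- calls + 1L
           if (calls <= 2L) {
             stop(structure(
               class = c("floramine_fetch_error", "error", "condition"),
               list(message = "transient", call = NULL)))
           }
           "<html><head><meta name=\"checklist-dialect\" content=\"v1\"/></head><body></body></html>"
         }),
    class = "page_source")
  clock <- mock_clock()
  fetcher <- page_fetcher(flaky, rate_limit_policy(1000, 300), clock)
  html <- fetcher$fetch("x")
  expect_match(html, "checklist-dialect")
  expect_identical(calls, 3L)
  expect_identical(clock$log, c(1, 2))   # backoff doubles
  expect_identical(fetcher$request_count(), 3L)  # retries count as hits

  # permanent failure propagates as a classed error after 4 attempts
  dead <- structure(
    list(kind = "local", root = ".",
         read = function(uri) {
           stop(structure(
             class = c("floramine_fetch_error", "error", "condition"),
             list(message = "gone", call = NULL)))
         }),
    class = "page_source")
  f2 <- page_fetcher(dead, rate_limit_policy(1000, 300), mock_clock())
  expect_error(f2$fetch("x"), class = "floramine_fetch_error")
})

test_that("a fresh crawl of the demo site retrieves every record", {
  d <- demo_site()
  res <- crawl(site_roots(d), local_site(d), clock = mock_clock())
  expect_length(res$records, 4L)
  expect_length(res$genera, 2L)
  expect_length(res$failures, 0L)
  expect_true(res$complete)
  expect_identical(res$request_count, 7L)
  expect_identical(anyDuplicated(res$fetch_log), 0L)
  # missing pages are recorded as failures, never silently dropped
  roots <- c(site_roots(d), list(taxon_uri("family/nope.html", "family")))
  clock <- mock_clock()
  res2 <- crawl(roots, local_site(d), clock = clock)
  expect_length(res2$failures, 1L)
  expect_match(res2$failures[[1]]$reason, "nope")
  expect_length(res2$records, 4L)
})

test_that("checkpoints round-trip and reject corruption", {
  d <- demo_site()
  ckpt <- tempfile(fileext = ".jsonl")
  res <- crawl(site_roots(d), local_site(d), checkpoint_path = ckpt,
               clock = mock_clock())
  expect_true(file.exists(ckpt))
  state <- read_checkpoint(ckpt)
  expect_length(state$completed, 7L)
  expect_length(state$records, 4L)
  expect_identical(
    sorted_names_table(ground_truth_table(state$records)),
    sorted_names_table(ground_truth_table(res$records)))

  # flip a byte in the body: integrity hash must catch it
  lines <- readLines(ckpt)
  lines[2] <- sub("family", "Family", lines[2])
  writeLines(lines, ckpt)
  expect_error(read_checkpoint(ckpt), "integrity")

  # truncation loses the footer
  writeLines(lines[1:3], ckpt)
  expect_error(read_checkpoint(ckpt), "footer|integrity")

  writeLines("not json at all", ckpt)
  expect_error(read_checkpoint(ckpt), "JSON|lines")
})

test_that("an interrupted crawl resumes without refetching", {
  d <- demo_site()
  full <- crawl(site_roots(d), local_site(d), clock = mock_clock())
  full_tab <- sorted_names_table(ground_truth_table(full$records))

  ckpt <- tempfile(fileext = ".jsonl")
  first <- crawl(site_roots(d), local_site(d), checkpoint_path = ckpt,
                 clock = mock_clock(), max_requests = 4)
  expect_false(first$complete)
  second <- crawl(site_roots(d), local_site(d), checkpoint_path = ckpt,
                  clock = mock_clock())
  expect_true(second$complete)
  expect_identical(
    sorted_names_table(ground_truth_table(second$records)), full_tab)
  # the request log shows no repeats across the two runs
  expect_length(intersect(first$fetch_log, second$fetch_log), 0L)
  expect_identical(second$request_count, 7L)
})
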