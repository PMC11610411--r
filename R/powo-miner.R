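# Resumable, rate-limited crawler over a POWO-style site, plus the page
# parsers that turn taxon pages into species records. The same TaxonURI
# abstraction addresses a live base URL or a local directory, so tests
# and live runs share one code path.

#' Construct a taxon URI
#'
#' Locates one taxon page: its family, rank and the locator the page
#' source resolves (a path relative to the site root, or a URL path).
#'
#' @param uri Non-empty locator string.
#' @param rank One of `"family"`, `"genus"`, `"species"`.
#' @param family Family name, when known.
#' @param record_id Stable identifier, when known.
#' @return An object of class `taxon_uri`.
#' @export
taxon_uri <- function(uri, rank = c("family", "genus", "species"),
                      family = "", record_id = "") {
  rank <- match.arg(rank)
  if (!nzchar(uri)) stop("taxon_uri: uri must be non-empty")
  structure(list(family = as.character(family), rank = rank,
                 record_id = as.character(record_id),
                 uri = as.character(uri)),
            class = "taxon_uri")
}

#' Rate-limit policy for polite crawling
#'
#' After every `requests_per_pause`-th request the crawler sleeps for
#' `pause_seconds`, so a long mining run does not overload the server.
#' Defaults: a 300-second pause after every 500th request.
#'
#' @param requests_per_pause Positive integer (default 500).
#' @param pause_seconds Non-negative pause length in seconds
#'   (default 300).
#' @return An object of class `rate_limit_policy`.
#' @export
rate_limit_policy <- function(requests_per_pause = 500L,
                              pause_seconds = 300) {
  requests_per_pause <- as.integer(requests_per_pause)
  if (is.na(requests_per_pause) || requests_per_pause < 1L) {
    stop("rate_limit_policy: requests_per_pause must be >= 1")
  }
  if (pause_seconds < 0) {
    stop("rate_limit_policy: pause_seconds must be >= 0")
  }
  structure(list(requests_per_pause = requests_per_pause,
                 pause_seconds = as.numeric(pause_seconds)),
            class = "rate_limit_policy")
}

#' Injectable clock
#'
#' The crawler never calls `Sys.sleep` directly; it asks a clock object,
#' so tests can verify a 300-second pause schedule in milliseconds.
#' `system_clock()` really sleeps; `mock_clock()` records requested
#' sleeps in `$log` and accumulates `$elapsed`.
#'
#' @return A list with a `sleep(seconds)` function; mock clocks also
#'   expose `$elapsed` and `$log`.
#' @export
system_clock <- function() {
  list(sleep = function(seconds) Sys.sleep(seconds))
}

#' @rdname system_clock
#' @export
mock_clock <- function() {
  env <- new.env()
  env$elapsed <- 0
  env$log <- numeric()
  env$sleep <- function(seconds) {
    env$elapsed <- env$elapsed + seconds
    env$log <- c(env$log, seconds)
    invisible(NULL)
  }
  env
}

#' Page sources: local directory or remote base URL
#'
#' A page source resolves a [taxon_uri()] locator to raw HTML.
#' `local_site()` reads files under a directory; `remote_site()` fetches
#' `base_url/uri` over HTTP(S). Both raise a classed resolution error
#' (`floramine_fetch_error`) on failure, which the crawler's retry logic
#' handles.
#'
#' @param dir Site root directory.
#' @param base_url Base URL, joined to each locator with `/`.
#' @return An object of class `page_source` with a `read(uri)` function.
#' @export
local_site <- function(dir) {
  if (!dir.exists(dir)) stop("local_site: directory not found: ", dir)
  structure(
    list(kind = "local", root = dir,
         read = function(uri) {
           path <- file.path(dir, uri)
           if (!file.exists(path)) {
             stop(structure(
               class = c("floramine_fetch_error", "error", "condition"),
               list(message = paste0("cannot resolve local page: ", path),
                    call = NULL)))
           }
           paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
         }),
    class = "page_source")
}

#' @rdname local_site
#' @export
remote_site <- function(base_url) {
  base_url <- sub("/+$", "", base_url)
  structure(
    list(kind = "remote", root = base_url,
         read = function(uri) {
           con <- url(paste(base_url, uri, sep = "/"), encoding = "UTF-8")
           on.exit(close(con))
           tryCatch(
             paste(readLines(con, warn = FALSE), collapse = "\n"),
             error = function(e) {
               stop(structure(
                 class = c("floramine_fetch_error", "error", "condition"),
                 list(message = paste0("fetch failed for ", uri, ": ",
                                       conditionMessage(e)),
                      call = NULL)))
             })
         }),
    class = "page_source")
}

#' Create a fetcher with rate limiting and retries
#'
#' Returns a stateful fetcher over a page source. Every attempt — retries
#' included, since a retry is still a server hit — increments the request
#' counter, and after every `requests_per_pause`-th request the policy's
#' pause is requested from the clock. Transient failures are retried up
#' to 3 times with doubling backoff (1, 2, 4 s); a fourth failure
#' propagates as a `floramine_fetch_error` for the crawler to record.
#'
#' @param source A [local_site()] or [remote_site()].
#' @param policy A [rate_limit_policy()].
#' @param clock A [system_clock()] or [mock_clock()].
#' @return A list with `fetch(uri)` returning the page HTML,
#'   `request_count()` and `fetch_log()`.
#' @export
page_fetcher <- function(source, policy = rate_limit_policy(),
                         clock = system_clock()) {
  stopifnot(inherits(source, "page_source"),
            inherits(policy, "rate_limit_policy"))
  env <- new.env()
  env$count <- 0L
  env$log <- character()
  attempt_one <- function(uri) {
    env$count <- env$count + 1L
    env$log <- c(env$log, uri)
    out <- tryCatch(source$read(uri), floramine_fetch_error = identity)
    if (env$count %% policy$requests_per_pause == 0L) {
      clock$sleep(policy$pause_seconds)
    }
    out
  }
  list(
    fetch = function(uri) {
      if (inherits(uri, "taxon_uri")) uri <- uri$uri
      backoff <- 1
      for (try in 1:4) {
        out <- attempt_one(uri)
        if (!inherits(out, "condition")) return(out)
        if (try < 4) {
          clock$sleep(backoff)
          backoff <- backoff * 2
        }
      }
      stop(out)
    },
    request_count = function() env$count,
    fetch_log = function() env$log)
}

# Selector tables per markup dialect. Unknown dialect -> explicit error,
# never best-effort scraping.
.dialects <- list(
  v1 = list(
    dialect_meta = "//meta[@name='checklist-dialect']",
    heading = "//h1[@class='taxon-name']",
    genus_list = "//ul[@class='genus-list']",
    genus_link = ".//li/a[@class='genus-link']",
    species_list = "//ul[@class='species-list']",
    species_link = ".//li/a[@class='species-link']",
    protologue = "//p[@class='protologue']",
    distribution = "//div[@class='distribution']",
    native = ".//ul[@class='native']/li",
    introduced = ".//ul[@class='introduced']/li",
    synonyms = "//div[@class='synonyms']//li"))

.page_dialect <- function(doc) {
  meta <- xml2::xml_find_first(doc, "//meta[@name='checklist-dialect']")
  if (inherits(meta, "xml_missing")) {
    stop("page carries no checklist-dialect meta tag; cannot select a parser")
  }
  tag <- xml2::xml_attr(meta, "content")
  if (!tag %in% names(.dialects)) {
    stop("unsupported markup dialect '", tag, "'")
  }
  tag
}

.heading_node <- function(doc, sel, expected_rank) {
  h <- xml2::xml_find_first(doc, sel$heading)
  if (inherits(h, "xml_missing")) {
    stop("parse error: missing selector ", sel$heading,
         " (accepted-name heading)")
  }
  rank <- xml2::xml_attr(h, "data-rank")
  if (!identical(rank, expected_rank)) {
    stop("parse error: expected a ", expected_rank,
         " page but heading rank is '", rank, "'")
  }
  h
}

.name_parts <- function(node) {
  list(
    genus = xml2::xml_text(
      xml2::xml_find_first(node, ".//i[@class='genus']")),
    epithet = xml2::xml_text(
      xml2::xml_find_first(node, ".//i[@class='epithet']")),
    authorship = xml2::xml_text(
      xml2::xml_find_first(node, ".//span[@class='authorship']")))
}

#' Parse a family page
#'
#' Extracts the family name and its genus links, in page order.
#'
#' @param html Raw HTML string of a family page.
#' @return A list with `family` (name string) and `genera` (list of
#'   genus-rank [taxon_uri()]s). A family with no genera yields an empty
#'   list; markup lacking the genus-list container raises a parse error
#'   naming the missing selector.
#' @export
parse_family_page <- function(html) {
  doc <- xml2::read_html(html)
  sel <- .dialects[[.page_dialect(doc)]]
  h <- .heading_node(doc, sel, "family")
  family <- xml2::xml_text(h)
  container <- xml2::xml_find_first(doc, sel$genus_list)
  if (inherits(container, "xml_missing")) {
    stop("parse error: missing selector ", sel$genus_list,
         " (genus-list container)")
  }
  links <- xml2::xml_find_all(container, sel$genus_link)
  genera <- lapply(links, function(a) {
    taxon_uri(sub("^\\.\\./", "", xml2::xml_attr(a, "href")),
              rank = "genus", family = family,
              record_id = xml2::xml_attr(a, "data-record-id"))
  })
  list(family = family, genera = genera)
}

#' Parse a genus page
#'
#' Extracts the genus summary (name, authorship, protologue, record id)
#' and the accepted-species links; `species_count` equals the number of
#' species links found.
#'
#' @param html Raw HTML string of a genus page.
#' @param uri Locator of the page itself (stored on the summary).
#' @return A list with `summary` (a [genus_summary()]), `family` and
#'   `species` (list of species-rank [taxon_uri()]s).
#' @export
parse_genus_page <- function(html, uri = "") {
  doc <- xml2::read_html(html)
  sel <- .dialects[[.page_dialect(doc)]]
  h <- .heading_node(doc, sel, "genus")
  parts <- .name_parts(h)
  family <- xml2::xml_attr(h, "data-family")
  prot <- xml2::xml_find_first(doc, sel$protologue)
  container <- xml2::xml_find_first(doc, sel$species_list)
  if (inherits(container, "xml_missing")) {
    stop("parse error: missing selector ", sel$species_list,
         " (species-list container)")
  }
  links <- xml2::xml_find_all(container, sel$species_link)
  species <- lapply(links, function(a) {
    taxon_uri(sub("^\\.\\./", "", xml2::xml_attr(a, "href")),
              rank = "species", family = family,
              record_id = xml2::xml_attr(a, "data-record-id"))
  })
  summary <- genus_summary(
    genus = parts$genus, authorship = parts$authorship,
    protologue = if (inherits(prot, "xml_missing")) ""
                 else xml2::xml_text(prot),
    species_count = length(species),
    record_id = xml2::xml_attr(h, "data-record-id"), uri = uri)
  list(summary = summary, family = family, species = species)
}

#' Parse a species page
#'
#' Extracts the full species record: accepted name with authorship and
#' protologue (year parsed from the citation), the synonym list with
#' homotypic/heterotypic status, and the native/introduced
#' botanical-country sets. A page without a distribution section yields
#' a distribution flagged unknown — missing information is assigned
#' unknown, never dropped.
#'
#' @param html Raw HTML string of a species page.
#' @param uri Locator of the page itself.
#' @return A [species_record()].
#' @export
parse_species_page <- function(html, uri = "") {
  doc <- xml2::read_html(html)
  sel <- .dialects[[.page_dialect(doc)]]
  h <- .heading_node(doc, sel, "species")
  parts <- .name_parts(h)
  family <- xml2::xml_attr(h, "data-family")
  prot_node <- xml2::xml_find_first(doc, sel$protologue)
  protologue <- if (inherits(prot_node, "xml_missing")) ""
                else xml2::xml_text(prot_node)
  accepted <- name_record(
    genus = parts$genus, epithet = parts$epithet,
    authorship = parts$authorship, protologue = protologue,
    status = "accepted",
    record_id = xml2::xml_attr(h, "data-record-id"), uri = uri)
  dist_node <- xml2::xml_find_first(doc, sel$distribution)
  if (inherits(dist_node, "xml_missing")) {
    dist <- distribution()
  } else {
    native <- xml2::xml_text(xml2::xml_find_all(dist_node, sel$native))
    intro <- xml2::xml_text(xml2::xml_find_all(dist_node, sel$introduced))
    dist <- distribution(native, intro)
  }
  syn_nodes <- xml2::xml_find_all(doc, sel$synonyms)
  synonyms <- lapply(syn_nodes, function(node) {
    p <- .name_parts(node)
    cls <- xml2::xml_attr(node, "class")
    status <- if (grepl("\\bhomotypic\\b", cls)) "homotypic_synonym"
              else "heterotypic_synonym"
    sprot <- xml2::xml_find_first(node, ".//span[@class='protologue']")
    name_record(
      genus = p$genus, epithet = p$epithet, authorship = p$authorship,
      protologue = if (inherits(sprot, "xml_missing")) ""
                   else xml2::xml_text(sprot),
      status = status,
      record_id = xml2::xml_attr(node, "data-record-id"), uri = uri)
  })
  species_record(accepted, synonyms, dist, family = family)
}

## Checkpoints -------------------------------------------------------------

.uri_to_list <- function(u) {
  list(family = u$family, rank = u$rank, record_id = u$record_id,
       uri = u$uri)
}

.uri_from_list <- function(l) {
  taxon_uri(l$uri, rank = l$rank, family = l$family,
            record_id = l$record_id)
}

.record_to_list <- function(sp) {
  name_to_list <- function(n) {
    list(genus = n$genus, epithet = n$epithet, authorship = n$authorship,
         protologue = n$protologue,
         year = if (is.na(n$year)) NULL else n$year,
         status = n$status, record_id = n$record_id, uri = n$uri)
  }
  list(family = sp$family, accepted = name_to_list(sp$accepted),
       synonyms = lapply(sp$synonyms, name_to_list),
       native = as.list(sp$distribution$native_botanical),
       introduced = as.list(sp$distribution$introduced_botanical))
}

.record_from_list <- function(l) {
  name_from_list <- function(n) {
    name_record(n$genus, n$epithet, n$authorship, n$protologue,
                year = if (is.null(n$year)) NA_integer_
                       else as.integer(n$year),
                status = n$status, record_id = n$record_id, uri = n$uri)
  }
  species_record(
    name_from_list(l$accepted),
    lapply(l$synonyms, name_from_list),
    distribution(unlist(l$native), unlist(l$introduced)),
    family = l$family)
}

.checkpoint_lines <- function(state) {
  lines <- c(
    jsonlite::toJSON(list(type = "header", version = 1L,
                          dialect = "v1",
                          request_count = state$request_count),
                     auto_unbox = TRUE),
    vapply(state$completed, function(u) {
      as.character(jsonlite::toJSON(
        list(type = "completed", uri = .uri_to_list(u)),
        auto_unbox = TRUE))
    }, character(1)),
    vapply(state$pending, function(u) {
      as.character(jsonlite::toJSON(
        list(type = "pending", uri = .uri_to_list(u)),
        auto_unbox = TRUE))
    }, character(1)),
    vapply(state$records, function(r) {
      as.character(jsonlite::toJSON(
        list(type = "record", species = .record_to_list(r)),
        auto_unbox = TRUE))
    }, character(1)),
    vapply(state$genera, function(g) {
      as.character(jsonlite::toJSON(
        list(type = "genus",
             genus = list(genus = g$genus, authorship = g$authorship,
                          protologue = g$protologue,
                          species_count = g$species_count,
                          record_id = g$record_id, uri = g$uri)),
        auto_unbox = TRUE))
    }, character(1)),
    vapply(seq_along(state$failures), function(i) {
      f <- state$failures[[i]]
      as.character(jsonlite::toJSON(
        list(type = "failure", uri = .uri_to_list(f$uri),
             reason = f$reason), auto_unbox = TRUE))
    }, character(1)))
  unlist(lines)
}

.body_md5 <- function(lines) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines, tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a crawl checkpoint atomically
#'
#' Serializes the crawl state as line-oriented JSON (one object per
#' line) followed by a footer carrying an MD5 integrity hash of the
#' body. The file is written to a temporary sibling and renamed into
#' place, so a crash never leaves a half-written checkpoint.
#'
#' @param state Crawl state (as built by [crawl()]).
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(state, path) {
  lines <- .checkpoint_lines(state)
  footer <- as.character(jsonlite::toJSON(
    list(type = "footer", md5 = .body_md5(lines)), auto_unbox = TRUE))
  tmp <- paste0(path, ".tmp")
  writeLines(c(lines, footer), tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) {
    stop("write_checkpoint: cannot rename ", tmp, " to ", path)
  }
  invisible(path)
}

#' Read and verify a crawl checkpoint
#'
#' Parses a line-oriented JSON checkpoint, verifies its footer MD5
#' against the body, and reconstructs the crawl state. A corrupt file —
#' bad JSON, missing footer, or hash mismatch — refuses to load and
#' names the defect, rather than resuming from damaged state.
#'
#' @param path Checkpoint file path.
#' @return Crawl state: list with `completed`, `pending`, `records`,
#'   `genera`, `failures`, `request_count`.
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2L) {
    stop("corrupt checkpoint ", path, ": fewer than two lines")
  }
  objs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) {
               stop("corrupt checkpoint ", path, ": line ", i,
                    " is not valid JSON (", conditionMessage(e), ")",
                    call. = FALSE)
             })
  })
  footer <- objs[[length(objs)]]
  if (!identical(footer$type, "footer")) {
    stop("corrupt checkpoint ", path, ": missing footer line")
  }
  body <- lines[-length(lines)]
  if (!identical(unname(footer$md5), unname(.body_md5(body)))) {
    stop("corrupt checkpoint ", path,
         ": integrity hash mismatch (file was modified or truncated)")
  }
  objs <- objs[-length(objs)]
  header <- objs[[1]]
  if (!identical(header$type, "header")) {
    stop("corrupt checkpoint ", path, ": missing header line")
  }
  state <- list(completed = list(), pending = list(), records = list(),
                genera = list(), failures = list(),
                request_count = as.integer(header$request_count))
  for (o in objs[-1]) {
    switch(o$type,
      completed = {
        state$completed[[length(state$completed) + 1L]] <-
          .uri_from_list(o$uri)
      },
      pending = {
        state$pending[[length(state$pending) + 1L]] <-
          .uri_from_list(o$uri)
      },
      record = {
        state$records[[length(state$records) + 1L]] <-
          .record_from_list(o$species)
      },
      genus = {
        g <- o$genus
        state$genera[[length(state$genera) + 1L]] <-
          genus_summary(g$genus, g$authorship, g$protologue,
                        g$species_count, g$record_id, g$uri)
      },
      failure = {
        state$failures[[length(state$failures) + 1L]] <-
          list(uri = .uri_from_list(o$uri), reason = o$reason)
      },
      stop("corrupt checkpoint ", path, ": unknown line type '",
           o$type, "'"))
  }
  state
}

#' Discover family-page roots of a local site
#'
#' Lists the family pages under a rendered site directory and returns
#' them as family-rank [taxon_uri()]s, the natural roots for [crawl()].
#'
#' @param dir Site root directory.
#' @return List of [taxon_uri()]s.
#' @export
site_roots <- function(dir) {
  files <- sort(list.files(file.path(dir, "family"), pattern = "\\.html$"))
  lapply(files, function(f) {
    taxon_uri(file.path("family", f), rank = "family",
              record_id = sub("\\.html$", "", f))
  })
}

#' Crawl a POWO-style site into species records
#'
#' Walks the taxon hierarchy breadth-first (family pages, then genus
#' pages, then species pages), parsing each page and persisting a
#' checkpoint after every completed taxon. A run interrupted at any
#' point can be restarted with the same `checkpoint_path`: completed
#' pages are never re-fetched, the crawl continues from the pending
#' queue, and the returned record set covers both runs. Fetch failures
#' are retried (with backoff) and, if persistent, recorded in
#' `failures` — never silently dropped.
#'
#' @param roots List of family-rank [taxon_uri()]s (see [site_roots()]).
#' @param source A [local_site()] or [remote_site()].
#' @param policy A [rate_limit_policy()].
#' @param checkpoint_path File for the resumable checkpoint, or `NULL`
#'   to keep state in memory only.
#' @param clock A [system_clock()] or [mock_clock()].
#' @param max_requests Stop (gracefully, checkpoint intact) after this
#'   many page requests; `Inf` to run to completion.
#' @return A list with `records` (all [species_record()]s retrieved so
#'   far, including those recovered from the checkpoint), `genera`
#'   (list of [genus_summary()]s), `failures`, `complete` (logical:
#'   pending queue empty), `request_count` and `fetch_log`.
#' @export
crawl <- function(roots, source, policy = rate_limit_policy(),
                  checkpoint_path = NULL, clock = system_clock(),
                  max_requests = Inf) {
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    state <- read_checkpoint(checkpoint_path)
  } else {
    if (length(roots) == 0L) stop("crawl: roots must be non-empty")
    state <- list(completed = list(), pending = roots, records = list(),
                  genera = list(), failures = list(), request_count = 0L)
  }
  fetcher <- page_fetcher(source, policy, clock)
  base_requests <- state$request_count
  done_uris <- vapply(state$completed, function(u) u$uri, character(1))
  persist <- function() {
    if (!is.null(checkpoint_path)) write_checkpoint(state, checkpoint_path)
  }
  n_this_run <- 0L
  while (length(state$pending) > 0L) {
    if (n_this_run >= max_requests) break
    u <- state$pending[[1]]
    state$pending <- state$pending[-1]
    if (u$uri %in% done_uris) next
    html <- tryCatch(fetcher$fetch(u),
                     floramine_fetch_error = identity)
    n_this_run <- n_this_run + 1L
    state$request_count <- base_requests + fetcher$request_count()
    if (inherits(html, "condition")) {
      state$failures[[length(state$failures) + 1L]] <-
        list(uri = u, reason = conditionMessage(html))
      persist()
      next
    }
    parsed <- tryCatch(switch(u$rank,
      family = {
        fp <- parse_family_page(html)
        state$pending <- c(state$pending, fp$genera)
        NULL
      },
      genus = {
        gp <- parse_genus_page(html, uri = u$uri)
        state$genera[[length(state$genera) + 1L]] <- gp$summary
        state$pending <- c(state$pending, gp$species)
        NULL
      },
      species = {
        state$records[[length(state$records) + 1L]] <-
          parse_species_page(html, uri = u$uri)
        NULL
      }), error = function(e) e)
    if (inherits(parsed, "error")) {
      state$failures[[length(state$failures) + 1L]] <-
        list(uri = u, reason = conditionMessage(parsed))
    }
    state$completed[[length(state$completed) + 1L]] <- u
    done_uris <- c(done_uris, u$uri)
    persist()
  }
  persist()
  list(records = state$records, genera = state$genera,
       failures = state$failures,
       complete = length(state$pending) == 0L,
       request_count = state$request_count,
       fetch_log = fetcher$fetch_log())
}

#' Mine a local site end-to-end
#'
#' Convenience wrapper: discover family roots under `dir`, crawl them
#' with an in-memory checkpoint, and return the records and genus
#' summaries. Errors if any page failed.
#'
#' @param dir Site root directory (as written by [render_site()]).
#' @param policy A [rate_limit_policy()].
#' @param clock Clock for pauses (defaults to a mock: local reads need
#'   no politeness).
#' @return As [crawl()].
#' @export
mine_site <- function(dir, policy = rate_limit_policy(),
                      clock = mock_clock()) {
  res <- crawl(site_roots(dir), local_site(dir), policy = policy,
               clock = clock)
  if (length(res$failures)) {
    stop("mine_site: ", length(res$failures), " page(s) failed, first: ",
         res$failures[[1]]$reason)
  }
  res
}
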