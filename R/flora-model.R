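#' Construct a published-name record
#'
#' A `name_record` holds one published plant name: either the currently
#' accepted name of a species or one of its synonyms. Fields mirror what a
#' POWO-style taxon page exposes: the binomial parts, authorship string,
#' protologue citation (from which the publication year is parsed), the
#' nomenclatural status, a stable record identifier (the "Kew ID" analog)
#' and the page locator.
#'
#' @param genus Genus name part (non-empty string).
#' @param epithet Species epithet (non-empty string). A leading hybrid
#'   marker ("× ") is kept for display but stripped for identity
#'   comparisons (see [name_key()]).
#' @param authorship Author citation, free-form (e.g. `"L."`).
#' @param protologue Protologue citation string, e.g.
#'   `"Sp. Pl.: 1042 (1753)"`. May be empty.
#' @param year Publication year as integer, or `NA` when unknown. If
#'   missing, parsed from `protologue` with [parse_publication_year()].
#' @param status One of `"accepted"`, `"homotypic_synonym"`,
#'   `"heterotypic_synonym"`.
#' @param record_id Opaque stable identifier.
#' @param uri Locator of the source page (URL or relative path).
#'
#' @return An object of class `name_record`.
#' @examples
#' name_record("Alpha", "unus", "L.", "Sp. Pl.: 12 (1753)",
#'             status = "accepted", record_id = "id-1", uri = "t/id-1")
#' @export
name_record <- function(genus, epithet, authorship = "",
                        protologue = "", year = NULL,
                        status = c("accepted", "homotypic_synonym",
                                   "heterotypic_synonym"),
                        record_id = "", uri = "") {
  status <- match.arg(status)
  if (is.null(year)) year <- parse_publication_year(protologue)
  structure(
    list(genus = as.character(genus), epithet = as.character(epithet),
         authorship = as.character(authorship),
         protologue = as.character(protologue),
         year = as.integer(year), status = status,
         record_id = as.character(record_id), uri = as.character(uri)),
    class = "name_record")
}

#' @export
print.name_record <- function(x, ...) {
  yr <- if (is.na(x$year)) "year unknown" else x$year
  cat(sprintf("<name_record> %s %s %s [%s, %s]\n",
              x$genus, x$epithet, x$authorship, x$status, yr))
  invisible(x)
}

#' Identity key of a published name
#'
#' Names are identified by the (genus, epithet, authorship) triple:
#' homonyms differ only by author, so authorship is compared
#' case-sensitively. Hybrid markers are stripped from the epithet before
#' comparison.
#'
#' @param x A [name_record()].
#' @return A single string key.
#' @export
name_key <- function(x) {
  epi <- gsub("×\\s*", "", x$epithet)
  paste(x$genus, epi, x$authorship, sep = "|")
}

#' Construct a distribution at the botanical-country level
#'
#' POWO pages list native and introduced occurrences as TDWG level-3
#' "botanical countries". A species whose page carries no distribution
#' section at all is flagged unknown; by construction the flag is true
#' exactly when both region sets are empty.
#'
#' @param native_botanical Character vector of native botanical countries.
#' @param introduced_botanical Character vector of introduced botanical
#'   countries.
#' @return An object of class `distribution` with fields
#'   `native_botanical`, `introduced_botanical`, `is_unknown`.
#' @export
distribution <- function(native_botanical = character(),
                         introduced_botanical = character()) {
  native <- unique(as.character(native_botanical))
  intro <- unique(as.character(introduced_botanical))
  structure(
    list(native_botanical = native, introduced_botanical = intro,
         is_unknown = length(native) == 0L && length(intro) == 0L),
    class = "distribution")
}

#' Construct an accepted-species record
#'
#' Bundles one accepted name with its synonyms (homotypic and
#' heterotypic), its botanical-country distribution and the family it
#' belongs to. This is the unit every downstream query, map and curve
#' operates on.
#'
#' @param accepted A [name_record()] with status `"accepted"`.
#' @param synonyms List of [name_record()]s with synonym status.
#' @param distribution A [distribution()].
#' @param family Family name string.
#' @return An object of class `species_record`.
#' @export
species_record <- function(accepted, synonyms = list(),
                           distribution = floramine::distribution(),
                           family = "") {
  structure(
    list(accepted = accepted, synonyms = synonyms,
         distribution = distribution, family = as.character(family)),
    class = "species_record")
}

#' @export
print.species_record <- function(x, ...) {
  cat(sprintf("<species_record> %s %s %s (%s); %d synonym(s); %s\n",
              x$accepted$genus, x$accepted$epithet, x$accepted$authorship,
              x$family, length(x$synonyms),
              if (x$distribution$is_unknown) "distribution unknown"
              else sprintf("%d native / %d introduced region(s)",
                           length(x$distribution$native_botanical),
                           length(x$distribution$introduced_botanical))))
  invisible(x)
}

#' Construct a genus-level summary row
#'
#' One row of a genus checklist: name, authorship, protologue citation,
#' number of accepted species, record identifier and page locator.
#'
#' @param genus Genus name.
#' @param authorship Author citation.
#' @param protologue Protologue citation string.
#' @param species_count Non-negative number of accepted species.
#' @param record_id Stable identifier.
#' @param uri Page locator.
#' @return An object of class `genus_summary`.
#' @export
genus_summary <- function(genus, authorship = "", protologue = "",
                          species_count = 0L, record_id = "", uri = "") {
  stopifnot(species_count >= 0)
  structure(
    list(genus = as.character(genus), authorship = as.character(authorship),
         protologue = as.character(protologue),
         species_count = as.integer(species_count),
         record_id = as.character(record_id), uri = as.character(uri)),
    class = "genus_summary")
}

# Nomenclature began with Species Plantarum (1753); later years are
# treated as database errors and mapped to unknown.
.year_min <- 1753L

.year_max <- function() as.integer(format(Sys.Date(), "%Y"))

#' Parse a publication year from a protologue citation
#'
#' Extracts the publication year from a free-form protologue citation.
#' The first parenthesized 4-digit number within the nomenclaturally
#' valid window (1753 to the current calendar year) wins, matching the
#' dominant POWO citation style `"Sp. Pl.: 1042 (1753)"`; failing that,
#' the last bare 4-digit token in the window (older citation styles such
#' as `"Fl. Bras. 2(2): 44. 1877"`); otherwise `NA`. Never errors:
#' unparseable input yields `NA`.
#'
#' @param citation Character vector of citation strings (may be empty
#'   strings or `NA`).
#' @return Integer vector of years, `NA` where no year is found.
#' @examples
#' parse_publication_year("Sp. Pl.: 1042 (1753)")       # 1753
#' parse_publication_year("Fl. Bras. 2(2): 44. 1877")   # 1877
#' parse_publication_year("")                           # NA
#' @export
parse_publication_year <- function(citation) {
  vapply(as.character(citation), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    ymax <- .year_max()
    in_window <- function(y) y >= .year_min & y <= ymax
    paren <- regmatches(s, gregexpr("\\((\\d{4})\\)", s))[[1]]
    if (length(paren)) {
      yrs <- as.integer(gsub("[()]", "", paren))
      yrs <- yrs[in_window(yrs)]
      if (length(yrs)) return(yrs[1L])
    }
    bare <- regmatches(s, gregexpr("(?<!\\d)\\d{4}(?!\\d)", s,
                                   perl = TRUE))[[1]]
    if (length(bare)) {
      yrs <- as.integer(bare)
      yrs <- yrs[in_window(yrs)]
      if (length(yrs)) return(yrs[length(yrs)])
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Publication year of a species' basionym
#'
#' The basionym of an accepted name shares its type, so it is found among
#' the homotypic synonyms; its publication year marks the actual species
#' discovery, as opposed to the (possibly much later) recombination date
#' of the accepted name. Returns the minimum known year over the accepted
#' name and its homotypic synonyms; heterotypic synonyms never
#' participate. `NA` if no year is known.
#'
#' @param species A [species_record()].
#' @return Integer year or `NA`.
#' @export
basionym_year <- function(species) {
  yrs <- species$accepted$year
  for (syn in species$synonyms) {
    if (identical(syn$status, "homotypic_synonym")) yrs <- c(yrs, syn$year)
  }
  yrs <- yrs[!is.na(yrs)]
  if (length(yrs) == 0L) NA_integer_ else min(yrs)
}

.validate_name <- function(n, label) {
  v <- character()
  ok_status <- c("accepted", "homotypic_synonym", "heterotypic_synonym")
  if (!inherits(n, "name_record")) {
    return(sprintf("%s: not a name_record", label))
  }
  if (!nzchar(n$genus)) v <- c(v, sprintf("%s: genus is empty", label))
  if (!nzchar(n$epithet)) v <- c(v, sprintf("%s: epithet is empty", label))
  if (!is.na(n$year) && (n$year < .year_min || n$year > .year_max())) {
    v <- c(v, sprintf("%s: year %d outside [%d, %d]",
                      label, n$year, .year_min, .year_max()))
  }
  if (!(n$status %in% ok_status)) {
    v <- c(v, sprintf(
      "%s: status '%s' is not one of accepted/homotypic_synonym/heterotypic_synonym",
      label, n$status))
  }
  v
}

#' Validate a species record against the data-model invariants
#'
#' Checks every structural rule of the data model: non-empty name parts,
#' years within the nomenclatural window \[1753, current year\], a status
#' drawn from the three supported values (POWO's "unplaced" and
#' "artificial hybrid" statuses are rejected, not coerced), exactly one
#' accepted name, no synonym duplicating the accepted name's identity
#' key, duplicate-free region sets, and the unknown-distribution flag
#' holding exactly when both region sets are empty.
#'
#' @param record A candidate [species_record()].
#' @return Character vector of violation descriptions; empty when the
#'   record is well-formed. Never errors.
#' @export
validate_species <- function(record) {
  v <- character()
  if (!inherits(record, "species_record")) {
    return("record: not a species_record")
  }
  v <- c(v, .validate_name(record$accepted, "accepted"))
  if (inherits(record$accepted, "name_record") &&
      !identical(record$accepted$status, "accepted")) {
    v <- c(v, sprintf("accepted: status is '%s', must be 'accepted'",
                      record$accepted$status))
  }
  acc_key <- if (inherits(record$accepted, "name_record")) {
    name_key(record$accepted)
  } else {
    NA_character_
  }
  for (i in seq_along(record$synonyms)) {
    syn <- record$synonyms[[i]]
    lab <- sprintf("synonym[%d]", i)
    v <- c(v, .validate_name(syn, lab))
    if (inherits(syn, "name_record")) {
      if (identical(syn$status, "accepted")) {
        v <- c(v, sprintf("%s: status 'accepted' not allowed in synonym list",
                          lab))
      }
      if (!is.na(acc_key) && identical(name_key(syn), acc_key)) {
        v <- c(v, sprintf(
          "%s: duplicates the accepted name's (genus, epithet, authorship)",
          lab))
      }
    }
  }
  d <- record$distribution
  if (!inherits(d, "distribution")) {
    v <- c(v, "distribution: not a distribution object")
  } else {
    if (anyDuplicated(d$native_botanical)) {
      v <- c(v, "distribution: duplicate native botanical countries")
    }
    if (anyDuplicated(d$introduced_botanical)) {
      v <- c(v, "distribution: duplicate introduced botanical countries")
    }
    empty <- length(d$native_botanical) == 0L &&
      length(d$introduced_botanical) == 0L
    if (!identical(d$is_unknown, empty)) {
      v <- c(v, "distribution: is_unknown must hold iff both region sets are empty")
    }
  }
  v
}
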