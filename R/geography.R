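# TDWG level-3 "botanical country" <-> political country conversion.
# POWO distributions come as level-3 units (Borneo, Cape Provinces, ...);
# country-level conservation work needs political countries, so every
# checklist the package delivers carries both levels.

.normalize_region <- function(x) {
  x <- trimws(as.character(x))
  x <- tolower(x)
  # diacritic-insensitive lookup; byte-identical names still round-trip
  # because normalization only keys the lookup table. glibc TRANSLIT
  # renders accents as combining marks ("panam'a"), so strip them.
  ascii <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  ascii <- gsub("['`^~\"]", "", ascii)
  ifelse(is.na(ascii), x, ascii)
}

#' Load a botanical-country to political-country mapping table
#'
#' Reads a many-to-many mapping between TDWG level-3 botanical countries
#' and political countries from a CSV with header columns
#' `botanical_country,political_country` and an optional `alias` column
#' for alternative country spellings (e.g. "Burma" for "Myanmar").
#' Duplicate rows are collapsed. The package bundles a subset of the
#' published WGSRPD level-3 scheme covering roughly a hundred units; a
#' fuller table in the same format can be dropped in.
#'
#' @param path Path to the mapping CSV; defaults to the bundled table.
#' @return An object of class `region_mapping`: a list with `entries`
#'   (data frame of the deduplicated pairs), `n_botanical`,
#'   `n_countries`, and an internal normalized lookup index.
#' @examples
#' m <- load_mapping()
#' m$n_botanical
#' @export
load_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "wgsrpd3_mapping.csv",
                        package = "floramine")
  }
  if (!file.exists(path)) stop("mapping file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         encoding = "UTF-8")
  required <- c("botanical_country", "political_country")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("mapping file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, intersect(c(required, "alias"), names(tab)), drop = FALSE]
  tab$botanical_country <- trimws(tab$botanical_country)
  tab$political_country <- trimws(tab$political_country)
  tab <- tab[nzchar(tab$botanical_country) & nzchar(tab$political_country), ,
             drop = FALSE]
  tab <- unique(tab[c("botanical_country", "political_country")])
  rownames(tab) <- NULL
  key <- .normalize_region(tab$botanical_country)
  index <- split(tab$political_country, key)
  structure(
    list(entries = tab,
         n_botanical = length(unique(tab$botanical_country)),
         n_countries = length(unique(tab$political_country)),
         index = index),
    class = "region_mapping")
}

#' @export
print.region_mapping <- function(x, ...) {
  cat(sprintf(
    "<region_mapping> %d pairs: %d botanical countries -> %d countries\n",
    nrow(x$entries), x$n_botanical, x$n_countries))
  invisible(x)
}

#' Convert botanical countries to political countries
#'
#' Maps a set of TDWG level-3 botanical-country names to the union of
#' their political countries. Lookup is insensitive to case, surrounding
#' whitespace and diacritics. Names that fail lookup are returned in
#' `unresolved` (with a warning) rather than raising an error: lookup
#' failures are data, not exceptions. An empty input yields an empty
#' result flagged unknown, mirroring the unknown-distribution rule for
#' species pages without a distribution section.
#'
#' @param botanical Character vector of botanical-country names.
#' @param mapping A [load_mapping()] result.
#' @return A list with `countries` (sorted unique character vector),
#'   `unresolved` (inputs that failed lookup) and `is_unknown`
#'   (`TRUE` iff the input set was empty).
#' @examples
#' m <- load_mapping()
#' convert_regions(c("Borneo", "Peru"), m)$countries
#' @export
convert_regions <- function(botanical, mapping) {
  stopifnot(inherits(mapping, "region_mapping"))
  botanical <- unique(as.character(botanical))
  botanical <- botanical[!is.na(botanical) & nzchar(trimws(botanical))]
  if (length(botanical) == 0L) {
    return(list(countries = character(), unresolved = character(),
                is_unknown = TRUE))
  }
  keys <- .normalize_region(botanical)
  hit <- keys %in% names(mapping$index)
  countries <- sort(unique(unlist(mapping$index[keys[hit]],
                                  use.names = FALSE)))
  unresolved <- botanical[!hit]
  if (length(unresolved)) {
    warning("unmapped botanical country name(s): ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  list(countries = if (is.null(countries)) character() else countries,
       unresolved = unresolved, is_unknown = FALSE)
}

#' Annotate a species record with political-country distributions
#'
#' Converts the native and introduced botanical-country sets of a record
#' independently, leaving the original botanical sets untouched, and
#' attaches a `country_distribution` element with `native_countries`,
#' `introduced_countries` and `unresolved_regions`.
#'
#' @param record A [species_record()].
#' @param mapping A [load_mapping()] result.
#' @return The record with `$country_distribution` attached.
#' @export
attach_country_distribution <- function(record, mapping) {
  stopifnot(inherits(record, "species_record"))
  nat <- suppressWarnings(
    convert_regions(record$distribution$native_botanical, mapping))
  intr <- suppressWarnings(
    convert_regions(record$distribution$introduced_botanical, mapping))
  unresolved <- sort(unique(c(nat$unresolved, intr$unresolved)))
  if (length(unresolved)) {
    warning("unmapped botanical country name(s) for ",
            record$accepted$genus, " ", record$accepted$epithet, ": ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  record$country_distribution <- list(
    native_countries = nat$countries,
    introduced_countries = intr$countries,
    unresolved_regions = unresolved,
    is_unknown = record$distribution$is_unknown)
  record
}
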