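# Brute-force oracles, deliberately independent of the package's own
# aggregation code paths: everything is a plain double loop over
# records, recomputed from first principles.

# distinct accepted binomials of a family
oracle_family_count <- function(species, family) {
  seen <- character()
  for (sp in species) {
    if (sp$family == family) {
      b <- paste(sp$accepted$genus, sp$accepted$epithet)
      if (!(b %in% seen)) seen <- c(seen, b)
    }
  }
  length(seen)
}

# per-region distinct-species counts via species x region double loop
oracle_richness <- function(species, level, mapping) {
  counts <- list()
  unknown <- 0L
  for (sp in species) {
    regs <- if (level == "botanical_country") {
      sp$distribution$native_botanical
    } else {
      out <- character()
      for (b in sp$distribution$native_botanical) {
        hit <- mapping$entries$political_country[
          tolower(trimws(mapping$entries$botanical_country)) ==
            tolower(trimws(b))]
        out <- c(out, hit)
      }
      unique(out)
    }
    regs <- unique(regs)
    if (length(regs) == 0L) {
      unknown <- unknown + 1L
      next
    }
    for (r in regs) {
      counts[[r]] <- (if (is.null(counts[[r]])) 0L else counts[[r]]) + 1L
    }
  }
  list(counts = counts, unknown = unknown)
}

# species natively occurring in ANY of the given countries
oracle_country_filter <- function(species, countries, mapping) {
  keep <- logical(length(species))
  for (i in seq_along(species)) {
    sp <- species[[i]]
    ctry <- character()
    for (b in sp$distribution$native_botanical) {
      ctry <- c(ctry, mapping$entries$political_country[
        tolower(mapping$entries$botanical_country) == tolower(b)])
    }
    keep[i] <- any(tolower(ctry) %in% tolower(countries))
  }
  species[keep]
}

# sort-and-count accumulation from a vector of (possibly NA) years
oracle_accumulation <- function(years) {
  known <- sort(years[!is.na(years)])
  uy <- unique(known)
  data.frame(year = uy,
             cumulative = vapply(uy, function(y) sum(known <= y),
                                 integer(1)))
}

# canonical ordering for flora comparisons
sorted_names_table <- function(tab) {
  tab <- tab[do.call(order, tab[c("genus", "epithet", "authorship")]), ]
  rownames(tab) <- NULL
  tab
}

# minimal species record for count-structured fixtures
quick_species <- function(genus, epithet, family = "Testaceae",
                          year = 1900L, native = "Peru",
                          synonyms = list()) {
  species_record(
    name_record(genus, epithet, "L.",
                sprintf("Sp. Pl.: 1 (%d)", year),
                status = "accepted",
                record_id = paste0(genus, "-", epithet),
                uri = paste0("species/", genus, "-", epithet, ".html")),
    synonyms,
    if (is.null(native)) distribution() else distribution(native),
    family = family)
}

# a genus of n trivially distinct species
quick_genus <- function(genus, n, family = "Testaceae") {
  lapply(seq_len(n), function(i) {
    quick_species(genus, sprintf("sp%04d", i), family = family)
  })
}

small_spec <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_families = 2, genera_per_family = c(2, 4),
         species_per_genus = c(2, 8), synonyms_per_species = c(0, 3),
         p_unknown_distribution = 0.1, seed = seed),
    list(...))
  do.call(flora_spec, args)
}
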