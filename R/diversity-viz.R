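# Richness aggregation + choropleth maps, and species-discovery
# accumulation / nomenclatural-change analytics + graphics. Renderers
# are pure functions of their input tables and always write a plot-data
# sidecar CSV, so every graphical claim is testable without image
# diffing.

#' Species richness per region
#'
#' Counts distinct accepted species per region over native ranges (plus
#' introduced ranges when `use_introduced`), at either the
#' political-country or botanical-country level. A species occurring in
#' three regions adds one to each of the three counts — richness is
#' distinct-species incidence, never occurrence multiplicity. Species
#' with unknown distribution contribute to no region and are tallied in
#' `unknown_count`, so totals are never silently misstated.
#'
#' @param species Annotated [species_record()]s (from [species_list()])
#'   or an [as_checklist()] result.
#' @param level `"country"` or `"botanical_country"`.
#' @param use_introduced Logical; also count introduced ranges.
#' @param group_by Optional `"family"` or `"genus"`: return one table
#'   per group (a named list), the per-taxon-group map semantics.
#' @return An object of class `richness_table` — list with `level`,
#'   `counts` (named integer vector, count-descending), `unknown_count`
#'   and `n_species` — or a named list of them when `group_by` is set.
#' @export
richness_table <- function(species,
                           level = c("country", "botanical_country"),
                           use_introduced = FALSE, group_by = NULL) {
  level <- match.arg(level)
  if (inherits(species, "checklist")) species <- species$species
  if (!is.null(group_by)) {
    if (!group_by %in% c("family", "genus")) {
      stop("richness_table: unknown group column '", group_by, "'")
    }
    labels <- vapply(species, function(sp) {
      if (group_by == "family") sp$family else sp$accepted$genus
    }, "")
    return(lapply(split(species, labels), richness_table,
                  level = level, use_introduced = use_introduced))
  }
  counts <- integer()
  unknown <- 0L
  for (sp in species) {
    regions <- if (level == "botanical_country") {
      c(sp$distribution$native_botanical,
        if (use_introduced) sp$distribution$introduced_botanical)
    } else {
      cd <- sp$country_distribution
      if (is.null(cd)) {
        stop("richness_table: species records lack country annotation; ",
             "build them with as_checklist()")
      }
      c(cd$native_countries,
        if (use_introduced) cd$introduced_countries)
    }
    regions <- unique(regions)
    if (length(regions) == 0L) {
      unknown <- unknown + 1L
      next
    }
    for (r in regions) {
      counts[r] <- (if (r %in% names(counts)) counts[[r]] else 0L) + 1L
    }
  }
  counts <- counts[order(-counts, names(counts))]
  structure(list(level = level, counts = counts,
                 unknown_count = unknown, n_species = length(species)),
            class = "richness_table")
}

#' @export
print.richness_table <- function(x, ...) {
  cat(sprintf("<richness_table> level=%s, %d region(s), %d species (%d unknown)\n",
              x$level, length(x$counts), x$n_species, x$unknown_count))
  if (length(x$counts)) {
    print(utils::head(x$counts, 10))
  }
  invisible(x)
}

#' Read region polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of `Polygon`/`MultiPolygon`
#' features and flattens the rings into a plotting table. Each feature
#' must carry a `region_name` property, the join key against
#' [richness_table()] counts.
#'
#' @param path GeoJSON file path.
#' @return A data frame with columns `long`, `lat`, `ring` (unique ring
#'   id) and `region_name`.
#' @export
read_region_geojson <- function(path) {
  if (!file.exists(path)) {
    stop("read_region_geojson: file not found: ", path)
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) {
    stop("read_region_geojson: not a FeatureCollection: ", path)
  }
  rows <- list()
  ring_id <- 0L
  for (feat in gj$features) {
    name <- feat$properties$region_name
    if (is.null(name)) {
      stop("read_region_geojson: feature without a region_name property")
    }
    geom <- feat$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("read_region_geojson: unsupported geometry type '",
           geom$type, "'"))
    for (poly in polys) {
      for (ring in poly) {
        ring_id <- ring_id + 1L
        xy <- do.call(rbind, lapply(ring, function(pt) {
          c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
        }))
        rows[[length(rows) + 1L]] <- data.frame(
          long = xy[, 1], lat = xy[, 2], ring = ring_id,
          region_name = name, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.viridis_options <- c("viridis", "magma", "plasma", "inferno", "cividis",
                      "rocket", "mako", "turbo")

.fill_scale <- function(palette) {
  if (palette %in% .viridis_options) {
    ggplot2::scale_fill_viridis_c(option = palette, na.value = "grey85",
                                  name = "species")
  } else {
    ggplot2::scale_fill_distiller(palette = palette, direction = 1,
                                  na.value = "grey85", name = "species")
  }
}

#' Render a species-richness choropleth
#'
#' Colors each region polygon by its distinct-species count on a
#' continuous scale. Available palettes include the
#' color-vision-deficiency-safe viridis family (`"viridis"`, `"rocket"`,
#' `"mako"`, ...) and ColorBrewer sequential palettes; regions with no
#' data are drawn in a neutral grey. Counted regions with no matching
#' geometry are returned in `unmatched`, never dropped silently. Passing
#' a named list of tables (from `richness_table(group_by=)`) writes one
#' file per group, suffixed with the group label.
#'
#' @param table A [richness_table()] or a named list of them.
#' @param geometries Path to a region GeoJSON, or a table from
#'   [read_region_geojson()].
#' @param palette Palette name (default `"viridis"`).
#' @param out Output image path; extension selects the device (PNG).
#' @return Invisibly, a list with `files` (written image paths),
#'   `unmatched` (count regions without geometry) and `data` (the
#'   plotted region/count table, also written as a `.csv` sidecar).
#' @export
render_richness_map <- function(table, geometries, palette = "viridis",
                                out) {
  if (is.data.frame(geometries)) {
    geo <- geometries
  } else {
    geo <- read_region_geojson(geometries)
  }
  if (!inherits(table, "richness_table")) {
    stopifnot(is.list(table), length(table) >= 1,
              !is.null(names(table)))
    base <- sub("\\.([a-zA-Z]+)$", "", out)
    ext <- sub(".*\\.", "", out)
    res <- list(files = character(), unmatched = character(),
                data = list())
    for (nm in names(table)) {
      safe <- gsub("[^A-Za-z0-9_-]", "_", nm)
      sub_out <- paste0(base, "_", safe, ".", ext)
      r <- render_richness_map(table[[nm]], geo, palette, sub_out)
      res$files <- c(res$files, r$files)
      res$unmatched <- unique(c(res$unmatched, r$unmatched))
      res$data[[nm]] <- r$data
    }
    return(invisible(res))
  }
  counts <- table$counts
  geo_names <- unique(geo$region_name)
  unmatched <- names(counts)[!(.normalize_region(names(counts)) %in%
                                 .normalize_region(geo_names))]
  fill <- counts[match(.normalize_region(geo$region_name),
                       .normalize_region(names(counts)))]
  geo$richness <- as.numeric(fill)
  plot_data <- data.frame(
    region_name = geo_names,
    richness = as.numeric(counts[match(
      .normalize_region(geo_names), .normalize_region(names(counts)))]),
    stringsAsFactors = FALSE)
  p <- ggplot2::ggplot(geo,
                       ggplot2::aes(x = .data$long, y = .data$lat,
                                    group = .data$ring,
                                    fill = .data$richness)) +
    ggplot2::geom_polygon(color = "grey30", linewidth = 0.2) +
    .fill_scale(palette) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      title = sprintf("Species richness by %s",
                      gsub("_", " ", table$level)),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(out, p, width = 8, height = 4.5, dpi = 120)
  sidecar <- paste0(sub("\\.[a-zA-Z]+$", "", out), ".csv")
  utils::write.csv(plot_data, sidecar, row.names = FALSE)
  invisible(list(files = out, unmatched = unmatched, data = plot_data))
}

#' Species-discovery accumulation series
#'
#' Cumulative count of species described up to each observed year. Two
#' date bases are supported: the publication year of the currently
#' accepted name (`"accepted_date"`), and the basionym year
#' (`"basionym_date"`, the earliest homotypic name — the actual
#' discovery date, disregarding later purely nomenclatural
#' recombinations). Species whose basis year is unknown are excluded
#' from the curve and tallied, so the end point plus the unknown tally
#' always equals the total species count.
#'
#' @param species [species_record()]s or an [as_checklist()] result.
#' @param basis `"accepted_date"` or `"basionym_date"`.
#' @return An object of class `accumulation_series`: list with `basis`,
#'   `points` (data frame `year`, `cumulative`, sorted by year),
#'   `n_unknown_year` and `n_total`.
#' @export
accumulation_series <- function(species,
                                basis = c("accepted_date",
                                          "basionym_date")) {
  basis <- match.arg(basis)
  if (inherits(species, "checklist")) species <- species$species
  years <- vapply(species, function(sp) {
    if (basis == "accepted_date") sp$accepted$year
    else basionym_year(sp)
  }, integer(1))
  known <- years[!is.na(years)]
  uy <- sort(unique(known))
  points <- data.frame(
    year = uy,
    cumulative = vapply(uy, function(y) sum(known <= y), integer(1)))
  structure(list(basis = basis, points = points,
                 n_unknown_year = sum(is.na(years)),
                 n_total = length(species)),
            class = "accumulation_series")
}

#' @export
print.accumulation_series <- function(x, ...) {
  last <- if (nrow(x$points)) x$points$cumulative[nrow(x$points)] else 0L
  cat(sprintf(
    "<accumulation_series> basis=%s, %d year(s), final count %d (+%d unknown-year)\n",
    x$basis, nrow(x$points), last, x$n_unknown_year))
  invisible(x)
}

#' Nomenclatural-change table
#'
#' One row per (accepted species, synonym) pair — plus a single row with
#' empty synonym fields for species without synonyms — pairing the
#' accepted name's year with each synonym's year and
#' homotypic/heterotypic status. An optional grouping label (`"family"`
#' or `"genus"`) is propagated for per-group plots; an unknown group
#' column raises a named error.
#'
#' @param species [species_record()]s or an [as_checklist()] result.
#' @param group_column `NULL`, `"family"` or `"genus"`.
#' @return A data frame with columns `binomial`, `accepted_year`,
#'   `synonym`, `synonym_year`, `synonym_status`, `n_synonyms` and
#'   (when grouped) `group`.
#' @export
nomenclatural_change_table <- function(species, group_column = NULL) {
  if (inherits(species, "checklist")) species <- species$species
  if (!is.null(group_column) &&
      !group_column %in% c("family", "genus")) {
    stop("nomenclatural_change_table: unknown group column '",
         group_column, "'")
  }
  rows <- lapply(species, function(sp) {
    binom <- paste(sp$accepted$genus, sp$accepted$epithet)
    grp <- if (is.null(group_column)) NULL
           else if (group_column == "family") sp$family
           else sp$accepted$genus
    n_syn <- length(sp$synonyms)
    base <- function(syn_name, syn_year, syn_status) {
      d <- data.frame(binomial = binom,
                      accepted_year = sp$accepted$year,
                      synonym = syn_name, synonym_year = syn_year,
                      synonym_status = syn_status, n_synonyms = n_syn,
                      stringsAsFactors = FALSE)
      if (!is.null(grp)) d$group <- grp
      d
    }
    if (n_syn == 0L) {
      base(NA_character_, NA_integer_, NA_character_)
    } else {
      do.call(rbind, lapply(sp$synonyms, function(syn) {
        base(paste(syn$genus, syn$epithet), syn$year,
             sub("_synonym$", "", syn$status))
      }))
    }
  })
  do.call(rbind, rows)
}

#' Render discovery-accumulation and nomenclatural-change graphics
#'
#' Writes two figures with plot-data sidecar CSVs: (a) dual
#' species-discovery accumulation curves — accepted-name basis in
#' black, basionym basis in red; the basionym curve can only run on or
#' above the accepted curve, since a basionym never postdates its
#' recombination — and (b) a per-year "violin" panel of nomenclatural
#' change: the density of synonym publication years in grey with
#' accepted names overplotted in yellow, sized by their number of
#' associated synonyms. The year axis starts at 1753 (the nomenclatural
#' origin) so cross-taxon panels align. Output is deterministic for
#' fixed inputs; the sidecar tables are the normative output, the
#' density rendering a presentation choice.
#'
#' @param accepted_series [accumulation_series()] with accepted basis.
#' @param basionym_series [accumulation_series()] with basionym basis.
#' @param change_table A [nomenclatural_change_table()].
#' @param out_prefix Path prefix; writes `<prefix>_curves.png/.csv` and
#'   `<prefix>_changes.png/.csv`.
#' @param format Image format extension (default `"png"`).
#' @return Invisibly, a list with `files` and `data` (the two sidecar
#'   tables).
#' @export
render_discovery_graph <- function(accepted_series, basionym_series,
                                   change_table, out_prefix,
                                   format = "png") {
  stopifnot(inherits(accepted_series, "accumulation_series"),
            inherits(basionym_series, "accumulation_series"))
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  curve_data <- rbind(
    cbind(accepted_series$points, basis = "accepted"),
    cbind(basionym_series$points, basis = "basionym"))
  year_max <- max(c(curve_data$year, change_table$accepted_year,
                    change_table$synonym_year, 1754), na.rm = TRUE)
  p1 <- ggplot2::ggplot(curve_data,
                        ggplot2::aes(x = .data$year,
                                     y = .data$cumulative,
                                     color = .data$basis)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_color_manual(
      values = c(accepted = "black", basionym = "red")) +
    ggplot2::coord_cartesian(xlim = c(1753, year_max)) +
    ggplot2::labs(x = "Year", y = "Cumulative accepted species",
                  color = "Date basis",
                  title = "Species-discovery accumulation") +
    ggplot2::theme_minimal()
  f1 <- paste0(out_prefix, "_curves.", format)
  ggplot2::ggsave(f1, p1, width = 7, height = 4.5, dpi = 120)
  s1 <- paste0(out_prefix, "_curves.csv")
  utils::write.csv(curve_data, s1, row.names = FALSE)

  ct <- change_table
  if (is.null(ct$group)) ct$group <- "all"
  acc <- unique(ct[, c("binomial", "accepted_year", "n_synonyms",
                       "group")])
  syn <- ct[!is.na(ct$synonym_year), , drop = FALSE]
  p2 <- ggplot2::ggplot(acc, ggplot2::aes(x = .data$group,
                                          y = .data$accepted_year))
  if (nrow(syn) >= 2L && length(unique(syn$synonym_year)) > 1L) {
    p2 <- p2 + ggplot2::geom_violin(
      data = syn,
      ggplot2::aes(x = .data$group, y = .data$synonym_year),
      fill = "grey60", color = "grey40", alpha = 0.6)
  } else if (nrow(syn) >= 1L) {
    p2 <- p2 + ggplot2::geom_point(
      data = syn,
      ggplot2::aes(x = .data$group, y = .data$synonym_year),
      color = "grey50", size = 1.5)
  }
  p2 <- p2 +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_synonyms),
                        color = "goldenrod2", alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::coord_cartesian(ylim = c(1753, year_max)) +
    ggplot2::labs(x = NULL, y = "Publication year",
                  size = "Synonyms",
                  title = "Nomenclatural changes over time") +
    ggplot2::theme_minimal()
  f2 <- paste0(out_prefix, "_changes.", format)
  ggplot2::ggsave(f2, p2, width = 7, height = 4.5, dpi = 120)
  s2 <- paste0(out_prefix, "_changes.csv")
  utils::write.csv(change_table, s2, row.names = FALSE)

  invisible(list(files = c(f1, f2),
                 data = list(curves = curve_data,
                             changes = change_table)))
}
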