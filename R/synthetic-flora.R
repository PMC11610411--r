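# Seeded synthetic floras with known ground truth, renderable as a
# static POWO-style site. The generator is the test bed for the whole
# crawl -> parse -> analyse pipeline: whatever the miner recovers can be
# compared field-for-field against the flora it was rendered from.

.syllables <- c("al", "be", "cor", "del", "eri", "fol", "gal", "hel",
                "ix", "jun", "kal", "lun", "mor", "nix", "oro", "pex",
                "qua", "rul", "sil", "tam", "ul", "vex", "wil", "xan",
                "yar", "zel")
.genus_endings <- c("ia", "us", "um", "era", "opsis", "anthus", "ella")
.epithet_endings <- c("ensis", "oides", "iana", "ula", "atum", "iflora",
                      "icola", "ifolius")
.family_endings <- "aceae"
.authors <- c("L.", "Kunth", "Mart.", "Benth.", "DC.", "Hook.f.",
              "Baker", "Ruiz & Pav.", "Sw.", "Aubl.", "Willd.", "Vell.",
              "Radlk.", "Standl.", "(L.) Druce", "Miq.")
.journals <- c("Sp. Pl.", "Gen. Pl.", "Fl. Bras.", "Prodr.",
               "Syst. Veg.", "Bull. Misc. Inform. Kew",
               "J. Bot.", "Novon", "Kew Bull.", "Phytotaxa")

.make_word <- function(n_syl, ending) {
  w <- paste0(paste(sample(.syllables, n_syl, replace = TRUE),
                    collapse = ""), ending)
  w
}

.fresh_name <- function(seen, n_syl_range, endings, capitalize = FALSE) {
  repeat {
    w <- .make_word(sample(n_syl_range[1]:n_syl_range[2], 1),
                    sample(endings, 1))
    if (capitalize) {
      w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }
    if (!(w %in% seen)) return(w)
  }
}

.make_protologue <- function(year) {
  sprintf("%s %d: %d (%d)", sample(.journals, 1),
          sample(1:60, 1), sample(1:900, 1), year)
}

# sample(x, 1) on a length-1 numeric x draws from 1:x; .pick avoids that
.pick <- function(v) if (length(v) == 1L) v else sample(v, 1)

.sample_count <- function(range) {
  if (length(range) == 1L) range <- c(range, range)
  .pick(range[1]:range[2])
}

#' Specify a synthetic flora
#'
#' Parameters of the synthetic-checklist generator. Counts are drawn
#' uniformly from inclusive `c(min, max)` ranges. Defaults describe a
#' modest tropical family set: a few families with a handful of genera
#' each, genus sizes from monotypic up to a few dozen species, most
#' species carrying up to a few synonyms, a small fraction of species
#' with no published distribution, and an occasional introduced range.
#'
#' @param n_families Number of families.
#' @param genera_per_family Range `c(min, max)` of genera per family.
#' @param species_per_genus Range of accepted species per genus.
#' @param synonyms_per_species Range of synonyms per species.
#' @param homotypic_fraction Probability a synonym is homotypic.
#' @param year_range Publication-year window, within \[1753, current\].
#' @param region_pool Botanical-country names to draw ranges from;
#'   defaults to the bundled WGSRPD level-3 mapping table.
#' @param p_unknown_distribution Probability a species has no
#'   distribution information at all.
#' @param p_introduced Probability a species also has introduced regions.
#' @param seed Integer seed; the generator's only source of randomness.
#' @return An object of class `flora_spec`.
#' @export
flora_spec <- function(n_families = 3,
                       genera_per_family = c(2, 6),
                       species_per_genus = c(1, 20),
                       synonyms_per_species = c(0, 4),
                       homotypic_fraction = 0.4,
                       year_range = c(1753, 2022),
                       region_pool = NULL,
                       p_unknown_distribution = 0.05,
                       p_introduced = 0.15,
                       seed = 1L) {
  if (is.null(region_pool)) {
    region_pool <- unique(load_mapping()$entries$botanical_country)
  }
  spec <- structure(
    list(n_families = as.integer(n_families),
         genera_per_family = as.integer(genera_per_family),
         species_per_genus = as.integer(species_per_genus),
         synonyms_per_species = as.integer(synonyms_per_species),
         homotypic_fraction = homotypic_fraction,
         year_range = as.integer(year_range),
         region_pool = as.character(region_pool),
         p_unknown_distribution = p_unknown_distribution,
         p_introduced = p_introduced,
         seed = as.integer(seed)),
    class = "flora_spec")
  probs <- c(spec$homotypic_fraction, spec$p_unknown_distribution,
             spec$p_introduced)
  if (any(probs < 0 | probs > 1)) {
    stop("flora_spec: probabilities must lie in [0, 1]")
  }
  if (spec$year_range[1] < 1753L || spec$year_range[2] > .year_max() ||
      spec$year_range[1] > spec$year_range[2]) {
    stop("flora_spec: year_range must lie within [1753, ",
         .year_max(), "]")
  }
  if (length(spec$region_pool) == 0L) {
    stop("flora_spec: region_pool must be non-empty")
  }
  if (spec$n_families < 1L) stop("flora_spec: n_families must be >= 1")
  spec
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic flora
#'
#' Builds a ground-truth checklist under the statistical structure of a
#' [flora_spec()]: families of genera of accepted species, each species
#' with synonyms, publication years and botanical-country ranges. Name
#' strings are synthesized from syllable templates and are unique within
#' the flora, so round-trip comparisons are collision-free. Homotypic
#' synonyms are always dated no later than their accepted name, because
#' a basionym precedes its recombination. Deterministic for a fixed
#' seed.
#'
#' @param spec A [flora_spec()].
#' @return An object of class `synthetic_flora`: list with `species`
#'   (list of [species_record()]), `genus_index` (list of
#'   [genus_summary()]), `family_names`, `genus_families` (named vector
#'   genus -> family), `dialect` (markup version tag) and `spec`.
#' @examples
#' fl <- generate_flora(flora_spec(n_families = 1, seed = 42))
#' length(fl$species)
#' @export
generate_flora <- function(spec) {
  if (!inherits(spec, "flora_spec")) {
    stop("generate_flora: `spec` must be a flora_spec object")
  }
  .with_seed(spec$seed, {
    seen_genera <- character()
    seen_binomials <- character()
    species <- list()
    genus_index <- list()
    family_names <- character()
    genus_families <- character()
    id_counter <- 0L
    next_id <- function(prefix) {
      id_counter <<- id_counter + 1L
      sprintf("%s-%06d", prefix, id_counter)
    }
    for (f in seq_len(spec$n_families)) {
      fam <- .fresh_name(family_names, c(2, 3), .family_endings,
                         capitalize = TRUE)
      family_names <- c(family_names, fam)
      n_gen <- .sample_count(spec$genera_per_family)
      for (g in seq_len(n_gen)) {
        gen <- .fresh_name(seen_genera, c(2, 3), .genus_endings,
                           capitalize = TRUE)
        seen_genera <- c(seen_genera, gen)
        gen_id <- next_id("gen")
        gen_year <- .pick(spec$year_range[1]:spec$year_range[2])
        gsum <- genus_summary(
          genus = gen, authorship = sample(.authors, 1),
          protologue = .make_protologue(gen_year),
          species_count = 0L, record_id = gen_id,
          uri = file.path("genus", paste0(gen_id, ".html")))
        n_sp <- .sample_count(spec$species_per_genus)
        for (s in seq_len(n_sp)) {
          repeat {
            epi <- .fresh_name(character(), c(2, 3), .epithet_endings)
            if (!(paste(gen, epi) %in% seen_binomials)) break
          }
          seen_binomials <- c(seen_binomials, paste(gen, epi))
          sp_id <- next_id("sp")
          acc_year <- .pick(spec$year_range[1]:spec$year_range[2])
          acc <- name_record(
            genus = gen, epithet = epi,
            authorship = sample(.authors, 1),
            protologue = .make_protologue(acc_year),
            status = "accepted", record_id = sp_id,
            uri = file.path("species", paste0(sp_id, ".html")))
          n_syn <- .sample_count(spec$synonyms_per_species)
          syns <- list()
          if (n_syn > 0) {
            for (k in seq_len(n_syn)) {
              homotypic <- stats::runif(1) < spec$homotypic_fraction
              syn_year <- if (homotypic) {
                .pick(spec$year_range[1]:acc_year)
              } else {
                .pick(spec$year_range[1]:spec$year_range[2])
              }
              repeat {
                sg <- .fresh_name(character(), c(2, 3), .genus_endings,
                                  capitalize = TRUE)
                se <- .fresh_name(character(), c(2, 3), .epithet_endings)
                if (!(paste(sg, se) %in% seen_binomials)) break
              }
              seen_binomials <- c(seen_binomials, paste(sg, se))
              syns[[k]] <- name_record(
                genus = sg, epithet = se,
                authorship = sample(.authors, 1),
                protologue = .make_protologue(syn_year),
                status = if (homotypic) "homotypic_synonym"
                         else "heterotypic_synonym",
                record_id = next_id("syn"), uri = acc$uri)
            }
          }
          unknown <- stats::runif(1) < spec$p_unknown_distribution
          if (unknown) {
            dist <- distribution()
          } else {
            n_nat <- sample(1:min(5, length(spec$region_pool)), 1)
            native <- sample(spec$region_pool, n_nat)
            intro <- character()
            if (stats::runif(1) < spec$p_introduced) {
              remaining <- setdiff(spec$region_pool, native)
              if (length(remaining)) {
                intro <- sample(remaining,
                                sample(1:min(2, length(remaining)), 1))
              }
            }
            dist <- distribution(native, intro)
          }
          species[[length(species) + 1L]] <-
            species_record(acc, syns, dist, family = fam)
          gsum$species_count <- gsum$species_count + 1L
        }
        genus_index[[length(genus_index) + 1L]] <- gsum
        genus_families[gen] <- fam
      }
    }
    structure(
      list(species = species, genus_index = genus_index,
           family_names = family_names, genus_families = genus_families,
           site_manifest = NULL, dialect = "v1", spec = spec),
      class = "synthetic_flora")
  })
}

#' @export
print.synthetic_flora <- function(x, ...) {
  cat(sprintf(
    "<synthetic_flora> %d species in %d genera, %d family/families%s\n",
    length(x$species), length(x$genus_index), length(x$family_names),
    if (is.null(x$site_manifest)) "" else " (site rendered)"))
  invisible(x)
}

#' A small fixed demonstration flora
#'
#' Four accepted species in two genera (Alpha: unus, duo, tres; Beta:
#' quattuor) of one family (Demoaceae), with hand-picked years,
#' synonyms and ranges exercising every rule of the data model: a
#' basionym shifting *Alpha duo* from 1850 back to 1801, an
#' unknown-distribution species (*Alpha tres*), a multi-country
#' botanical region (Borneo) and an introduced range (Madagascar).
#' Used throughout examples and tests.
#'
#' @return A `synthetic_flora` object with 4 species.
#' @examples
#' fl <- demo_flora()
#' vapply(fl$species, function(s) s$accepted$epithet, "")
#' @export
demo_flora <- function() {
  mk_uri <- function(kind, id) file.path(kind, paste0(id, ".html"))
  sp <- list(
    species_record(
      name_record("Alpha", "unus", "L.", "Sp. Pl.: 12 (1753)",
                  status = "accepted", record_id = "sp-000001",
                  uri = mk_uri("species", "sp-000001")),
      list(),
      distribution(native_botanical = "Borneo"),
      family = "Demoaceae"),
    species_record(
      name_record("Alpha", "duo", "Benth.", "Gen. Pl. 3: 101 (1850)",
                  status = "accepted", record_id = "sp-000002",
                  uri = mk_uri("species", "sp-000002")),
      list(
        name_record("Gamma", "duo", "Ruiz & Pav.",
                    "Syst. Veg. 1: 44 (1801)",
                    status = "homotypic_synonym",
                    record_id = "syn-000001",
                    uri = mk_uri("species", "sp-000002")),
        name_record("Delta", "falsum", "DC.", "Prodr. 7: 9 (1838)",
                    status = "heterotypic_synonym",
                    record_id = "syn-000002",
                    uri = mk_uri("species", "sp-000002"))),
      distribution(native_botanical = "Peru"),
      family = "Demoaceae"),
    species_record(
      name_record("Alpha", "tres", "Mart.", "Fl. Bras. 2(2): 44 (1820)",
                  status = "accepted", record_id = "sp-000003",
                  uri = mk_uri("species", "sp-000003")),
      list(),
      distribution(),
      family = "Demoaceae"),
    species_record(
      name_record("Beta", "quattuor", "Baker",
                  "Bull. Misc. Inform. Kew 1900: 5 (1900)",
                  status = "accepted", record_id = "sp-000004",
                  uri = mk_uri("species", "sp-000004")),
      list(),
      distribution(native_botanical = c("Borneo", "Peru"),
                   introduced_botanical = "Madagascar"),
      family = "Demoaceae"),
  NULL)
  sp <- sp[!vapply(sp, is.null, logical(1))]
  gidx <- list(
    genus_summary("Alpha", "L.", "Gen. Pl.: 5 (1753)", 3L,
                  "gen-000001", mk_uri("genus", "gen-000001")),
    genus_summary("Beta", "Kunth", "Syst. Veg. 2: 12 (1817)", 1L,
                  "gen-000002", mk_uri("genus", "gen-000002")))
  structure(
    list(species = sp, genus_index = gidx,
         family_names = "Demoaceae",
         genus_families = c(Alpha = "Demoaceae", Beta = "Demoaceae"),
         site_manifest = NULL, dialect = "v1",
         spec = NULL),
    class = "synthetic_flora")
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.page_shell <- function(title, body, dialect) {
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    sprintf("<meta name=\"checklist-dialect\" content=\"%s\"/>\n",
            dialect),
    sprintf("<title>%s</title>\n</head>\n<body>\n", .html_escape(title)),
    body, "\n</body>\n</html>\n")
}

.render_species_page <- function(sp, dialect) {
  acc <- sp$accepted
  body <- sprintf(
    paste0("<h1 class=\"taxon-name\" data-rank=\"species\" ",
           "data-record-id=\"%s\" data-family=\"%s\">",
           "<i class=\"genus\">%s</i> <i class=\"epithet\">%s</i> ",
           "<span class=\"authorship\">%s</span></h1>\n",
           "<p class=\"protologue\">%s</p>\n"),
    .html_escape(acc$record_id), .html_escape(sp$family),
    .html_escape(acc$genus), .html_escape(acc$epithet),
    .html_escape(acc$authorship), .html_escape(acc$protologue))
  if (!sp$distribution$is_unknown) {
    items <- function(v) paste(sprintf("<li>%s</li>", .html_escape(v)),
                               collapse = "\n")
    dist <- "<div class=\"distribution\">\n"
    if (length(sp$distribution$native_botanical)) {
      dist <- paste0(dist, "<h2>Native to:</h2>\n<ul class=\"native\">\n",
                     items(sp$distribution$native_botanical), "\n</ul>\n")
    }
    if (length(sp$distribution$introduced_botanical)) {
      dist <- paste0(dist,
                     "<h2>Introduced into:</h2>\n<ul class=\"introduced\">\n",
                     items(sp$distribution$introduced_botanical),
                     "\n</ul>\n")
    }
    body <- paste0(body, dist, "</div>\n")
  }
  if (length(sp$synonyms)) {
    rows <- vapply(sp$synonyms, function(syn) {
      cls <- if (identical(syn$status, "homotypic_synonym")) {
        "homotypic"
      } else {
        "heterotypic"
      }
      sprintf(
        paste0("<li class=\"synonym %s\" data-record-id=\"%s\">",
               "<i class=\"genus\">%s</i> <i class=\"epithet\">%s</i> ",
               "<span class=\"authorship\">%s</span> ",
               "<span class=\"protologue\">%s</span></li>"),
        cls, .html_escape(syn$record_id), .html_escape(syn$genus),
        .html_escape(syn$epithet), .html_escape(syn$authorship),
        .html_escape(syn$protologue))
    }, character(1))
    body <- paste0(body, "<div class=\"synonyms\">\n<ul>\n",
                   paste(rows, collapse = "\n"), "\n</ul>\n</div>\n")
  }
  .page_shell(paste(acc$genus, acc$epithet), body, dialect)
}

.render_genus_page <- function(gsum, fam, species_in_genus, dialect) {
  body <- sprintf(
    paste0("<h1 class=\"taxon-name\" data-rank=\"genus\" ",
           "data-record-id=\"%s\" data-family=\"%s\">",
           "<i class=\"genus\">%s</i> ",
           "<span class=\"authorship\">%s</span></h1>\n",
           "<p class=\"protologue\">%s</p>\n"),
    .html_escape(gsum$record_id), .html_escape(fam),
    .html_escape(gsum$genus), .html_escape(gsum$authorship),
    .html_escape(gsum$protologue))
  rows <- vapply(species_in_genus, function(sp) {
    sprintf(
      paste0("<li><a class=\"species-link\" data-record-id=\"%s\" ",
             "href=\"../%s\"><i>%s %s</i></a></li>"),
      .html_escape(sp$accepted$record_id), sp$accepted$uri,
      .html_escape(sp$accepted$genus), .html_escape(sp$accepted$epithet))
  }, character(1))
  body <- paste0(body, "<ul class=\"species-list\">\n",
                 paste(rows, collapse = "\n"),
                 if (length(rows)) "\n" else "", "</ul>\n")
  .page_shell(gsum$genus, body, dialect)
}

.render_family_page <- function(fam, fam_id, genera, dialect) {
  body <- sprintf(
    paste0("<h1 class=\"taxon-name\" data-rank=\"family\" ",
           "data-record-id=\"%s\">%s</h1>\n"),
    .html_escape(fam_id), .html_escape(fam))
  rows <- vapply(genera, function(g) {
    sprintf(
      paste0("<li><a class=\"genus-link\" data-record-id=\"%s\" ",
             "href=\"../%s\">%s</a></li>"),
      .html_escape(g$record_id), g$uri, .html_escape(g$genus))
  }, character(1))
  body <- paste0(body, "<ul class=\"genus-list\">\n",
                 paste(rows, collapse = "\n"),
                 if (length(rows)) "\n" else "", "</ul>\n")
  .page_shell(fam, body, dialect)
}

#' Render a flora as a static POWO-style site
#'
#' Writes one HTML page per taxon under `out_dir`: a family page linking
#' its genus pages, a genus page per genus (name header, protologue,
#' species links), and a species page per species (accepted name with
#' authorship, protologue, native/introduced botanical-country lists,
#' and a synonym section tagging each synonym homotypic or heterotypic).
#' A species with unknown distribution gets no distribution section at
#' all — the rule the parser's unknown flag relies on. Page markup
#' carries a dialect tag (`<meta name="checklist-dialect">`) matching
#' the parser's selector table.
#'
#' @param flora A `synthetic_flora` (from [generate_flora()] or
#'   [demo_flora()]).
#' @param out_dir Writable output directory (created if absent).
#' @return The flora with `$site_manifest` set: a data frame with
#'   columns `taxon`, `rank`, `record_id`, `path` (relative to
#'   `out_dir`).
#' @export
render_site <- function(flora, out_dir) {
  stopifnot(inherits(flora, "synthetic_flora"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("render_site: cannot create output directory ", out_dir)
  }
  for (d in c("family", "genus", "species")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  manifest <- list()
  add <- function(taxon, rank, record_id, path) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(taxon = taxon, rank = rank, record_id = record_id,
                 path = path, stringsAsFactors = FALSE)
  }
  genus_of <- vapply(flora$species, function(s) s$accepted$genus, "")
  for (fi in seq_along(flora$family_names)) {
    fam <- flora$family_names[fi]
    fam_id <- sprintf("fam-%06d", fi)
    genera <- Filter(function(g) flora$genus_families[[g$genus]] == fam,
                     flora$genus_index)
    path <- file.path("family", paste0(fam_id, ".html"))
    writeLines(.render_family_page(fam, fam_id, genera, flora$dialect),
               file.path(out_dir, path), useBytes = TRUE)
    add(fam, "family", fam_id, path)
    for (g in genera) {
      spp <- flora$species[genus_of == g$genus]
      writeLines(.render_genus_page(g, fam, spp, flora$dialect),
                 file.path(out_dir, g$uri), useBytes = TRUE)
      add(g$genus, "genus", g$record_id, g$uri)
      for (sp in spp) {
        writeLines(.render_species_page(sp, flora$dialect),
                   file.path(out_dir, sp$accepted$uri), useBytes = TRUE)
        add(paste(sp$accepted$genus, sp$accepted$epithet), "species",
            sp$accepted$record_id, sp$accepted$uri)
      }
    }
  }
  flora$site_manifest <- do.call(rbind, manifest)
  flora
}

.gt_columns <- c("family", "genus", "epithet", "authorship", "protologue",
                 "year", "status", "record_id", "uri",
                 "accepted_genus", "accepted_epithet",
                 "native_botanical", "introduced_botanical", "is_unknown")

#' Tabulate a flora's names (ground truth)
#'
#' One row per published name — accepted names and synonyms alike — with
#' every name and distribution field. Synonym rows point back to their
#' accepted binomial via `accepted_genus`/`accepted_epithet`.
#' Multi-value region cells are joined with `"|"`.
#'
#' @param flora A `synthetic_flora`, or a plain list of
#'   [species_record()]s.
#' @return A data frame with columns `family, genus, epithet,
#'   authorship, protologue, year, status, record_id, uri,
#'   accepted_genus, accepted_epithet, native_botanical,
#'   introduced_botanical, is_unknown`.
#' @export
ground_truth_table <- function(flora) {
  species <- if (inherits(flora, "synthetic_flora")) flora$species
             else flora
  rows <- list()
  for (sp in species) {
    acc <- sp$accepted
    rows[[length(rows) + 1L]] <- data.frame(
      family = sp$family, genus = acc$genus, epithet = acc$epithet,
      authorship = acc$authorship, protologue = acc$protologue,
      year = acc$year, status = acc$status, record_id = acc$record_id,
      uri = acc$uri, accepted_genus = acc$genus,
      accepted_epithet = acc$epithet,
      native_botanical = paste(sp$distribution$native_botanical,
                               collapse = "|"),
      introduced_botanical = paste(sp$distribution$introduced_botanical,
                                   collapse = "|"),
      is_unknown = sp$distribution$is_unknown,
      stringsAsFactors = FALSE)
    for (syn in sp$synonyms) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = sp$family, genus = syn$genus, epithet = syn$epithet,
        authorship = syn$authorship, protologue = syn$protologue,
        year = syn$year, status = syn$status, record_id = syn$record_id,
        uri = syn$uri, accepted_genus = acc$genus,
        accepted_epithet = acc$epithet,
        native_botanical = "", introduced_botanical = "",
        is_unknown = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(.gt_columns)))
    names(out) <- .gt_columns
    return(out)
  }
  do.call(rbind, rows)
}

#' Export a flora's ground truth to CSV
#'
#' Writes the [ground_truth_table()] as a UTF-8 comma-separated file
#' with a header row. [read_ground_truth()] reconstructs the flora
#' exactly from it.
#'
#' @param flora A `synthetic_flora`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(flora, path) {
  tab <- ground_truth_table(flora)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!file.exists(path)) stop("export_ground_truth: failed to write ", path)
  invisible(path)
}

.split_bar <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|",
                                                        fixed = TRUE)[[1]]
}

#' Read a ground-truth CSV back into a flora
#'
#' Inverse of [export_ground_truth()]: rebuilds the species records
#' (with synonyms reattached to their accepted names) and recomputes the
#' genus index from the accepted rows.
#'
#' @param path Path to a ground-truth CSV.
#' @return A `synthetic_flora` object (without a site manifest).
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         encoding = "UTF-8",
                         colClasses = c(year = "integer"))
  missing <- setdiff(.gt_columns, names(tab))
  if (length(missing)) {
    stop("ground-truth file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  acc_rows <- tab[tab$status == "accepted", , drop = FALSE]
  species <- list()
  for (i in seq_len(nrow(acc_rows))) {
    r <- acc_rows[i, ]
    syn_rows <- tab[tab$status != "accepted" &
                      tab$accepted_genus == r$genus &
                      tab$accepted_epithet == r$epithet, , drop = FALSE]
    syns <- lapply(seq_len(nrow(syn_rows)), function(j) {
      s <- syn_rows[j, ]
      name_record(s$genus, s$epithet, s$authorship, s$protologue,
                  year = s$year, status = s$status,
                  record_id = s$record_id, uri = s$uri)
    })
    species[[i]] <- species_record(
      name_record(r$genus, r$epithet, r$authorship, r$protologue,
                  year = r$year, status = "accepted",
                  record_id = r$record_id, uri = r$uri),
      syns,
      distribution(.split_bar(r$native_botanical),
                   .split_bar(r$introduced_botanical)),
      family = r$family)
  }
  fam_of_genus <- tapply(acc_rows$family, acc_rows$genus,
                         function(x) x[1])
  genus_names <- names(fam_of_genus)
  genus_index <- lapply(seq_along(genus_names), function(i) {
    g <- genus_names[i]
    genus_summary(g, species_count =
                    sum(acc_rows$genus == g),
                  record_id = sprintf("gen-%06d", i),
                  uri = file.path("genus",
                                  sprintf("gen-%06d.html", i)))
  })
  structure(
    list(species = species, genus_index = genus_index,
         family_names = unique(acc_rows$family),
         genus_families = stats::setNames(as.character(fam_of_genus),
                                          genus_names),
         site_manifest = NULL, dialect = "v1", spec = NULL),
    class = "synthetic_flora")
}
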