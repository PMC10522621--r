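#' @keywords internal
"_PACKAGE"

## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies for stomach-content data
#'
#' Character vectors of admissible values for the categorical fields of the
#' stomach-content data model.
#'
#' @format
#' * `predator_species_default`: the three predator species covered by the
#'   default catalog and generator. The vocabulary is extensible: readers
#'   accept any species listed in `schema$species_vocabulary`.
#' * `taxon_ranks`: admissible taxonomic ranks for prey identifications.
#' * `prey_classes`: broad prey types used for prey-type rollups.
#' * `length_types`: length conventions (standard length for fishes, mantle
#'   length for cephalopods, total length for crustaceans).
#' * `coarse_groups`: non-family prey categories that are treated as
#'   family-level analysis units because they are mutually exclusive with all
#'   true families (one superfamily of hyperiid amphipods, crustacean
#'   megalopa, fish leptocephali, and ceratioid anglerfishes).
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
predator_species_default <- c(
  "Alepisaurus ferox", "Anoplogaster cornuta", "Omosudis lowii"
)

#' @rdname vocabularies
#' @export
taxon_ranks <- c(
  "species", "genus", "family", "superfamily", "suborder",
  "order", "class", "other"
)

#' @rdname vocabularies
#' @export
prey_classes <- c("fish", "mollusk", "crustacean", "other")

#' @rdname vocabularies
#' @export
length_types <- c("SL", "ML", "TL")

#' @rdname vocabularies
#' @export
coarse_groups <- c("Platysceloidea", "megalopa", "leptocephali", "Ceratioidei")

## Constructors ---------------------------------------------------------------

#' Construct a stomach (predator specimen) table
#'
#' One row per predator specimen. Predator mass is derived as
#' `whole_mass_g - stomach_content_mass_g` when a whole mass is present and no
#' explicit predator mass is supplied; an explicit `predator_mass_g` column
#' always takes precedence. A negative derived mass is set to `NA` and
#' flagged, never clamped to zero.
#'
#' @param specimen_id character identifiers, unique.
#' @param predator_species species names; checked against `species_vocabulary`.
#' @param standard_length_mm standard length in mm (`NA` allowed).
#' @param stomach_content_mass_g total stomach content mass in g.
#' @param whole_mass_g whole specimen mass in g (optional).
#' @param predator_mass_g explicit predator mass in g (optional; overrides the
#'   derived value).
#' @param fork_length_cm fork length in cm (optional).
#' @param capture_date ISO-8601 dates (optional).
#' @param latitude,longitude decimal degrees, west-negative (optional).
#' @param source `"direct"` (caught on the gear) or `"secondary"` (recovered
#'   from a primary predator's stomach).
#' @param species_vocabulary admissible species names.
#' @return A `data.frame` of class `stomach_table` with a
#'   `derived_mass_flagged` attribute listing specimens whose derived predator
#'   mass was negative.
#' @export
stomach_table <- function(specimen_id, predator_species,
                          standard_length_mm = NA_real_,
                          stomach_content_mass_g = 0,
                          whole_mass_g = NA_real_,
                          predator_mass_g = NA_real_,
                          fork_length_cm = NA_real_,
                          capture_date = NA_character_,
                          latitude = NA_real_, longitude = NA_real_,
                          source = "secondary",
                          species_vocabulary = predator_species_default) {
  n <- length(specimen_id)
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    predator_species = as.character(predator_species),
    standard_length_mm = rep_len(as.numeric(standard_length_mm), n),
    fork_length_cm = rep_len(as.numeric(fork_length_cm), n),
    whole_mass_g = rep_len(as.numeric(whole_mass_g), n),
    stomach_content_mass_g = rep_len(as.numeric(stomach_content_mass_g), n),
    predator_mass_g = rep_len(as.numeric(predator_mass_g), n),
    capture_date = rep_len(as.character(capture_date), n),
    latitude = rep_len(as.numeric(latitude), n),
    longitude = rep_len(as.numeric(longitude), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  derive <- is.na(df$predator_mass_g) & !is.na(df$whole_mass_g)
  df$predator_mass_g[derive] <-
    df$whole_mass_g[derive] - df$stomach_content_mass_g[derive]
  neg <- !is.na(df$predator_mass_g) & df$predator_mass_g < 0
  flagged <- df$specimen_id[neg & derive]
  df$predator_mass_g[neg & derive] <- NA_real_
  if (any(neg & !derive)) {
    stop("negative predator_mass_g supplied for: ",
         paste(df$specimen_id[neg & !derive], collapse = ", "))
  }
  validate_stomach_table(df, species_vocabulary)
  attr(df, "derived_mass_flagged") <- flagged
  class(df) <- c("stomach_table", class(df))
  df
}

validate_stomach_table <- function(df, species_vocabulary) {
  if (anyDuplicated(df$specimen_id)) {
    stop("duplicate specimen_id: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
               collapse = ", "))
  }
  bad_sp <- setdiff(unique(df$predator_species), species_vocabulary)
  if (length(bad_sp)) {
    stop("predator_species outside vocabulary: ",
         paste(bad_sp, collapse = ", "))
  }
  if (any(df$stomach_content_mass_g < 0, na.rm = TRUE)) {
    stop("stomach_content_mass_g must be >= 0")
  }
  if (any(df$standard_length_mm <= 0, na.rm = TRUE)) {
    stop("standard_length_mm must be > 0 when present")
  }
  invisible(df)
}

#' Construct a prey-group table
#'
#' One row per prey group: all individuals of one taxon at one digestion
#' state within a single stomach. Per-individual measurements are carried as
#' a list column of data frames with columns `mass_g`, `length_mm`,
#' `length_type`.
#'
#' @param specimen_id foreign keys into a stomach table.
#' @param taxon prey taxon name.
#' @param rank taxonomic rank of the identification (see [taxon_ranks]).
#' @param prey_class broad prey type (see [prey_classes]).
#' @param digestion_state integer 1 (intact) to 4 (heavily digested).
#' @param count number of individuals in the group (>= 1).
#' @param total_mass_g total wet mass of the group in g (> 0).
#' @param measurements either a list of data frames (one per row, possibly
#'   zero-row) or `NULL` for no measurements anywhere.
#' @param mass_tolerance measured masses may sum to at most
#'   `total_mass_g * (1 + mass_tolerance)`.
#' @return A `data.frame` of class `prey_table`.
#' @export
prey_table <- function(specimen_id, taxon, rank = "species",
                       prey_class = "fish", digestion_state = 1L,
                       count = 1L, total_mass_g = 1,
                       measurements = NULL, mass_tolerance = 0.05) {
  n <- length(specimen_id)
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    taxon = as.character(taxon),
    rank = rep_len(as.character(rank), n),
    prey_class = rep_len(as.character(prey_class), n),
    digestion_state = rep_len(as.integer(digestion_state), n),
    count = rep_len(as.integer(count), n),
    total_mass_g = rep_len(as.numeric(total_mass_g), n),
    stringsAsFactors = FALSE
  )
  if (is.null(measurements)) {
    measurements <- rep(list(empty_measurements()), n)
  }
  stopifnot(length(measurements) == n)
  df$measurements <- lapply(measurements, as_measurements)
  validate_prey_table(df, mass_tolerance = mass_tolerance)
  class(df) <- c("prey_table", class(df))
  df
}

empty_measurements <- function() {
  data.frame(mass_g = numeric(0), length_mm = numeric(0),
             length_type = character(0), stringsAsFactors = FALSE)
}

as_measurements <- function(m) {
  if (is.null(m) || (is.data.frame(m) && nrow(m) == 0)) {
    return(empty_measurements())
  }
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  if (is.null(m$length_mm)) m$length_mm <- NA_real_
  if (is.null(m$length_type)) m$length_type <- NA_character_
  m[, c("mass_g", "length_mm", "length_type")]
}

validate_prey_table <- function(df, mass_tolerance = 0.05) {
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    row_bad <- character(0)
    if (is.na(df$digestion_state[i]) || df$digestion_state[i] < 1L ||
        df$digestion_state[i] > 4L) {
      row_bad <- c(row_bad, "digestion_state outside 1-4")
    }
    if (is.na(df$count[i]) || df$count[i] < 1L) {
      row_bad <- c(row_bad, "count < 1")
    }
    if (is.na(df$total_mass_g[i]) || df$total_mass_g[i] <= 0) {
      row_bad <- c(row_bad, "total_mass_g <= 0")
    }
    if (!df$rank[i] %in% taxon_ranks) {
      row_bad <- c(row_bad, "unknown rank")
    }
    if (!df$prey_class[i] %in% prey_classes) {
      row_bad <- c(row_bad, "unknown prey_class")
    }
    m <- df$measurements[[i]]
    if (nrow(m)) {
      if (nrow(m) > df$count[i]) {
        row_bad <- c(row_bad, "more measurements than individuals")
      }
      if (any(m$mass_g <= 0, na.rm = TRUE)) {
        row_bad <- c(row_bad, "measured mass <= 0")
      }
      if (sum(m$mass_g, na.rm = TRUE) >
          df$total_mass_g[i] * (1 + mass_tolerance)) {
        row_bad <- c(row_bad, "measured masses exceed group total")
      }
    }
    if (length(row_bad)) {
      problems <- c(problems,
                    sprintf("row %d (%s): %s", i, df$taxon[i],
                            paste(row_bad, collapse = "; ")))
    }
  }
  if (length(problems)) {
    stop("invalid prey groups:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(df)
}

## Canonical CSV I/O ----------------------------------------------------------

canonical_stomach_cols <- c(
  "specimen_id", "predator_species", "standard_length_mm", "fork_length_cm",
  "whole_mass_g", "stomach_content_mass_g", "predator_mass_g",
  "capture_date", "latitude", "longitude", "source"
)
canonical_prey_cols <- c(
  "specimen_id", "taxon", "rank", "prey_class", "digestion_state",
  "count", "total_mass_g", "measurements"
)

pack_measurements <- function(m) {
  if (nrow(m) == 0) return("")
  paste(sprintf("%s:%s:%s",
                format(m$mass_g, trim = TRUE, digits = 15),
                ifelse(is.na(m$length_mm), "",
                       format(m$length_mm, trim = TRUE, digits = 15)),
                ifelse(is.na(m$length_type), "", m$length_type)),
        collapse = ";")
}

unpack_measurements <- function(s) {
  if (is.na(s) || !nzchar(s)) return(empty_measurements())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(
    mass_g = vapply(parts, function(p) as.numeric(p[1]), 0),
    length_mm = vapply(parts, function(p) {
      if (length(p) < 2 || !nzchar(p[2])) NA_real_ else as.numeric(p[2])
    }, 0),
    length_type = vapply(parts, function(p) {
      if (length(p) < 3 || !nzchar(p[3])) NA_character_ else p[3]
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Read a stomach-content dataset from canonical CSV files
#'
#' Reads a specimen table and a prey-group table in the package's canonical
#' long format (one prey group per row; per-individual measurements packed in
#' a `mass:length:type;...` sub-field) and returns validated tables. Column
#' names can be remapped through `schema`, a named character vector
#' `c(canonical_name = "actual_name", ...)`, so external layouts can be
#' adapted without editing files.
#'
#' Stomachs with no prey rows are retained as empty stomachs.
#'
#' @param stomach_path CSV with one row per predator specimen.
#' @param prey_path CSV with one row per prey group; may be `NULL` for a
#'   specimen-only dataset.
#' @param schema optional named character vector remapping column names.
#' @param species_vocabulary admissible predator species.
#' @return `list(stomachs = stomach_table, prey = prey_table)`.
#' @export
read_stomach_table <- function(stomach_path, prey_path = NULL, schema = NULL,
                               species_vocabulary = predator_species_default) {
  sraw <- utils::read.csv(stomach_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  sraw <- apply_schema(sraw, schema,
                       required = c("specimen_id", "predator_species",
                                    "stomach_content_mass_g"))
  for (col in setdiff(canonical_stomach_cols, names(sraw))) {
    sraw[[col]] <- NA
  }
  stomachs <- stomach_table(
    specimen_id = sraw$specimen_id,
    predator_species = sraw$predator_species,
    standard_length_mm = as.numeric(sraw$standard_length_mm),
    fork_length_cm = as.numeric(sraw$fork_length_cm),
    whole_mass_g = as.numeric(sraw$whole_mass_g),
    stomach_content_mass_g = as.numeric(sraw$stomach_content_mass_g),
    predator_mass_g = as.numeric(sraw$predator_mass_g),
    capture_date = sraw$capture_date,
    latitude = as.numeric(sraw$latitude),
    longitude = as.numeric(sraw$longitude),
    source = ifelse(is.na(sraw$source), "secondary", sraw$source),
    species_vocabulary = species_vocabulary
  )
  if (is.null(prey_path)) {
    prey <- prey_table(character(0), character(0))
  } else {
    praw <- utils::read.csv(prey_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    praw <- apply_schema(praw, schema,
                         required = c("specimen_id", "taxon", "rank",
                                      "prey_class", "digestion_state",
                                      "count", "total_mass_g"))
    if (is.null(praw$measurements)) praw$measurements <- ""
    orphan <- setdiff(unique(praw$specimen_id), stomachs$specimen_id)
    if (length(orphan)) {
      stop("prey rows reference unknown specimens: ",
           paste(orphan, collapse = ", "))
    }
    ds <- suppressWarnings(as.integer(praw$digestion_state))
    bad <- which(is.na(ds) | ds < 1L | ds > 4L)
    if (length(bad)) {
      stop("digestion_state outside 1-4 in prey rows: ",
           paste(bad, collapse = ", "))
    }
    prey <- prey_table(
      specimen_id = praw$specimen_id,
      taxon = praw$taxon,
      rank = praw$rank,
      prey_class = praw$prey_class,
      digestion_state = ds,
      count = as.integer(praw$count),
      total_mass_g = as.numeric(praw$total_mass_g),
      measurements = lapply(praw$measurements, unpack_measurements)
    )
  }
  list(stomachs = stomachs, prey = prey)
}

apply_schema <- function(df, schema, required) {
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      actual <- schema[[canon]]
      if (actual %in% names(df)) {
        names(df)[names(df) == actual] <- canon
      }
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a stomach-content dataset to canonical CSV files
#'
#' Inverse of [read_stomach_table()]; a write/read round trip reproduces the
#' dataset (text fields bit-for-bit, numerics to full double precision).
#'
#' @param stomachs,prey validated tables.
#' @param stomach_path,prey_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_stomach_table <- function(stomachs, prey, stomach_path, prey_path) {
  s <- as.data.frame(stomachs)[, canonical_stomach_cols]
  utils::write.csv(format(s, digits = 15, trim = TRUE, scientific = FALSE),
                   stomach_path, row.names = FALSE, na = "")
  p <- as.data.frame(prey)
  p$measurements <- vapply(prey$measurements, pack_measurements, "")
  p <- p[, canonical_prey_cols]
  utils::write.csv(format(p, digits = 15, trim = TRUE, scientific = FALSE),
                   prey_path, row.names = FALSE, na = "")
  invisible(c(stomach_path, prey_path))
}

## Taxonomy -------------------------------------------------------------------

#' Read a taxonomy edge list
#'
#' CSV with columns `name`, `rank`, `parent_name`. The taxonomy must be
#' acyclic; any species- or genus-level prey identification used in
#' family-level analyses must reach a family node (or be one of the
#' sanctioned coarse groups, see [coarse_groups]).
#'
#' @param path CSV path.
#' @return A `data.frame` with columns `name`, `rank`, `parent_name`.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_taxonomy(tx)
}

#' @rdname read_taxonomy
#' @param taxonomy a taxonomy data frame to validate.
#' @export
validate_taxonomy <- function(taxonomy) {
  stopifnot(all(c("name", "rank", "parent_name") %in% names(taxonomy)))
  for (nm in taxonomy$name) {
    seen <- character(0)
    cur <- nm
    while (!is.na(cur) && nzchar(cur)) {
      if (cur %in% seen) stop("taxonomy cycle at: ", cur)
      seen <- c(seen, cur)
      idx <- match(cur, taxonomy$name)
      if (is.na(idx)) break
      cur <- taxonomy$parent_name[idx]
    }
  }
  taxonomy
}

#' Find the family-level analysis unit for a taxon
#'
#' Walks the taxonomy upwards from `taxon` until a family node is reached.
#' Coarse groups sanctioned as family-level units are returned as
#' themselves. Two hyperiid families are lumped into their superfamily so
#' that family categories stay mutually exclusive (see [family_rollup()]).
#'
#' @param taxon taxon name.
#' @param taxonomy taxonomy edge list.
#' @param lump named character vector mapping family names to their
#'   replacement analysis unit.
#' @return The family-level unit name, or `NA_character_` if none is
#'   reachable.
#' @export
family_of <- function(taxon, taxonomy,
                      lump = c(Brachyscelidae = "Platysceloidea",
                               Lycaeidae = "Platysceloidea")) {
  if (taxon %in% coarse_groups) return(taxon)
  cur <- taxon
  for (step in seq_len(nrow(taxonomy) + 1L)) {
    idx <- match(cur, taxonomy$name)
    if (is.na(idx)) return(NA_character_)
    if (taxonomy$rank[idx] == "family") {
      if (cur %in% names(lump)) return(unname(lump[cur]))
      return(cur)
    }
    cur <- taxonomy$parent_name[idx]
    if (is.na(cur) || !nzchar(cur)) return(NA_character_)
    if (cur %in% coarse_groups) return(cur)
    if (cur %in% names(lump)) return(unname(lump[cur]))
  }
  NA_character_
}

## Dataset-level validation ---------------------------------------------------

#' Validate a stomach-content dataset
#'
#' Report-only consistency checks across the specimen table, prey table and
#' taxonomy. The dataset is never modified.
#'
#' @param stomachs,prey validated tables.
#' @param taxonomy optional taxonomy edge list; family-reachability checks are
#'   skipped when absent.
#' @return A data frame with one row per check: `check`, `n_pass`, `n_fail`,
#'   `detail`.
#' @export
validate_dataset <- function(stomachs, prey, taxonomy = NULL) {
  checks <- list()
  add <- function(check, ok_mask, detail_vec) {
    failing <- detail_vec[!ok_mask]
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, n_pass = sum(ok_mask), n_fail = sum(!ok_mask),
      detail = paste(utils::head(failing, 5L), collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  add("prey rows reference known specimens",
      prey$specimen_id %in% stomachs$specimen_id, prey$specimen_id)
  add("digestion states in 1-4",
      prey$digestion_state >= 1L & prey$digestion_state <= 4L,
      paste0("row ", seq_len(nrow(prey))))
  n_meas <- vapply(prey$measurements, nrow, 0L)
  add("measurement count within group count", n_meas <= prey$count,
      paste0("row ", seq_len(nrow(prey))))
  add("positive prey group mass", prey$total_mass_g > 0,
      paste0("row ", seq_len(nrow(prey))))
  add("predator mass nonnegative",
      is.na(stomachs$predator_mass_g) | stomachs$predator_mass_g >= 0,
      stomachs$specimen_id)
  if (!is.null(taxonomy)) {
    fams <- vapply(unique(prey$taxon), family_of, "", taxonomy = taxonomy)
    add("taxa reach a family-level unit", !is.na(fams), unique(prey$taxon))
  }
  do.call(rbind, checks)
}
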