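## Depth reference table: per-taxon median depths of occurrence.

#' Construct a depth-reference table
#'
#' One entry per taxon giving its median depth of occurrence: day and night
#' median depths (m), a diel-vertical-migration flag, optionally a set of
#' length-specific depth rules for taxa whose habitat depth changes across
#' ontogeny, and a `fixed_depth` flag for fragile taxa that are assigned a
#' single depth regardless of estimated size.
#'
#' @param taxon taxon names (unique).
#' @param rank taxonomic rank of each entry.
#' @param day_median_m,night_median_m median depths of occurrence in m
#'   (`NA` allowed when size rules are supplied).
#' @param migratory logical; migratory taxa resolve to the mean of day and
#'   night medians.
#' @param size_rules list of data frames with columns `length_min_mm`,
#'   `length_max_mm`, `depth_m` (non-overlapping intervals), or `NULL`.
#' @param fixed_depth logical; when `TRUE` size rules are ignored and the
#'   day/night depths are always used.
#' @return A `data.frame` of class `depth_reference`.
#' @export
depth_reference <- function(taxon, rank = "species",
                            day_median_m = NA_real_,
                            night_median_m = NA_real_,
                            migratory = FALSE, size_rules = NULL,
                            fixed_depth = FALSE) {
  n <- length(taxon)
  df <- data.frame(
    taxon = as.character(taxon),
    rank = rep_len(as.character(rank), n),
    day_median_m = rep_len(as.numeric(day_median_m), n),
    night_median_m = rep_len(as.numeric(night_median_m), n),
    migratory = rep_len(as.logical(migratory), n),
    fixed_depth = rep_len(as.logical(fixed_depth), n),
    stringsAsFactors = FALSE
  )
  if (is.null(size_rules)) size_rules <- rep(list(empty_size_rules()), n)
  stopifnot(length(size_rules) == n)
  df$size_rules <- lapply(size_rules, as_size_rules)
  validate_depth_reference(df)
  class(df) <- c("depth_reference", class(df))
  df
}

empty_size_rules <- function() {
  data.frame(length_min_mm = numeric(0), length_max_mm = numeric(0),
             depth_m = numeric(0))
}

as_size_rules <- function(r) {
  if (is.null(r) || (is.data.frame(r) && nrow(r) == 0)) {
    return(empty_size_rules())
  }
  r <- as.data.frame(r)[, c("length_min_mm", "length_max_mm", "depth_m")]
  r[order(r$length_min_mm), , drop = FALSE]
}

validate_depth_reference <- function(df) {
  if (anyDuplicated(df$taxon)) {
    stop("duplicate depth-reference taxa: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    r <- df$size_rules[[i]]
    has_depth <- !is.na(df$day_median_m[i]) || !is.na(df$night_median_m[i])
    if (!has_depth && nrow(r) == 0) {
      stop("taxon '", df$taxon[i],
           "' has neither day/night depths nor size rules")
    }
    depths <- c(df$day_median_m[i], df$night_median_m[i], r$depth_m)
    if (any(depths <= 0, na.rm = TRUE)) {
      stop("taxon '", df$taxon[i], "': depths must be > 0")
    }
    if (nrow(r) > 1) {
      if (any(r$length_min_mm[-1] < r$length_max_mm[-nrow(r)])) {
        stop("taxon '", df$taxon[i], "': overlapping size-class intervals")
      }
    }
  }
  invisible(df)
}

#' Read a depth-reference table from CSV
#'
#' Expects columns `taxon`, `rank`, `day_median_m`, `night_median_m`,
#' `migratory`, optionally `fixed_depth` and size-class triples
#' `length_min_mm`, `length_max_mm`, `depth_m`. Multiple rows for the same
#' taxon are merged: the first row provides the day/night depths, and every
#' row carrying a size-class triple contributes one size rule.
#'
#' @param path CSV path.
#' @return A `depth_reference` table.
#' @export
read_depth_reference <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "rank") %in% names(raw)))
  for (col in c("day_median_m", "night_median_m", "length_min_mm",
                "length_max_mm", "depth_m")) {
    if (is.null(raw[[col]])) raw[[col]] <- NA_real_
  }
  if (is.null(raw$migratory)) raw$migratory <- FALSE
  if (is.null(raw$fixed_depth)) raw$fixed_depth <- FALSE
  taxa <- unique(raw$taxon)
  rows <- lapply(taxa, function(tx) {
    sub <- raw[raw$taxon == tx, , drop = FALSE]
    has_rule <- !is.na(sub$depth_m) & !is.na(sub$length_min_mm)
    rules <- sub[has_rule, c("length_min_mm", "length_max_mm", "depth_m"),
                 drop = FALSE]
    list(
      taxon = tx, rank = sub$rank[1],
      day = sub$day_median_m[which(!is.na(sub$day_median_m))[1]],
      night = sub$night_median_m[which(!is.na(sub$night_median_m))[1]],
      migratory = isTRUE(any(as.logical(sub$migratory))),
      fixed = isTRUE(any(as.logical(sub$fixed_depth))),
      rules = rules
    )
  })
  depth_reference(
    taxon = vapply(rows, `[[`, "", "taxon"),
    rank = vapply(rows, `[[`, "", "rank"),
    day_median_m = vapply(rows, function(r) {
      if (length(r$day)) as.numeric(r$day) else NA_real_
    }, 0),
    night_median_m = vapply(rows, function(r) {
      if (length(r$night)) as.numeric(r$night) else NA_real_
    }, 0),
    migratory = vapply(rows, `[[`, TRUE, "migratory"),
    fixed_depth = vapply(rows, `[[`, TRUE, "fixed"),
    size_rules = lapply(rows, `[[`, "rules")
  )
}

#' Write a depth-reference table to CSV
#'
#' @param reference a `depth_reference` table.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_depth_reference <- function(reference, path) {
  rows <- list()
  for (i in seq_len(nrow(reference))) {
    base <- data.frame(
      taxon = reference$taxon[i], rank = reference$rank[i],
      day_median_m = reference$day_median_m[i],
      night_median_m = reference$night_median_m[i],
      migratory = reference$migratory[i],
      fixed_depth = reference$fixed_depth[i],
      length_min_mm = NA_real_, length_max_mm = NA_real_, depth_m = NA_real_,
      stringsAsFactors = FALSE
    )
    r <- reference$size_rules[[i]]
    if (nrow(r)) {
      base <- base[rep(1L, nrow(r)), , drop = FALSE]
      base$length_min_mm <- r$length_min_mm
      base$length_max_mm <- r$length_max_mm
      base$depth_m <- r$depth_m
      base$day_median_m[-1] <- NA_real_
      base$night_median_m[-1] <- NA_real_
    }
    rows[[i]] <- base
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
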