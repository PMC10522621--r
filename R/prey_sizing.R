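## Prey-size imputation: expand prey groups to individuals; family-level
## length-mass models.

#' Expand a prey group into individual prey
#'
#' Groups are enumerated and weighed as a whole; only a subset of
#' individuals is usually measured (at most the minimum, median and maximum
#' sized individuals when a group holds more than three). Unmeasured
#' individuals take the median mass and length of the measured individuals in
#' the same group; when nothing was measured, each individual receives an
#' equal share of the group's total mass and no length. Only digestion
#' states 1-3 are considered measurable; measurements attached to state-4
#' groups are ignored and the group expands by mass splitting.
#'
#' @param prey a `prey_table` (one or more rows).
#' @param measurable_states digestion states whose measurements are used.
#' @return A data frame with one row per individual: `specimen_id`, `taxon`,
#'   `rank`, `prey_class`, `digestion_state`, `mass_g`, `length_mm`,
#'   `length_type`, `mass_source` (`measured`, `group_median`, `mass_split`),
#'   `length_source` (`measured`, `group_median`, `missing`).
#' @export
expand_group <- function(prey, measurable_states = 1:3) {
  out <- vector("list", nrow(prey))
  for (i in seq_len(nrow(prey))) {
    g <- prey[i, , drop = FALSE]
    m <- prey$measurements[[i]]
    usable <- g$digestion_state %in% measurable_states && nrow(m) > 0
    cnt <- g$count
    if (!usable) {
      ind <- data.frame(
        mass_g = rep(g$total_mass_g / cnt, cnt),
        length_mm = NA_real_, length_type = NA_character_,
        mass_source = "mass_split", length_source = "missing",
        stringsAsFactors = FALSE
      )
    } else {
      med_mass <- stats::median(m$mass_g)
      med_len <- if (all(is.na(m$length_mm))) NA_real_ else
        stats::median(m$length_mm, na.rm = TRUE)
      lt <- if (all(is.na(m$length_type))) NA_character_ else
        m$length_type[which(!is.na(m$length_type))[1]]
      n_imp <- cnt - nrow(m)
      ind <- data.frame(
        mass_g = c(m$mass_g, rep(med_mass, n_imp)),
        length_mm = c(m$length_mm, rep(med_len, n_imp)),
        length_type = c(m$length_type, rep(lt, n_imp)),
        mass_source = c(rep("measured", nrow(m)), rep("group_median", n_imp)),
        length_source = c(ifelse(is.na(m$length_mm), "missing", "measured"),
                          rep(if (is.na(med_len)) "missing" else
                            "group_median", n_imp)),
        stringsAsFactors = FALSE
      )
    }
    ind <- cbind(
      data.frame(specimen_id = g$specimen_id, taxon = g$taxon, rank = g$rank,
                 prey_class = g$prey_class,
                 digestion_state = g$digestion_state,
                 group_row = i, stringsAsFactors = FALSE),
      ind
    )
    out[[i]] <- ind
  }
  do.call(rbind, out)
}

#' Fit a family-level length-mass model
#'
#' Fits a monotone smooth of mass on length on the log-log scale. The smooth
#' is an isotonized penalized spline: a [mgcv::gam()] fit evaluated on a fine
#' grid, made non-decreasing by pool-adjacent-violators, and interpolated.
#' With fewer than `powerlaw_threshold` pairs the prediction map falls back
#' to a log-log power law `mass = a * length^b`; the power-law coefficients
#' are recorded in every model as a diagnostic. Models are fit per
#' (family, length type); never pool standard lengths with mantle or total
#' lengths.
#'
#' @param family prey family name (label only).
#' @param lengths_mm,masses_g paired positive measurements.
#' @param length_type length convention of the pairs.
#' @param powerlaw_threshold below this number of pairs the power-law branch
#'   is used for prediction.
#' @return An object of class `length_mass_model` with elements `family`,
#'   `length_type`, `branch` (`"smooth"` or `"powerlaw"`), `powerlaw`
#'   (`a`, `b`, `sigma_log`), `grid` (log-length, log-mass lookup for the
#'   smooth branch), `n_fit`, `length_range_mm`, `mass_range_g`.
#' @export
fit_length_mass <- function(family, lengths_mm, masses_g, length_type = "SL",
                            powerlaw_threshold = 8L) {
  ok <- is.finite(lengths_mm) & is.finite(masses_g) &
    lengths_mm > 0 & masses_g > 0
  lengths_mm <- lengths_mm[ok]
  masses_g <- masses_g[ok]
  if (length(unique(lengths_mm)) < 2L) {
    stop("cannot fit length-mass model for '", family,
         "': fewer than 2 distinct lengths")
  }
  lx <- log(lengths_mm)
  ly <- log(masses_g)
  pl <- stats::lm(ly ~ lx)
  powerlaw <- list(a = exp(unname(stats::coef(pl)[1])),
                   b = unname(stats::coef(pl)[2]),
                   sigma_log = stats::sigma(pl))
  n <- length(lx)
  branch <- if (n >= powerlaw_threshold) "smooth" else "powerlaw"
  grid <- NULL
  if (branch == "smooth") {
    k <- max(4L, min(10L, n - 1L))
    fit <- mgcv::gam(ly ~ s(lx, k = k))
    gx <- seq(min(lx), max(lx), length.out = 200L)
    gy <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(lx = gx)))
    gy <- isotonize(gy)
    # enforce strict increase so the inverse map is well defined
    gy <- gy + seq_along(gy) * 1e-9
    grid <- list(log_length = gx, log_mass = gy)
  }
  structure(
    list(family = family, length_type = length_type, branch = branch,
         powerlaw = powerlaw, grid = grid, n_fit = n,
         length_range_mm = range(lengths_mm),
         mass_range_g = range(masses_g)),
    class = "length_mass_model"
  )
}

isotonize <- function(y) {
  # pool-adjacent-violators for a nondecreasing fit, unit weights
  n <- length(y)
  vals <- numeric(n)
  wts <- numeric(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]
    wts[m] <- 1
    while (m > 1L && vals[m - 1L] > vals[m]) {
      vals[m - 1L] <- (wts[m - 1L] * vals[m - 1L] + wts[m] * vals[m]) /
        (wts[m - 1L] + wts[m])
      wts[m - 1L] <- wts[m - 1L] + wts[m]
      m <- m - 1L
    }
  }
  rep(vals[seq_len(m)], times = wts[seq_len(m)])
}

#' Predict mass from length under a fitted length-mass model
#'
#' @param model a `length_mass_model`.
#' @param length_mm lengths in mm.
#' @return Predicted masses in g.
#' @export
predict_mass_from_length <- function(model, length_mm) {
  if (model$branch == "powerlaw") {
    return(model$powerlaw$a * length_mm^model$powerlaw$b)
  }
  lx <- log(length_mm)
  g <- model$grid
  ly <- stats::approx(g$log_length, g$log_mass, xout = lx, rule = 2)$y
  exp(ly)
}

#' Predict length from mass by inverting a length-mass model
#'
#' The monotone map is inverted by interpolation (smooth branch) or in
#' closed form (power-law branch: `L = (m / a)^(1/b)`). Masses outside
#' `[0.5x, 2x]` of the fitted mass range trigger an extrapolation warning but
#' still return the extrapolated value.
#'
#' @param model a `length_mass_model`.
#' @param mass_g masses in g.
#' @return Predicted lengths in mm.
#' @export
predict_length_from_mass <- function(model, mass_g) {
  lo <- 0.5 * model$mass_range_g[1]
  hi <- 2 * model$mass_range_g[2]
  if (any(mass_g < lo | mass_g > hi, na.rm = TRUE)) {
    warning("mass outside [0.5x, 2x] of the fitted range for family '",
            model$family, "': extrapolating")
  }
  if (model$branch == "powerlaw") {
    return((mass_g / model$powerlaw$a)^(1 / model$powerlaw$b))
  }
  g <- model$grid
  ly <- log(mass_g)
  lx <- stats::approx(g$log_mass, g$log_length, xout = ly, rule = 2)$y
  exp(lx)
}

#' Serialize or restore a length-mass model as JSON text
#'
#' @param model a `length_mass_model`.
#' @param path file path.
#' @return `write_length_mass_model` invisibly returns `path`;
#'   `read_length_mass_model` returns the model.
#' @export
write_length_mass_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_length_mass_model
#' @export
read_length_mass_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$length_range_mm <- as.numeric(m$length_range_mm)
  m$mass_range_g <- as.numeric(m$mass_range_g)
  if (!is.null(m$grid)) m$grid <- lapply(m$grid, as.numeric)
  structure(m, class = "length_mass_model")
}

#' Fit length-mass models for every (family, length type) stratum
#'
#' @param individuals output of [expand_group()] restricted to measured
#'   individuals, with a `family` column attached.
#' @param min_pairs strata with fewer pairs are skipped.
#' @param powerlaw_threshold passed to [fit_length_mass()].
#' @return A named list of `length_mass_model`s keyed `family:length_type`.
#' @export
fit_length_mass_by_family <- function(individuals, min_pairs = 4L,
                                      powerlaw_threshold = 8L) {
  meas <- individuals[individuals$mass_source == "measured" &
                        individuals$length_source == "measured" &
                        !is.na(individuals$family), , drop = FALSE]
  keys <- unique(paste(meas$family, meas$length_type, sep = ":"))
  models <- list()
  for (key in keys) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    sub <- meas[meas$family == parts[1] & meas$length_type == parts[2], ]
    if (nrow(sub) < min_pairs || length(unique(sub$length_mm)) < 2L) next
    models[[key]] <- fit_length_mass(parts[1], sub$length_mm, sub$mass_g,
                                     length_type = parts[2],
                                     powerlaw_threshold = powerlaw_threshold)
  }
  models
}
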