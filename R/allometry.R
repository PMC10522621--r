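## Log-scale linear models of prey size/number against predator mass and
## species, with type-III ANCOVA; smooth prey-type proportion trends.

#' Fit a log-scale allometric model of stomach contents on predator mass
#'
#' Ordinary least squares of a transformed response on
#' `log10(predator mass) * species` (full interaction). Transforms follow
#' the field convention that makes slopes comparable across studies:
#' individual prey mass and total prey mass per stomach are
#' log10-transformed, prey counts per stomach are log2-transformed.
#' Confidence intervals and p-values use the Wald t approximation.
#'
#' @param data data frame with columns `response` (raw, positive for log
#'   responses), `predator_mass_g` (> 0) and `species`.
#' @param response one of `"individual_mass"`, `"total_mass"`
#'   (log10-transformed) or `"prey_count"` (log2-transformed).
#' @param conf_level Wald confidence level.
#' @return `list(model (lm), response, transform, coefficients (estimate,
#'   se, t, p, CI), fit (adj R2, F, df), n, dropped)` of class
#'   `prey_scaling_fit`. Rows with nonpositive response or predator mass are
#'   dropped with a warning.
#' @export
fit_prey_scaling <- function(data,
                             response = c("individual_mass", "total_mass",
                                          "prey_count"),
                             conf_level = 0.95) {
  response <- match.arg(response)
  stopifnot(all(c("response", "predator_mass_g", "species") %in%
                  names(data)))
  bad <- !is.finite(data$response) | data$response <= 0 |
    !is.finite(data$predator_mass_g) | data$predator_mass_g <= 0
  if (any(bad)) {
    warning(sum(bad), " observation(s) with nonpositive values dropped ",
            "before log transform")
  }
  d <- data[!bad, , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 usable observations")
  trans <- if (response == "prey_count") "log2" else "log10"
  d$y <- if (trans == "log2") log2(d$response) else log10(d$response)
  d$log_mass <- log10(d$predator_mass_g)
  d$species <- factor(d$species)
  fit <- if (nlevels(d$species) > 1) {
    stats::lm(y ~ log_mass * species, data = d)
  } else {
    stats::lm(y ~ log_mass, data = d)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    t = sm$coefficients[, 3],
    p = sm$coefficients[, 4],
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(model = fit, response = response, transform = trans,
         coefficients = coefs,
         fit = list(adj_r_squared = sm$adj.r.squared,
                    f = unname(sm$fstatistic[1]),
                    df = unname(sm$fstatistic[2:3])),
         n = nrow(d), dropped = sum(bad)),
    class = "prey_scaling_fit"
  )
}

#' Type-III ANCOVA on a fitted allometric model
#'
#' Marginal (type III) sums of squares per term against the full
#' interaction model, with F and p values. Factors are refit with sum
#' contrasts, as type-III tests require.
#'
#' @param fit a `prey_scaling_fit` from [fit_prey_scaling()].
#' @return Data frame with one row per term: `term`, `ss`, `df`, `f`, `p`.
#' @export
type3_ancova <- function(fit) {
  stopifnot(inherits(fit, "prey_scaling_fit"))
  m <- fit$model
  d <- stats::model.frame(m)
  if ("species" %in% names(d) && nlevels(d$species) > 1) {
    refit <- stats::update(
      m, data = d,
      contrasts = list(species = "contr.sum")
    )
  } else {
    refit <- m
  }
  a <- car::Anova(refit, type = 3)
  out <- data.frame(term = rownames(a), ss = a[["Sum Sq"]], df = a[["Df"]],
                    f = a[["F value"]], p = a[["Pr(>F)"]],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Smooth trend of a prey-type proportion over predator mass
#'
#' Models a per-stomach proportional-mass response in \[0, 1\] as a smooth
#' logit-link function of log10 predator mass. When more than
#' `binomial_threshold` of the responses are exactly 0 or 1 the
#' quasi-likelihood logit smooth degenerates, so the fit is routed to a
#' binomial-family branch on the binarized response (the same fallback a
#' beta-likelihood model needs when dominated by zeros and ones).
#'
#' @param proportions per-stomach proportional masses in \[0, 1\].
#' @param predator_mass_g predator masses (> 0).
#' @param binomial_threshold fraction of \{0, 1\} responses that triggers
#'   the binomial branch.
#' @return `list(model (gam), branch ("quasi-logit" or "binomial"),
#'   smooth_p (approximate p-value of the smooth term), fitted_curve
#'   (function of mass), trivial)`.
#' @export
proportion_trend <- function(proportions, predator_mass_g,
                             binomial_threshold = 0.9) {
  ok <- is.finite(proportions) & is.finite(predator_mass_g) &
    predator_mass_g > 0
  p <- proportions[ok]
  x <- log10(predator_mass_g[ok])
  stopifnot(all(p >= 0 & p <= 1))
  if (length(unique(p)) == 1L) {
    return(list(model = NULL, branch = "trivial", smooth_p = NA_real_,
                fitted_curve = function(mass_g) rep(p[1], length(mass_g)),
                trivial = TRUE))
  }
  extreme <- mean(p %in% c(0, 1))
  d <- data.frame(p = p, x = x)
  if (extreme > binomial_threshold) {
    d$p <- as.numeric(d$p >= 0.5)
    fit <- mgcv::gam(p ~ s(x), data = d, family = stats::binomial())
    branch <- "binomial"
  } else {
    fit <- mgcv::gam(p ~ s(x), data = d, family = stats::quasibinomial())
    branch <- "quasi-logit"
  }
  sm <- summary(fit)
  curve_fun <- function(mass_g) {
    as.numeric(mgcv::predict.gam(
      fit, newdata = data.frame(x = log10(mass_g)), type = "response"))
  }
  list(model = fit, branch = branch, smooth_p = sm$s.table[1, "p-value"],
       fitted_curve = curve_fun, trivial = FALSE)
}
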