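ref_small <- depth_reference(
  taxon = c("Sternoptyx diaphana", "Phrosina semilunata", "Migrator",
            "Sizer", "Genus sp A", "Genus sp B", "Fragile"),
  rank = "species",
  day_median_m = c(675, 185.38, 300, 500, 100, 300, 50),
  night_median_m = c(675, 185.38, 100, 500, 100, 300, 50),
  migratory = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
  size_rules = list(
    NULL, NULL, NULL,
    data.frame(length_min_mm = c(0, 50), length_max_mm = c(50, 500),
               depth_m = c(150, 700)),
    NULL, NULL,
    data.frame(length_min_mm = 0, length_max_mm = 1000, depth_m = 900)
  ),
  fixed_depth = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
)

tax_small <- data.frame(
  name = c("Genus sp A", "Genus sp B", "Genus", "Fam"),
  rank = c("species", "species", "genus", "family"),
  parent_name = c("Genus", "Genus", "Fam", NA)
)

test_that("depth resolution follows the documented precedence", {
  r <- resolve_depth("Sternoptyx diaphana", ref_small)
  expect_equal(r$depth_m, 675)
  expect_equal(r$path, "species-direct")
  r2 <- resolve_depth("Migrator", ref_small)
  expect_equal(r2$depth_m, 200)
  expect_equal(r2$path, "dvm-averaged")
  r3 <- resolve_depth("Sizer", ref_small, length_mm = 80)
  expect_equal(r3$depth_m, 700)
  expect_equal(r3$path, "size-rule")
  # no length supplied: falls back to day/night entry
  r4 <- resolve_depth("Sizer", ref_small)
  expect_equal(r4$depth_m, 500)
  expect_equal(r4$path, "species-direct")
  # genus-level query averages member species
  r5 <- resolve_depth("Genus", ref_small, taxonomy = tax_small)
  expect_equal(r5$depth_m, 200)
  expect_equal(r5$path, "genus-mean")
  expect_setequal(r5$members, c("Genus sp A", "Genus sp B"))
  r6 <- resolve_depth("Fam", ref_small, taxonomy = tax_small)
  expect_equal(r6$path, "family-mean")
  # fragile taxa keep one depth regardless of size
  r7 <- resolve_depth("Fragile", ref_small, length_mm = 500)
  expect_equal(r7$depth_m, 50)
  r8 <- resolve_depth("Nobody", ref_small, taxonomy = tax_small)
  expect_equal(r8$path, "unavailable")
  expect_true(is.na(r8$depth_m))
})

test_that("foraging depth is the mass-weighted mean of prey depths", {
  expect_equal(foraging_depth(675, 1), 675)
  expect_equal(foraging_depth(185.38, 3.2), 185.38)
  expect_equal(foraging_depth(c(185.38, 675), c(1, 1)), 430.19)
  expect_error(foraging_depth(numeric(0), numeric(0)), "no prey")
})

test_that("foraging depth is convex and scale invariant", {
  set.seed(12)
  for (i in 1:25) {
    z <- runif(5, 50, 900)
    w <- rgamma(5, 1)
    zf <- foraging_depth(z, w)
    expect_gte(zf, min(z))
    expect_lte(zf, max(z))
    expect_equal(foraging_depth(z, 7.3 * w), zf, tolerance = 1e-12)
  }
})

test_that("adjusted proportions renormalize over resolvable prey", {
  ap <- adjusted_proportions(c(9, 1), c(675, NA))
  expect_equal(ap$mass_coverage, 0.9)
  expect_equal(ap$weights, 1)
  ap2 <- adjusted_proportions(c(2, 2), c(100, 300))
  expect_equal(ap2$weights, c(0.5, 0.5))
  expect_equal(ap2$mass_coverage, 1)
  expect_error(adjusted_proportions(c(1, 1), c(NA, NA)), "no depth")
})

test_that("single-layer feeding yields exactly the layer depth", {
  config <- two_layer_config(w_deep = 0, n = 40L, seed = 3)
  d <- generate_dataset(config)
  fd <- foraging_depths(d$stomachs, d$prey, d$reference, d$taxonomy)
  expect_equal(fd$Zf_m, rep(185.38, nrow(fd)), tolerance = 1e-12)
  expect_true(all(fd$mass_coverage == 1))
})

test_that("two-layer mixture mean depth matches truth within MC error", {
  w <- 0.3
  d <- generate_dataset(two_layer_config(w_deep = w, n = 200L, seed = 13))
  fd <- foraging_depths(d$stomachs, d$prey, d$reference, d$taxonomy)
  truth <- 185.38 + w * (675 - 185.38)
  se <- sd(fd$Zf_m) / sqrt(nrow(fd))
  expect_lt(abs(mean(fd$Zf_m) - truth), 3 * se)
})

test_that("depth trend recovers flat truth and species ordering", {
  set.seed(14)
  n <- 60
  est <- data.frame(
    specimen_id = paste0("s", 1:(3 * n)),
    predator_species = rep(c("sh", "mid", "deep"), each = n),
    predator_mass_g = exp(runif(3 * n, log(1), log(100))),
    Zf_m = rep(c(200, 350, 500), each = n) + rnorm(3 * n, 0, 40),
    mass_coverage = 1, n_taxa = 2
  )
  tr <- depth_trend(est)
  expect_false(tr$fallback)
  mm <- tr$species_means
  ord <- mm$mean_Zf_m[match(c("sh", "mid", "deep"), mm$species)]
  expect_true(all(diff(ord) > 0))
  for (sp in c("sh", "mid", "deep")) {
    truth <- c(sh = 200, mid = 350, deep = 500)[[sp]]
    row <- mm[mm$species == sp, ]
    expect_lt(abs(row$mean_Zf_m - truth), 4 * row$se + 20)
  }
  # too few estimates: falls back to species means
  tr2 <- depth_trend(est[c(1:5, n + (1:5), 2 * n + (1:5)), ])
  expect_true(tr2$fallback)
})

test_that("occurrence trend is calibrated and recovers logistic truth", {
  set.seed(15)
  n <- 500
  mass <- exp(runif(n, log(1), log(1000)))
  # constant probability: slope ~ 0
  y0 <- rbinom(n, 1, 0.5)
  fit0 <- occurrence_trend(y0, mass)
  expect_lt(abs(fit0$coefficients["slope"]), 2 * fit0$se["slope"])
  # known logistic truth on log10 mass
  b0 <- -2; b1 <- 1.5
  p <- plogis(b0 + b1 * log10(mass))
  y1 <- rbinom(n, 1, p)
  fit1 <- occurrence_trend(y1, mass)
  expect_lt(abs(fit1$coefficients["intercept"] - b0),
            2 * fit1$se["intercept"])
  expect_lt(abs(fit1$coefficients["slope"] - b1), 2 * fit1$se["slope"])
  expect_equal(fit1$fitted_curve(10), 100 * plogis(
    fit1$coefficients[["intercept"]] + fit1$coefficients[["slope"]]),
    tolerance = 1e-9)
  # all-absent input: degenerate flag
  fit2 <- occurrence_trend(rep(0, n), mass)
  expect_true(fit2$degenerate)
  # complete separation: penalized fallback with warning
  ysep <- as.numeric(log10(mass) > 1)
  expect_warning(fit3 <- occurrence_trend(ysep, mass), "separation")
  expect_true(fit3$separation)
  expect_true(is.finite(fit3$coefficients["slope"]))
})
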