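test_that("exact linear truth is recovered perfectly", {
  x <- seq(0.5, 50, length.out = 20)
  d <- data.frame(response = 10^(2 + 3 * log10(x)),
                  predator_mass_g = x, species = "only")
  fit <- fit_prey_scaling(d, "individual_mass")
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 2, tolerance = 1e-9)
  expect_equal(co$estimate[co$term == "log_mass"], 3, tolerance = 1e-9)
  expect_equal(fit$fit$adj_r_squared, 1, tolerance = 1e-9)
})

test_that("a pure intercept offset between species is estimated exactly", {
  x <- rep(seq(1, 30, length.out = 15), 2)
  sp <- rep(c("A", "B"), each = 15)
  y <- 10^(1 + 0.5 * log10(x) + ifelse(sp == "B", 1, 0))
  fit <- fit_prey_scaling(
    data.frame(response = y, predator_mass_g = x, species = sp),
    "individual_mass")
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "speciesB"], 1, tolerance = 1e-9)
  expect_equal(co$estimate[co$term == "log_mass:speciesB"], 0,
               tolerance = 1e-9)
})

test_that("count responses use the log2 transform", {
  x <- seq(1, 100, length.out = 20)
  d <- data.frame(response = 2^(1 + 2 * log10(x)), predator_mass_g = x,
                  species = "only")
  fit <- fit_prey_scaling(d, "prey_count")
  expect_equal(fit$transform, "log2")
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 1e-9)
})

test_that("nonpositive observations are dropped with a warning", {
  d <- data.frame(response = c(rep(1, 12), 0),
                  predator_mass_g = c(rep(10, 12), 10), species = "only")
  expect_warning(fit <- fit_prey_scaling(d, "total_mass"), "dropped")
  expect_equal(fit$n, 12)
  expect_equal(fit$dropped, 1)
})

test_that("known per-species slopes are recovered within 2 se", {
  set.seed(16)
  n <- 100
  slopes <- c(A = 0.2, B = 0.35, C = 0.5)
  d <- do.call(rbind, lapply(names(slopes), function(sp) {
    m <- exp(runif(n, log(1), log(500)))
    data.frame(
      response = 10^(-0.5 + slopes[[sp]] * log10(m) + rnorm(n, 0, 0.3)),
      predator_mass_g = m, species = sp)
  }))
  fit <- fit_prey_scaling(d, "individual_mass")
  co <- fit$coefficients
  base <- co[co$term == "log_mass", ]
  expect_lt(abs(base$estimate - slopes["A"]), 2 * base$se)
  for (sp in c("B", "C")) {
    inter <- co[co$term == paste0("log_mass:species", sp), ]
    expect_lt(abs(inter$estimate - (slopes[[sp]] - slopes[["A"]])),
              2 * inter$se)
  }
  # Wald CIs contain their estimates
  expect_true(all(co$ci_lower <= co$estimate & co$estimate <= co$ci_upper))
})

test_that("type-III equals sequential sums of squares in a balanced design", {
  set.seed(17)
  x <- rep(c(-1, 1), each = 20)
  sp <- rep(rep(c("A", "B"), each = 10), 2)
  y <- 1 + 0.5 * x + ifelse(sp == "B", 0.3, 0) + rnorm(40, 0, 0.2)
  d <- data.frame(response = 10^y, predator_mass_g = 10^x, species = sp)
  fit <- fit_prey_scaling(d, "individual_mass")
  t3 <- type3_ancova(fit)
  seq_ss <- anova(fit$model)
  expect_equal(t3$ss[t3$term == "log_mass"],
               seq_ss["log_mass", "Sum Sq"], tolerance = 1e-8)
  expect_equal(t3$ss[t3$term == "species"],
               seq_ss["species", "Sum Sq"], tolerance = 1e-8)
  expect_equal(t3$ss[t3$term == "log_mass:species"],
               seq_ss["log_mass:species", "Sum Sq"], tolerance = 1e-8)
})

test_that("null interaction yields F statistics near 1 over replicates", {
  set.seed(18)
  f_vals <- replicate(120, {
    n <- 30
    x <- runif(2 * n, 0, 2)
    sp <- rep(c("A", "B"), each = n)
    y <- 0.2 + 0.4 * x + ifelse(sp == "B", 0.5, 0) + rnorm(2 * n, 0, 0.3)
    d <- data.frame(response = 10^y, predator_mass_g = 10^x, species = sp)
    t3 <- type3_ancova(fit_prey_scaling(d, "individual_mass"))
    t3$f[t3$term == "log_mass:species"]
  })
  # under the null the interaction F follows F(1, 56): compare the observed
  # median against the theoretical one and check p-value uniformity
  expect_lt(abs(median(f_vals) - qf(0.5, 1, 56)), 0.35)
  expect_lt(abs(mean(pf(f_vals, 1, 56, lower.tail = FALSE)) - 0.5), 0.1)
})

test_that("OLS residuals are orthogonal to the design", {
  set.seed(19)
  n <- 80
  d <- data.frame(
    response = 10^rnorm(n), predator_mass_g = exp(runif(n, 0, 5)),
    species = sample(c("A", "B", "C"), n, replace = TRUE))
  fit <- fit_prey_scaling(d, "individual_mass")
  X <- scale(stats::model.matrix(fit$model)[, -1])
  r <- stats::residuals(fit$model)
  expect_lt(max(abs(crossprod(X, r))) / n, 1e-8)
})

test_that("proportion trends recover constants, signs, and the binomial branch", {
  set.seed(20)
  n <- 150
  mass <- exp(runif(n, log(1), log(500)))
  # constant truth 0.7 with modest noise
  p_const <- pmin(pmax(0.7 + rnorm(n, 0, 0.08), 0), 1)
  tr <- proportion_trend(p_const, mass)
  expect_equal(tr$branch, "quasi-logit")
  preds <- tr$fitted_curve(c(2, 20, 200))
  expect_true(all(abs(preds - 0.7) < 0.05))
  # monotone logistic truth: fitted curve increases
  p_mono <- plogis(-1.5 + 1.2 * log10(mass)) + rnorm(n, 0, 0.05)
  tr2 <- proportion_trend(pmin(pmax(p_mono, 0), 1), mass)
  grid <- tr2$fitted_curve(c(1, 10, 100, 500))
  expect_true(all(diff(grid) > 0))
  # dominated by exact zeros and ones: binomial branch
  p_ext <- as.numeric(log10(mass) + rnorm(n, 0, 0.3) > 1)
  tr3 <- proportion_trend(p_ext, mass)
  expect_equal(tr3$branch, "binomial")
  # single-valued input: trivial model flag
  tr4 <- proportion_trend(rep(1, n), mass)
  expect_true(tr4$trivial)
  expect_equal(tr4$fitted_curve(c(1, 10)), c(1, 1))
})
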