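test_that("pooled t-test matches the closed form and its symmetries", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # hand computation: pooled sd = 1, se = sqrt(2/3), t = -3/se, df = 4
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$p.value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(res$p.value, 0.0213, tolerance = 1e-3)
  # swapping groups negates t, keeps p
  rev <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p.value, res$p.value)
  # degenerate cases by convention
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p.value, 1)
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p.value, 0)
})

test_that("one-factor two-level ANOVA F equals the pooled t squared", {
  set.seed(11)
  d <- data.frame(g = rep(c("a", "b"), each = 6), y = rnorm(12, c(0, 1)))
  a <- factorial_anova(d, "y", "g")
  t2 <- two_sample_t(d$y[d$g == "a"], d$y[d$g == "b"])$statistic^2
  expect_equal(a$anova$statistic, t2, tolerance = 1e-12)
})

test_that("a pure main effect is detected and null terms stay near zero", {
  set.seed(12)
  d <- expand.grid(a = c("lo", "hi"), b = c("x", "y"), rep = 1:5)
  d$y <- ifelse(d$a == "hi", 20, 10) + rnorm(nrow(d), 0, 1e-3)
  fit <- factorial_anova(d, "y", c("a", "b"))
  tab <- tidy(fit)
  expect_lt(tab$p.value[tab$term == "a"], 1e-6)
  expect_gt(tab$p.value[tab$term == "b"], 0.05)
  expect_gt(tab$p.value[tab$term == "a:b"], 0.05)
})

test_that("marginal means equal cell means in a balanced design", {
  set.seed(13)
  d <- expand.grid(a = c("lo", "hi"), b = c("x", "y"), rep = 1:4)
  d$y <- rnorm(nrow(d), 5)
  fit <- factorial_anova(d, "y", c("a", "b"))
  emm <- fit$emmeans
  for (i in seq_len(nrow(emm))) {
    cell <- d$y[d$a == emm$a[i] & d$b == emm$b[i]]
    expect_equal(emm$emmean[i], mean(cell), tolerance = 1e-10)
  }
})

test_that("degenerate and saturated designs are handled by convention", {
  d <- expand.grid(a = c("lo", "hi"), rep = 1:3)
  d$y <- 5
  fit <- factorial_anova(d, "y", "a")
  expect_true(all(fit$anova$statistic == 0))
  expect_equal(fit$adj_r2, 0)
  d2 <- expand.grid(a = c("lo", "hi"), b = c("x", "y"))
  d2$y <- rnorm(4)
  expect_error(factorial_anova(d2, "y", c("a", "b")), "saturated")
})

test_that("adjusted R2 agrees with the brute-force residual formula", {
  set.seed(14)
  d <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  d$y <- 1 + 0.5 * d$x1 + rnorm(20, 0, 0.5)
  fit <- backward_stepwise(d, "y", c("x1", "x2"), alpha = 1)  # keep both
  m <- fit$model
  n <- nrow(d); p <- 2
  r2 <- 1 - sum(residuals(m)^2) / sum((d$y - mean(d$y))^2)
  expect_equal(fit$r2, r2, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1 - (1 - r2) * (n - 1) / (n - p - 1),
               tolerance = 1e-12)
  expect_lte(fit$adj_r2, fit$r2)
})

test_that("Tukey p-values are monotone in the mean difference", {
  # equal-n groups with means 0, 1, 2, 4: larger gaps, smaller p
  set.seed(15)
  d <- data.frame(g = rep(c("g1", "g2", "g3", "g4"), each = 5))
  d$y <- rep(c(0, 1, 2, 4), each = 5) + rnorm(20, 0, 0.8)
  fit <- factorial_anova(d, "y", "g")
  tk <- fit$tukey
  ord <- order(abs(tk$estimate))
  expect_true(all(diff(tk$p.value[ord]) <= 1e-12))
})

test_that("backward stepwise recovers a planted filter + flow model", {
  set.seed(16)
  design <- study_truth(generate_study(noise_cv = 0))
  d <- data.frame(
    filter_code = filter_code(design$filter),
    flow = design$effluent_flow_L_h,
    mode_code = ifelse(design$mode == "CVVH", 1, 2),
    dilution = ifelse(is.na(design$dilution_split), 0,
                      design$dilution_split)
  )
  d$cl <- 1.469 - 0.821 * d$filter_code + 0.612 * d$flow +
    rnorm(nrow(d), 0, 1e-3)
  fit <- backward_stepwise(d, "cl", c("mode_code", "filter_code", "flow",
                                      "dilution"))
  expect_setequal(fit$retained, c("filter_code", "flow"))
  cf <- coef(fit$model)
  expect_equal(unname(cf["filter_code"]), -0.821, tolerance = 1e-2)
  expect_equal(unname(cf["flow"]), 0.612, tolerance = 1e-2)
  expect_true(all(tidy(fit)$p.value[tidy(fit)$term != "(Intercept)"] <= 0.05))
  # zero-noise recovery is exact
  d$cl <- 1.469 - 0.821 * d$filter_code + 0.612 * d$flow
  fit0 <- suppressWarnings(
    backward_stepwise(d, "cl", c("mode_code", "filter_code", "flow",
                                 "dilution")))
  cf0 <- coef(fit0$model)
  expect_equal(unname(cf0["filter_code"]), -0.821, tolerance = 1e-6)
  expect_equal(unname(cf0["flow"]), 0.612, tolerance = 1e-6)
})

test_that("degenerate stepwise cases behave sensibly", {
  set.seed(17)
  d <- data.frame(x = rnorm(24))
  d$y <- d$x
  fit <- suppressWarnings(backward_stepwise(d, "y", "x"))
  expect_identical(fit$retained, "x")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # all-noise candidates: intercept-only is the majority outcome
  n_empty <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    dn <- data.frame(a = rnorm(24), b = rnorm(24), c = rnorm(24))
    dn$y <- rnorm(24)
    fitn <- suppressWarnings(backward_stepwise(dn, "y", c("a", "b", "c")))
    if (!length(fitn$retained)) n_empty <- n_empty + 1
  }
  expect_gt(n_empty, 10)
})

test_that("collinearity diagnostics report VIF and tolerance", {
  set.seed(18)
  d <- data.frame(x1 = rnorm(30))
  d$x2 <- d$x1 + rnorm(30, 0, 0.3)
  d$y <- d$x1 + d$x2 + rnorm(30, 0, 0.2)
  fit <- backward_stepwise(d, "y", c("x1", "x2"))
  if (length(fit$retained) >= 2) {
    expect_true(all(fit$diagnostics$vif >= 1))
    expect_equal(fit$diagnostics$tolerance, 1 / fit$diagnostics$vif)
  }
  g <- glance(fit)
  expect_lte(g$adj.r.squared, g$r.squared)
})
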