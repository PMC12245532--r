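test_that("wald ratio follows the delta-method closed form", {
  p <- make_pairs(0.5, 0.1, sy = 0.05)
  e <- wald_ratio(p)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1)
  # null outcome effect
  e0 <- wald_ratio(make_pairs(0.5, 0, sy = 0.05))
  expect_equal(e0$beta, 0)
  expect_equal(e0$pvalue, 1)
  # harmonization sign flips leave the ratio unchanged
  e2 <- wald_ratio(make_pairs(-0.5, -0.1, sy = 0.05))
  expect_equal(e2$beta, e$beta)
  expect_error(wald_ratio(make_pairs(0, 0.1)), "exposure effect")
})

test_that("ivw reproduces its closed form and the single-IV reduction", {
  p <- make_pairs(c(0.5, 0.4), c(0.1, 0.08), sy = 0.05)
  e <- mr_ivw(p)
  expect_equal(e$beta, 0.2, tolerance = 1e-12)
  expect_equal(e$se_fixed, sqrt(1 / (0.41 / 0.0025)), tolerance = 1e-12)
  expect_equal(e$se, e$se_fixed)         # zero heterogeneity: no inflation
  one <- make_pairs(0.5, 0.1, sy = 0.05)
  expect_equal(mr_ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(one)$se)
  expect_error(mr_ivw(make_pairs(c(0, 0), c(0.1, 0.2))), "all exposure")
})

test_that("ivw and egger agree with weighted-least-squares oracles", {
  for (s in 1:60) {
    set.seed(s)
    k <- sample(3:10, 1)
    p <- make_pairs(runif(k, 0.1, 0.6) * sample(c(-1, 1), k, TRUE),
                    rnorm(k, 0, 0.2), sy = runif(k, 0.02, 0.1))
    w <- 1 / p$se_outcome^2
    ivw_fit <- mr_ivw(p)
    lm0 <- lm(beta_outcome ~ 0 + beta_exposure, data = p, weights = w)
    expect_equal(ivw_fit$beta, unname(coef(lm0)), tolerance = 1e-10)
    # Egger on non-negatively oriented exposure effects
    flip <- ifelse(p$beta_exposure < 0, -1, 1)
    pe <- p; pe$beta_exposure <- p$beta_exposure * flip
    pe$beta_outcome <- p$beta_outcome * flip
    lm1 <- lm(beta_outcome ~ beta_exposure, data = pe, weights = w)
    egger_fit <- mr_egger(p)
    expect_equal(egger_fit$beta,
                 unname(coef(lm1)["beta_exposure"]), tolerance = 1e-10)
    expect_equal(egger_fit$intercept,
                 unname(coef(lm1)["(Intercept)"]), tolerance = 1e-10)
    sm <- summary(lm1)$coefficients
    expect_equal(egger_fit$se, unname(sm["beta_exposure", 2]),
                 tolerance = 1e-10)
    expect_equal(egger_fit$intercept_p, unname(sm["(Intercept)", 4]),
                 tolerance = 1e-10)
  }
})

test_that("egger recovers an exact linear relation exactly", {
  p <- make_pairs(c(0.2, 0.4, 0.6), c(0.14, 0.24, 0.34), sy = 0.05)
  e <- mr_egger(p)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$intercept, 0.04, tolerance = 1e-12)
  expect_s3_class(mr_egger(make_pairs(c(0.2, 0.4), c(0.1, 0.2))),
                  "mr_estimate")
  expect_false(mr_egger(make_pairs(c(0.2, 0.4), c(0.1, 0.2)))$estimable)
})

test_that("weighted median interpolates the 50% weight crossing", {
  p <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9), sy = 0.05)
  e <- mr_weighted_median(p, n_boot = 50, seed = 1)
  expect_equal(e$beta, 0.2, tolerance = 1e-12)
  # weights concentrated on one instrument pull the estimate to its ratio
  p2 <- make_pairs(c(5, 0.1, 0.1), c(5 * 0.33, 0.01, 0.09), sy = 0.05)
  e2 <- mr_weighted_median(p2, n_boot = 50, seed = 1)
  expect_equal(e2$beta, 0.33, tolerance = 1e-6)
  # independent order-statistic oracle on random instances
  for (s in 1:40) {
    set.seed(s)
    k <- sample(3:10, 1)
    p <- make_pairs(runif(k, 0.2, 0.6), rnorm(k, 0.1, 0.1),
                    sy = runif(k, 0.02, 0.1))
    r <- p$beta_outcome / p$beta_exposure
    w <- p$beta_exposure^2 / p$se_outcome^2
    o <- order(r)
    rs <- r[o]; ws <- w[o] / sum(w)
    s_j <- cumsum(ws) - ws / 2
    want <- if (s_j[1] >= 0.5) rs[1] else if (max(s_j) < 0.5) rs[k] else {
      j <- findInterval(0.5 - 1e-15, s_j)
      rs[j] + (rs[j + 1] - rs[j]) * (0.5 - s_j[j]) / (s_j[j + 1] - s_j[j])
    }
    got <- mr_weighted_median(p, n_boot = 10, seed = s)$beta
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  p <- make_pairs(rep(1, 4), c(0.2, 0.2, 0.2, 0.9), sy = 0.05)
  e <- mr_weighted_mode(p, n_boot = 50, seed = 3)
  expect_lt(abs(e$beta - 0.2), 0.06)
  # identical ratios: exactly that ratio
  pid <- make_pairs(c(0.5, 0.4, 0.2), c(0.15, 0.12, 0.06), sy = 0.05)
  expect_equal(mr_weighted_mode(pid, n_boot = 10, seed = 1)$beta, 0.3,
               tolerance = 1e-12)
  # grid argmax matches a much finer brute-force grid
  for (s in 1:10) {
    set.seed(s)
    k <- 8
    p <- make_pairs(runif(k, 0.2, 0.6), rnorm(k, 0.1, 0.08),
                    sy = runif(k, 0.02, 0.1))
    r <- p$beta_outcome / p$beta_exposure
    w <- p$beta_exposure^2 / p$se_outcome^2
    w <- w / sum(w)
    h <- 0.9 * min(sd(r), mad(r)) * k^(-1 / 5)
    fine <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 8192)
    dens <- vapply(fine, function(x) sum(w * dnorm(x, r, h)), numeric(1))
    want <- fine[which.max(dens)]
    got <- mr_weighted_mode(p, n_boot = 10, seed = s)$beta
    expect_lt(abs(got - want), (max(r) - min(r) + 6 * h) / 500)
  }
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(99)
  k <- 8
  p <- make_pairs(runif(k, 0.2, 0.6), rnorm(k, 0.1, 0.05),
                  sy = runif(k, 0.02, 0.08))
  neg <- p; neg$beta_outcome <- -neg$beta_outcome
  scl <- p; scl$beta_exposure <- 2 * scl$beta_exposure
  for (fun in list(function(q) mr_ivw(q)$beta,
                   function(q) mr_egger(q)$beta,
                   function(q) mr_weighted_median(q, 30, seed = 1)$beta,
                   function(q) mr_weighted_mode(q, 30, seed = 1)$beta)) {
    expect_equal(fun(neg), -fun(p), tolerance = 1e-9)
    expect_equal(fun(scl), fun(p) / 2, tolerance = 1e-9)
  }
})

test_that("fixed-seed fits are bit-reproducible", {
  set.seed(7)
  p <- make_pairs(runif(5, 0.2, 0.5), rnorm(5, 0.1, 0.05))
  f1 <- mr_fit(p, seed = 11, n_boot = 100)
  f2 <- mr_fit(p, seed = 11, n_boot = 100)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("the model object supports the standard accessors", {
  set.seed(8)
  p <- make_pairs(runif(6, 0.2, 0.5), rnorm(6, 0.15, 0.03))
  f <- mr_fit(p, seed = 2, n_boot = 50, exposure_id = "P1",
              outcome_id = "D1")
  expect_named(coef(f), c("ivw", "egger", "weighted_median",
                          "weighted_mode"))
  ci <- confint(f)
  expect_equal(dim(ci), c(4, 2))
  expect_true(all(ci[, 1] < coef(f) & coef(f) < ci[, 2]))
  expect_output(print(f), "P1 -> D1")
  expect_output(print(summary(f)), "Odds ratios")
  expect_equal(length(residuals(f)), 6)
  pdf(NULL)
  expect_invisible(plot(f))
  dev.off()
})
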