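# Synthetic call library: sites x recordings x calls annotation table.
make_library <- function(n_sites, n_rec, n_calls) {
  g <- expand.grid(call = seq_len(n_calls), rec = seq_len(n_rec),
                   site = seq_len(n_sites))
  data.frame(recording_id = sprintf("s%d_r%d", g$site, g$rec),
             start_s = g$call * 2, end_s = g$call * 2 + 0.3,
             n_syllables = 2L, site_id = sprintf("s%d", g$site),
             year = "Y1", group = "lib", stringsAsFactors = FALSE)
}

test_that("training subsets are nested with other axes held constant", {
  lib <- make_library(5, 4, 6)
  subs <- build_training_subsets(lib, "among_site", c(1, 2, 5),
                                 held = list(calls_per_recording = 6,
                                             recordings_per_site = 4,
                                             n_sites = 5), seed = 2)
  sites <- lapply(subs, function(s) unique(s$annotations$site_id))
  expect_length(sites[[1]], 1)
  expect_true(all(sites[[1]] %in% sites[[2]]))
  expect_true(all(sites[[2]] %in% sites[[3]]))
  # call rows nest too
  rows <- lapply(subs, function(s) rownames(s$annotations))
  expect_true(all(rows[[1]] %in% rows[[2]]))
  expect_true(all(rows[[2]] %in% rows[[3]]))
  expect_equal(vapply(subs, function(s) s$total_calls, 0),
               c(1, 2, 5) * 4 * 6)
})

test_that("level one samples a single unit per grouping", {
  lib <- make_library(3, 3, 4)
  s_call <- build_training_subsets(lib, "within_recording", c(1, 2),
                                   held = list(calls_per_recording = 4,
                                               recordings_per_site = 3,
                                               n_sites = 3), seed = 1)
  expect_equal(s_call[[1]]$mean_calls_per_recording, 1)
  expect_equal(s_call[[1]]$total_calls, 9)
})

test_that("achieved counts fall short with a warning when the library is small", {
  lib <- make_library(2, 2, 3)
  expect_warning(
    subs <- build_training_subsets(lib, "among_site", c(1, 2, 4),
                                   held = list(calls_per_recording = 3,
                                               recordings_per_site = 2,
                                               n_sites = 2), seed = 1),
    "fall short")
  expect_equal(subs[[3]]$achieved, 2)
  expect_lt(subs[[3]]$achieved, subs[[3]]$target)
})

test_that("a full-library subset counts every call", {
  lib <- make_library(4, 3, 5)
  subs <- build_training_subsets(lib, "among_site", c(4),
                                 held = list(calls_per_recording = 5,
                                             recordings_per_site = 3,
                                             n_sites = 4), seed = 3)
  expect_equal(subs[[1]]$total_calls, 4 * 3 * 5)
  expect_equal(subs[[1]]$achieved, 4)
})

test_that("beta regression recovers known coefficients", {
  set.seed(31)
  n <- 500
  x <- stats::rnorm(n)
  mu <- stats::plogis(0.4 + 0.9 * x)
  phi <- 15
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  fit <- fit_beta_regression(y, cbind("(Intercept)" = 1, x = x))
  expect_lt(abs(fit$coefficients["(Intercept)"] - 0.4),
            3 * fit$se["(Intercept)"])
  expect_lt(abs(fit$coefficients["x"] - 0.9), 3 * fit$se["x"])
  expect_lt(abs(fit$phi - phi) / phi, 0.25)
  expect_equal(fit$K, 3)
  expect_gt(fit$pseudo_r2, 0.3)
})

test_that("beta regression log-likelihood matches a direct recomputation", {
  set.seed(32)
  y <- stats::rbeta(60, 4, 2)
  fit <- fit_beta_regression(y)
  mu <- stats::plogis(fit$coefficients[1])
  ll <- sum(stats::dbeta(y, mu * fit$phi, (1 - mu) * fit$phi,
                         log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  # intercept-only fit has K = 2 and centres near the logit of the mean
  expect_equal(fit$K, 2)
  expect_lt(abs(mu - mean(y)), 0.05)

  # duplicated data: identical estimates, doubled log-likelihood
  fit2 <- fit_beta_regression(c(y, y))
  expect_equal(unname(fit2$coefficients[1]),
               unname(fit$coefficients[1]), tolerance = 1e-4)
  expect_equal(fit2$loglik, 2 * ll, tolerance = 1e-3)
})

test_that("beta regression agrees with an independent ML implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(33)
  n <- 150
  x <- stats::rnorm(n)
  mu <- stats::plogis(-0.2 + 0.6 * x)
  y <- stats::rbeta(n, mu * 10, (1 - mu) * 10)
  fit <- fit_beta_regression(y, cbind(1, x))
  d <- data.frame(y = y, x = x)
  ref <- suppressWarnings(
    glmmTMB::glmmTMB(y ~ x, data = d,
                     family = glmmTMB::beta_family(link = "logit")))
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
})

test_that("boundary responses are shrunk, invalid inputs rejected", {
  y <- c(0, 0.2, 0.5, 0.9, 1, 0.4, 0.6, 0.7, 0.1, 0.8)
  fit <- fit_beta_regression(y)
  expect_true(is.finite(fit$loglik))
  expect_error(fit_beta_regression(c(-0.1, 0.5, 0.7, 0.2, 0.4, 0.3)),
               "\\[0, 1\\]")
  expect_error(fit_beta_regression(stats::runif(3)), "too few")
  X_bad <- cbind(1, c(2, 2, 2, 2, 2, 2, 2, 2))
  expect_error(fit_beta_regression(stats::runif(8, 0.2, 0.8), X_bad),
               "full rank")
})

test_that("AICc follows its formula and limits", {
  expect_equal(aicc(0, K = 2, n = 10), 4 + 12 / 7)
  # penalty vanishes for large n
  expect_lt(abs(aicc(0, K = 2, n = 1e7) - 4), 1e-5)
  # equal loglik: smaller K wins
  expect_lt(aicc(-10, K = 2, n = 20), aicc(-10, K = 3, n = 20))
  expect_error(aicc(0, K = 5, n = 6), "undefined")
})

test_that("model selection table computes weights and evidence ratios", {
  set.seed(34)
  y <- stats::rbeta(50, 3, 3)
  f1 <- fit_beta_regression(y)
  # identical fits -> equal weights
  tab <- rank_models(list(a = f1, b = f1))
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)

  # frozen delta patterns: 0.08 -> evidence ratio exp(0.04) ~ 1.041;
  # 10.25 -> second weight ~ 0.0059
  w <- exp(-c(0, 0.08) / 2); w <- w / sum(w)
  expect_equal(w, c(0.510, 0.490), tolerance = 1e-3)
  expect_equal(w[1] / w[2], exp(0.04), tolerance = 1e-12)
  w2 <- exp(-c(0, 10.25) / 2); w2 <- w2 / sum(w2)
  expect_equal(w2[2], 0.006, tolerance = 0.02)

  x <- stats::rnorm(50)
  f2 <- fit_beta_regression(y, cbind(1, x))
  tab2 <- rank_models(list(null = f1, x = f2))
  expect_equal(tab2$delta_aicc[1], 0)
  expect_equal(sum(tab2$weight), 1, tolerance = 1e-12)
  expect_equal(tab2$evidence_ratio,
               max(tab2$weight) / tab2$weight, tolerance = 1e-12)
  y2 <- stats::rbeta(40, 3, 3)
  f3 <- fit_beta_regression(y2)
  expect_error(rank_models(list(f1, f3)), "different numbers")
})

test_that("site-dominated worlds favour the among-site model", {
  # recognizer-level responses where the site axis drives the metric:
  # among-site AICc should beat among-recording AICc in most replicates
  set.seed(35)
  wins <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    n_sites_lv <- c(1, 2, 5, 8, 11, 14, 17, 20, 23, 25, 28)
    n_rec_lv <- c(1, 2, 4, 6, 8, 9, 10, 11, 13, 14, 15)
    n <- length(n_sites_lv) + length(n_rec_lv)
    sites <- c(n_sites_lv, rep(15, length(n_rec_lv)))
    recs <- c(rep(8, length(n_sites_lv)), n_rec_lv)
    mu <- stats::plogis(-0.3 + 0.05 * sites + 0 * recs)
    y <- stats::rbeta(n, mu * 40, (1 - mu) * 40)
    f_site <- fit_beta_regression(y, cbind(1, sites))
    f_rec <- fit_beta_regression(y, cbind(1, recs))
    if (f_site$aicc < f_rec$aicc) wins <- wins + 1
  }
  expect_gt(wins, n_rep / 2)
})
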