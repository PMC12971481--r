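test_that("the probit translation maps acoustic to app detection", {
  identity <- translation_params(0, 0, 0, 0, 1)
  d <- c(0.1, 0.4, 0.9)
  expect_equal(d_mk(identity, rep("direct", 3), rep(1.5, 3), d), d,
               tolerance = 1e-9)
  half <- translation_params(0.5, 0, 0, 0, 1)
  expect_equal(d_mk(half, "interval", 0, 0.5), pnorm(0.5), tolerance = 1e-12)
  p <- translation_params(0, 0.6, 0, 0, 0.5)
  x <- seq(-1, 3, by = 0.5)
  out <- d_mk(p, rep("direct", length(x)), x, rep(0.3, length(x)))
  expect_true(all(diff(out) > 0))
  expect_warning(d_mk(identity, "direct", 0, 1), "clamped")
})

test_that("the translation objective matches its analytic pieces", {
  expect_equal(translation_neg_log_posterior(rep(0, 5), numeric(0),
                                             character(0), numeric(0),
                                             numeric(0), numeric(0)), 0)
  # one record, Y = 1, m = s = 1, d_mk = Phi(0) = 0.5
  v <- translation_neg_log_posterior(c(0, 0, 0, 0, 1), 1, "direct", 0, 0.5, 1)
  expect_equal(v, -log(0.5) + 1 / 50, tolerance = 1e-12)

  withr::with_seed(41, {
    n <- 50
    y <- rbinom(n, 1, 0.5)
    rt <- sample(c("direct", "interval", "point"), n, replace = TRUE)
    x <- rnorm(n)
    dp <- runif(n, 0.05, 0.9)
    ms <- runif(n, 0.3, 1)
    par <- rnorm(5, 0, 0.5)
    g <- birdtwin:::translation_gradient(par, y, rt, x, dp, ms)
    # central finite-difference oracle
    fd <- vapply(1:5, function(j) {
      h <- 1e-6
      e <- replace(rep(0, 5), j, h)
      (translation_neg_log_posterior(par + e, y, rt, x, dp, ms) -
         translation_neg_log_posterior(par - e, y, rt, x, dp, ms)) / (2 * h)
    }, 0)
    expect_equal(g, fd, tolerance = 1e-5)
  })
})

test_that("the translation MAP minimises and respects symmetries", {
  withr::with_seed(43, {
    n <- 4000
    truth <- translation_params(0.4, 0.6, 0.25, 0.4, 0.8)
    rt <- sample(c("direct", "interval", "point"), n, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
    x <- ifelse(rt == "direct", log(pmax(rlnorm(n, log(0.55), 0.5), 0.1)),
                ifelse(rt == "interval", 0, log(5)))
    dp <- runif(n, 0.05, 0.7)
    ms <- runif(n, 0.3, 1)
    y <- rbinom(n, 1, ms * d_mk(truth, rt, x, dp))
    rec <- tibble::tibble(rec_type = rt, log_duration = x, sp = y)
    fit <- fit_translation(rec, "sp", dp, ms)
    expect_true(fit$converged)
    expect_lt(fit$grad_norm, 1e-6)

    obj <- function(par) translation_neg_log_posterior(par, y, rt, x, dp, ms)
    v_hat <- obj(birdtwin:::as_translation_vector(fit$params))
    expect_lte(v_hat, obj(rep(0, 5)) + 1e-8)
    expect_lte(v_hat, obj(birdtwin:::as_translation_vector(truth)) + 1e-8)

    # doubling the data pulls the MAP toward the MLE: the likelihood part
    # of the objective (prior removed) cannot get worse
    rec2 <- dplyr::bind_rows(rec, rec)
    fit2 <- fit_translation(rec2, "sp", c(dp, dp), c(ms, ms))
    like <- function(par) obj(par) - sum(par^2) / 50
    expect_lte(like(birdtwin:::as_translation_vector(fit2$params)),
               like(birdtwin:::as_translation_vector(fit$params)) + 1e-6)

    # gamma = 0 makes the model ignore the acoustic probabilities
    g0 <- translation_params(0.2, 0.3, 0.1, 0.2, 0)
    expect_equal(d_mk(g0, rt, x, dp), d_mk(g0, rt, x, sample(dp)),
                 tolerance = 1e-15)

    # record order cannot matter
    ord <- sample(n)
    fit3 <- fit_translation(rec[ord, ], "sp", dp[ord], ms[ord])
    expect_equal(birdtwin:::as_translation_vector(fit3$params),
                 birdtwin:::as_translation_vector(fit$params),
                 tolerance = 1e-6)
  })
  expect_error(fit_translation(tibble::tibble(rec_type = "direct",
                                              log_duration = 0, sp = 0),
                               "sp", 0.5, 1), "at least one detection")
})

test_that("translation fits tidy, glance and round-trip through CSV", {
  withr::with_seed(47, {
    n <- 800
    rt <- sample(c("direct", "interval", "point"), n, replace = TRUE)
    rec <- tibble::tibble(rec_type = rt, log_duration = rnorm(n),
                          sp = rbinom(n, 1, 0.3))
    fit <- fit_translation(rec, "sp", runif(n, 0.1, 0.6), runif(n, 0.4, 1))
    td <- tidy(fit)
    expect_equal(td$term, c("alpha", "beta_direct", "beta_interval",
                            "beta_point", "gamma"))
    expect_true(glance(fit)$converged)
    path <- withr::local_tempfile(fileext = ".csv")
    write_translation_params(
      tibble::tibble(species_id = "sp", !!!as.list(td$estimate) |>
                       rlang::set_names(td$term), fit_year = 2024L), path)
    expect_equal(read_translation_params(path)$gamma, td$estimate[5])
  })
})
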