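# hand-rolled conditional-logit probability for the brute-force oracles:
# builds the encoded matrix from first principles for the tiny space
# (asc, pol dummy, fee) and multiplies softmax terms task by task
oracle_clogit_ll <- function(df, beta) {
  X <- cbind(asc = df$left_asc, pol = as.numeric(df$pol == "act"), fee = df$fee)
  u <- drop(X %*% beta)
  ll <- 0
  for (key in unique(paste(df$resp_id, df$task))) {
    rows <- paste(df$resp_id, df$task) == key
    p <- exp(u[rows]) / sum(exp(u[rows]))
    ll <- ll + log(p[df$chosen[rows] == 1])
  }
  ll
}

tiny_dataset <- function(n_resp = 2, a = 3, seed = 61, beta_pol = 0.6) {
  d <- paired_tiny_design(a = a)
  pr <- tiny_profiles(n_resp, seed = seed)
  nm <- predictor_names(tiny_space())
  simulate_choices(d, pr, simulation_config(
    beta = setNames(c(0.1, beta_pol, -0.05), nm)), seed = seed + 1)
}

test_that("conditional-logit log-likelihood matches brute-force products", {
  dat <- tiny_dataset(n_resp = 1, a = 3)
  df <- as.data.frame(dat)
  for (beta in list(c(0, 0, 0), c(0.2, 0.6, -0.04), c(-1, 2, 0.1))) {
    expect_equal(clogit_loglik(dat, setNames(beta, predictor_names(tiny_space()))),
                 oracle_clogit_ll(df, beta), tolerance = 1e-12)
  }
})

test_that("zero coefficients on binary tasks give -N log 2", {
  dat <- tiny_dataset(n_resp = 4, a = 5)
  ll <- clogit_loglik(dat, setNames(rep(0, 3), predictor_names(tiny_space())))
  expect_equal(ll, -20 * log(2), tolerance = 1e-12)
})

test_that("perfect separation drives the log-likelihood to zero", {
  d <- paired_tiny_design(a = 4)
  pr <- tiny_profiles(3, seed = 71)
  nm <- predictor_names(tiny_space())
  dat <- simulate_choices(d, pr, simulation_config(
    beta = setNames(c(0, 50, 0), nm)), seed = 72)
  # every chosen alternative carries the dummy; a huge coefficient fits
  stopifnot(all(as.data.frame(dat)$chosen[as.data.frame(dat)$pol == "act"] == 1))
  ll <- clogit_loglik(dat, setNames(c(0, 200, 0), nm))
  expect_lte(ll, 0)
  expect_gt(ll, -1e-10)
})

test_that("Newton conditional logit agrees with survival::clogit", {
  library(survival)
  dat <- small_npi_data()$data
  own <- fit_clogit(dat)
  expect_true(own$converged)
  enc <- dcemix:::encode_choice_data(dat)
  strat <- rep(seq_len(enc$n_task), diff(enc$task_start))
  df <- data.frame(y = 0, enc$X, strat = strat, check.names = FALSE)
  df$y[enc$chosen_row + 1] <- 1
  ref <- survival::clogit(
    y ~ asc_left + masks.indoors + masks.public + dining.five_people +
      dining.two_people + dining.not_allowed + vocalization.not_allowed +
      events.not_allowed + quarantine.home + quarantine.government_facility +
      booster.compulsory + fee + survival::strata(strat),
    data = as.data.frame(lapply(df, as.numeric)))
  expect_equal(unname(own$coef), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(own$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("the simulated likelihood collapses to the conditional logit at sigma 0", {
  dat <- tiny_dataset(n_resp = 6, a = 4)
  nm <- predictor_names(tiny_space())
  beta <- setNames(c(0.1, 0.5, -0.03), nm)
  cl <- clogit_loglik(dat, beta)
  for (R in c(1, 25, 200)) {
    p0 <- mxl_parameters(beta, sigma = c(pol.act = 0))
    expect_equal(mxl_loglik(dat, p0, R = R, seed = 3), cl, tolerance = 1e-12)
  }
  # and with an empty random set
  expect_equal(mxl_loglik(dat, mxl_parameters(beta), R = 10, seed = 3), cl,
               tolerance = 1e-12)
})

test_that("simulated likelihood matches Gauss-Hermite quadrature", {
  # one respondent, one binary task, one random coefficient: the chosen
  # alternative's probability is the normal mixture of a logistic
  d <- paired_tiny_design(a = 1)
  pr <- tiny_profiles(1, seed = 81)
  nm <- predictor_names(tiny_space())
  dat <- simulate_choices(d, pr, simulation_config(
    beta = setNames(c(0, 3, 0), nm)), seed = 82)
  df <- as.data.frame(dat)
  chose_act <- df$chosen[df$pol == "act"] == 1
  b <- 0.8; s <- 1.1
  gh <- pracma::gaussHermite(64)
  integrand <- plogis((b + s * sqrt(2) * gh$x) * if (chose_act) 1 else -1)
  exact <- sum(gh$w * integrand) / sqrt(pi)
  params <- mxl_parameters(setNames(c(0, b, 0), nm), sigma = c(pol.act = s))
  sim <- mxl_loglik(dat, params, R = 2000, seed = 83)
  expect_lt(abs(sim - log(exact)), 1e-3)
})

test_that("simulated likelihood is draw-deterministic and sign-invariant in sigma", {
  dat <- tiny_dataset(n_resp = 8, a = 4)
  nm <- predictor_names(tiny_space())
  params <- mxl_parameters(setNames(c(0, 0.5, -0.02), nm), sigma = c(pol.act = 0.7))
  l1 <- mxl_loglik(dat, params, R = 100, seed = 5)
  l2 <- mxl_loglik(dat, params, R = 100, seed = 5)
  expect_identical(l1, l2)
  expect_false(identical(l1, mxl_loglik(dat, params, R = 100, seed = 6)))
  # sign of sigma is irrelevant (evaluated below the public abs barrier)
  enc <- dcemix:::encode_choice_data(dat)
  dr <- halton_normal_draws(enc$n_resp, 50, 1, seed = 7)
  sp <- dcemix:::msl_eval(enc, params$beta, c(pol.act = 0.7), R = 50, draws = dr)
  sn <- dcemix:::msl_eval(enc, params$beta, c(pol.act = -0.7), R = 50, draws = dr)
  expect_false(identical(sp$S, sn$S))        # draws enter with flipped sign
  expect_equal(sum(log(sp$S)), sum(log(sn$S)), tolerance = 1e-9)
})

test_that("the simulated likelihood converges as draws increase", {
  dat <- tiny_dataset(n_resp = 5, a = 6)
  nm <- predictor_names(tiny_space())
  params <- mxl_parameters(setNames(c(0, 0.6, -0.03), nm), sigma = c(pol.act = 0.9))
  ref <- mxl_loglik(dat, params, R = 20000, seed = 9)
  errs <- vapply(c(250, 1000, 4000), function(R) {
    abs(mxl_loglik(dat, params, R = R, seed = 9) - ref)
  }, 0)
  expect_identical(order(errs, decreasing = TRUE), 1:3)
  expect_lt(errs[3], 1e-3)
})

test_that("a sigma-free MXL fit reproduces the Newton conditional logit", {
  dat <- small_npi_data()$data
  cl <- fit_clogit(dat)
  fit <- fit_mxl(dat, random_set = character(0), R = 5, seed = 2, se = "none")
  expect_true(fit$convergence)
  expect_equal(unname(fit$params$beta), unname(cl$coef), tolerance = 1e-4)
  expect_equal(fit$loglik, cl$loglik, tolerance = 1e-6)
})

test_that("MXL fits recover structure on a moderate panel", {
  fit <- small_mxl_fit()
  expect_true(fit$convergence)
  expect_s3_class(fit, "mxl_fit")
  # likelihood improves on the conditional-logit start
  expect_gte(fit$loglik, fit$clogit$loglik - 1e-6)
  expect_lte(fit$loglik, 0)
  tab <- fit$coefficients
  expect_equal(tab$ci_low, tab$estimate - 1.96 * tab$se)
  expect_equal(tab$ci_high, tab$estimate + 1.96 * tab$se)
  expect_true(all(tab$estimate[tab$type == "sd"] >= 0))
  # the dominant signs of the generating process come through
  expect_gt(fit$params$beta[["masks.public"]], 0)
  expect_lt(fit$params$beta[["dining.not_allowed"]], 0)
  expect_lt(fit$params$beta[["fee"]], 0)
})

test_that("rescaling the fee divides its coefficient and preserves WTP", {
  base <- small_npi_data()
  df <- as.data.frame(base$data)
  sp2 <- attribute_space(
    categorical = lapply(npi_attribute_space()$attributes[1:6], `[[`, "levels"),
    cost_name = "fee", cost_levels = c(0, 10, 30, 50) * 2
  )
  names(sp2$attributes)[1:6] <- names(npi_attribute_space()$attributes)[1:6]
  df2 <- df
  df2$fee <- df$fee * 2
  dat2 <- choice_data(df2, sp2)
  f1 <- fit_mxl(base$data, R = 60, seed = 23)
  f2 <- fit_mxl(dat2, R = 60, seed = 23)
  expect_equal(f2$params$beta[["fee"]], f1$params$beta[["fee"]] / 2,
               tolerance = 1e-3)
  # doubling the recorded fee halves its coefficient; WTP doubles in the new
  # fee units, i.e. is unchanged in money terms (one new unit = half the money)
  w1 <- compute_wtp(f1)
  w2 <- compute_wtp(f2)
  expect_equal(w2$wtp / 2, w1$wtp, tolerance = 1e-3)
})

test_that("recovery error shrinks as the panel grows", {
  # alternate which side shows the active policy, so the left ASC is not
  # collinear with the policy dummy
  lv <- do.call(rbind, lapply(1:6, function(t) {
    if (t %% 2) rbind(c(2L, 1L), c(1L, 1L)) else rbind(c(1L, 1L), c(2L, 1L))
  }))
  d <- manual_design(tiny_space(), lv, B = 1, a = 6, t = 2)
  nm <- predictor_names(tiny_space())
  truth <- setNames(c(0, 0.8, -0.05), nm)
  cfg <- simulation_config(beta = truth, sigma = c(pol.act = 0.5))
  err_at <- function(n) {
    mean(vapply(1:3, function(r) {
      pr <- tiny_profiles(n, seed = 300 + r)
      dat <- simulate_choices(d, pr, cfg, seed = 400 + r)
      fit <- fit_mxl(dat, random_set = "pol.act", R = 50, seed = 500 + r,
                     se = "none")
      abs(fit$params$beta[["pol.act"]] - truth[["pol.act"]])
    }, 0))
  }
  expect_gte(err_at(80), err_at(800))
})
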