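#' Default sociodemographic marginals of the reference population
#'
#' Marginal distributions used by [simulate_profiles()]: the sociodemographic
#' composition of the Singapore online-panel sample behind the package's
#' reference application (n = 1552 respondents; 58.2% female, 84.7% Chinese
#' ethnicity, 92.8% with three or more COVID-19 vaccine doses, mean age 48
#' years (SD 14, truncated at the eligibility age of 18), mean 13-item Health
#' Risk Attitude Scale sum score 42 (SD 8)). Categorical fields are drawn
#' independently; no cross-tabulations are emulated.
#'
#' @return named list of probability vectors and moment parameters.
#' @export
default_profile_marginals <- function() {
  list(
    sex        = c(female = 0.582, male = 0.418),
    ethnicity  = c(chinese = 0.847, non_chinese = 0.153),
    education  = c(secondary_or_below = 0.216, post_secondary = 0.268,
                   university = 0.516),
    housing    = c(hdb_1_3 = 0.221, hdb_4_5_or_private = 0.779),
    marital    = c(unmarried = 0.353, married = 0.647),
    parental   = c(no_children = 0.397, children = 0.603),
    employment = c(full_time = 0.568, self_employed = 0.086,
                   homemaker = 0.062, other = 0.284),
    vaccine_shots = c(shots_0_2 = 0.072, shots_3_plus = 0.928),
    age_mean = 48, age_sd = 14, age_min = 18,
    hras_mean = 42, hras_sd = 8
  )
}

#' Simulate a table of respondent profiles
#'
#' Draws `n` synthetic respondents with independent categorical covariates
#' from the supplied marginals, age from a normal distribution truncated
#' below at the eligibility age, and a continuous health-risk-attitude score
#' from a normal distribution.
#'
#' @param n number of respondents.
#' @param marginals list as returned by [default_profile_marginals()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return data.frame with one row per respondent: `id`, factor covariates
#'   (reference category first), `age`, `hras`.
#' @export
simulate_profiles <- function(n, marginals = default_profile_marginals(), seed = 1) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  cat_fields <- c("sex", "ethnicity", "education", "housing", "marital",
                  "parental", "employment", "vaccine_shots")
  for (f in cat_fields) {
    p <- marginals[[f]]
    if (is.null(p) || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
      stop("invalid marginals for '", f, "': probabilities must lie in [0,1] and sum to 1",
           call. = FALSE)
    }
  }
  out <- with_seed(seed, {
    df <- data.frame(id = seq_len(n))
    for (f in cat_fields) {
      p <- marginals[[f]]
      lab <- names(p)
      v <- if (n > 0) sample(lab, n, replace = TRUE, prob = p) else character(0)
      df[[f]] <- factor(v, levels = lab)
    }
    # inverse-CDF truncated normal keeps the draw count fixed (reproducible)
    lo <- stats::pnorm(marginals$age_min, marginals$age_mean, marginals$age_sd)
    df$age <- stats::qnorm(stats::runif(n, lo, 1), marginals$age_mean, marginals$age_sd)
    df$hras <- stats::rnorm(n, marginals$hras_mean, marginals$hras_sd)
    df
  })
  out
}

#' Class-membership covariate matrix
#'
#' Builds the design matrix of the class-membership multinomial logit from a
#' profile table: an intercept, a dummy per non-reference category of each
#' factor covariate, age in decades centred at 48 years, and the
#' health-risk-attitude score centred at 42 and scaled by 8 points (one
#' reference SD). Centring/scaling only conditions the optimisation; odds
#' ratios for the dummies are unaffected.
#'
#' @param profiles data.frame from [simulate_profiles()] (or with the same
#'   columns).
#' @param covariates character vector of profile columns to include; default
#'   is the full set.
#' @return numeric matrix, one row per respondent, first column `intercept`.
#' @export
class_covariates <- function(profiles,
                             covariates = c("sex", "ethnicity", "marital",
                                            "parental", "education", "housing",
                                            "employment", "vaccine_shots",
                                            "age", "hras")) {
  missing_cov <- setdiff(covariates, names(profiles))
  if (length(missing_cov)) {
    stop("covariates missing from profiles: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  Z <- matrix(1, nrow(profiles), 1, dimnames = list(NULL, "intercept"))
  for (f in covariates) {
    v <- profiles[[f]]
    if (f == "age") {
      Z <- cbind(Z, age_decades = (v - 48) / 10)
    } else if (f == "hras") {
      Z <- cbind(Z, hras_sd = (v - 42) / 8)
    } else {
      v <- as.factor(v)
      for (l in levels(v)[-1]) {
        col <- matrix(as.numeric(v == l), ncol = 1,
                      dimnames = list(NULL, paste(f, l, sep = ".")))
        Z <- cbind(Z, col)
      }
    }
  }
  Z
}

#' Assign latent-class labels from a membership model
#'
#' Draws a class label for each respondent from the multinomial-logit
#' probabilities implied by membership coefficients `gamma` on the profile
#' covariates. Class 1 is the reference (coefficient vector fixed at zero).
#'
#' @param profiles respondent table.
#' @param gamma numeric matrix with one row per non-reference class; columns
#'   must be named after columns of [class_covariates()] (an `intercept`
#'   column is allowed). A vector is taken as the single non-reference class
#'   of a 2-class model.
#' @param seed integer seed.
#' @param covariates covariate subset passed to [class_covariates()];
#'   defaults to the columns named in `gamma`.
#' @return integer vector of class labels in `1:(nrow(gamma)+1)`.
#' @export
assign_classes <- function(profiles, gamma, seed = 1, covariates = NULL) {
  pi <- class_membership_probs(profiles, gamma, covariates)
  with_seed(seed, {
    u <- stats::runif(nrow(pi))
    cum <- t(apply(pi, 1, cumsum))
    as.integer(rowSums(u > cum) + 1L)
  })
}

# multinomial-logit membership probabilities; class 1 = reference
class_membership_probs <- function(profiles, gamma, covariates = NULL) {
  if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = 1,
                                           dimnames = list(NULL, names(gamma)))
  if (is.null(colnames(gamma))) stop("gamma needs named columns", call. = FALSE)
  if (is.null(covariates)) {
    # derive the profile fields gamma actually references
    cn <- setdiff(colnames(gamma), "intercept")
    covariates <- unique(vapply(cn, function(s) {
      if (s == "age_decades") "age" else if (s == "hras_sd") "hras"
      else sub("\\..*$", "", s)
    }, ""))
  }
  Zfull <- class_covariates(profiles, covariates)
  bad <- setdiff(colnames(gamma), colnames(Zfull))
  if (length(bad)) stop("unknown membership covariates: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  Z <- Zfull[, colnames(gamma), drop = FALSE]
  eta <- cbind(0, Z %*% t(gamma))          # reference class first
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Simulation configuration for the random-utility choice model
#'
#' Bundles the parameters of the data-generating utility model
#' U = x'beta_i + eps, beta_i = beta + eta_i: population taste means `beta`
#' (one entry per encoded predictor, including the left ASC and the fee),
#' heterogeneity SDs `sigma` for the predictors in `random_set` (eta_i is
#' diagonal multivariate normal), and optionally K latent classes, each with
#' its own means/SDs, whose membership follows a multinomial logit with
#' coefficients `gamma` on respondent covariates. The noise eps is i.i.d.
#' type-1 extreme value (Gumbel) per respondent-task-alternative.
#'
#' @param beta named numeric vector of taste means.
#' @param sigma named numeric vector of heterogeneity SDs (entries >= 0);
#'   names define `random_set`. Use `numeric(0)` for a fixed-coefficient
#'   model.
#' @param classes optional list of `list(beta=, sigma=)` per class; overrides
#'   `beta`/`sigma` when present.
#' @param gamma membership coefficient matrix (see [assign_classes()]);
#'   required when `classes` is given.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(beta, sigma = numeric(0), classes = NULL, gamma = NULL) {
  if (any(sigma < 0)) stop("sigma must be >= 0 elementwise", call. = FALSE)
  if (length(sigma) && is.null(names(sigma))) {
    stop("sigma must be named after predictors", call. = FALSE)
  }
  if (!is.null(classes)) {
    if (is.null(gamma)) stop("class simulation needs membership coefficients `gamma`",
                             call. = FALSE)
    for (cl in classes) {
      if (any(cl$sigma < 0)) stop("class sigma must be >= 0", call. = FALSE)
    }
  }
  structure(list(beta = beta, sigma = sigma, classes = classes, gamma = gamma),
            class = "simulation_config")
}

#' Reference taste parameters of the NPI application
#'
#' Coefficient patterns used as the package's simulation-truth defaults.
#' `"pooled"` returns the population-level pattern of the reference
#' mixed-logit analysis (mask mandates valued, strict dining limits and
#' facility quarantine opposed, fee coefficient -0.02 per SGD, slight
#' left-position aversion), with heterogeneity SD 0.8 on the five predictors
#' that showed individual-level preference heterogeneity (both mask levels,
#' full dining prohibition, facility quarantine, booster mandate).
#' `"two_class"` returns the two-segment pattern: a pro-NPI class (strong
#' mask support) and an anti-NPI class, about 39/61 in size, with membership
#' driven by an intercept and a male dummy (men more likely anti-NPI), and
#' within-class heterogeneity SD 0.5 on the same five predictors.
#'
#' @param model `"pooled"` or `"two_class"`.
#' @return a `simulation_config`.
#' @export
npi_simulation_config <- function(model = c("pooled", "two_class")) {
  model <- match.arg(model)
  nm <- predictor_names(npi_attribute_space())
  pooled <- c(asc_left = -0.08,
              masks.indoors = 0.59, masks.public = 0.54,
              dining.five_people = 0.19, dining.two_people = -0.33,
              dining.not_allowed = -0.89,
              vocalization.not_allowed = -0.05, events.not_allowed = -0.07,
              quarantine.home = 0.10, quarantine.government_facility = -0.37,
              booster.compulsory = 0.03, fee = -0.02)
  stopifnot(identical(sort(names(pooled)), sort(nm)))
  random_set <- c("masks.indoors", "masks.public", "dining.not_allowed",
                  "quarantine.government_facility", "booster.compulsory")
  if (model == "pooled") {
    sig <- rep(0.8, length(random_set)); names(sig) <- random_set
    return(simulation_config(beta = pooled[nm], sigma = sig))
  }
  class1 <- c(asc_left = -0.19,
              masks.indoors = 1.76, masks.public = 1.98,
              dining.five_people = 0.49, dining.two_people = 0.18,
              dining.not_allowed = -0.51,
              vocalization.not_allowed = -0.06, events.not_allowed = 0.21,
              quarantine.home = 0.56, quarantine.government_facility = 0.35,
              booster.compulsory = -0.02, fee = -0.02)
  class2 <- c(asc_left = 0.11,
              masks.indoors = 0.04, masks.public = -0.37,
              dining.five_people = -0.08, dining.two_people = -0.87,
              dining.not_allowed = -1.72,
              vocalization.not_allowed = -0.12, events.not_allowed = -0.29,
              quarantine.home = -0.19, quarantine.government_facility = -1.01,
              booster.compulsory = -0.02, fee = -0.04)
  sig <- rep(0.5, length(random_set)); names(sig) <- random_set
  gamma <- matrix(c(0.13, 0.8), nrow = 1,
                  dimnames = list(NULL, c("intercept", "sex.male")))
  simulation_config(
    beta = pooled[nm], sigma = sig,
    classes = list(list(beta = class1[nm], sigma = sig),
                   list(beta = class2[nm], sigma = sig)),
    gamma = gamma
  )
}

#' Simulate panel choices from a design and a utility model
#'
#' Assigns each respondent to one design block uniformly at random, draws the
#' respondent's taste vector once (class mean plus independent normal
#' deviations on the random predictors), computes the utility of every
#' alternative of every task in the block, adds i.i.d. Gumbel noise, and
#' marks the maximum-utility alternative as chosen.
#'
#' @param design a `choice_design`.
#' @param profiles respondent table ([simulate_profiles()]); one simulated
#'   respondent per row.
#' @param config a `simulation_config`.
#' @param seed integer seed controlling block assignment, class labels, taste
#'   draws and noise.
#' @return a `choice_data` data.frame (one row per respondent-task-
#'   alternative) with attributes `space` and, for class models,
#'   `true_classes`.
#' @export
simulate_choices <- function(design, profiles, config, seed = 1) {
  stopifnot(inherits(design, "choice_design"), inherits(config, "simulation_config"))
  n <- nrow(profiles)
  sp <- design$space
  nm <- predictor_names(sp)
  if (!identical(sort(names(config$beta)), sort(nm))) {
    stop("config beta names do not match the encoded predictors of the design",
         call. = FALSE)
  }
  Xd <- encoded_design_matrix(design)[, nm, drop = FALSE]
  ddf <- as.data.frame(design)
  dims <- design$dims

  with_seed(seed, {
    block_of <- sample.int(dims$B, n, replace = TRUE)
    K <- if (is.null(config$classes)) 1L else length(config$classes)
    labels <- if (K > 1) {
      pi <- class_membership_probs(profiles, config$gamma)
      u <- stats::runif(n)
      cum <- t(apply(pi, 1, cumsum))
      as.integer(rowSums(u > cum) + 1L)
    } else rep(1L, n)

    rows_of_block <- lapply(seq_len(dims$B), function(b) which(design$block == b))
    rpt <- dims$a * dims$t
    out_rows <- integer(n * rpt)
    chosen <- numeric(n * rpt)
    resp_col <- integer(n * rpt)
    for (i in seq_len(n)) {
      rows <- rows_of_block[[block_of[i]]]
      if (K > 1) {
        beta_i <- config$classes[[labels[i]]]$beta[nm]
        sig <- config$classes[[labels[i]]]$sigma
      } else {
        beta_i <- config$beta[nm]
        sig <- config$sigma
      }
      if (length(sig)) {
        beta_i[names(sig)] <- beta_i[names(sig)] + sig * stats::rnorm(length(sig))
      }
      u <- Xd[rows, , drop = FALSE] %*% beta_i
      eps <- -log(-log(stats::runif(length(rows))))
      util <- u + eps
      um <- matrix(util, nrow = dims$t)          # column per task
      pick <- max.col(t(um), ties.method = "first")
      ch <- numeric(length(rows))
      ch[(seq_len(dims$a) - 1L) * dims$t + pick] <- 1
      at <- (i - 1L) * rpt + seq_len(rpt)
      out_rows[at] <- rows
      chosen[at] <- ch
      resp_col[at] <- i
    }
    df <- ddf[out_rows, , drop = FALSE]
    rownames(df) <- NULL
    df <- cbind(resp_id = profiles$id[resp_col], df)
    df$chosen <- chosen
    structure(df, space = sp, true_classes = if (K > 1) labels else NULL,
              class = c("choice_data", class(df)))
  })
}
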