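#' Parameters of the mixed-mixed multinomial logit
#'
#' A K-class finite mixture of panel mixed logits: each class c has its own
#' taste means `beta_c` and heterogeneity SDs `sigma_c` (same random set in
#' every class), and class membership follows a multinomial logit on
#' respondent covariates with coefficients `gamma` (class 1 is the reference
#' with coefficients fixed at zero). With K = 1 the model collapses to the
#' plain mixed logit.
#'
#' @param class_means list of K named mean vectors (or a single vector for
#'   K = 1).
#' @param class_sds list of K named SD vectors (>= 0), all with the same
#'   names (the random set).
#' @param gamma (K-1) x m membership coefficient matrix with named columns
#'   (see [class_covariates()]); omit for K = 1.
#' @return an `mmml_parameters` object.
#' @export
mmml_parameters <- function(class_means, class_sds, gamma = NULL) {
  if (!is.list(class_means)) class_means <- list(class_means)
  if (!is.list(class_sds)) class_sds <- list(class_sds)
  K <- length(class_means)
  if (length(class_sds) != K) stop("need one SD vector per class", call. = FALSE)
  if (K > 1) {
    if (is.null(gamma)) stop("K > 1 needs membership coefficients `gamma`",
                             call. = FALSE)
    if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = 1,
                                             dimnames = list(NULL, names(gamma)))
    if (nrow(gamma) != K - 1) stop("gamma needs K-1 rows", call. = FALSE)
  }
  rs <- names(class_sds[[1]])
  for (s in class_sds) {
    if (!identical(names(s), rs)) stop("all classes must share one random set",
                                       call. = FALSE)
  }
  structure(list(class_means = class_means, class_sds = lapply(class_sds, abs),
                 gamma = gamma, K = K, random_set = rs),
            class = "mmml_parameters")
}

#' Simulated log-likelihood of the mixed-mixed multinomial logit
#'
#' For each respondent: the membership probabilities pi_c implied by their
#' covariates weight the class-specific simulated panel mixed-logit
#' probabilities, and the log of the weighted sum is accumulated. With K = 1
#' this equals [mxl_loglik()] exactly (shared draws).
#'
#' @param data a `choice_data` object.
#' @param profiles respondent covariate table (rows matched to respondents
#'   by `id` against `resp_id`).
#' @param params an `mmml_parameters` object.
#' @param R draws per respondent.
#' @param seed draw seed (ignored when `draws` given).
#' @param draws optional draw array shared across classes.
#' @return scalar simulated log-likelihood.
#' @export
mmml_loglik <- function(data, profiles, params, R = 500, seed = 1, draws = NULL) {
  stopifnot(inherits(params, "mmml_parameters"))
  enc <- encode_choice_data(data)
  q <- length(params$random_set)
  if (!is.null(draws)) R <- dim(draws)[2]
  if (is.null(draws)) {
    draws <- if (q > 0) halton_normal_draws(enc$n_resp, R, q, seed = seed)
             else array(0, dim = c(0, R, enc$n_resp))
  }
  S <- matrix(0, enc$n_resp, params$K)
  for (k in seq_len(params$K)) {
    ms <- msl_eval(enc, params$class_means[[k]], params$class_sds[[k]],
                   R = R, draws = draws, want_grad = FALSE)
    S[, k] <- ms$S
  }
  pi <- mixture_priors(profiles, params, enc)
  sum(log(pmax(rowSums(pi * S), 1e-300)))
}

# membership priors aligned to the respondent index order of the encoding
mixture_priors <- function(profiles, params, enc) {
  if (params$K == 1) return(matrix(1, enc$n_resp, 1))
  ord <- match(enc$resp_ids, profiles$id)
  if (anyNA(ord)) stop("profiles are missing respondents present in the choice data",
                       call. = FALSE)
  class_membership_probs(profiles[ord, , drop = FALSE], params$gamma)
}

#' Fit a mixed-mixed multinomial logit
#'
#' Direct BFGS maximisation of the simulated mixture likelihood with analytic
#' gradients: class-specific taste means and SDs plus membership coefficients
#' are estimated jointly. Multiple starts guard against local maxima: the
#' first start splits the mixed-logit solution along `relabel_by` (one class
#' shifted up, one down), the remaining starts add seeded normal noise.
#' After fitting, classes are relabelled in decreasing order of their
#' `relabel_by` mean so that reported class 1 is the most pro-intervention
#' segment, resolving label switching.
#'
#' @param data a `choice_data` object.
#' @param profiles respondent covariate table.
#' @param K number of latent classes (>= 1).
#' @param covariates profile columns entering the membership model (default:
#'   the full covariate set of [class_covariates()]).
#' @param random_set predictors with within-class heterogeneity (default as
#'   in [fit_mxl()]).
#' @param R draws per respondent (default 500).
#' @param seed integer seed (draws and start noise).
#' @param n_starts number of optimisation starts for K > 1 (default 5).
#' @param se standard-error method as in [fit_mxl()].
#' @param relabel_by predictor whose class means order the labels (default
#'   `"masks.public"` when present).
#' @param mxl_fit optional pre-computed K = 1 fit used for starting values.
#' @param control passed to [stats::optim()].
#' @return an `mmml_fit` object: per-class coefficient tables, membership
#'   coefficients with odds ratios, class shares, per-respondent posterior
#'   class probabilities, log-likelihood, BIC, convergence flag.
#' @export
fit_mmml <- function(data, profiles, K = 2, covariates = NULL, random_set = NULL,
                     R = 500, seed = 1, n_starts = 5,
                     se = c("hessian", "bhhh", "robust", "none"),
                     relabel_by = "masks.public", mxl_fit = NULL,
                     control = list()) {
  se <- match.arg(se)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  enc <- encode_choice_data(data)
  cols <- colnames(enc$X)
  if (is.null(random_set)) random_set <- default_random_set(cols)
  P <- length(cols); q <- length(random_set)

  base <- if (is.null(mxl_fit)) {
    fit_mxl(data, random_set = random_set, R = R, seed = seed,
            se = if (K == 1) se else "none", control = control)
  } else mxl_fit

  if (K == 1) {
    return(as_mmml_fit_k1(base, enc))
  }

  Zall <- class_covariates(resp_profiles(profiles, enc),
                           covariates = covariates %||%
                             intersect(c("sex", "ethnicity", "marital", "parental",
                                         "education", "housing", "employment",
                                         "vaccine_shots", "age", "hras"),
                                       names(profiles)))
  m <- ncol(Zall)
  n_par <- K * (P + q) + (K - 1) * m
  if (enc$n_resp <= n_par) {
    stop("more parameters (", n_par, ") than respondents (", enc$n_resp, ")",
         call. = FALSE)
  }
  draws <- if (q > 0) halton_normal_draws(enc$n_resp, R, q, seed = seed)
           else array(0, dim = c(0, R, enc$n_resp))
  obj <- mmml_objective(enc, Zall, K, P, q, random_set, R, draws)
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-9), control)

  beta0 <- base$params$beta
  sigma0 <- base$params$sigma
  dir <- numeric(P)
  split_on <- if (relabel_by %in% cols) relabel_by else cols[min(2, P)]
  dir[match(split_on, cols)] <- 1
  starts <- with_seed(seed + 1L, {
    lapply(seq_len(n_starts), function(s) {
      off <- if (s == 1) {
        # deterministic split along the relabelling coordinate
        lapply(seq_len(K), function(k2) (K + 1 - 2 * k2) / (K - 1) * dir)
      } else {
        lapply(seq_len(K), function(k2) stats::rnorm(P, 0, 0.5))
      }
      th <- unlist(lapply(seq_len(K), function(k2) {
        c(beta0 + off[[k2]], pmax(sigma0, 0.2))
      }))
      c(th, rep(0, (K - 1) * m))
    })
  })

  # coarse-to-fine multistart: explore all starts with a quarter of the
  # draws, then polish the best coarse optimum with the full draw set
  theta_starts <- starts
  if (length(starts) > 1) {
    Rc <- max(25L, ceiling(R / 4))
    obj_c <- mmml_objective(enc, Zall, K, P, q, random_set, Rc,
                            draws[, seq_len(Rc), , drop = FALSE])
    ctrl_c <- utils::modifyList(ctrl, list(reltol = 1e-7))
    coarse <- lapply(starts, function(th) {
      tryCatch(stats::optim(th * obj_c$sfull, fn = obj_c$fn, gr = obj_c$gr,
                            method = "BFGS", control = ctrl_c),
               error = function(e) NULL)
    })
    vals <- vapply(coarse, function(o) if (is.null(o)) Inf else o$value, 0)
    if (all(!is.finite(vals))) stop("all optimisation starts failed", call. = FALSE)
    theta_starts <- list(coarse[[which.min(vals)]]$par / obj_c$sfull)
  }
  best <- NULL
  for (s in seq_along(theta_starts)) {
    opt <- tryCatch(
      stats::optim(theta_starts[[s]] * obj$sfull, fn = obj$fn, gr = obj$gr,
                   method = "BFGS", control = ctrl),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  theta <- relabel_theta(best$par / obj$sfull, K, P, q, m, cols, split_on)
  theta_int <- theta * obj$sfull
  ll <- -obj$fn(theta_int)
  grad_ok <- max(abs(obj$gr(theta_int))) < 0.01 * sqrt(enc$n_resp)
  vcv <- msl_vcov(obj, theta_int, se, enc$n_resp) / outer(obj$sfull, obj$sfull)
  build_mmml_fit(theta, theta_int, vcv, ll, K, cols, random_set, Zall, enc, R,
                 seed, best, obj, converged = best$convergence == 0 || grad_ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resp_profiles <- function(profiles, enc) {
  ord <- match(enc$resp_ids, profiles$id)
  if (anyNA(ord)) stop("profiles are missing respondents present in the choice data",
                       call. = FALSE)
  profiles[ord, , drop = FALSE]
}

# theta layout: [beta_1, sigma_1, ..., beta_K, sigma_K, gamma_2, ..., gamma_K]
unpack_theta <- function(theta, K, P, q, m) {
  out <- list(beta = vector("list", K), sigma = vector("list", K))
  at <- 0L
  for (k in seq_len(K)) {
    out$beta[[k]] <- theta[at + seq_len(P)]; at <- at + P
    out$sigma[[k]] <- theta[at + seq_len(q)]; at <- at + q
  }
  out$gamma <- if (K > 1) matrix(theta[at + seq_len((K - 1) * m)],
                                 nrow = K - 1, byrow = TRUE) else NULL
  out
}

# Negative simulated mixture log-likelihood with analytic gradient.
# Like msl_objective, works in an internally scaled space: each predictor
# column is divided by its max absolute value and theta_int = theta * sfull
# (membership coefficients unscaled). fn is value-only; gr/scores/posterior
# trigger the full computation.
mmml_objective <- function(enc, Z, K, P, q, random_set, R, draws) {
  cols <- colnames(enc$X)
  rand_idx <- match(random_set, cols)
  sc_col <- pmax(1, apply(abs(enc$X), 2, max))
  m <- ncol(Z)
  sfull <- c(rep(c(sc_col, sc_col[rand_idx]), K), rep(1, (K - 1) * m))
  X <- sweep(enc$X, 2, sc_col, "/")
  Xt <- t(X)
  Xrt <- t(X[, rand_idx, drop = FALSE])
  rts <- resp_task_starts(enc)
  n <- enc$n_resp
  cache <- new.env(parent = emptyenv())
  cache$vpar <- cache$gpar <- NULL
  run_class <- function(beta, sigma, grad) {
    msl_components_cpp(Xt, Xrt, enc$task_start, enc$chosen_row, rts,
                       as.numeric(beta), as.numeric(sigma),
                       as.integer(rand_idx - 1L), as.numeric(draws),
                       as.integer(dim(draws)[2]), grad)
  }
  priors <- function(pp) {
    eta <- cbind(0, Z %*% t(pp$gamma))
    eta <- eta - apply(eta, 1, max)
    pi <- exp(eta)
    pi / rowSums(pi)
  }
  value_only <- function(theta) {
    pp <- unpack_theta(theta, K, P, q, m)
    S <- vapply(seq_len(K), function(k) {
      run_class(pp$beta[[k]], pp$sigma[[k]], FALSE)$S
    }, numeric(n))
    pi <- priors(pp)
    -sum(log(pmax(rowSums(pi * S), 1e-300)))
  }
  full <- function(theta) {
    if (!is.null(cache$gpar) && identical(theta, cache$gpar)) return(invisible(NULL))
    pp <- unpack_theta(theta, K, P, q, m)
    S <- matrix(0, n, K)
    G <- vector("list", K)
    for (k in seq_len(K)) {
      ms <- run_class(pp$beta[[k]], pp$sigma[[k]], TRUE)
      S[, k] <- ms$S
      G[[k]] <- ms$G
    }
    pi <- priors(pp)
    L <- pmax(rowSums(pi * S), 1e-300)
    post <- (pi * S) / L                        # posterior class probabilities
    sc <- matrix(0, n, length(theta))
    at <- 0L
    for (k in seq_len(K)) {
      sc[, at + seq_len(P + q)] <- G[[k]] * (pi[, k] / L)
      at <- at + P + q
    }
    for (k in seq_len(K)[-1]) {
      sc[, at + seq_len(m)] <- Z * (post[, k] - pi[, k])
      at <- at + m
    }
    cache$gpar <- cache$vpar <- theta
    cache$gvalue <- cache$value <- -sum(log(L))
    cache$scores <- sc
    cache$grad <- -colSums(sc)
    cache$post <- post
    invisible(NULL)
  }
  list(
    fn = function(theta) {
      if (!is.null(cache$vpar) && identical(theta, cache$vpar)) return(cache$value)
      if (!is.null(cache$gpar) && identical(theta, cache$gpar)) return(cache$gvalue)
      cache$vpar <- theta
      cache$value <- value_only(theta)
      cache$value
    },
    gr = function(theta) { full(theta); cache$grad },
    scores = function(theta) { full(theta); cache$scores },
    posterior = function(theta) { full(theta); cache$post },
    sfull = sfull
  )
}

# reorder classes by decreasing mean on the relabelling coordinate and move
# the membership reference to the new class 1
relabel_theta <- function(theta, K, P, q, m, cols, split_on) {
  pp <- unpack_theta(theta, K, P, q, m)
  j <- match(split_on, cols)
  ord <- order(vapply(pp$beta, `[`, 0, j), decreasing = TRUE)
  gam_full <- rbind(0, pp$gamma)[ord, , drop = FALSE]
  gam_new <- sweep(gam_full[-1, , drop = FALSE], 2, gam_full[1, ])
  unlist(c(
    lapply(ord, function(k) c(pp$beta[[k]], abs(pp$sigma[[k]]))),
    list(as.numeric(t(gam_new)))
  ))
}

build_mmml_fit <- function(theta, theta_int, vcv, ll, K, cols, random_set, Z,
                           enc, R, seed, opt, obj, converged) {
  P <- length(cols); q <- length(random_set); m <- ncol(Z)
  ses <- sqrt(pmax(diag(vcv), 0))
  pp <- unpack_theta(theta, K, P, q, m)
  pse <- unpack_theta(ses, K, P, q, m)
  mk_tab <- function(est, s, terms, type) {
    data.frame(term = terms, type = type, estimate = est, se = s,
               ci_low = est - 1.96 * s, ci_high = est + 1.96 * s,
               p = 2 * stats::pnorm(-abs(est / s)), row.names = NULL)
  }
  classes <- lapply(seq_len(K), function(k) {
    tab <- rbind(
      mk_tab(pp$beta[[k]], pse$beta[[k]], cols, "mean"),
      if (q) mk_tab(abs(pp$sigma[[k]]), pse$sigma[[k]],
                    paste0("sd.", random_set), "sd")
    )
    beta <- stats::setNames(pp$beta[[k]], cols)
    sigma <- stats::setNames(abs(pp$sigma[[k]]), random_set)
    list(coefficients = tab, beta = beta, sigma = sigma)
  })
  gamma <- pp$gamma
  if (!is.null(gamma)) colnames(gamma) <- colnames(Z)
  gamma_se <- pse$gamma
  if (!is.null(gamma_se)) colnames(gamma_se) <- colnames(Z)
  post <- obj$posterior(theta_int)
  colnames(post) <- paste0("class", seq_len(K))
  shares <- colMeans(post)
  n_par <- length(theta)
  structure(
    list(classes = classes, gamma = gamma, gamma_se = gamma_se,
         K = K, shares = shares,
         posterior = data.frame(resp_id = enc$resp_ids, post),
         loglik = ll, bic = -2 * ll + n_par * log(enc$n_resp),
         n_par = n_par, vcov = vcv, R = R, seed = seed,
         convergence = converged,
         n_resp = enc$n_resp, n_task = enc$n_task,
         predictor_names = cols, random_set = random_set,
         covariate_names = colnames(Z)),
    class = "mmml_fit"
  )
}

# wrap a K = 1 mixed-logit fit in the mmml interface
as_mmml_fit_k1 <- function(fit, enc) {
  tab <- fit$coefficients
  structure(
    list(classes = list(list(coefficients = tab, beta = fit$params$beta,
                             sigma = fit$params$sigma)),
         gamma = NULL, gamma_se = NULL, K = 1L, shares = c(class1 = 1),
         posterior = data.frame(resp_id = enc$resp_ids, class1 = 1),
         loglik = fit$loglik,
         bic = -2 * fit$loglik + nrow(tab) * log(enc$n_resp),
         n_par = nrow(tab), vcov = fit$vcov, R = fit$R, seed = fit$seed,
         convergence = fit$convergence,
         n_resp = enc$n_resp, n_task = enc$n_task,
         predictor_names = fit$predictor_names, random_set = fit$random_set,
         covariate_names = character(0)),
    class = "mmml_fit"
  )
}

#' @export
print.mmml_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed-mixed multinomial logit: K=%d classes, %d respondents\n",
              x$K, x$n_resp))
  cat(sprintf("  log-likelihood %.2f  BIC %.2f  converged: %s\n",
              x$loglik, x$bic, x$convergence))
  cat("  class shares:", paste(sprintf("%.3f", x$shares), collapse = " / "), "\n")
  for (k in seq_len(x$K)) {
    cat(sprintf("-- class %d --\n", k))
    tab <- x$classes[[k]]$coefficients
    tab$estimate <- round(tab$estimate, digits)
    tab$ci <- sprintf("[%.*f, %.*f]", digits, tab$ci_low, digits, tab$ci_high)
    print(tab[, c("term", "type", "estimate", "ci", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
logLik.mmml_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' Bayesian information criterion of a fitted mixture
#'
#' BIC = -2 log L + p log(n), with n the number of respondents (the
#' independent sampling units of the panel).
#'
#' @param object an `mmml_fit`.
#' @param ... unused.
#' @return scalar BIC.
#' @export
BIC.mmml_fit <- function(object, ...) object$bic

#' Select the number of latent classes by BIC
#'
#' Fits the mixture for every K in `k_range` on one dataset (shared settings)
#' and returns the BIC-minimising class count together with the full table.
#' Values of K whose fit fails or does not converge are excluded with a
#' warning, never silently chosen.
#'
#' @param data a `choice_data` object.
#' @param profiles respondent covariate table.
#' @param k_range integer vector of candidate class counts.
#' @param ... passed to [fit_mmml()] (`covariates`, `random_set`, `R`,
#'   `seed`, `n_starts`, `se`, `control`, ...).
#' @return list with `best_k`, `table` (K, loglik, n_par, bic, converged) and
#'   `fits` (one `mmml_fit` per converged K).
#' @export
select_k <- function(data, profiles, k_range = 1:3, ...) {
  if (length(k_range) == 0) stop("k_range must be nonempty", call. = FALSE)
  dots <- list(...)
  if (is.null(dots$mxl_fit)) {
    # one shared mixed-logit base fit for every candidate K
    base_args <- dots[intersect(names(dots),
                                c("random_set", "R", "seed", "control"))]
    base_args$se <- if (1 %in% k_range) dots[["se"]] %||% "hessian" else "none"
    dots$mxl_fit <- do.call(fit_mxl, c(list(data), base_args))
  }
  fits <- list()
  rows <- list()
  for (K in k_range) {
    fit <- tryCatch(do.call(fit_mmml, c(list(data, profiles, K = K), dots)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("K=", K, " failed: ", conditionMessage(fit), call. = FALSE)
      rows[[as.character(K)]] <- data.frame(K = K, loglik = NA, n_par = NA,
                                            bic = NA, converged = FALSE)
      next
    }
    if (!fit$convergence) {
      warning("K=", K, " did not converge; excluded from selection", call. = FALSE)
    }
    fits[[as.character(K)]] <- fit
    rows[[as.character(K)]] <- data.frame(K = K, loglik = fit$loglik,
                                          n_par = fit$n_par, bic = fit$bic,
                                          converged = fit$convergence)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab$converged & !is.na(tab$bic)
  if (!any(ok)) stop("no candidate class count converged", call. = FALSE)
  best <- tab$K[ok][which.min(tab$bic[ok])]
  list(best_k = best, table = tab, fits = fits)
}

#' Class-membership odds ratios
#'
#' Exponentiated membership coefficients of each non-reference class:
#' OR = exp(gamma) with 95% CI exp(gamma +- 1.96 SE). An OR above 1 means the
#' named group (the dummy's level, vs its reference category) is more likely
#' to belong to that class than to class 1; for the continuous covariates the
#' OR is per unit of the scaled covariate (a decade of age; one reference SD
#' of the risk-attitude score).
#'
#' @param fit a converged `mmml_fit` with K >= 2.
#' @return data.frame with class, covariate, odds ratio, CI bounds, p-value.
#' @export
membership_odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "mmml_fit"))
  if (fit$K < 2) stop("odds ratios need at least two classes", call. = FALSE)
  if (!fit$convergence) stop("fit did not converge; odds ratios withheld",
                             call. = FALSE)
  if (is.null(fit$gamma_se) || anyNA(fit$gamma_se)) {
    stop("membership standard errors unavailable", call. = FALSE)
  }
  out <- list()
  for (k in 2:fit$K) {
    g <- fit$gamma[k - 1, ]
    s <- fit$gamma_se[k - 1, ]
    out[[k - 1]] <- data.frame(
      class = k, covariate = fit$covariate_names,
      or = exp(g), ci_low = exp(g - 1.96 * s), ci_high = exp(g + 1.96 * s),
      p = 2 * stats::pnorm(-abs(g / s)), row.names = NULL
    )
  }
  do.call(rbind, out)
}
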