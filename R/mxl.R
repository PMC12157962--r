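#' Mixed-logit parameter bundle
#'
#' Holds population taste means `beta` (one entry per encoded predictor,
#' left ASC and fee included) and heterogeneity SDs `sigma` for the
#' predictors in `random_set`.
#'
#' @param beta named numeric vector of taste means.
#' @param sigma named numeric vector of SDs (>= 0); its names are the random
#'   set. `numeric(0)` gives a fixed-coefficient (conditional logit) model.
#' @return an `mxl_parameters` object.
#' @export
mxl_parameters <- function(beta, sigma = numeric(0)) {
  if (length(sigma) && is.null(names(sigma))) {
    stop("sigma must be named after predictors", call. = FALSE)
  }
  if (length(sigma) && !all(names(sigma) %in% names(beta))) {
    stop("sigma names must be a subset of beta names", call. = FALSE)
  }
  structure(list(beta = beta, sigma = abs(sigma),
                 random_set = names(sigma)),
            class = "mxl_parameters")
}

#' Conditional-logit log-likelihood
#'
#' Log-likelihood of the fixed-coefficient multinomial (conditional) logit:
#' the sum over all chosen alternatives of the log softmax probability
#' within their choice set. This is the degenerate mixed logit with all
#' heterogeneity SDs at zero.
#'
#' @param data a `choice_data` object.
#' @param beta coefficient vector, named after [predictor_names()] or in
#'   that order.
#' @return scalar log-likelihood (<= 0).
#' @export
clogit_loglik <- function(data, beta) {
  enc <- encode_choice_data(data)
  beta <- align_beta(beta, colnames(enc$X))
  clogit_ll_enc(enc, beta)$ll
}

align_beta <- function(beta, cols) {
  if (length(beta) != length(cols)) {
    stop("coefficient length ", length(beta), " does not match the ",
         length(cols), " encoded predictors", call. = FALSE)
  }
  if (!is.null(names(beta))) {
    miss <- setdiff(cols, names(beta))
    if (length(miss)) stop("missing coefficients: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    beta <- beta[cols]
  }
  as.numeric(beta)
}

# conditional-logit log-likelihood, gradient, Hessian from encoded arrays
clogit_ll_enc <- function(enc, beta, hessian = FALSE) {
  u <- drop(enc$X %*% beta)
  task_of <- rep(seq_len(enc$n_task), diff(enc$task_start))
  um <- as.numeric(tapply(u, task_of, max))[task_of]
  eu <- exp(u - um)
  denom <- rowsum(eu, task_of)[task_of, 1]
  p <- as.numeric(eu / denom)
  ll <- sum(log(p[enc$chosen_row + 1L]))
  xbar <- rowsum(enc$X * p, task_of)
  gr <- colSums(enc$X[enc$chosen_row + 1L, , drop = FALSE]) - colSums(xbar)
  H <- NULL
  if (hessian) {
    Xc <- enc$X - xbar[task_of, , drop = FALSE]
    H <- -crossprod(Xc * sqrt(p), Xc * sqrt(p))
  }
  list(ll = ll, gr = gr, H = H)
}

#' Fit a conditional logit by Newton-Raphson
#'
#' Maximum-likelihood conditional logit on the encoded predictors; used as
#' the warm start of [fit_mxl()] and as the sigma = 0 reference model.
#'
#' @param data a `choice_data` object.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter iteration cap.
#' @return list with `coef`, `vcov`, `loglik`, `converged`.
#' @export
fit_clogit <- function(data, tol = 1e-8, max_iter = 50) {
  enc <- encode_choice_data(data)
  P <- ncol(enc$X)
  beta <- numeric(P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- clogit_ll_enc(enc, beta, hessian = TRUE)
    if (max(abs(f$gr)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(f$H, f$gr), error = function(e) NULL)
    if (is.null(step)) break
    # damped Newton: halve until the likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta - lam * step
      if (clogit_ll_enc(enc, cand)$ll >= f$ll - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    beta <- beta - lam * step
  }
  f <- clogit_ll_enc(enc, beta, hessian = TRUE)
  vc <- tryCatch(solve(-f$H), error = function(e) matrix(NA, P, P))
  names(beta) <- colnames(enc$X)
  dimnames(vc) <- list(colnames(enc$X), colnames(enc$X))
  list(coef = beta, vcov = vc, loglik = f$ll,
       converged = converged || max(abs(f$gr)) < 1e-4)
}

#' Simulated mixed-logit log-likelihood
#'
#' Maximum-simulated-likelihood objective of the panel mixed logit: for each
#' respondent, the product over their tasks of conditional-logit choice
#' probabilities is averaged over `R` scrambled-Halton normal draws of the
#' random coefficients; the function returns the sum of the log averages.
#' With all SDs zero it equals [clogit_loglik()] for any `R`. Repeated
#' evaluation with the same draws is bit-identical.
#'
#' @param data a `choice_data` object.
#' @param params an `mxl_parameters` object.
#' @param R number of draws per respondent (>= 1).
#' @param seed seed for the draws (ignored when `draws` given).
#' @param draws optional draw array from [halton_normal_draws()].
#' @return scalar simulated log-likelihood.
#' @export
mxl_loglik <- function(data, params, R = 500, seed = 1, draws = NULL) {
  stopifnot(inherits(params, "mxl_parameters"))
  if (!is.null(draws)) R <- dim(draws)[2]
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  enc <- encode_choice_data(data)
  ms <- msl_eval(enc, params$beta, params$sigma, R = R, seed = seed,
                 draws = draws, want_grad = FALSE)
  sum(log(pmax(ms$S, 1e-300)))
}

# shared simulated-likelihood evaluation machinery
msl_eval <- function(enc, beta, sigma, R, seed = 1, draws = NULL, want_grad = TRUE) {
  cols <- colnames(enc$X)
  beta <- align_beta(beta, cols)
  rand_idx <- if (length(sigma)) match(names(sigma), cols) else integer(0)
  if (anyNA(rand_idx)) stop("random-set names not among the encoded predictors",
                            call. = FALSE)
  q <- length(rand_idx)
  if (is.null(draws)) {
    draws <- if (q > 0) halton_normal_draws(enc$n_resp, R, q, seed = seed)
             else array(0, dim = c(0, R, enc$n_resp))
  }
  stopifnot(dim(draws)[1] == q, dim(draws)[2] == R, dim(draws)[3] == enc$n_resp)
  rts <- resp_task_starts(enc)
  msl_components_cpp(t(enc$X), t(enc$X[, rand_idx, drop = FALSE]),
                     enc$task_start, enc$chosen_row, rts,
                     as.numeric(beta), as.numeric(sigma),
                     as.integer(rand_idx - 1L), as.numeric(draws),
                     as.integer(R), want_grad)
}

resp_task_starts <- function(enc) {
  as.integer(c(0L, cumsum(tabulate(enc$task_resp + 1L, enc$n_resp))))
}

#' Fit a panel mixed logit by maximum simulated likelihood
#'
#' Estimates taste means for every encoded predictor and heterogeneity SDs
#' for the predictors in `random_set`, by BFGS maximisation of the simulated
#' log-likelihood with analytic gradients, warm-started at the conditional
#' logit. Draws are scrambled Halton, one fixed block per respondent.
#' Standard errors come from the inverse numerical Hessian (default), from
#' the outer product of respondent scores (`"bhhh"`), or a robust sandwich
#' of the two (`"robust"`). SDs are reported as absolute values (the
#' likelihood is invariant to their sign).
#'
#' @param data a `choice_data` object.
#' @param random_set character vector of predictors carrying a random
#'   coefficient; defaults to the five heterogeneous predictors of the NPI
#'   application when present, otherwise all attribute dummies except the
#'   cost and ASC.
#' @param R draws per respondent (default 500).
#' @param seed integer seed for the draws.
#' @param se one of `"hessian"`, `"bhhh"`, `"robust"`, `"none"`.
#' @param start optional named start values for the means.
#' @param sigma_start start value for each SD (default 0.3).
#' @param control passed to [stats::optim()] (`maxit`, `reltol`).
#' @return an `mxl_fit` object: coefficient table (`$coefficients` with
#'   estimate, SE, 95% CI, p-value, and a `type` column distinguishing means
#'   from SDs), `$loglik`, `$vcov`, `$convergence`, draw settings and sizes.
#' @export
fit_mxl <- function(data, random_set = NULL, R = 500, seed = 1,
                    se = c("hessian", "bhhh", "robust", "none"),
                    start = NULL, sigma_start = 0.3, control = list()) {
  se <- match.arg(se)
  enc <- encode_choice_data(data)
  cols <- colnames(enc$X)
  if (is.null(random_set)) random_set <- default_random_set(cols)
  if (!all(random_set %in% cols)) {
    stop("random_set entries not among predictors: ",
         paste(setdiff(random_set, cols), collapse = ", "), call. = FALSE)
  }
  q <- length(random_set)
  P <- length(cols)

  cl <- fit_clogit(data)
  beta0 <- if (is.null(start)) cl$coef else align_beta(start, cols)
  theta0 <- c(beta0, rep(sigma_start, q))

  draws <- if (q > 0) halton_normal_draws(enc$n_resp, R, q, seed = seed)
           else array(0, dim = c(0, R, enc$n_resp))

  obj <- msl_objective(enc, P, q, random_set, R, draws)
  ctrl <- utils::modifyList(list(maxit = 400, reltol = 1e-9), control)
  opt <- stats::optim(theta0 * obj$sfull, fn = obj$fn, gr = obj$gr,
                      method = "BFGS", control = ctrl)
  theta_int <- opt$par
  theta_int[P + seq_len(q)] <- abs(theta_int[P + seq_len(q)])  # report |sigma|
  ll <- -obj$fn(theta_int)
  grad_ok <- max(abs(obj$gr(theta_int))) < 0.01 * sqrt(enc$n_resp)

  vcv <- msl_vcov(obj, theta_int, se, enc$n_resp) / outer(obj$sfull, obj$sfull)
  theta <- theta_int / obj$sfull
  build_mxl_fit(theta, vcv, ll, cols, random_set, R, seed, opt, enc, cl,
                converged = opt$convergence == 0 || grad_ok)
}

default_random_set <- function(cols) {
  npi <- c("masks.indoors", "masks.public", "dining.not_allowed",
           "quarantine.government_facility", "booster.compulsory")
  if (all(npi %in% cols)) return(npi)
  setdiff(cols, c("asc_left", cols[length(cols)]))
}

# Negative simulated log-likelihood closure. Works in an internally scaled
# parameter space (each predictor column divided by its max absolute value,
# so the fee coefficient lives on the same scale as the dummies; theta_int =
# theta * sfull). Line-search calls (`fn`) skip the gradient; `gr`/`scores`
# trigger the full computation, cached per parameter vector.
msl_objective <- function(enc, P, q, random_set, R, draws) {
  cols <- colnames(enc$X)
  rand_idx <- match(random_set, cols)
  sc <- pmax(1, apply(abs(enc$X), 2, max))
  sfull <- c(sc, sc[rand_idx])
  X <- sweep(enc$X, 2, sc, "/")
  Xt <- t(X)
  Xrt <- t(X[, rand_idx, drop = FALSE])
  rts <- resp_task_starts(enc)
  cache <- new.env(parent = emptyenv())
  cache$vpar <- cache$gpar <- NULL
  run <- function(theta, grad) {
    beta <- theta[seq_len(P)]
    sigma <- if (q > 0) theta[P + seq_len(q)] else numeric(0)
    msl_components_cpp(Xt, Xrt, enc$task_start, enc$chosen_row, rts,
                       as.numeric(beta), as.numeric(sigma),
                       as.integer(rand_idx - 1L), as.numeric(draws),
                       as.integer(dim(draws)[2]), grad)
  }
  full <- function(theta) {
    if (!is.null(cache$gpar) && identical(theta, cache$gpar)) return(invisible(NULL))
    ms <- run(theta, TRUE)
    S <- pmax(ms$S, 1e-300)
    cache$gpar <- cache$vpar <- theta
    cache$gvalue <- cache$value <- -sum(log(S))
    cache$scores <- ms$G / S                 # n_resp x (P+q) respondent scores
    cache$grad <- -colSums(cache$scores)
    invisible(NULL)
  }
  list(
    fn = function(theta) {
      if (!is.null(cache$vpar) && identical(theta, cache$vpar)) return(cache$value)
      if (!is.null(cache$gpar) && identical(theta, cache$gpar)) return(cache$gvalue)
      S <- pmax(run(theta, FALSE)$S, 1e-300)
      cache$vpar <- theta
      cache$value <- -sum(log(S))
      cache$value
    },
    gr = function(theta) { full(theta); cache$grad },
    scores = function(theta) { full(theta); cache$scores },
    sfull = sfull
  )
}

# covariance of the MSL estimator
msl_vcov <- function(obj, theta, se, n_resp) {
  np <- length(theta)
  if (se == "none") return(matrix(NA_real_, np, np))
  sc <- obj$scores(theta)
  B <- crossprod(sc)
  if (se == "bhhh") return(safe_inverse(B))
  H <- tryCatch(fd_hessian(obj$gr, theta), error = function(e) NULL)
  if (is.null(H)) return(matrix(NA_real_, np, np))
  Hi <- safe_inverse(H)
  if (se == "robust") Hi %*% B %*% Hi else Hi
}

# inverse with a Moore-Penrose fallback: heterogeneity-SD estimates on the
# zero boundary have identically zero scores, which makes the information
# matrix rank-deficient without invalidating the remaining standard errors
safe_inverse <- function(M) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) out <- tryCatch(MASS::ginv(M),
                                    error = function(e) {
                                      matrix(NA_real_, nrow(M), ncol(M))
                                    })
  out
}

# forward-difference Hessian of the (negative log-likelihood) objective from
# its analytic gradient, symmetrised; parameters live in the scaled space so
# one relative step size serves all coordinates
fd_hessian <- function(gr, theta, eps = 1e-5) {
  g0 <- gr(theta)
  np <- length(theta)
  H <- matrix(0, np, np)
  for (j in seq_len(np)) {
    h <- eps * max(1, abs(theta[j]))
    tp <- theta
    tp[j] <- tp[j] + h
    H[, j] <- (gr(tp) - g0) / h
  }
  (H + t(H)) / 2
}

build_mxl_fit <- function(theta, vcv, ll, cols, random_set, R, seed, opt, enc,
                          cl, converged) {
  P <- length(cols); q <- length(random_set)
  est <- theta
  ses <- sqrt(pmax(diag(vcv), 0))
  terms <- c(cols, if (q) paste0("sd.", random_set))
  tab <- data.frame(
    term = terms,
    type = c(rep("mean", P), rep("sd", q)),
    estimate = est, se = ses,
    ci_low = est - 1.96 * ses, ci_high = est + 1.96 * ses,
    p = 2 * stats::pnorm(-abs(est / ses)),
    row.names = NULL
  )
  beta <- est[seq_len(P)]; names(beta) <- cols
  sigma <- if (q) abs(est[P + seq_len(q)]) else numeric(0)
  if (q) names(sigma) <- random_set
  structure(
    list(coefficients = tab, params = mxl_parameters(beta, sigma),
         loglik = ll, vcov = vcv, R = R, seed = seed,
         convergence = converged,
         n_resp = enc$n_resp, n_task = enc$n_task, n_obs = nrow(enc$X),
         clogit = cl, optim = opt[c("convergence", "counts", "message")],
         predictor_names = cols, random_set = random_set),
    class = "mxl_fit"
  )
}

#' @export
print.mxl_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Panel mixed logit (MSL, %d Halton draws): %d respondents, %d tasks\n",
              x$R, x$n_resp, x$n_task))
  cat(sprintf("  log-likelihood %.2f  converged: %s\n", x$loglik, x$convergence))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$ci <- sprintf("[%.*f, %.*f]", digits, tab$ci_low, digits, tab$ci_high)
  print(tab[, c("term", "type", "estimate", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.mxl_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.mxl_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$coefficients), class = "logLik")
}

#' @export
vcov.mxl_fit <- function(object, ...) object$vcov

#' Export a coefficient table to CSV
#'
#' Writes the fitted coefficient table (term, estimate, CI bounds, p-value)
#' in the layout of a publication regression table.
#'
#' @param fit an `mxl_fit` or `mmml_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coef_table <- function(fit, path) {
  utils::write.csv(coef_frame(fit), path, row.names = FALSE)
  invisible(path)
}

coef_frame <- function(fit) {
  if (inherits(fit, "mmml_fit")) {
    do.call(rbind, lapply(seq_along(fit$classes), function(k) {
      cbind(class = k, fit$classes[[k]]$coefficients)
    }))
  } else {
    fit$coefficients
  }
}
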