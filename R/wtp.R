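#' Willingness to pay from a fitted choice model
#'
#' Converts taste coefficients into money terms: WTP_k = beta_k / |beta_fee|,
#' the one-time fee a respondent would pay to have attribute level k
#' implemented (positive WTP) or to avoid it (negative WTP). Requires a
#' negative fee coefficient; otherwise the ratio is uninterpretable and an
#' error is raised. Confidence intervals come from the delta method or from
#' Krinsky-Robb resampling of the joint coefficient distribution (default
#' 10,000 multivariate-normal parameter draws, percentile interval, seeded).
#'
#' @param fit an `mxl_fit`, or an `mmml_fit` together with `class`.
#' @param class for `mmml_fit`: which class's coefficients (and class-specific
#'   fee coefficient) to convert.
#' @param method `"delta"` or `"krinsky-robb"`.
#' @param n_draws parameter draws for Krinsky-Robb.
#' @param seed seed for Krinsky-Robb.
#' @return a `wtp_table` data.frame: term, wtp, ci_low, ci_high, direction
#'   (`"pay_to_implement"` / `"pay_to_avoid"`).
#' @export
compute_wtp <- function(fit, class = NULL, method = c("delta", "krinsky-robb"),
                        n_draws = 10000, seed = 1) {
  method <- match.arg(method)
  ex <- extract_means(fit, class)
  beta <- ex$beta; vcv <- ex$vcov; cols <- names(beta)
  fee_col <- ex$fee_col
  bf <- beta[[fee_col]]
  if (is.na(bf) || bf >= 0) {
    stop("fee coefficient is not negative; WTP is ill-posed", call. = FALSE)
  }
  keep <- setdiff(cols, fee_col)
  wtp <- beta[keep] / abs(bf)
  if (method == "delta") {
    lo <- hi <- numeric(length(keep))
    for (j in seq_along(keep)) {
      k <- keep[j]
      g <- c(-1 / bf, beta[[k]] / bf^2)       # d(-bk/bf)/d(bk,bf)
      v <- vcv[c(k, fee_col), c(k, fee_col)]
      s <- sqrt(max(drop(t(g) %*% v %*% g), 0))
      lo[j] <- wtp[[k]] - 1.96 * s
      hi[j] <- wtp[[k]] + 1.96 * s
    }
  } else {
    dr <- with_seed(seed, MASS::mvrnorm(n_draws, beta, vcv))
    fee_dr <- dr[, fee_col]
    ok <- fee_dr < 0
    if (mean(ok) < 0.5) stop("fee coefficient too uncertain for Krinsky-Robb WTP",
                             call. = FALSE)
    ratios <- dr[ok, keep, drop = FALSE] / abs(fee_dr[ok])
    qs <- apply(ratios, 2, stats::quantile, probs = c(0.025, 0.975))
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  structure(
    data.frame(term = keep, wtp = as.numeric(wtp),
               ci_low = as.numeric(lo), ci_high = as.numeric(hi),
               direction = ifelse(wtp >= 0, "pay_to_implement", "pay_to_avoid"),
               row.names = NULL),
    class = c("wtp_table", "data.frame"), method = method
  )
}

# mean coefficients and their covariance block from a fit (one class of a
# mixture, or the single class of an mxl fit)
extract_means <- function(fit, class = NULL) {
  if (inherits(fit, "mmml_fit")) {
    if (is.null(class)) {
      if (fit$K > 1) stop("specify `class` for a mixture fit", call. = FALSE)
      class <- 1L
    }
    cols <- fit$predictor_names
    P <- length(cols); q <- length(fit$random_set)
    off <- (class - 1L) * (P + q)
    idx <- off + seq_len(P)
    beta <- fit$classes[[class]]$beta
    vcv <- fit$vcov[idx, idx, drop = FALSE]
    dimnames(vcv) <- list(cols, cols)
  } else if (inherits(fit, "mxl_fit")) {
    cols <- fit$predictor_names
    beta <- fit$params$beta
    vcv <- fit$vcov[seq_along(cols), seq_along(cols), drop = FALSE]
    dimnames(vcv) <- list(cols, cols)
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  fee_col <- cols[length(cols)]
  list(beta = beta, vcov = vcv, fee_col = fee_col)
}

#' Classify preference direction of each attribute level
#'
#' Labels every non-reference attribute level as `"preferred"` when its 95%
#' CI lies above zero, `"opposed"` when below zero, and `"indifferent"` when
#' the CI spans zero. The ASC and the fee are excluded (they are not policy
#' levels).
#'
#' @param fit an `mxl_fit` or `mmml_fit` (all classes reported).
#' @return data.frame with term, estimate, CI bounds and `direction`
#'   (plus a `class` column for mixtures).
#' @export
preference_summary <- function(fit) {
  fee_col <- utils::tail(fit$predictor_names, 1)
  one <- function(tab, cls = NULL) {
    tab <- tab[tab$type == "mean" & !(tab$term %in% c("asc_left", fee_col)), ]
    dir <- ifelse(pmin(tab$ci_low, tab$ci_high) > 0, "preferred",
                  ifelse(pmax(tab$ci_low, tab$ci_high) < 0, "opposed", "indifferent"))
    out <- data.frame(term = tab$term, estimate = tab$estimate,
                      ci_low = pmin(tab$ci_low, tab$ci_high),
                      ci_high = pmax(tab$ci_low, tab$ci_high),
                      direction = dir, row.names = NULL)
    if (!is.null(cls)) out <- cbind(class = cls, out)
    out
  }
  if (inherits(fit, "mmml_fit")) {
    do.call(rbind, lapply(seq_len(fit$K), function(k) {
      one(fit$classes[[k]]$coefficients, k)
    }))
  } else {
    one(fit$coefficients)
  }
}

#' Write a WTP table to CSV
#'
#' @param wtp a `wtp_table`.
#' @param path output path.
#' @param round_money round WTP and CI bounds to whole currency units in the
#'   file (full precision is retained in the R object).
#' @return `path`, invisibly.
#' @export
write_wtp <- function(wtp, path, round_money = TRUE) {
  out <- as.data.frame(wtp)
  if (round_money) {
    for (cn in c("wtp", "ci_low", "ci_high")) out[[cn]] <- round(out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
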