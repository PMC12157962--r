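# Shared fixtures, memoised so expensive objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) assign(name, force(expr), .fixture_env)
  .fixture_env[[name]]
}

# one binary policy attribute plus a two-level fee
tiny_space <- function() {
  attribute_space(categorical = list(pol = c("ref", "act")),
                  cost_name = "fee", cost_levels = c(0, 10))
}

# two categorical attributes and a three-level fee; small enough for
# exhaustive checks, rich enough to exercise balance/overlap scoring
small_space <- function() {
  attribute_space(
    categorical = list(a1 = c("l0", "l1", "l2"), a2 = c("no", "yes")),
    cost_name = "fee", cost_levels = c(0, 10, 30)
  )
}

# build a choice_design directly from a level-index matrix (rows =
# alternatives in block/task/alt order), bypassing the optimiser so tests
# control the profiles exactly
manual_design <- function(space, levels, B, a, t) {
  structure(
    list(space = space, dims = design_dims(B, a, t, space),
         levels = levels,
         block = rep(seq_len(B), each = a * t),
         task = rep(seq_len(a), times = B, each = t),
         alt = rep(seq_len(t), times = B * a),
         seed = 0L,
         score = list(total = NA, balance = NA, d_error = NA, overlap = NA)),
    class = "choice_design"
  )
}

# single-block design on tiny_space(): `a` copies of the task
# {pol=act vs pol=ref}, both at fee 0 — choice shares follow a binary logit
# in the pol coefficient
paired_tiny_design <- function(a = 1) {
  lv <- do.call(rbind, replicate(a, rbind(c(2L, 1L), c(1L, 1L)), simplify = FALSE))
  manual_design(tiny_space(), lv, B = 1, a = a, t = 2)
}

tiny_profiles <- function(n, seed = 1) {
  simulate_profiles(n, seed = seed)[seq_len(n), c("id", "sex", "age", "hras")]
}

# moderate simulated dataset on the canonical space (cached)
canonical_design <- function() {
  fixture("canonical_design", {
    sp <- npi_attribute_space()
    generate_design(sp, design_dims(20, 7, 2, sp), seed = 11, n_iter = 1500)
  })
}

small_npi_data <- function() {
  fixture("small_npi_data", {
    pr <- simulate_profiles(200, seed = 21)
    dat <- simulate_choices(canonical_design(), pr,
                            npi_simulation_config("pooled"), seed = 22)
    list(profiles = pr, data = dat)
  })
}

small_mxl_fit <- function() {
  fixture("small_mxl_fit", {
    fit_mxl(small_npi_data()$data, R = 60, seed = 23)
  })
}

# fabricate a minimal mxl_fit-shaped object from a coefficient table; used to
# test reporting operations at exactly controlled values
stub_mxl_fit <- function(beta, se = NULL, sigma = numeric(0), vcov = NULL) {
  cols <- names(beta)
  if (is.null(se)) se <- rep(0.01, length(beta))
  if (is.null(vcov)) vcov <- diag(se^2, length(beta))
  dimnames(vcov) <- list(cols, cols)
  tab <- data.frame(term = cols, type = "mean", estimate = as.numeric(beta),
                    se = se, ci_low = as.numeric(beta) - 1.96 * se,
                    ci_high = as.numeric(beta) + 1.96 * se,
                    p = 2 * pnorm(-abs(as.numeric(beta) / se)))
  structure(list(coefficients = tab, params = mxl_parameters(beta, sigma),
                 loglik = -1, vcov = vcov, R = 1, seed = 1, convergence = TRUE,
                 predictor_names = cols, random_set = names(sigma)),
            class = "mxl_fit")
}
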