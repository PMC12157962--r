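#' Construct a blocked balanced-overlap choice design
#'
#' Builds a blocked experimental design for an unlabeled, single-stage choice
#' experiment: `B` blocks of `a` choice sets, each set showing `t`
#' full-profile alternatives. Starting from a random design (with duplicate
#' alternatives within a set forbidden), a seeded swap heuristic minimises a
#' composite score:
#' level-balance deviation (how far each level's usage is from uniform),
#' the D-error of the dummy-coded design under zero coefficients (statistical
#' efficiency), and an overlap penalty that pushes the per-task fraction of
#' attributes sharing a level across alternatives towards a moderate target —
#' penalising both zero overlap (hard tasks) and full overlap (uninformative
#' tasks), the "balanced overlap" compromise between statistical and response
#' efficiency.
#'
#' @param space an `attribute_space`.
#' @param dims a `design_dims` object consistent with `space`.
#' @param seed integer seed; designs are bit-identical for equal seeds.
#' @param weights named non-negative weights `c(balance=, d_error=, overlap=)`
#'   for the three score components.
#' @param overlap_target desired per-task fraction of overlapping attributes
#'   (default 1/3).
#' @param n_iter number of single-attribute swap proposals (default 4000).
#' @return a `choice_design` object.
#' @export
#' @examples
#' sp <- npi_attribute_space()
#' d <- generate_design(sp, design_dims(2, 3, 2, sp), seed = 1, n_iter = 200)
#' head(as.data.frame(d))
generate_design <- function(space, dims, seed = 1,
                            weights = c(balance = 1, d_error = 1, overlap = 1),
                            overlap_target = 1 / 3, n_iter = 4000) {
  stopifnot(inherits(space, "attribute_space"), inherits(dims, "design_dims"))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  w <- c(balance = 1, d_error = 1, overlap = 1)
  w[names(weights)] <- weights
  nlev <- attr_n_levels(space)
  n_profiles <- prod(nlev)
  if (dims$t > n_profiles) {
    stop("infeasible: ", dims$t, " distinct alternatives requested but only ",
         n_profiles, " profiles exist", call. = FALSE)
  }
  n_alt <- dims$B * dims$a * dims$t
  n_attr <- length(nlev)

  with_seed(seed, {
    idx <- matrix(0L, n_alt, n_attr)
    for (k in seq_len(n_attr)) idx[, k] <- sample.int(nlev[k], n_alt, replace = TRUE)
    task_of <- rep(seq_len(dims$B * dims$a), each = dims$t)
    idx <- fix_duplicates(idx, task_of, nlev)

    sc <- design_score(idx, task_of, space, nlev, w, overlap_target)
    for (it in seq_len(n_iter)) {
      r <- sample.int(n_alt, 1L)
      k <- sample.int(n_attr, 1L)
      old <- idx[r, k]
      new <- sample.int(nlev[k], 1L)
      if (new == old) next
      idx[r, k] <- new
      if (task_has_duplicate(idx, task_of, r)) {
        idx[r, k] <- old
        next
      }
      sc_new <- design_score(idx, task_of, space, nlev, w, overlap_target)
      if (sc_new$total <= sc$total) sc <- sc_new else idx[r, k] <- old
    }
  })

  structure(
    list(space = space, dims = dims, levels = idx,
         block = rep(seq_len(dims$B), each = dims$a * dims$t),
         task = rep(seq_len(dims$a), times = dims$B, each = dims$t),
         alt = rep(seq_len(dims$t), times = dims$B * dims$a),
         seed = seed, score = sc),
    class = "choice_design"
  )
}

# resample attributes of duplicated alternatives until all tasks are clean
fix_duplicates <- function(idx, task_of, nlev) {
  for (tries in 1:100) {
    key <- apply(idx, 1, paste, collapse = ",")
    bad <- unlist(lapply(split(seq_along(key), task_of), function(rows) {
      rows[duplicated(key[rows])]
    }), use.names = FALSE)
    if (length(bad) == 0) return(idx)
    for (r in bad) {
      k <- sample.int(ncol(idx), 1L)
      idx[r, k] <- sample.int(nlev[k], 1L)
    }
  }
  stop("could not construct duplicate-free choice sets", call. = FALSE)
}

task_has_duplicate <- function(idx, task_of, r) {
  t <- sum(task_of == task_of[1])
  tr <- task_of[r]
  rows <- ((tr - 1L) * t + 1L):(tr * t)
  key <- apply(idx[rows, , drop = FALSE], 1, paste, collapse = ",")
  anyDuplicated(key) > 0
}

# composite design score; lower is better
design_score <- function(idx, task_of, space, nlev, w, overlap_target) {
  n_alt <- nrow(idx)
  # level balance: mean absolute deviation of level counts from uniform,
  # normalised per attribute
  bal <- 0
  for (k in seq_along(nlev)) {
    cnt <- tabulate(idx[, k], nbins = nlev[k])
    bal <- bal + sum(abs(cnt - n_alt / nlev[k])) / n_alt
  }
  bal <- bal / length(nlev)

  # D-error under zero coefficients, fee scaled to [0,1]
  X <- encode_index_matrix(idx, space)
  X[, ncol(X)] <- X[, ncol(X)] / max(abs(space$cost_levels))
  t_per <- tabulate(task_of)
  Xbar <- rowsum(X, task_of) / t_per
  Xc <- X - Xbar[task_of, , drop = FALSE]
  M <- crossprod(Xc) / max(task_of)
  P <- ncol(X)
  dt <- det(M)
  derr <- if (!is.finite(dt) || dt <= 1e-300) 1e6 else dt^(-1 / P) / 10

  # overlap: fraction of attributes with a shared level within each task
  ov <- overlap_fractions(idx, task_of)
  ovp <- mean((ov - overlap_target)^2)

  total <- w[["balance"]] * bal + w[["d_error"]] * derr + w[["overlap"]] * ovp
  list(total = total, balance = bal, d_error = derr, overlap = ovp)
}

# per-task fraction of attributes on which all alternatives share one level;
# relies on rows being ordered task-by-task with a constant t per task
overlap_fractions <- function(idx, task_of) {
  t <- sum(task_of == task_of[1])
  n_task <- max(task_of)
  n_attr <- ncol(idx)
  same <- matrix(0, n_task, n_attr)
  for (k in seq_len(n_attr)) {
    m <- matrix(idx[, k], nrow = t)
    same[, k] <- as.numeric(colSums(m == m[rep(1L, t), , drop = FALSE]) == t)
  }
  rowMeans(same)
}

#' @export
print.choice_design <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Choice design: %d blocks x %d tasks x %d alternatives (seed %d)\n",
              d$B, d$a, d$t, x$seed))
  cat(sprintf("  score: balance %.4f, D-error %.4f, overlap penalty %.4f\n",
              x$score$balance, x$score$d_error * 10, x$score$overlap))
  invisible(x)
}

#' @export
as.data.frame.choice_design <- function(x, ...) {
  sp <- x$space
  df <- data.frame(block = x$block, task = x$task, alt = x$alt)
  for (k in seq_along(sp$attributes)) {
    a <- sp$attributes[[k]]
    if (a$kind == "categorical") {
      df[[a$name]] <- a$levels[x$levels[, k]]
    } else {
      df[[a$name]] <- sp$cost_levels[x$levels[, k]]
    }
  }
  df$left_asc <- as.numeric(x$alt == 1L)
  df
}

#' Encoded predictor matrix of a design
#'
#' @param design a `choice_design`.
#' @return numeric matrix with one row per alternative and columns
#'   `predictor_names(space)`.
#' @export
encoded_design_matrix <- function(design) {
  stopifnot(inherits(design, "choice_design"))
  X <- encode_index_matrix(design$levels, design$space)
  cbind(asc_left = as.numeric(design$alt == 1L), X)
}

#' Write a design to CSV
#'
#' Writes the profile table (block, task, alt, level labels, fee, left ASC)
#' and, optionally, the dummy-encoded matrix alongside it.
#'
#' @param design a `choice_design`.
#' @param path output CSV path for the profile table.
#' @param encoded_path optional path for the encoded matrix CSV.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, encoded_path = NULL) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  if (!is.null(encoded_path)) {
    df <- data.frame(block = design$block, task = design$task, alt = design$alt,
                     encoded_design_matrix(design), check.names = FALSE)
    utils::write.csv(df, encoded_path, row.names = FALSE)
  }
  invisible(path)
}

# evaluate a seed-free RNG scope: run `code` under `seed`, restore global RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
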