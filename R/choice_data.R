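#' Construct / validate a long-format choice dataset
#'
#' A `choice_data` object is a data.frame with one row per
#' respondent-task-alternative: columns `resp_id`, `block`, `task`, `alt`,
#' one column per attribute (level labels; money values for the cost
#' attribute), `left_asc` and `chosen`. Invariants enforced: exactly one
#' chosen alternative per respondent-task, every respondent sits in exactly
#' one block, and each respondent answers every task of their block.
#'
#' @param df data.frame in the long format above.
#' @param space the `attribute_space` the level columns refer to.
#' @return the validated `choice_data` object (rows ordered by respondent,
#'   task, alternative).
#' @export
choice_data <- function(df, space) {
  stopifnot(inherits(space, "attribute_space"))
  need <- c("resp_id", "block", "task", "alt", names(space$attributes),
            "left_asc", "chosen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("choice data missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[order(df$resp_id, df$task, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  validate_choice_data(df, space)
  structure(df, space = space, class = c("choice_data", "data.frame"))
}

validate_choice_data <- function(df, space) {
  key <- paste(df$resp_id, df$task)
  ch <- rowsum(df$chosen, key)
  bad <- rownames(ch)[ch[, 1] != 1]
  if (length(bad)) {
    stop("tasks without exactly one chosen alternative (respondent task): ",
         paste(utils::head(bad, 5), collapse = "; "), call. = FALSE)
  }
  nb <- tapply(df$block, df$resp_id, function(b) length(unique(b)))
  if (any(nb != 1)) {
    stop("respondents assigned to more than one block: ",
         paste(utils::head(names(nb)[nb != 1], 5), collapse = ", "), call. = FALSE)
  }
  # level labels must be known
  for (a in space$attributes) {
    if (a$kind == "categorical") {
      bad <- setdiff(unique(as.character(df[[a$name]])), a$levels)
      if (length(bad)) stop("unknown levels for '", a$name, "': ",
                            paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.choice_data <- function(x, ...) {
  cat(sprintf("Choice data: %d respondents, %d tasks, %d rows\n",
              length(unique(x$resp_id)),
              length(unique(paste(x$resp_id, x$task))), nrow(x)))
  NextMethod()
}

# Build the estimation arrays from a choice_data object:
#   X           encoded matrix (rows ordered resp, task, alt)
#   task_start  0-based first-row index per task, length n_task+1
#   chosen_row  0-based row index of the chosen alternative per task
#   task_resp   0-based respondent index per task
#   resp_ids    unique respondent ids in index order
encode_choice_data <- function(data) {
  space <- attr(data, "space")
  if (is.null(space)) stop("choice data carries no attribute space", call. = FALSE)
  df <- as.data.frame(data)
  o <- order(df$resp_id, df$task, df$alt)
  df <- df[o, , drop = FALSE]
  idx <- matrix(0L, nrow(df), length(space$attributes))
  for (k in seq_along(space$attributes)) {
    a <- space$attributes[[k]]
    labs <- as.character(df[[a$name]])
    j <- match(labs, a$levels)
    if (a$kind == "cost" && anyNA(j)) j[is.na(j)] <- match(as.numeric(labs[is.na(j)]),
                                                           space$cost_levels)
    if (anyNA(j)) stop("unknown level in column '", a$name, "'", call. = FALSE)
    idx[, k] <- j
  }
  X <- cbind(asc_left = df$left_asc, encode_index_matrix(idx, space))
  # cost column: pass through the raw fee value (supports off-grid fees)
  X[, ncol(X)] <- as.numeric(df[[space$cost_name]])

  task_key <- paste(df$resp_id, df$task, sep = "\r")
  task_id <- match(task_key, unique(task_key))
  n_task <- max(task_id)
  task_start <- c(0L, cumsum(tabulate(task_id, n_task)))
  ch <- which(df$chosen == 1)
  if (length(ch) != n_task) stop("each task needs exactly one chosen alternative",
                                 call. = FALSE)
  chosen_row <- ch - 1L
  resp_ids <- unique(df$resp_id)
  resp_of_task <- match(df$resp_id[task_start[-length(task_start)] + 1L], resp_ids) - 1L
  list(X = X, task_start = as.integer(task_start),
       chosen_row = as.integer(chosen_row), task_resp = as.integer(resp_of_task),
       resp_ids = resp_ids, n_resp = length(resp_ids), n_task = n_task)
}
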