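#' Names of the encoded predictors
#'
#' Column names of the dummy-coded design matrix: `asc_left` (the
#' left-position alternative-specific constant), then one `attribute.level`
#' dummy per non-reference level of each categorical attribute in attribute
#' order, then the cost attribute.
#'
#' @param space an `attribute_space`.
#' @param asc include the `asc_left` column name first (default TRUE).
#' @return character vector of predictor names.
#' @export
predictor_names <- function(space, asc = TRUE) {
  stopifnot(inherits(space, "attribute_space"))
  nm <- character(0)
  for (a in space$attributes) {
    if (a$kind == "categorical") {
      nm <- c(nm, paste(a$name, a$levels[-1], sep = "."))
    }
  }
  nm <- c(nm, space$cost_name)
  if (asc) nm <- c("asc_left", nm)
  nm
}

#' Dummy-encode one alternative
#'
#' Turns a full profile (one level per attribute) into the predictor vector
#' used by the choice models: 0/1 indicators for every non-reference level of
#' each categorical attribute, the cost value passed through in money units,
#' and a left-position indicator. An alternative at all reference levels with
#' zero cost encodes to the zero vector (ASC aside).
#'
#' @param levels named character vector or list giving one level label per
#'   attribute of `space` (the cost attribute's label is its money value).
#' @param space an `attribute_space`.
#' @param position `"left"` if the alternative is listed first in its choice
#'   set, `"right"` (or anything else) otherwise.
#' @return named numeric vector of length `n_predictors(space) + 1`.
#' @export
#' @examples
#' sp <- npi_attribute_space()
#' encode_profile(c(masks = "public", dining = "any_group",
#'                  vocalization = "allowed", events = "allowed",
#'                  quarantine = "none", booster = "not_compulsory",
#'                  fee = "30"), sp, position = "left")
encode_profile <- function(levels, space, position = "right") {
  stopifnot(inherits(space, "attribute_space"))
  idx <- levels_to_index(levels, space)
  x <- encode_index_matrix(matrix(idx, nrow = 1), space)[1, ]
  x <- c(asc_left = as.numeric(identical(position, "left")), x)
  x
}

# level labels (named vector/list) -> integer index vector in attribute order
levels_to_index <- function(levels, space) {
  idx <- integer(length(space$attributes))
  for (i in seq_along(space$attributes)) {
    a <- space$attributes[[i]]
    lab <- as.character(levels[[a$name]])
    if (length(lab) != 1 || is.na(lab)) {
      stop("missing level for attribute '", a$name, "'", call. = FALSE)
    }
    j <- match(lab, a$levels)
    if (is.na(j) && a$kind == "cost") {
      # allow numeric fee values written without the exact label formatting
      j <- match(as.numeric(lab), space$cost_levels)
    }
    if (is.na(j)) {
      stop("unknown level '", lab, "' for attribute '", a$name, "'", call. = FALSE)
    }
    idx[i] <- j
  }
  idx
}

# integer index matrix (rows = alternatives, cols = attributes) -> dummy matrix
# with fee in money units; no ASC column.
encode_index_matrix <- function(idx, space) {
  n <- nrow(idx)
  cols <- predictor_names(space, asc = FALSE)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  p <- 0L
  for (k in seq_along(space$attributes)) {
    a <- space$attributes[[k]]
    if (a$kind == "categorical") {
      L <- length(a$levels)
      for (l in 2:L) {
        p <- p + 1L
        X[, p] <- as.numeric(idx[, k] == l)
      }
    }
  }
  X[, length(cols)] <- space$cost_levels[idx[, ncol(idx)]]
  X
}

#' Decode an encoded alternative back to its profile
#'
#' Inverse of [encode_profile()] on valid encodings: recovers the level label
#' of every attribute (reference level where all of an attribute's dummies
#' are zero) and the listing position from the ASC.
#'
#' @param x named numeric vector as produced by [encode_profile()].
#' @param space an `attribute_space`.
#' @return list with `levels` (named character vector) and `position`.
#' @export
decode_profile <- function(x, space) {
  stopifnot(inherits(space, "attribute_space"))
  out <- character(length(space$attributes))
  names(out) <- names(space$attributes)
  for (a in space$attributes) {
    if (a$kind == "categorical") {
      d <- x[paste(a$name, a$levels[-1], sep = ".")]
      hit <- which(d == 1)
      if (length(hit) > 1) stop("invalid encoding: multiple dummies set for '", a$name, "'")
      out[a$name] <- if (length(hit) == 0) a$levels[1] else a$levels[1 + hit]
    } else {
      fee <- x[[space$cost_name]]
      j <- match(fee, space$cost_levels)
      out[a$name] <- if (is.na(j)) as.character(fee) else a$levels[j]
    }
  }
  list(levels = out, position = if (isTRUE(x[["asc_left"]] == 1)) "left" else "right")
}
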