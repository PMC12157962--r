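#' Define the attribute space of a discrete choice experiment
#'
#' An attribute space lists the attributes shown to respondents, each with an
#' ordered set of levels. Exactly one attribute is the cost attribute, whose
#' levels are money values; all others are categorical. The first level of
#' each categorical attribute is the reference category (by convention the
#' least stringent policy option, e.g. "no restriction"), against which the
#' remaining levels are dummy-coded.
#'
#' @param categorical named list; each element is a character vector of level
#'   labels (length >= 2) for one categorical attribute, reference level first.
#' @param cost_name name of the cost attribute (a one-time fee in the default
#'   application).
#' @param cost_levels numeric vector of money values (length >= 2) used as the
#'   levels of the cost attribute.
#' @return An object of class `attribute_space`.
#' @seealso [npi_attribute_space()] for the canonical space used throughout
#'   the package's examples and simulation defaults.
#' @export
#' @examples
#' sp <- attribute_space(
#'   categorical = list(masks = c("none", "required")),
#'   cost_name = "fee", cost_levels = c(0, 10)
#' )
#' n_predictors(sp)
attribute_space <- function(categorical, cost_name = "fee", cost_levels) {
  if (!is.list(categorical) || length(categorical) < 1 ||
      is.null(names(categorical)) || any(names(categorical) == "")) {
    stop("`categorical` must be a named list of level-label vectors", call. = FALSE)
  }
  for (nm in names(categorical)) {
    lv <- categorical[[nm]]
    if (!is.character(lv) || length(lv) < 2 || anyDuplicated(lv)) {
      stop("attribute '", nm, "' needs >= 2 distinct character levels", call. = FALSE)
    }
  }
  if (!is.numeric(cost_levels) || length(cost_levels) < 2 || anyDuplicated(cost_levels)) {
    stop("`cost_levels` must be >= 2 distinct money values", call. = FALSE)
  }
  if (cost_name %in% names(categorical)) {
    stop("cost attribute name clashes with a categorical attribute", call. = FALSE)
  }
  attrs <- c(
    lapply(names(categorical), function(nm) {
      list(name = nm, levels = categorical[[nm]], kind = "categorical")
    }),
    list(list(name = cost_name, levels = as.character(cost_levels), kind = "cost"))
  )
  names(attrs) <- vapply(attrs, `[[`, "", "name")
  structure(
    list(attributes = attrs, cost_name = cost_name, cost_levels = as.numeric(cost_levels)),
    class = "attribute_space"
  )
}

#' Canonical NPI attribute space
#'
#' The seven-attribute space of the package's reference application: public
#' preferences for nonpharmaceutical interventions (NPIs) against a new
#' SARS-CoV-2 variant in Singapore. Six categorical NPI attributes (masking,
#' dining-group limits, vocalization activities, large-scale events,
#' post-travel quarantine, booster mandate) plus a one-time fee in SGD with
#' levels $0/$10/$30/$50. Reference levels are the least stringent option of
#' each attribute.
#'
#' @return An `attribute_space` with 7 attributes; the dummy encoding of this
#'   space has 11 attribute predictors plus the fee.
#' @export
npi_attribute_space <- function() {
  attribute_space(
    categorical = list(
      masks        = c("none", "indoors", "public"),
      dining       = c("any_group", "five_people", "two_people", "not_allowed"),
      vocalization = c("allowed", "not_allowed"),
      events       = c("allowed", "not_allowed"),
      quarantine   = c("none", "home", "government_facility"),
      booster      = c("not_compulsory", "compulsory")
    ),
    cost_name = "fee",
    cost_levels = c(0, 10, 30, 50)
  )
}

#' Serialise / deserialise an attribute space
#'
#' Writes the attribute definitions (names, ordered levels, cost levels) to
#' JSON or YAML, chosen by file extension, and reads them back.
#'
#' @param space an `attribute_space`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_attribute_space` returns `path` invisibly;
#'   `read_attribute_space` returns the `attribute_space`.
#' @export
write_attribute_space <- function(space, path) {
  stopifnot(inherits(space, "attribute_space"))
  cats <- Filter(function(a) a$kind == "categorical", space$attributes)
  obj <- list(categorical = lapply(cats, `[[`, "levels"),
              cost_name = space$cost_name, cost_levels = space$cost_levels)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_attribute_space
#' @export
read_attribute_space <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  attribute_space(categorical = lapply(obj$categorical, as.character),
                  cost_name = obj$cost_name,
                  cost_levels = as.numeric(obj$cost_levels))
}

#' @export
print.attribute_space <- function(x, ...) {
  cat("Attribute space:", length(x$attributes), "attributes\n")
  for (a in x$attributes) {
    tag <- if (a$kind == "cost") " [cost]" else ""
    cat("  ", a$name, tag, ": ", paste(a$levels, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

# number of levels per attribute, in attribute order
attr_n_levels <- function(space) {
  vapply(space$attributes, function(a) length(a$levels), 0L)
}

#' Number of encoded predictors of an attribute space
#'
#' Dummy coding contributes one column per non-reference level of each
#' categorical attribute, plus one column for the (continuous) cost value.
#' The left-position alternative-specific constant is counted separately.
#'
#' @param space an `attribute_space`.
#' @return integer predictor count (dummies + cost, excluding the ASC).
#' @export
n_predictors <- function(space) {
  stopifnot(inherits(space, "attribute_space"))
  ncat <- sum(vapply(space$attributes, function(a) {
    if (a$kind == "categorical") length(a$levels) - 1L else 0L
  }, 0L))
  ncat + 1L
}

#' Design dimensions of a blocked choice experiment
#'
#' @param n_blocks number of questionnaire blocks (B).
#' @param tasks_per_block choice sets per block (a).
#' @param alts_per_task alternatives per choice set (t, >= 2).
#' @param space the `attribute_space`; supplies c, the largest number of
#'   levels over attributes.
#' @return a `design_dims` object with fields `B`, `a`, `t`, `c`.
#' @export
design_dims <- function(n_blocks, tasks_per_block, alts_per_task, space) {
  stopifnot(inherits(space, "attribute_space"))
  B <- as.integer(n_blocks); a <- as.integer(tasks_per_block); t <- as.integer(alts_per_task)
  if (is.na(B) || B < 1 || is.na(a) || a < 1 || is.na(t) || t < 2) {
    stop("need n_blocks >= 1, tasks_per_block >= 1, alts_per_task >= 2", call. = FALSE)
  }
  structure(list(B = B, a = a, t = t, c = max(attr_n_levels(space))),
            class = "design_dims")
}

#' @export
print.design_dims <- function(x, ...) {
  cat(sprintf("Design dimensions: B=%d blocks x a=%d tasks x t=%d alternatives (c=%d)\n",
              x$B, x$a, x$t, x$c))
  invisible(x)
}

#' Sample-size requirements for a blocked choice experiment
#'
#' Two standard rules of thumb: the Johnson--Orme rule
#' n > 500 c / (t a), where c is the largest number of levels of any
#' attribute, t the alternatives per choice set and a the sets per block
#' (rounded up); and the Lancsar--Louviere rule of a fixed number of
#' responses (default 20) per questionnaire block. The recommendation is the
#' larger of the two.
#'
#' @param dims a `design_dims` object, or NULL if `c`, `t`, `a`, `B` are
#'   given directly.
#' @param c,t,a,B scalar dimensions (largest level count, alternatives per
#'   set, sets per block, blocks); ignored when `dims` is supplied.
#' @param per_block_rule responses required per block (default 20).
#' @return list with `orme_n`, `block_rule_n` and `recommended_n`.
#' @export
#' @examples
#' # canonical design: 4-level fee attribute, 2 alternatives, 7 tasks, 20 blocks
#' sample_size_requirements(c = 4, t = 2, a = 7, B = 20)
sample_size_requirements <- function(dims = NULL, c = NULL, t = NULL, a = NULL,
                                     B = NULL, per_block_rule = 20) {
  if (!is.null(dims)) {
    stopifnot(inherits(dims, "design_dims"))
    c <- dims$c; t <- dims$t; a <- dims$a; B <- dims$B
  }
  vals <- c(c = c, t = t, a = a, B = B, per_block_rule = per_block_rule)
  if (any(is.na(vals)) || any(vals <= 0)) {
    stop("all design dimensions must be positive", call. = FALSE)
  }
  if (t < 2) stop("need at least 2 alternatives per choice set", call. = FALSE)
  orme <- as.integer(ceiling(500 * c / (t * a)))
  block <- as.integer(per_block_rule * B)
  list(orme_n = orme, block_rule_n = block, recommended_n = max(orme, block))
}
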