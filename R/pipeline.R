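#' Read long-format choice data from CSV
#'
#' Ingests a long-format choice CSV (columns `resp_id`, `block`, `task`,
#' `alt`, one column per attribute, `left_asc`, `chosen`) and validates it
#' against the attribute space. Respondents with incomplete or inconsistent
#' tasks (no chosen alternative, more than one chosen alternative, or fewer
#' tasks than their block requires) are removed listwise — mirroring the
#' exclusion of survey respondents who skip questions — and the count is
#' reported via a message and the `n_excluded` attribute. Structural errors
#' that survive exclusion (unknown levels, duplicated chosen rows across all
#' respondents) abort with the offending rows named.
#'
#' @param path CSV path.
#' @param space the `attribute_space` describing the level columns.
#' @param tasks_per_block expected tasks per respondent; default infers the
#'   maximum observed.
#' @return a `choice_data` object with attribute `n_excluded`.
#' @export
read_choice_data <- function(path, space, tasks_per_block = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("resp_id", "block", "task", "alt", names(space$attributes),
            "left_asc", "chosen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("input CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(df$resp_id, df$task)
  chosen_per_task <- rowsum(df$chosen, key)
  bad_tasks <- rownames(chosen_per_task)[chosen_per_task[, 1] != 1]
  bad_resp <- unique(df$resp_id[key %in% bad_tasks])
  if (length(bad_tasks)) {
    message("dropping ", length(bad_resp),
            " respondent(s) with malformed tasks (respondent task): ",
            paste(utils::head(bad_tasks, 5), collapse = "; "))
  }
  a_expected <- tasks_per_block %||% max(tapply(df$task, df$resp_id,
                                                function(t) length(unique(t))))
  n_tasks <- tapply(df$task, df$resp_id, function(t) length(unique(t)))
  incomplete <- names(n_tasks)[n_tasks < a_expected]
  if (length(incomplete)) {
    message("dropping ", length(incomplete),
            " respondent(s) with incomplete blocks (fewer than ",
            a_expected, " tasks)")
  }
  drop_ids <- union(as.character(bad_resp), incomplete)
  df <- df[!(as.character(df$resp_id) %in% drop_ids), , drop = FALSE]
  if (nrow(df) == 0) stop("no complete respondents remain after exclusion",
                          call. = FALSE)
  out <- choice_data(df, space)
  attr(out, "n_excluded") <- length(drop_ids)
  out
}

#' Write choice data to CSV
#'
#' @param data a `choice_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_choice_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()]. Exactly one of `simulate` (generate a
#' synthetic panel) or `data_path` (ingest a long-format CSV) must be
#' active. All stage seeds are derived from `seed`.
#'
#' @param n_blocks,tasks_per_block,alts_per_task design dimensions.
#' @param n_respondents panel size for simulation.
#' @param simulate logical: simulate choices (TRUE) or read `data_path`.
#' @param sim_model `"pooled"` or `"two_class"` simulation truth
#'   ([npi_simulation_config()]).
#' @param data_path long-format CSV when `simulate = FALSE`.
#' @param profiles_path covariate CSV when `simulate = FALSE` (needs an `id`
#'   column matching `resp_id`).
#' @param R draws per respondent for estimation.
#' @param k_range candidate class counts for BIC selection.
#' @param n_starts optimisation starts per mixture fit.
#' @param design_iter swap proposals for the design optimiser.
#' @param seed master seed.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(n_blocks = 20, tasks_per_block = 7, alts_per_task = 2,
                            n_respondents = 1500, simulate = TRUE,
                            sim_model = "pooled", data_path = NULL,
                            profiles_path = NULL, R = 500, k_range = 1:3,
                            n_starts = 5, design_iter = 4000, seed = 1) {
  if (simulate && !is.null(data_path)) {
    stop("exactly one of simulation or a data path may be active", call. = FALSE)
  }
  if (!simulate && is.null(data_path)) {
    stop("simulate = FALSE requires `data_path`", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`; keys as in
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg$k_range <- if (!is.null(cfg$k_range)) as.integer(unlist(cfg$k_range))
  do.call(pipeline_config, cfg[!vapply(cfg, is.null, TRUE)])
}

#' Run the full design-simulate-fit-report pipeline
#'
#' End-to-end orchestration: construct the blocked design, simulate (or
#' ingest) the choice panel, fit the mixed logit, fit the mixture over the
#' candidate class counts and select K by BIC, convert the selected model to
#' willingness-to-pay and preference summaries, and write every table plus a
#' JSON run manifest (seeds, settings, convergence flags) to `out_dir`.
#' Re-running with the same configuration is bit-identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param space attribute space (default [npi_attribute_space()]).
#' @return the report bundle (design, data, fits, BIC table, WTP and
#'   preference tables, manifest), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, space = npi_attribute_space()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  dims <- design_dims(config$n_blocks, config$tasks_per_block,
                      config$alts_per_task, space)

  design <- generate_design(space, dims, seed = seed + 1L,
                            n_iter = config$design_iter)

  if (config$simulate) {
    profiles <- simulate_profiles(config$n_respondents, seed = seed + 2L)
    sim <- npi_simulation_config(config$sim_model)
    data <- simulate_choices(design, profiles, sim, seed = seed + 3L)
  } else {
    data <- read_choice_data(config$data_path, space,
                             tasks_per_block = dims$a)
    profiles <- if (!is.null(config$profiles_path)) {
      utils::read.csv(config$profiles_path, stringsAsFactors = TRUE)
    } else NULL
  }

  n_resp <- length(unique(data$resp_id))
  req <- sample_size_requirements(dims)
  if (n_resp < req$recommended_n) {
    warning(sprintf(paste0(
      "sample size %d is below the recommendation of %d ",
      "(Orme rule-of-thumb 500c/(ta): %d; 20-per-block rule: %d)"),
      n_resp, req$recommended_n, req$orme_n, req$block_rule_n), call. = FALSE)
  }

  mxl <- fit_mxl(data, R = config$R, seed = seed + 4L)
  sel <- if (!is.null(profiles)) {
    select_k(data, profiles, k_range = config$k_range, R = config$R,
             seed = seed + 5L, n_starts = config$n_starts)
  } else NULL
  best <- if (!is.null(sel)) sel$fits[[as.character(sel$best_k)]] else NULL

  wtp_mxl <- tryCatch(compute_wtp(mxl), error = function(e) NULL)
  wtp_classes <- if (!is.null(best) && best$K >= 1) {
    lapply(seq_len(best$K), function(k) {
      tryCatch(compute_wtp(best, class = k), error = function(e) NULL)
    })
  } else NULL
  ors <- if (!is.null(best) && best$K >= 2) {
    tryCatch(membership_odds_ratios(best), error = function(e) NULL)
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcemix")),
    seed = seed,
    stage_seeds = list(design = seed + 1L, profiles = seed + 2L,
                       choices = seed + 3L, mxl = seed + 4L, mmml = seed + 5L),
    dims = unclass(dims), n_respondents = n_resp,
    sample_size_rules = req, R = config$R,
    k_range = config$k_range,
    mxl_converged = mxl$convergence, mxl_loglik = mxl$loglik,
    best_k = if (!is.null(sel)) sel$best_k else NA,
    bic_table = if (!is.null(sel)) sel$table else NULL,
    excluded = attr(data, "n_excluded") %||% 0L
  )

  bundle <- list(design = design, data = data, profiles = profiles,
                 mxl = mxl, selection = sel, best = best,
                 wtp_mxl = wtp_mxl, wtp_classes = wtp_classes,
                 membership_or = ors,
                 preference_mxl = preference_summary(mxl),
                 preference_best = if (!is.null(best)) preference_summary(best),
                 manifest = manifest)
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  invisible(bundle)
}

#' Write a pipeline report bundle to disk
#'
#' Canonical file layout: design and encoded-design CSVs, the choice data and
#' profiles, mixed-logit and per-class coefficient tables, the BIC table,
#' WTP and preference-direction tables, membership odds ratios, per-
#' respondent posteriors and `manifest.json`.
#'
#' @param bundle as returned by [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_design(bundle$design, fp("design.csv"), fp("design_encoded.csv"))
  write_choice_data(bundle$data, fp("choices.csv"))
  if (!is.null(bundle$profiles)) {
    utils::write.csv(bundle$profiles, fp("profiles.csv"), row.names = FALSE)
  }
  write_coef_table(bundle$mxl, fp("mxl_coefficients.csv"))
  if (!is.null(bundle$best)) {
    write_coef_table(bundle$best, fp("mmml_coefficients.csv"))
    utils::write.csv(bundle$best$posterior, fp("posteriors.csv"), row.names = FALSE)
    utils::write.csv(data.frame(class = seq_along(bundle$best$shares),
                                share = as.numeric(bundle$best$shares)),
                     fp("class_shares.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$selection)) {
    utils::write.csv(bundle$selection$table, fp("bic_table.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$wtp_mxl)) write_wtp(bundle$wtp_mxl, fp("wtp_mxl.csv"))
  if (!is.null(bundle$wtp_classes)) {
    for (k in seq_along(bundle$wtp_classes)) {
      if (!is.null(bundle$wtp_classes[[k]])) {
        write_wtp(bundle$wtp_classes[[k]], fp(sprintf("wtp_class%d.csv", k)))
      }
    }
  }
  if (!is.null(bundle$membership_or)) {
    utils::write.csv(bundle$membership_or, fp("membership_odds_ratios.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$preference_mxl, fp("preference_mxl.csv"), row.names = FALSE)
  if (!is.null(bundle$preference_best)) {
    utils::write.csv(bundle$preference_best, fp("preference_classes.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}
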