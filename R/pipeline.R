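#' Complete-case sensitivity subset
#'
#' Restricts a cohort table to children with a valid weighted-week
#' composition at both timepoints (and, optionally, a non-missing outcome),
#' the subset used for sensitivity analyses when per-timepoint model
#' samples differ.
#'
#' @param children Cohort children table with `valid_y5`/`valid_y8` flags
#'   (or equivalently non-missing compositions at both timepoints).
#' @param outcome Optional outcome column that must also be non-missing.
#' @return The filtered children table.
#' @export
complete_case_subset <- function(children, outcome = NULL) {
  comp_cols <- c(paste0(mb_behaviors(), "_y5"), paste0(mb_behaviors(), "_y8"))
  miss <- setdiff(comp_cols, names(children))
  if (length(miss)) stop("both-timepoint composition columns required; missing: ",
                         paste(miss, collapse = ", "))
  keep <- complete.cases(children[, comp_cols, drop = FALSE])
  if (!is.null(outcome)) keep <- keep & !is.na(children[[outcome]])
  children[keep, , drop = FALSE]
}

#' Worked example: substitution estimates from a published rotation table
#'
#' Reproduces the pencil-and-paper check that links a published
#' per-behavior association table to published substitution estimates: clr
#' coefficients are reconstructed from the four rotation-wise ilr1 mean
#' differences ([reconstruct_clr_coefficients]) and applied to a 30-min
#' MVPA/sleep reallocation at the published compositional mean. The default
#' inputs are the covariate-adjusted academic-achievement estimates and
#' compositional means of the motivating cohort study (point estimates as
#' printed, used as fixed numeric inputs).
#'
#' @param b_y5,b_y8 Rotation-wise ilr1 estimates (MVPA, LPA, inactivity,
#'   sleep lead) at the two timepoints.
#' @param mean_y5,mean_y8 Reference compositional means (min/day).
#' @param minutes Reallocation duration (default 30).
#' @return Data frame with one row per (timepoint, direction): the
#'   predicted academic-achievement change in z-score units.
#' @export
worked_example <- function(b_y5 = c(-0.367, 0.08, -0.291, 0.578),
                           b_y8 = c(-0.282, 0.125, -0.374, 0.532),
                           mean_y5 = c(mvpa = 68, lpa = 343,
                                       inactivity = 487, sleep = 542),
                           mean_y8 = c(mvpa = 67, lpa = 336,
                                       inactivity = 509, sleep = 527),
                           minutes = 30) {
  one <- function(b, base, tp) {
    g <- reconstruct_clr_coefficients(b)
    fwd <- predict_difference(g, base, reallocate(base, "mvpa", "sleep", minutes))
    rev <- predict_difference(g, base, reallocate(base, "sleep", "mvpa", minutes))
    data.frame(timepoint = tp,
               reallocation = c("mvpa_to_sleep", "sleep_to_mvpa"),
               minutes = minutes, delta = c(fwd$delta, rev$delta))
  }
  rbind(one(b_y5, mean_y5, "y5"), one(b_y8, mean_y8, "y8"))
}

default_model_grid <- function() {
  expand.grid(outcome = c("ef_score", "academic_score"),
              timepoint = c("y5", "y8"), model = 1:2,
              stringsAsFactors = FALSE)
}

covariate_rhs <- function(timepoint)
  c("sex", "ethnicity", "maternal_age", "maternal_education",
    paste0("bmi_", timepoint))

## fit one Table-3-style block: rotation table for outcome x timepoint x model
fit_coda_block <- function(children, outcome, timepoint, model) {
  rhs <- if (model == 1) "1" else covariate_rhs(timepoint)
  rotation_table(reformulate(rhs, response = outcome), children,
                 parts = paste0(mb_behaviors(), "_", timepoint))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: simulate a cohort (or read one from
#' file), score the latent cognitive outcomes, fit the compositional
#' rotation tables for every outcome x timepoint x model, evaluate the
#' isotemporal substitution surface for the adjusted models, and fit the
#' domain-specific activity models. All tables are returned and, when
#' `output_dir` is given, written as tab-delimited text along with the
#' configuration and seed.
#'
#' @param config Either a list / YAML file path with fields `n_children`,
#'   `seed`, optional `cohort` overrides (passed to [cohort_config]),
#'   optional `durations`, and optional logical `complete_case`; or an
#'   `"mb_cohort"` object to analyze directly.
#' @param output_dir Optional directory for the report bundle.
#' @param seed Overrides the config seed.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `children`, `daily`, `scores` (latent
#'   fits), `coda` (named list of rotation tables), `substitution` (named
#'   list of surfaces), `domain` (data frame of all domain-model rows), and
#'   `meta`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message("[movecoda] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)

  if (inherits(config, "mb_cohort")) {
    cohort <- config
    opts <- list()
  } else {
    opts <- config
    cfg_args <- c(list(n_children = opts$n_children %||% 432),
                  opts$cohort %||% list())
    cc <- do.call(cohort_config, cfg_args)
    seed <- seed %||% opts$seed %||% stop("a seed is required")
    cohort <- stage("simulate", simulate_cohort(cc, seed = seed))
    log_msg("simulate: n = ", nrow(cohort$children), ", seed = ", seed)
  }
  children <- cohort$children
  durations <- opts$durations %||% seq(5, 60, by = 5)

  sc <- stage("score", score_cohort(children))
  children <- sc$children
  log_msg("score: EF n = ", sum(!is.na(children$ef_score)),
          ", academic n = ", sum(!is.na(children$academic_score)))

  if (isTRUE(opts$complete_case)) {
    children <- stage("sensitivity-subset", complete_case_subset(children))
    log_msg("complete-case subset: n = ", nrow(children))
  }

  grid <- default_model_grid()
  coda <- list()
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$outcome[i], grid$timepoint[i], paste0("m", grid$model[i]),
                 sep = "_")
    coda[[key]] <- stage(paste0("coda:", key),
                         fit_coda_block(children, grid$outcome[i],
                                        grid$timepoint[i], grid$model[i]))
    log_msg("coda ", key, ": n = ", attr(coda[[key]], "n"))
  }

  substitution <- list()
  for (tp in c("y5", "y8")) {
    for (outc in c("ef_score", "academic_score")) {
      key <- paste(outc, tp, sep = "_")
      fit <- attr(coda[[paste(outc, tp, "m2", sep = "_")]], "fits")[[1]]
      substitution[[key]] <- stage(paste0("substitute:", key),
                                   substitution_surface(fit,
                                                        durations = durations))
    }
  }
  log_msg("substitution surfaces: ", length(substitution), " (",
          length(durations), " durations x 12 ordered pairs)")

  domain_rows <- list()
  for (expo in names(domain_variable_specs())) {
    for (i in seq_len(nrow(grid))) {
      key <- paste(expo, grid$outcome[i], grid$timepoint[i], grid$model[i],
                   sep = "_")
      dl <- stage(paste0("domain:", key),
                  domain_lm(children, expo, grid$outcome[i],
                            grid$timepoint[i], model = grid$model[i]))
      domain_rows[[key]] <- cbind(
        data.frame(exposure = expo, block = dl$block,
                   outcome = grid$outcome[i], timepoint = grid$timepoint[i],
                   model = grid$model[i], n = dl$n, joint_p = dl$joint_p),
        dl$table)
    }
  }
  domain <- do.call(rbind, domain_rows)
  rownames(domain) <- NULL
  log_msg("domain models: ", length(domain_rows), " fits")

  meta <- list(seed = cohort$seed %||% seed, n_children = nrow(children),
               complete_case = isTRUE(opts$complete_case),
               durations = durations)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(x, file.path(output_dir, f), sep = "\t",
                                     row.names = FALSE, quote = FALSE)
    wt(children, "cohort.tsv")
    if (!is.null(cohort$daily)) wt(cohort$daily, "daily.tsv")
    coda_tab <- do.call(rbind, lapply(names(coda), function(k) {
      x <- coda[[k]]
      cbind(data.frame(model = k, n = attr(x, "n"),
                       joint_p = attr(x, "joint_p")), as.data.frame(x))
    }))
    wt(coda_tab, "coda_rotation_tables.tsv")
    sub_tab <- do.call(rbind, lapply(names(substitution), function(k)
      cbind(data.frame(model = k), as.data.frame(substitution[[k]]))))
    wt(sub_tab, "substitution_surfaces.tsv")
    wt(domain, "domain_models.tsv")
    loads <- rbind(
      data.frame(outcome = "ef", indicator = names(sc$ef_fit$loadings),
                 loading = unname(sc$ef_fit$loadings),
                 method = sc$ef_fit$method),
      data.frame(outcome = "academic",
                 indicator = names(sc$academic_fit$loadings),
                 loading = unname(sc$academic_fit$loadings),
                 method = sc$academic_fit$method))
    wt(loads, "factor_loadings.tsv")
    yaml::write_yaml(meta, file.path(output_dir, "run_meta.yaml"))
    log_msg("report bundle written to ", output_dir)
  }

  invisible(list(children = children, daily = cohort$daily,
                 scores = sc[c("ef_fit", "academic_fit")], coda = coda,
                 substitution = substitution, domain = domain, meta = meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
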