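#' Dichotomize an activity duration into participation yes/no
#'
#' For activities with near-zero participation in about half the sample
#' (organized PA/sports, active commuting, board/card games), minutes are
#' collapsed to "yes" iff strictly positive.
#'
#' @param minutes Non-negative numeric vector.
#' @return Factor with levels `c("no", "yes")`.
#' @export
dichotomize <- function(minutes) {
  if (any(minutes < 0, na.rm = TRUE)) stop("minutes must be non-negative")
  factor(ifelse(minutes > 0, "yes", "no"), levels = c("no", "yes"))
}

#' Categorize a duration into tertiles
#'
#' Cuts at the empirical 1/3 and 2/3 quantiles of the analysis sample.
#' Values exactly on a boundary fall in the lower category, which makes the
#' assignment deterministic under re-runs and permutation-invariant. If
#' more than a third of the values tie at a single value, a boundary is
#' undefined and a warning reports the tie count.
#'
#' @param minutes Numeric vector, length >= 3.
#' @return Factor with levels `c("low", "medium", "high")`; the cutpoints
#'   are attached as attribute `cutpoints`.
#' @export
tertile_categorize <- function(minutes) {
  x <- minutes[!is.na(minutes)]
  if (length(x) < 3) stop("need at least 3 observations")
  q <- quantile(x, c(1 / 3, 2 / 3), names = FALSE)
  tie_n <- max(table(x))
  if (tie_n > length(x) / 3)
    warning("a tertile boundary is undefined: ", tie_n,
            " observations tie at a single value")
  brk <- unique(c(-Inf, q[1], q[2], Inf))
  labs <- c("low", "medium", "high")[c(TRUE, q[1] < q[2], TRUE)]
  out <- cut(minutes, breaks = brk, labels = labs, right = TRUE)
  out <- factor(out, levels = c("low", "medium", "high"))
  attr(out, "cutpoints") <- q
  out
}

## the fixed treatment of each domain variable and its adjustment block
domain_variable_specs <- function() {
  list(
    organized_pa = list(treatment = "binary", block = "pa"),
    indoor_play = list(treatment = "tertile", block = "pa"),
    outdoor_play = list(treatment = "tertile", block = "pa"),
    active_commute = list(treatment = "binary", block = "pa"),
    svt = list(treatment = "continuous", block = "sb"),
    tv = list(treatment = "continuous", block = "sb"),
    handheld = list(treatment = "continuous", block = "sb"),
    board_games = list(treatment = "binary", block = "sb"),
    reading = list(treatment = "continuous", block = "sb"))
}

#' Domain-specific activity regression
#'
#' Fits the linear model for one parent-reported activity exposure against
#' a cognitive outcome. Variable treatment is fixed by convention:
#' organized PA, active commuting and board/card games are binary (yes/no);
#' indoor and outdoor active play are tertile-categorized on the analysis
#' sample; screen times and reading enter continuously in h/day.
#'
#' `model = 1` is unadjusted (exposure only). `model = 2` adjusts for sex,
#' ethnicity, maternal age, maternal education and child BMI, plus the
#' exposure's block: physical-activity exposures are co-adjusted for all
#' other PA domain variables and accelerometer-measured inactivity and
#' total sleep; sedentary exposures are co-adjusted for the remaining SB
#' variables, accelerometer-measured MVPA and total sleep. Screen-time
#' terms use either total screen-viewing time or its TV + handheld
#' components, never both (they are an exact linear combination); asking
#' for both is an error.
#'
#' @param data Cohort children table.
#' @param exposure One of `organized_pa`, `indoor_play`, `outdoor_play`,
#'   `active_commute`, `svt`, `tv`, `handheld`, `board_games`, `reading`.
#' @param outcome Outcome column name (e.g., `"ef_score"`).
#' @param timepoint `"y5"` or `"y8"`; domain and accelerometer columns are
#'   taken with this suffix.
#' @param model 1 (unadjusted) or 2 (adjusted).
#' @param screen_terms For SB models, `"svt"` or `"components"`
#'   (TV + handheld); defaults to the form implied by the exposure. A
#'   request that would place total SVT and a component in the same design
#'   is an error.
#' @param level Confidence level.
#' @return Object of class `"domain_lm"`: list with `lm`, `table` (one row
#'   per exposure contrast: estimate, CI, p), `joint_p` (partial F over the
#'   exposure's dummies; equals the single-coefficient p for non-tertile
#'   exposures), `n`, `exposure`, `block`, `model`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_children = 400), seed = 4)
#' sc <- score_cohort(coh$children)
#' domain_lm(sc$children, "reading", "academic_score", "y8", model = 2)
#' @export
domain_lm <- function(data, exposure, outcome, timepoint = c("y5", "y8"),
                      model = 2, screen_terms = NULL, level = 0.95) {
  timepoint <- match.arg(timepoint)
  specs <- domain_variable_specs()
  if (!exposure %in% names(specs)) stop("unknown domain exposure: ", exposure)
  spec <- specs[[exposure]]
  if (!model %in% 1:2) stop("'model' must be 1 or 2")

  if (is.null(screen_terms))
    screen_terms <- if (exposure %in% c("tv", "handheld")) "components" else "svt"
  screen_terms <- match.arg(screen_terms, c("svt", "components"))
  if (exposure == "svt" && screen_terms == "components")
    stop("total SVT and its components cannot enter the same model")
  if (exposure %in% c("tv", "handheld") && screen_terms == "svt")
    stop("total SVT and its components cannot enter the same model")

  tp <- function(v)
    if (length(v)) paste0(v, "_", timepoint) else character(0)
  covars <- c("sex", "ethnicity", "maternal_age", "maternal_education", tp("bmi"))
  pa_vars <- c("organized_pa", "indoor_play", "outdoor_play", "active_commute")
  sb_screen <- if (screen_terms == "svt") "svt" else c("tv", "handheld")
  sb_vars <- c(sb_screen, "board_games", "reading")

  adj_domain <- if (model == 1) character() else
    if (spec$block == "pa") setdiff(pa_vars, exposure) else
      setdiff(sb_vars, exposure)
  adj_accel <- if (model == 1) character() else
    if (spec$block == "pa") c("inactivity", "sleep") else c("mvpa", "sleep")
  adj_cov <- if (model == 1) character() else covars

  need <- c(outcome, tp(exposure), tp(adj_domain), tp(adj_accel), adj_cov)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  if (nrow(d) < 10) stop("too few complete cases")

  ## build analysis variables with treatment applied on the analysis sample
  prep <- function(v) {
    col <- d[[tp(v)]]
    switch(specs[[v]]$treatment,
           binary = if (is.factor(col)) col else dichotomize(col),
           tertile = tertile_categorize(col),
           continuous = col / 60)  # min/day -> h/day
  }
  av <- data.frame(.outcome = d[[outcome]])
  av[[exposure]] <- prep(exposure)
  for (v in adj_domain) av[[v]] <- prep(v)
  for (v in adj_accel) av[[v]] <- d[[tp(v)]]
  for (v in adj_cov) av[[sub(paste0("_", timepoint, "$"), "", v)]] <- d[[v]]

  fit <- lm(reformulate(setdiff(names(av), ".outcome"), response = ".outcome"),
            data = av)
  if (anyNA(coef(fit)))
    stop("collinear design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))

  cf <- summary(fit)$coefficients
  zq <- qnorm(1 - (1 - level) / 2)
  terms_of <- grep(paste0("^", exposure), rownames(cf), value = TRUE)
  tab <- data.frame(
    term = terms_of,
    contrast = sub(paste0("^", exposure), "", terms_of),
    estimate = cf[terms_of, 1],
    ci_low = cf[terms_of, 1] - zq * cf[terms_of, 2],
    ci_high = cf[terms_of, 1] + zq * cf[terms_of, 2],
    p_value = cf[terms_of, 4], row.names = NULL)

  ## joint p over the exposure's design columns (partial F)
  X <- model.matrix(fit)
  drop_cols <- colnames(X) %in% terms_of
  red <- lm.fit(X[, !drop_cols, drop = FALSE], av$.outcome)
  rss1 <- sum(residuals(fit)^2); rss0 <- sum(red$residuals^2)
  df1 <- sum(drop_cols); df2 <- fit$df.residual
  Fs <- ((rss0 - rss1) / df1) / (rss1 / df2)
  joint_p <- pf(Fs, df1, df2, lower.tail = FALSE)

  structure(list(lm = fit, table = tab, joint_p = joint_p, n = nrow(av),
                 exposure = exposure, block = spec$block,
                 treatment = specs[[exposure]]$treatment,
                 outcome = outcome, timepoint = timepoint, model = model),
            class = "domain_lm")
}

#' @export
print.domain_lm <- function(x, digits = 3, ...) {
  cat(sprintf("Domain model (%s block, model %d): %s ~ %s at %s, n = %d\n",
              toupper(x$block), x$model, x$outcome, x$exposure, x$timepoint, x$n))
  df <- x$table
  df$estimate <- sprintf("%.*f (%.*f, %.*f)", digits, df$estimate,
                         digits, df$ci_low, digits, df$ci_high)
  print(df[, c("contrast", "estimate", "p_value")], row.names = FALSE)
  if (x$treatment == "tertile")
    cat("joint p (2 df):", format.pval(x$joint_p, digits = 3), "\n")
  invisible(x)
}
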