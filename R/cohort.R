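#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter list that drives [simulate_cohort]. Defaults are
#' calibrated so that, at the default sample size, the generated cohort
#' reproduces the headline features of a Singaporean mother-child cohort
#' with wrist-accelerometer time use at ages 5.5 and 8 years:
#' weighted-week behavior minutes with arithmetic means/SDs near
#' 72/347/487/535 (SD 24/48/67/42) min/day at age 5.5 and 72/335/510/523
#' (SD 26/54/68/45) at age 8, organized-PA participation near 45%, active
#' commuting 58%/52%, board/card games 33%/35%, and covariate distributions
#' (sex 47% girls; ethnicity 58/27/15; maternal education 32/35/33;
#' maternal age bands 23/41/36; BMI 15.49 (1.85) and 16.42 (2.84) kg/m2).
#'
#' Daily behavior minutes follow a logistic-normal law: Gaussian on the
#' log-part scale (equivalently Gaussian in ilr coordinates) with a
#' child-level random effect plus independent day-level noise, a weekend
#' shift on the log scale, and closure of every day to 1440 min. Day
#' validity (the wear-time criterion) is emulated as a Bernoulli flag; a
#' child's timepoint is retained only if at least two weekdays and one
#' weekend day are valid, and the retained days are combined with 5:2
#' weekday:weekend weighting. The within-child weekday/weekend correlation
#' is governed by the child-level versus day-level variance split.
#'
#' Cognitive outcomes are generated from a planted linear model: a latent
#' outcome equals a linear predictor on the MVPA-first ilr coordinates of
#' the weighted-week composition, plus named domain/covariate terms, plus
#' Gaussian noise; indicator scores load on the standardized latent with
#' unit-variance residual split. All planted effects default to zero.
#'
#' @param n_children Number of children (default 432).
#' @param seed Optional integer recorded in the config and used as the
#'   default seed of [simulate_cohort].
#' @param ... Named overrides of any default component (top-level names of
#'   the returned list), merged recursively.
#' @return A list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_children = 500, p_valid_day = 0.9)
#' @export
cohort_config <- function(n_children = 432, seed = NULL, ...) {
  cfg <- list(
    n_children = n_children,
    seed = seed,
    timepoints = c("y5", "y8"),
    ## logistic-normal behavior law, log-minute scale (calibrated; see the
    ## methods vignette for the moment-matching procedure)
    behavior = list(
      y5 = list(logmean = c(4.182017, 5.849238, 6.211448, 6.297289),
                child_logsd = c(0.298878, 0.130069, 0.200743, 0.038189),
                day_logsd = c(0.35, 0.18, 0.15, 0.10),
                weekend_logshift = c(0.08, 0.03, -0.04, 0.02),
                child_cor_inact_sleep = 0.51),
      y8 = list(logmean = c(4.166046, 5.803313, 6.251126, 6.266527),
                child_logsd = c(0.329460, 0.167220, 0.191996, 0.050474),
                day_logsd = c(0.35, 0.18, 0.15, 0.10),
                weekend_logshift = c(0.08, 0.03, -0.04, 0.02),
                child_cor_inact_sleep = 0.30)),
    total = 1440,
    p_valid_day = 0.85,
    p_measured = c(y5 = 0.73, y8 = 0.90),
    sex_logpart_shift = c(0, 0, 0, 0),
    covariates = list(
      p_female = 0.47,
      ethnicity = c(chinese = 0.58, malay = 0.27, indian = 0.15),
      maternal_education = c(before_secondary = 0.32, post_secondary = 0.35,
                             university = 0.33),
      maternal_age = c(lt27 = 0.23, from27to33 = 0.41, gt33 = 0.36),
      bmi_y5 = c(mean = 15.49, sd = 1.85),
      bmi_y8 = c(mean = 16.42, sd = 2.84),
      bmi_corr = 0.7),
    ## parent-reported domain variables; durations in min/day, means on the
    ## weighted-day scale
    domain = list(
      y5 = list(p_organized = 0.45, p_commute = 0.58, p_board = 0.33,
                durations = list(
                  indoor_play = c(mean = 60, cv = 0.80),
                  outdoor_play = c(mean = 60, cv = 0.90),
                  tv = c(mean = 57, cv = 0.89),
                  handheld = c(mean = 40, cv = 1.10),
                  computer = c(mean = 10, cv = 1.20),
                  games = c(mean = 7, cv = 1.30),
                  reading = c(mean = 25, cv = 1.04))),
      y8 = list(p_organized = 0.45, p_commute = 0.52, p_board = 0.35,
                durations = list(
                  indoor_play = c(mean = 55, cv = 0.80),
                  outdoor_play = c(mean = 65, cv = 0.90),
                  tv = c(mean = 88, cv = 0.85),
                  handheld = c(mean = 64, cv = 1.10),
                  computer = c(mean = 18, cv = 1.20),
                  games = c(mean = 11, cv = 1.30),
                  reading = c(mean = 34, cv = 1.03)))),
    domain_weekend_mult = c(indoor_play = 1.3, outdoor_play = 1.3, tv = 1.5,
                            handheld = 1.5, computer = 1.5, games = 1.5,
                            reading = 1.0),
    domain_day_logsd = 0.3,
    ## planted outcome model (all null by default)
    effects = list(
      ef = list(ilr_y5 = c(0, 0, 0), ilr_y8 = c(0, 0, 0), vars = numeric()),
      academic = list(ilr_y5 = c(0, 0, 0), ilr_y8 = c(0, 0, 0), vars = numeric())),
    noise_sd = c(ef = 0.70, academic = 0.91),
    loadings = list(
      ef = c(inhibition_errors = 0.7, switching_errors = 0.7,
             working_memory = 0.7),
      academic = c(spelling = 0.8, reading_rate = 0.8,
                   reading_accuracy = 0.8, numerical_ops = 0.8)),
    ## raw indicator scales: mean, sd, and orientation (1 = higher is worse)
    indicator_raw = list(
      inhibition_errors = c(mean = 11, sd = 5, flip = 1),
      switching_errors = c(mean = 13, sd = 6, flip = 1),
      working_memory = c(mean = 10, sd = 3, flip = 0),
      spelling = c(mean = 100, sd = 15, flip = 0),
      reading_rate = c(mean = 95, sd = 18, flip = 0),
      reading_accuracy = c(mean = 100, sd = 12, flip = 0),
      numerical_ops = c(mean = 100, sd = 15, flip = 0)))
  cfg <- modifyList(cfg, list(...))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_children > 0)
  probs <- c(cfg$p_valid_day, cfg$p_measured, cfg$covariates$p_female,
             cfg$covariates$ethnicity, cfg$covariates$maternal_education,
             cfg$covariates$maternal_age,
             unlist(lapply(cfg$domain, function(d)
               c(d$p_organized, d$p_commute, d$p_board))))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (tp in cfg$timepoints) {
    b <- cfg$behavior[[tp]]
    if (is.null(b)) stop("missing behavior parameters for timepoint ", tp)
    if (any(b$child_logsd < 0) || any(b$day_logsd < 0))
      stop("log-scale SDs must be non-negative")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:", x$n_children, "children,",
      "timepoints", paste(x$timepoints, collapse = "/"), "\n")
  cat("p_valid_day =", x$p_valid_day,
      " p_measured =", paste(sprintf("%s %.2f", names(x$p_measured),
                                     x$p_measured), collapse = ", "), "\n")
  has_eff <- any(vapply(x$effects, function(e)
    any(c(e$ilr_y5, e$ilr_y8, e$vars) != 0), logical(1)))
  cat("planted outcome effects:", if (has_eff) "yes" else "none (null model)", "\n")
  invisible(x)
}

#' Simulate daily behavior minutes for one child
#'
#' Draws valid-day compositions from the configured logistic-normal law:
#' one child-level effect (shared across the returned days) plus day-level
#' noise, a weekend shift when `day_type = "weekend"`, and closure to the
#' daily total. Day validity is a Bernoulli flag; invalid days carry no
#' composition.
#'
#' @param config A [cohort_config].
#' @param n_days Number of days to draw.
#' @param day_type `"weekday"` or `"weekend"` (recycled to `n_days`).
#' @param timepoint `"y5"` or `"y8"`.
#' @param child_log Optional length-4 vector of the child's log-minute
#'   effect; drawn from the child-level law when `NULL`.
#' @param sex `"female"` or `"male"` (male receives
#'   `config$sex_logpart_shift`).
#' @return Data frame with columns `day_type`, `valid`, and the four
#'   behavior minutes (NA on invalid days).
#' @export
generate_daily_minutes <- function(config, n_days = 1,
                                   day_type = "weekday", timepoint = "y5",
                                   child_log = NULL, sex = "female") {
  bp <- config$behavior[[timepoint]]
  if (is.null(bp)) stop("unknown timepoint: ", timepoint)
  day_type <- rep(day_type, length.out = n_days)
  if (!all(day_type %in% c("weekday", "weekend")))
    stop("day_type must be 'weekday' or 'weekend'")
  if (is.null(child_log))
    child_log <- bp$logmean + (sex == "male") * config$sex_logpart_shift +
      drop(child_log_noise(1, bp))
  we <- day_type == "weekend"
  logm <- matrix(child_log, n_days, 4, byrow = TRUE) +
    outer(as.numeric(we), bp$weekend_logshift) +
    matrix(rnorm(n_days * 4), n_days, 4) %*% diag(bp$day_logsd)
  minutes <- close_composition(exp(logm), total = config$total)
  colnames(minutes) <- mb_behaviors()
  valid <- rbinom(n_days, 1, config$p_valid_day) == 1
  minutes[!valid, ] <- NA_real_
  data.frame(day_type = day_type, valid = valid, minutes)
}

#' Wear-validity inclusion rule
#'
#' A child's measurement week is retained only with at least two valid
#' weekdays and at least one valid weekend day.
#'
#' @param days Data frame with columns `day_type` (`"weekday"`/`"weekend"`)
#'   and `valid` (logical), one row per day of the protocol.
#' @return Logical scalar: include the child or not.
#' @export
apply_validity_rules <- function(days) {
  stopifnot(all(c("day_type", "valid") %in% names(days)))
  sum(days$valid & days$day_type == "weekday") >= 2 &&
    sum(days$valid & days$day_type == "weekend") >= 1
}

#' Weighted-week average composition
#'
#' Combines valid days into a weekly composition with weekend days weighted
#' 2/5 relative to weekdays: per behavior,
#' `(5 * mean(valid weekdays) + 2 * mean(valid weekend days)) / 7`, closed
#' to the daily total.
#'
#' @param days Data frame as returned by [generate_daily_minutes]: columns
#'   `day_type`, `valid`, and the behavior minutes.
#' @param parts Behavior column names (default [mb_behaviors()]).
#' @param total Closure total (default 1440).
#' @return Named composition vector.
#' @export
weighted_week_average <- function(days, parts = mb_behaviors(), total = 1440) {
  v <- days[days$valid, , drop = FALSE]
  wd <- v[v$day_type == "weekday", parts, drop = FALSE]
  we <- v[v$day_type == "weekend", parts, drop = FALSE]
  if (nrow(we) == 0L) stop("cannot weight: no valid weekend day")
  if (nrow(wd) == 0L) stop("cannot weight: no valid weekday")
  avg <- (5 * colMeans(wd) + 2 * colMeans(we)) / 7
  close_composition(setNames(avg, parts), total = total)
}

#' Weighted day average for parent-reported activities
#'
#' `(5 * weekday + 2 * weekend) / 7`, the conventional weighting of a
#' school-day report and a weekend-day report into minutes per average day.
#'
#' @param weekday_min,weekend_min Non-negative minutes (vectorized).
#' @return Minutes per day.
#' @examples
#' domain_day_average(60, 120)  # 600/7
#' @export
domain_day_average <- function(weekday_min, weekend_min) {
  if (any(weekday_min < 0) || any(weekend_min < 0))
    stop("minutes must be non-negative")
  (5 * weekday_min + 2 * weekend_min) / 7
}

#' Total screen-viewing time
#'
#' Sum of TV, computer, mobile/handheld device, and electronic-game
#' viewing minutes.
#'
#' @param tv,computer,mobile,games Non-negative minutes/day (vectorized).
#' @return Minutes/day.
#' @export
total_svt <- function(tv, computer, mobile, games) {
  if (any(c(tv, computer, mobile, games) < 0))
    stop("minutes must be non-negative")
  tv + computer + mobile + games
}

## child-level log-part deviations: independent except a positive
## inactivity-sleep correlation, which (through closure) reproduces the
## compensation between waking inactivity and sleep seen in real time use
child_log_noise <- function(n, bp) {
  z <- matrix(rnorm(n * 4), n, 4)
  r <- bp$child_cor_inact_sleep %||% 0
  z[, 4] <- r * z[, 3] + sqrt(1 - r^2) * z[, 4]
  z %*% diag(bp$child_logsd)
}

## vectorized one-timepoint behavior simulation; returns weekly composition
## matrix (NA rows for non-included children) and the daily long table
sim_behavior_timepoint <- function(config, tp, male) {
  n <- config$n_children
  bp <- config$behavior[[tp]]
  parts <- mb_behaviors()
  child_log <- matrix(bp$logmean, n, 4, byrow = TRUE) +
    outer(as.numeric(male), config$sex_logpart_shift) +
    child_log_noise(n, bp)
  measured <- runif(n) < config$p_measured[[tp]]
  valid <- matrix(rbinom(n * 7, 1, config$p_valid_day) == 1, n, 7)
  valid[!measured, ] <- FALSE
  day_minutes <- vector("list", 7)
  for (d in 1:7) {
    we <- d >= 6
    logm <- child_log + if (we) matrix(bp$weekend_logshift, n, 4, byrow = TRUE) else 0
    logm <- logm + matrix(rnorm(n * 4), n, 4) %*% diag(bp$day_logsd)
    m <- close_composition(exp(logm), total = config$total)
    colnames(m) <- parts
    day_minutes[[d]] <- m
  }
  nwd <- rowSums(valid[, 1:5, drop = FALSE])
  nwe <- rowSums(valid[, 6:7, drop = FALSE])
  included <- nwd >= 2 & nwe >= 1
  wdsum <- wesum <- matrix(0, n, 4)
  for (d in 1:5) wdsum <- wdsum + day_minutes[[d]] * valid[, d]
  for (d in 6:7) wesum <- wesum + day_minutes[[d]] * valid[, d]
  weekly <- matrix(NA_real_, n, 4, dimnames = list(NULL, parts))
  if (any(included)) {
    avg <- (5 * wdsum[included, , drop = FALSE] / nwd[included] +
            2 * wesum[included, , drop = FALSE] / nwe[included]) / 7
    weekly[included, ] <- close_composition(avg, total = config$total)
  }
  daily <- do.call(rbind, lapply(1:7, function(d) {
    m <- day_minutes[[d]]
    m[!valid[, d], ] <- NA_real_
    out <- data.frame(child_id = seq_len(n), timepoint = tp, day = d,
                      day_type = ifelse(d >= 6, "weekend", "weekday"),
                      valid = valid[, d])
    cbind(out, as.data.frame(m))
  }))
  daily <- daily[measured[daily$child_id], , drop = FALSE]
  list(weekly = weekly, included = included, daily = daily)
}

## vectorized domain variables for one timepoint; NA when not included
sim_domain_timepoint <- function(config, tp, included) {
  n <- config$n_children
  dp <- config$domain[[tp]]
  yes_no <- function(p) factor(ifelse(rbinom(n, 1, p) == 1, "yes", "no"),
                               levels = c("no", "yes"))
  out <- data.frame(organized_pa = yes_no(dp$p_organized),
                    active_commute = yes_no(dp$p_commute),
                    board_games = yes_no(dp$p_board))
  s_day <- config$domain_day_logsd
  for (v in names(dp$durations)) {
    pars <- dp$durations[[v]]
    mult <- config$domain_weekend_mult[[v]]
    ## set the child-level mean so the weighted day average hits the target
    target <- pars[["mean"]]
    adj <- target * 7 / ((5 + 2 * mult) * exp(s_day^2 / 2))
    s <- sqrt(log(1 + pars[["cv"]]^2))
    x <- rlnorm(n, meanlog = log(adj) - s^2 / 2, sdlog = s)
    wd <- x * exp(rnorm(n, 0, s_day))
    we <- x * mult * exp(rnorm(n, 0, s_day))
    out[[v]] <- domain_day_average(wd, we)
  }
  out$svt <- total_svt(out$tv, out$computer, out$handheld, out$games)
  out[!included, ] <- NA
  names(out) <- paste0(names(out), "_", tp)
  out
}

## resolve a named effect term to a numeric column of the children table
column_numeric <- function(df, nm) {
  if (nm == "sexmale") return(as.numeric(df$sex == "male"))
  v <- df[[nm]]
  if (is.null(v)) stop("unknown effect variable: ", nm)
  if (is.factor(v)) as.numeric(v == "yes") else as.numeric(v)
}

#' Simulate a synthetic cohort
#'
#' Generates a full cohort table (one row per child: covariates,
#' weighted-week behavior compositions at each timepoint, domain-specific
#' activity variables, latent cognitive outcomes and their indicator
#' scores) plus the underlying daily behavior table, from a
#' [cohort_config]. Identical config and seed give identical output.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed (default `config$seed`; required from one of
#'   the two places).
#' @return Object of class `"mb_cohort"`: list with `children` (data
#'   frame), `daily` (long data frame of measured days), `config`, `seed`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_children = 100), seed = 7)
#' head(coh$children)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  if (is.null(seed)) stop("a seed is required (argument or config$seed)")
  validate_cohort_config(config)
  set.seed(seed)
  n <- config$n_children
  cv <- config$covariates
  draw_cat <- function(p) factor(sample(names(p), n, replace = TRUE, prob = p),
                                 levels = names(p))
  children <- data.frame(
    child_id = seq_len(n),
    sex = factor(ifelse(runif(n) < cv$p_female, "female", "male"),
                 levels = c("female", "male")),
    ethnicity = draw_cat(cv$ethnicity),
    maternal_education = draw_cat(cv$maternal_education),
    maternal_age = draw_cat(cv$maternal_age))
  z1 <- rnorm(n)
  children$bmi_y5 <- cv$bmi_y5[["mean"]] + cv$bmi_y5[["sd"]] * z1
  children$bmi_y8 <- cv$bmi_y8[["mean"]] + cv$bmi_y8[["sd"]] *
    (cv$bmi_corr * z1 + sqrt(1 - cv$bmi_corr^2) * rnorm(n))

  daily <- list()
  coords <- list()
  male <- children$sex == "male"
  for (tp in config$timepoints) {
    beh <- sim_behavior_timepoint(config, tp, male)
    comp <- beh$weekly
    colnames(comp) <- paste0(mb_behaviors(), "_", tp)
    children <- cbind(children, as.data.frame(comp))
    children[[paste0("valid_", tp)]] <- beh$included
    children <- cbind(children, sim_domain_timepoint(config, tp, beh$included))
    daily[[tp]] <- beh$daily
    ic <- matrix(NA_real_, n, 3)
    if (any(beh$included))
      ic[beh$included, ] <- ilr_transform(beh$weekly[beh$included, , drop = FALSE],
                                          ilr_basis())
    coords[[tp]] <- ic
  }

  for (outc in c("ef", "academic")) {
    eff <- config$effects[[outc]]
    lp <- numeric(n)
    for (tp in c("y5", "y8")) {
      bet <- eff[[paste0("ilr_", tp)]]
      if (!is.null(bet) && any(bet != 0)) lp <- lp + drop(coords[[tp]] %*% bet)
    }
    for (nm in names(eff$vars))
      lp <- lp + eff$vars[[nm]] * column_numeric(children, nm)
    latent <- lp + rnorm(n, 0, config$noise_sd[[outc]])
    children[[paste0(outc, "_latent")]] <- latent
    ok <- !is.na(latent)
    lat_std <- rep(NA_real_, n)
    lat_std[ok] <- (latent[ok] - mean(latent[ok])) / sd(latent[ok])
    for (ind in names(config$loadings[[outc]])) {
      lam <- config$loadings[[outc]][[ind]]
      raw <- config$indicator_raw[[ind]]
      u <- lam * lat_std + sqrt(1 - lam^2) * rnorm(n)
      if (raw[["flip"]] == 1) u <- -u
      children[[ind]] <- raw[["mean"]] + raw[["sd"]] * u
    }
  }

  structure(list(children = children, daily = do.call(rbind, daily),
                 config = config, seed = seed),
            class = "mb_cohort")
}

#' @export
print.mb_cohort <- function(x, ...) {
  cat("Synthetic movement-behavior cohort:", nrow(x$children), "children",
      "(seed", x$seed, ")\n")
  for (tp in x$config$timepoints)
    cat(sprintf("  %s: %d with valid weighted-week composition\n", tp,
                sum(x$children[[paste0("valid_", tp)]])))
  invisible(x)
}

#' Score cohort cognitive outcomes
#'
#' Applies [latent_score] to the executive-function indicator panel
#' (inhibition errors and switching errors flagged higher-is-worse, working
#' memory) and the academic panel (spelling, oral reading rate, oral
#' reading accuracy, numerical operations), adding `ef_score` and
#' `academic_score` columns.
#'
#' @param children Cohort children table (from [simulate_cohort] or read
#'   from file with the same column names).
#' @return List with `children` (table with score columns) and the two
#'   `"latent_fit"` objects (`ef_fit`, `academic_fit`).
#' @export
score_cohort <- function(children) {
  ef_cols <- c("inhibition_errors", "switching_errors", "working_memory")
  ac_cols <- c("spelling", "reading_rate", "reading_accuracy", "numerical_ops")
  miss <- setdiff(c(ef_cols, ac_cols), names(children))
  if (length(miss)) stop("missing indicator columns: ", paste(miss, collapse = ", "))
  ef_ok <- complete.cases(children[, ef_cols])
  ac_ok <- complete.cases(children[, ac_cols])
  ef_fit <- latent_score(children[ef_ok, ef_cols],
                         higher_is_worse = c("inhibition_errors",
                                             "switching_errors"))
  ac_fit <- latent_score(children[ac_ok, ac_cols])
  children$ef_score <- NA_real_
  children$ef_score[ef_ok] <- ef_fit$scores
  children$academic_score <- NA_real_
  children$academic_score[ac_ok] <- ac_fit$scores
  list(children = children, ef_fit = ef_fit, academic_fit = ac_fit)
}
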