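#' Compositional multiple linear regression on ilr coordinates
#'
#' Fits ordinary least squares of an outcome on the D-1 ilr coordinates of a
#' movement-behavior composition, plus any covariates given on the right-hand
#' side of `formula`. The composition enters as a block: the three
#' coordinates of the sequential binary partition are added to the model
#' automatically, so the formula names only the outcome and the adjustment
#' set. An intercept-only right-hand side (`outcome ~ 1`) gives the
#' unadjusted model; adding sex, ethnicity, maternal age, maternal education
#' and child BMI gives the covariate-adjusted model.
#'
#' Under the lead rotation chosen by `lead`, the coefficient on the first
#' coordinate (`ilr1`) is interpreted as the outcome difference associated
#' with more time in the leading behavior relative to the geometric mean of
#' the remaining behaviors. Fitted values, residuals and the joint
#' composition test are identical across rotations, since all rotations span
#' the same coordinate subspace.
#'
#' Rows with any missing value among the outcome, the parts or the
#' covariates are dropped (listwise deletion). Compositions containing exact
#' zeros are repaired by [zero_replace] with floor `zero_floor` before the
#' log-ratio transform.
#'
#' @param formula Model formula `outcome ~ covariates`. Do not include the
#'   part columns or `ilr*` terms; they are added internally.
#' @param data Data frame containing the outcome, covariates, and one column
#'   per behavior part (in minutes/day).
#' @param parts Character vector naming the part columns, in partition
#'   order. Default [mb_behaviors()].
#' @param lead Behavior leading the first ilr coordinate (default first of
#'   `parts`).
#' @param total Closure total in minutes (default 1440).
#' @param zero_floor Floor passed to [zero_replace] for zero parts.
#' @return An object of class `"coda_lm"`: a list with components `lm` (the
#'   underlying [stats::lm] fit), `basis` (the [ilr_basis] used), `parts`,
#'   `composition` (the closed analysis compositions), `n`, `formula`,
#'   `model_data` (the complete-case analysis frame), and `call`.
#' @seealso [rotation_table], [joint_composition_test], [predict_difference],
#'   [substitution_surface]
#' @examples
#' coh <- simulate_cohort(cohort_config(n_children = 200), seed = 1)
#' fit <- coda_lm(academic_latent ~ sex + bmi_y5,
#'                data = coh$children,
#'                parts = c("mvpa_y5", "lpa_y5", "inactivity_y5", "sleep_y5"))
#' summary(fit)
#' @export
coda_lm <- function(formula, data, parts = mb_behaviors(), lead = NULL,
                    total = 1440, zero_floor = 1) {
  cl <- match.call()
  if (length(parts) < 2) stop("need at least two parts")
  missing_parts <- setdiff(parts, names(data))
  if (length(missing_parts))
    stop("part columns not found in data: ", paste(missing_parts, collapse = ", "))
  ilr_names <- paste0("ilr", seq_len(length(parts) - 1L))
  if (any(ilr_names %in% all.vars(formula)))
    stop("'ilr' terms are added automatically; remove them from the formula")

  ## part order given by `parts`; lead defaults to the first part
  part_labels <- parts
  if (is.null(lead)) lead <- parts[1]
  lead_idx <- match(lead, parts)
  if (is.na(lead_idx)) stop("unknown behavior name: ", lead)
  basis <- ilr_basis(part_labels, lead = lead)

  vars <- unique(c(all.vars(formula), parts))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variables not found in data: ", paste(missing_vars, collapse = ", "))
  keep <- complete.cases(data[, vars, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete cases")

  comp <- as.matrix(d[, parts, drop = FALSE])
  if (any(comp < 0)) stop("negative part values")
  if (any(comp == 0)) comp <- zero_replace(comp, floor = zero_floor)
  comp <- close_composition(comp, total = total)
  coords <- ilr_transform(comp, basis)
  colnames(coords) <- ilr_names

  mdata <- cbind(d, as.data.frame(coords))
  rhs <- attr(terms(formula, data = data), "term.labels")
  full_formula <- reformulate(c(ilr_names, rhs), response = formula[[2]],
                              intercept = TRUE)
  fit <- lm(full_formula, data = mdata)
  if (anyNA(coef(fit)))
    stop("collinear design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))

  structure(list(lm = fit, basis = basis, parts = part_labels,
                 lead = lead, total = total, ilr_names = ilr_names,
                 composition = comp, n = nrow(mdata),
                 formula = formula, model_data = d, call = cl),
            class = "coda_lm")
}

#' @export
print.coda_lm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Compositional linear model (ilr pivot coordinates)\n")
  cat("lead behavior:", x$lead, "   n =", x$n, "\n\n")
  cat("Coefficients:\n")
  print(round(coef(x$lm), digits))
  invisible(x)
}

#' @export
coef.coda_lm <- function(object, ...) coef(object$lm)

#' @export
vcov.coda_lm <- function(object, ...) vcov(object$lm)

#' @export
confint.coda_lm <- function(object, parm, level = 0.95, ...)
  confint(object$lm, parm = parm, level = level, ...)

#' @export
residuals.coda_lm <- function(object, ...) residuals(object$lm)

#' @export
fitted.coda_lm <- function(object, ...) fitted(object$lm)

#' Predict from a compositional linear model
#'
#' @param object A [coda_lm] fit.
#' @param newdata Data frame with the part columns (minutes) and any
#'   covariates in the model. If omitted, fitted values are returned.
#' @param ... Passed to [stats::predict.lm].
#' @return Numeric vector of predictions.
#' @export
predict.coda_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$lm, ...))
  comp <- as.matrix(newdata[, object$parts, drop = FALSE])
  if (any(comp == 0)) comp <- zero_replace(comp)
  comp <- close_composition(comp, total = object$total)
  coords <- ilr_transform(comp, object$basis)
  colnames(coords) <- object$ilr_names
  predict(object$lm, newdata = cbind(newdata, as.data.frame(coords)), ...)
}

#' @export
summary.coda_lm <- function(object, level = 0.95, ...) {
  s <- summary(object$lm)
  est <- coef(object$lm)["ilr1"]
  se <- sqrt(vcov(object$lm)["ilr1", "ilr1"])
  zq <- qnorm(1 - (1 - level) / 2)
  jt <- joint_composition_test(object)
  out <- list(lm_summary = s, lead = object$lead, n = object$n,
              ilr1 = c(estimate = unname(est),
                       ci_low = unname(est - zq * se),
                       ci_high = unname(est + zq * se),
                       p = unname(s$coefficients["ilr1", 4])),
              joint = jt, level = level)
  class(out) <- "summary.coda_lm"
  out
}

#' @export
print.summary.coda_lm <- function(x, digits = 3, ...) {
  cat("Compositional linear model, lead =", x$lead, " (n =", x$n, ")\n")
  cat(sprintf("%s relative to remaining behaviors: %.*f (%.*f, %.*f), p = %.3g\n",
              x$lead, digits, x$ilr1["estimate"], digits, x$ilr1["ci_low"],
              digits, x$ilr1["ci_high"], x$ilr1["p"]))
  cat(sprintf("Joint composition test: F(%d, %d) = %.3f, p = %.3g\n\n",
              x$joint$df[1], x$joint$df[2], x$joint$statistic, x$joint$p.value))
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' Joint test of the whole composition
#'
#' Partial F-test that all D-1 ilr coefficients are simultaneously zero,
#' comparing the fitted model against the covariate-only model on the same
#' complete-case data. The result does not depend on which rotation was
#' fitted, because all rotations span the same column space.
#'
#' @param fit A [coda_lm] object.
#' @return A list of class `"htest"` with `statistic` (F), `df`
#'   (numerator, denominator), and `p.value`.
#' @export
joint_composition_test <- function(fit) {
  if (!inherits(fit, "coda_lm")) stop("'fit' must be a coda_lm object")
  X <- model.matrix(fit$lm)
  drop_cols <- colnames(X) %in% fit$ilr_names
  if (sum(drop_cols) != length(fit$ilr_names))
    stop("nested model mismatch: ilr columns not found in the design matrix")
  y <- fit$lm$model[[1L]]
  rss_full <- sum(residuals(fit$lm)^2)
  reduced <- lm.fit(X[, !drop_cols, drop = FALSE], y)
  rss_red <- sum(reduced$residuals^2)
  df1 <- length(fit$ilr_names)
  df2 <- fit$lm$df.residual
  Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  structure(list(statistic = c(F = Fstat),
                 df = c(df1 = df1, df2 = df2),
                 p.value = pf(Fstat, df1, df2, lower.tail = FALSE),
                 method = "Partial F-test of the ilr coordinate block",
                 data.name = deparse(fit$call$data)),
            class = "htest")
}

#' Rotation-wise ilr1 summary table
#'
#' Refits the compositional model under each of the four behavior-first
#' rotations and reports, per leading behavior, the `ilr1` estimate (the
#' mean outcome difference for that behavior relative to the remaining
#' ones), its Wald confidence interval and p-value, together with the joint
#' composition p-value and the analysis n. This is the per-behavior summary
#' table conventionally reported for 24-h movement-behavior regressions.
#'
#' The four ilr1 coefficients obey an exact identity: scaled by
#' \eqn{\sqrt{(D-1)/D}} they are the clr coefficients of the model and sum
#' to zero. The achieved sum is returned as attribute `clr_sum_dev`.
#'
#' @inheritParams coda_lm
#' @param level Confidence level (default 0.95).
#' @return Data frame of class `"rotation_summary"` with one row per lead
#'   behavior and columns `lead`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`; attributes `joint_p`, `n`, `clr_sum_dev`, and `fits` (the
#'   four [coda_lm] objects).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_children = 300), seed = 2)
#' rotation_table(academic_latent ~ sex + bmi_y5, coh$children,
#'                parts = c("mvpa_y5", "lpa_y5", "inactivity_y5", "sleep_y5"))
#' @export
rotation_table <- function(formula, data, parts = mb_behaviors(),
                           total = 1440, zero_floor = 1, level = 0.95) {
  D <- length(parts)
  fits <- lapply(parts, function(ld)
    coda_lm(formula, data, parts = parts, lead = ld,
            total = total, zero_floor = zero_floor))
  names(fits) <- parts
  zq <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(fits, function(f) {
    b <- coef(f$lm)["ilr1"]
    se <- sqrt(vcov(f$lm)["ilr1", "ilr1"])
    p <- summary(f$lm)$coefficients["ilr1", 4]
    data.frame(lead = f$lead, estimate = unname(b),
               ci_low = unname(b - zq * se), ci_high = unname(b + zq * se),
               p_value = unname(p))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  jt <- joint_composition_test(fits[[1]])
  attr(tab, "joint_p") <- jt$p.value
  attr(tab, "n") <- fits[[1]]$n
  attr(tab, "level") <- level
  attr(tab, "clr_sum_dev") <- sqrt((D - 1) / D) * sum(tab$estimate)
  attr(tab, "fits") <- fits
  class(tab) <- c("rotation_summary", "data.frame")
  tab
}

#' @export
print.rotation_summary <- function(x, digits = 3, ...) {
  cat("Per-behavior compositional associations (ilr1 under each rotation)\n")
  cat("n =", attr(x, "n"),
      "  joint composition p =", format.pval(attr(x, "joint_p"), digits = 3), "\n\n")
  df <- data.frame(
    behavior = paste(x$lead, "relative to remaining behaviors"),
    `mean difference (CI)` = sprintf("%.*f (%.*f, %.*f)", digits, x$estimate,
                                     digits, x$ci_low, digits, x$ci_high),
    `p` = format.pval(x$p_value, digits = 3),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
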