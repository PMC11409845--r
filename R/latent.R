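#' Standardize a numeric vector to z-scores
#'
#' @param x Numeric vector with positive sample standard deviation.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x) {
  if (anyNA(x)) stop("missing values in indicator column")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("constant column cannot be z-scored")
  (x - mean(x)) / s
}

#' Latent score from an indicator panel by one-factor analysis
#'
#' Derives a per-child latent score (e.g., executive function from
#' inhibition errors, switching errors and working memory; or academic
#' achievement from four achievement domains) by fitting a one-factor
#' maximum-likelihood model to the z-scored indicators and extracting
#' regression-method factor scores.
#'
#' Indicators flagged in `higher_is_worse` are sign-flipped before scoring
#' so that a higher latent score always reads "better performance"; the
#' returned score is constrained to correlate positively with the mean of
#' the orientation-corrected z-scored indicators. Scores have mean 0; their
#' SD is below 1 by the usual regression-score shrinkage (it approaches 1
#' as the indicators become noiseless).
#'
#' If the ML solution is a Heywood case (an indicator uniqueness at its
#' boundary, i.e., communality >= 1) or fails to converge, a warning is
#' issued and the first principal component of the z-scored indicators is
#' used instead (standardized to unit variance).
#'
#' @param panel Data frame or matrix of indicator columns (no missing
#'   values among scored rows).
#' @param higher_is_worse Character vector of column names (or logical
#'   vector over columns) whose raw values are error counts or otherwise
#'   oriented "higher = worse". Default none.
#' @return Object of class `"latent_fit"`: list with `scores` (length n),
#'   `loadings` (named, on the orientation-corrected z-scored indicators),
#'   `uniquenesses`, `method` (`"ml"` or `"pca"`), and `higher_is_worse`.
#' @examples
#' set.seed(1)
#' lat <- rnorm(500)
#' panel <- data.frame(a = 0.7 * lat + rnorm(500, sd = sqrt(0.51)),
#'                     b = 0.7 * lat + rnorm(500, sd = sqrt(0.51)),
#'                     c = 0.7 * lat + rnorm(500, sd = sqrt(0.51)))
#' fit <- latent_score(panel)
#' cor(fit$scores, lat)
#' @export
latent_score <- function(panel, higher_is_worse = character()) {
  m <- as.matrix(panel)
  if (is.null(colnames(m))) colnames(m) <- paste0("ind", seq_len(ncol(m)))
  if (ncol(m) < 3) stop("need at least three indicators")
  if (nrow(m) <= ncol(m)) stop("need more observations than indicators")
  if (anyNA(m)) stop("missing values in indicator panel")
  if (is.logical(higher_is_worse)) {
    if (length(higher_is_worse) != ncol(m))
      stop("logical 'higher_is_worse' must have one entry per indicator")
    flip <- higher_is_worse
  } else {
    bad <- setdiff(higher_is_worse, colnames(m))
    if (length(bad)) stop("unknown indicator name: ", paste(bad, collapse = ", "))
    flip <- colnames(m) %in% higher_is_worse
  }
  z <- apply(m, 2, zscore)
  z[, flip] <- -z[, flip]

  fa <- tryCatch(factanal(z, factors = 1, scores = "regression"),
                 error = function(e) e)
  heywood <- !inherits(fa, "error") && any(fa$uniquenesses <= 0.005 + 1e-8)
  if (inherits(fa, "error") || heywood) {
    warning("one-factor ML solution ",
            if (heywood) "is a Heywood case" else "failed",
            "; falling back to the first principal component")
    pc <- prcomp(z, center = FALSE, scale. = FALSE)
    scores <- pc$x[, 1] / sd(pc$x[, 1])
    loadings <- pc$rotation[, 1]
    uniq <- pmax(0, 1 - loadings^2)
    method <- "pca"
  } else {
    scores <- drop(fa$scores)
    loadings <- drop(fa$loadings[, 1])
    uniq <- fa$uniquenesses
    method <- "ml"
  }
  ## sign convention: higher score = better (orientation-corrected) performance
  if (cor(scores, rowMeans(z)) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = unname(scores), loadings = loadings,
                 uniquenesses = uniq, method = method,
                 higher_is_worse = colnames(m)[flip]),
            class = "latent_fit")
}

#' @export
print.latent_fit <- function(x, digits = 3, ...) {
  cat("One-factor latent score (", x$method,
      if (x$method == "ml") ", regression scores" else "", ")\n", sep = "")
  if (length(x$higher_is_worse))
    cat("orientation-flipped indicators:",
        paste(x$higher_is_worse, collapse = ", "), "\n")
  cat("loadings:\n"); print(round(x$loadings, digits))
  cat(sprintf("score mean %.3g, sd %.3f, n = %d\n",
              mean(x$scores), sd(x$scores), length(x$scores)))
  invisible(x)
}
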