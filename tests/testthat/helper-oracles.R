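# independent oracles and fixture builders used across the suite

# brute-force centered log-ratio, written independently of the package
clr_oracle <- function(x) log(x) - mean(log(x))

# random strictly positive compositions closed to a total
random_comp <- function(n = 1, D = 4, total = 1440) {
  m <- matrix(exp(rnorm(n * D, mean = 5, sd = 1)), n, D)
  m * (total / rowSums(m))
}

parts_y5 <- paste0(mb_behaviors(), "_y5")
covars_y5 <- c("sex", "ethnicity", "maternal_age", "maternal_education", "bmi_y5")

# published per-behavior association inputs used by the worked example
B_Y5 <- c(-0.367, 0.08, -0.291, 0.578)
B_Y8 <- c(-0.282, 0.125, -0.374, 0.532)
MEAN_Y5 <- c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542)
MEAN_Y8 <- c(mvpa = 67, lpa = 336, inactivity = 509, sleep = 527)

# single-timepoint config for fast simulation-heavy tests; planted effects
# are passed through `effects`
fast_config <- function(n, effects = NULL, ...) {
  args <- list(n_children = n, timepoints = "y5",
               p_measured = c(y5 = 1, y8 = 1), p_valid_day = 1, ...)
  if (!is.null(effects)) args$effects <- effects
  do.call(cohort_config, args)
}

null_effects <- function()
  list(ef = list(ilr_y5 = c(0, 0, 0), ilr_y8 = c(0, 0, 0), vars = numeric()),
       academic = list(ilr_y5 = c(0, 0, 0), ilr_y8 = c(0, 0, 0), vars = numeric()))
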