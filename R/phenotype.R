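#' Correct phenotypes for fixed effects
#'
#' Removes fixed effects from raw trait values by ordinary least squares on an
#' intercept plus one-hot factor encodings (first level as reference), i.e.
#' the residuals of `lm(trait ~ year + season + sex + farm)`. Factors with a
#' single observed level are absorbed by the intercept and silently dropped
#' from the design; aliased columns in a rank-deficient design are dropped
#' with a warning (the residuals are unaffected by which aliased column is
#' dropped).
#'
#' @param pheno Data frame with columns `id`, a trait column, and the factor
#'   columns.
#' @param factors Character vector of factor column names to correct for.
#' @param trait Name of the trait column (default `"trait"`).
#' @return Data frame with columns `id` and `residual` (corrected phenotype,
#'   same units as the trait; residuals sum to ~0).
#' @export
correct_phenotypes <- function(pheno, factors = c("year", "season", "sex", "farm"),
                               trait = "trait") {
  if (nrow(pheno) < 2) stop2("need at least 2 phenotype rows")
  missing_cols <- setdiff(c("id", trait, factors), names(pheno))
  if (length(missing_cols)) {
    stop2("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dat <- pheno
  dat[[trait]] <- as.numeric(dat[[trait]])
  if (anyNA(dat[factors])) stop2("missing factor levels among analyzed rows")
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  usable <- factors[vapply(dat[factors], nlevels, 1L) > 1]
  form <- if (length(usable)) {
    stats::reformulate(usable, response = trait)
  } else {
    stats::as.formula(paste(trait, "~ 1"))
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient fixed-effect design; aliased columns dropped",
            call. = FALSE)
  }
  data.frame(id = dat$id, residual = unname(stats::residuals(fit)),
             stringsAsFactors = FALSE)
}

#' Descriptive statistics of a trait
#'
#' Summary statistics as reported in trait-description tables: count, range,
#' mean, sample standard deviation (n-1 denominator) and the coefficient of
#' variation `cv = 100 * sd / mean` (in percent; undefined when the mean is
#' zero, reported as NA with a warning).
#'
#' @param values Numeric vector, length >= 2.
#' @return One-row data frame with columns `n`, `min`, `max`, `mean`, `sd`,
#'   `cv`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop2("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  cv <- if (m == 0) {
    warning("mean is zero; CV undefined", call. = FALSE)
    NA_real_
  } else {
    coef_variation(m, s)
  }
  data.frame(n = length(values), min = min(values), max = max(values),
             mean = m, sd = s, cv = cv)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`; exposed separately so printed table cells can be
#' reproduced directly from a reported mean and standard deviation.
#'
#' @param mean Mean of the trait.
#' @param sd Sample standard deviation.
#' @return CV in percent.
#' @export
#' @examples
#' round_half_away(coef_variation(168.773, 13.982), 3)
coef_variation <- function(mean, sd) 100 * sd / mean
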