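#' Prediction model specification
#'
#' The five BLUP-family models and the kernels they require:
#' \describe{
#'   \item{GBLUP}{single kernel `G` (plain GRM, all variants).}
#'   \item{GFBLUP}{two kernels: `Gf` (plain GRM over the selected "feature"
#'     variants) plus `G`.}
#'   \item{TABLUP}{single kernel `Sa` (effect-weighted GRM over all
#'     variants).}
#'   \item{BLUPGA}{single kernel `T = omega * Sf + (1 - omega) * G` (blended
#'     trait-specific matrix); `omega` required.}
#'   \item{GTBLUP}{two kernels: `G` plus `Sf` (effect-weighted GRM over the
#'     selected variants).}
#' }
#'
#' @param name Model name.
#' @param omega Blending weight for BLUPGA, in \[0, 1\].
#' @return A `model_spec` list with the model's kernel requirements.
#' @export
model_spec <- function(name = c("GBLUP", "GFBLUP", "TABLUP", "BLUPGA", "GTBLUP"),
                       omega = NULL) {
  name <- match.arg(name)
  needs <- switch(name,
                  GBLUP = "G", GFBLUP = c("Gf", "G"), TABLUP = "Sa",
                  BLUPGA = c("Sf", "G"), GTBLUP = c("G", "Sf"))
  if (name == "BLUPGA") {
    if (is.null(omega)) stop2("BLUPGA requires `omega`")
    assert_scalar_in(omega, 0, 1, "omega")
  } else if (!is.null(omega)) {
    stop2("`omega` only applies to BLUPGA")
  }
  structure(list(name = name, omega = omega, needs = needs),
            class = "model_spec")
}

# resolve a model's covariance kernels from a named kernel list
model_kernels <- function(spec, kernels) {
  miss <- setdiff(spec$needs, names(kernels))
  if (length(miss)) {
    stop2(sprintf("model %s needs kernel(s): %s", spec$name,
                  paste(miss, collapse = ", ")))
  }
  if (spec$name == "BLUPGA") {
    list(blend_kernels(kernels$Sf, kernels$G, spec$omega))
  } else {
    unname(kernels[spec$needs])
  }
}

#' Fit a prediction model and predict held-out individuals
#'
#' Estimates variance components by REML on the training block only, then
#' predicts genomic breeding values for the test individuals by the
#' conditional expectation
#' `g_test = sum_c sigma_c^2 K_c[test, train] %*% V_train^-1 (y - mu)` with
#' `V_train = sum_c sigma_c^2 K_c[train, train] + sigma_e^2 I` — equivalent
#' to solving the mixed-model equations with test phenotypes missing. The
#' intercept is the training-block GLS estimate. For two-kernel models the
#' component breeding values are also returned separately.
#'
#' @param spec A [model_spec()].
#' @param y_train Training phenotypes: numeric vector aligned to `train_ids`
#'   or a data frame with `id`/`residual`.
#' @param train_ids,test_ids Disjoint character vectors of individual ids
#'   present in the kernels.
#' @param kernels Named list of `kernel_matrix` objects over all individuals
#'   (training and test); names among `G`, `Gf`, `Sa`, `Sf`.
#' @return A `fit_result` list: `mu`, `gebv` (data frame: `id`, `gebv`, one
#'   `gebv_k<i>` column per kernel component) for the test individuals,
#'   `gebv_train` (same layout, training individuals), and `vc`.
#' @export
fit_predict <- function(spec, y_train, train_ids, test_ids, kernels) {
  if (length(intersect(train_ids, test_ids))) {
    stop2("train and test ids overlap")
  }
  Klist <- model_kernels(spec, kernels)
  ids <- kernel_ids(Klist[[1]])
  if (is.null(ids)) stop2("kernels must carry individual ids as dimnames")
  if (!all(c(train_ids, test_ids) %in% ids)) {
    stop2("kernels do not cover all train/test individuals")
  }
  if (is.data.frame(y_train)) {
    pos <- match(train_ids, y_train$id)
    if (anyNA(pos)) stop2("training phenotypes missing for some ids")
    y <- as.numeric(y_train$residual[pos])
  } else {
    if (length(y_train) != length(train_ids)) {
      stop2("`y_train` length does not match `train_ids`")
    }
    y <- as.numeric(y_train)
  }

  Ktr <- lapply(Klist, function(K) unclass(K)[train_ids, train_ids])
  if (length(Klist) == 1L) {
    vc <- reml_one_kernel(y, Ktr[[1]])
    sig <- vc$sigma_g2
  } else {
    vc <- reml_two_kernels(y, Ktr[[1]], Ktr[[2]])
    sig <- vc$sigma_g2
  }

  n_tr <- length(train_ids)
  V <- Reduce(`+`, Map(function(s, K) s * K, sig, Ktr)) +
    diag(vc$sigma_e2, n_tr)
  alpha <- solve_with_jitter(V, y - vc$mu)

  comp <- function(ids_out) {
    parts <- Map(function(s, K) {
      s * unclass(K)[ids_out, train_ids, drop = FALSE] %*% alpha
    }, sig, Klist)
    total <- drop(Reduce(`+`, parts))
    out <- data.frame(id = ids_out, gebv = total, stringsAsFactors = FALSE)
    for (i in seq_along(parts)) out[[paste0("gebv_k", i)]] <- drop(parts[[i]])
    out
  }

  structure(list(mu = vc$mu, gebv = comp(test_ids),
                 gebv_train = comp(train_ids), vc = vc),
            class = "fit_result")
}

# Cholesky solve with escalating diagonal jitter (1e-10..1e-6 of mean diag)
solve_with_jitter <- function(V, b) {
  for (delta in c(0, 10^seq(-10, -6, by = 2))) {
    Vj <- if (delta == 0) V else V + diag(delta * mean(diag(V)), nrow(V))
    R <- tryCatch(chol(Vj), error = function(e) NULL)
    if (!is.null(R)) return(backsolve(R, forwardsolve(t(R), b)))
  }
  stop2("training covariance is singular")
}
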