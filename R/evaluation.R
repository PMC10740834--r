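#' Cross-validation plan
#'
#' Repeated k-fold cross-validation: per repeat, a uniform random partition
#' of the individuals into k near-equal folds (sizes differ by at most one).
#' The default 5 repeats x 10 folds yields 50 train/test evaluations.
#'
#' @param n_individuals Number of individuals.
#' @param k_folds Number of folds (>= 2).
#' @param repeats Number of independent repeats.
#' @param seed Integer seed; fold assignments are reproducible.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(n_individuals, k_folds = 10, repeats = 5, seed = 1L) {
  if (k_folds < 2) stop2("`k_folds` must be >= 2")
  if (k_folds > n_individuals) stop2("more folds than individuals")
  structure(list(n_individuals = as.integer(n_individuals),
                 k_folds = as.integer(k_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Fold assignments for a CV plan
#'
#' @param plan A [cv_plan()].
#' @return Integer matrix (`n_individuals` x `repeats`); entry (i, r) is the
#'   fold of individual i in repeat r. Within a repeat the folds partition
#'   all individuals with sizes differing by at most one.
#' @export
make_folds <- function(plan) {
  n <- plan$n_individuals
  k <- plan$k_folds
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  out <- matrix(0L, n, plan$repeats)
  for (r in seq_len(plan$repeats)) {
    set.seed(plan$seed + r)
    out[sample.int(n), r] <- rep(seq_len(k), times = sizes)
  }
  out
}

#' Prediction accuracy
#'
#' Sample Pearson correlation between corrected phenotypes and genomic
#' breeding values of the evaluated individuals.
#'
#' @param y_corrected Corrected phenotypes.
#' @param gebv Predicted breeding values, same length (>= 3).
#' @return Correlation in \[-1, 1\], or NA (with a warning) when either
#'   input has zero variance.
#' @export
prediction_accuracy <- function(y_corrected, gebv) {
  if (length(y_corrected) != length(gebv)) stop2("length mismatch")
  if (length(y_corrected) < 3) stop2("need at least 3 pairs")
  if (stats::sd(y_corrected) == 0 || stats::sd(gebv) == 0) {
    warning("zero variance; accuracy undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(y_corrected, gebv)
}

#' Paired t-test between two models' fold accuracies
#'
#' Two-sided paired t-test on per-fold accuracy differences (pairs matched
#' by repeat and fold). Degenerate zero-variance differences are flagged:
#' p = 0 when the mean difference is nonzero, p = 1 otherwise.
#'
#' @param acc_a,acc_b Equal-length accuracy vectors (length >= 2), paired.
#' @return List with `t`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop2("length mismatch")
  if (length(acc_a) < 2) stop2("need at least 2 paired values")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = if (mean(d) != 0) 0 else 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}

#' Run the cross-validated prediction grid
#'
#' Evaluates every (selection scenario x model) combination under a repeated
#' k-fold plan. Per fold, variance components and breeding values come from
#' the training individuals only. Selection scores obey the leakage rules:
#' p-value rankings (`P_top_*`) come from the external summary statistics
#' and are fold-independent, so their kernels are built once; absolute
#' rr-BLUP effect rankings (`G_top_*`) are refit from the training
#' individuals inside every fold. Kernel weights are always the (squared or
#' absolute) meta-analysis effects of the selected variants, rescaled to
#' mean 1 over the variant set entering each matrix.
#'
#' A baseline scenario with no preselection (GBLUP on all variants) can be
#' requested by including `NULL` in `selections`; only GBLUP runs there.
#' GBLUP's per-fold accuracy is selection-independent and computed once.
#'
#' @param genotypes Post-QC [geno_matrix()].
#' @param y Corrected phenotypes (vector in panel order, or data frame with
#'   `id`/`residual`).
#' @param models List of [model_spec()] objects.
#' @param plan A [cv_plan()].
#' @param selections List of [selection_spec()] objects (and/or NULL for the
#'   no-preselection baseline).
#' @param sumstats A `summary_stats` table (required unless only GBLUP runs).
#' @param weight_fn Weight function for [build_weight_vector()].
#' @return A `cv_result` data frame in long format: `strategy`,
#'   `proportion`, `model`, `omega`, `rep`, `fold`, `n_selected`,
#'   `accuracy`, `converged`.
#' @export
run_cv <- function(genotypes, y, models, plan, selections = list(NULL),
                   sumstats = NULL, weight_fn = "squared") {
  if (!length(models)) stop2("empty model grid")
  if (!length(selections)) stop2("empty selection grid")
  y <- align_response(genotypes, y)
  ids <- rownames(genotypes$dosages)
  if (plan$n_individuals != length(ids)) {
    stop2("plan does not match the panel's individual count")
  }
  folds <- make_folds(plan)
  G <- ensure_psd(build_grm(genotypes))
  meta <- NULL
  needs_meta <- any(!vapply(selections, is.null, TRUE))
  if (needs_meta) {
    if (is.null(sumstats)) stop2("preselection scenarios need `sumstats`")
    meta <- align_meta_to_panel(genotypes$map, sumstats)
    if (!any(meta$matched)) stop2("no study variant matches the summary statistics")
  }

  gblup_spec <- model_spec("GBLUP")
  gblup_cache <- new.env(parent = emptyenv())
  gblup_fold <- function(r, f, train, test) {
    key <- paste(r, f, sep = "_")
    if (is.null(gblup_cache[[key]])) {
      fit <- fit_predict(gblup_spec, y[match(train, ids)], train, test,
                         list(G = G))
      gblup_cache[[key]] <- list(
        accuracy = prediction_accuracy(y[match(test, ids)], fit$gebv$gebv),
        converged = fit$vc$converged)
    }
    gblup_cache[[key]]
  }

  rows <- list()
  add_row <- function(strategy, proportion, model, omega, r, f, n_sel, acc, conv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      strategy = strategy, proportion = proportion, model = model,
      omega = if (is.null(omega)) NA_real_ else omega,
      rep = r, fold = f, n_selected = n_sel, accuracy = acc,
      converged = conv, stringsAsFactors = FALSE)
  }

  for (sel_spec in selections) {
    if (is.null(sel_spec)) {
      for (r in seq_len(plan$repeats)) for (f in seq_len(plan$k_folds)) {
        test <- ids[folds[, r] == f]
        train <- setdiff(ids, test)
        gb <- gblup_fold(r, f, train, test)
        add_row("none", 1, "GBLUP", NULL, r, f, n_variants(genotypes),
                gb$accuracy, gb$converged)
      }
      next
    }
    p_based <- startsWith(sel_spec$strategy, "P_top")
    fixed_kernels <- NULL
    fixed_size <- NA_integer_
    if (p_based) {
      ranked <- rank_variants(meta$p, genotypes$map, "pvalue_ascending")
      vs <- select_top(ranked, sel_spec, pvalues = meta$p)
      fixed_kernels <- scenario_kernels(genotypes, vs$indices, meta$beta,
                                        weight_fn, G)
      fixed_size <- vs$size
    }
    for (r in seq_len(plan$repeats)) for (f in seq_len(plan$k_folds)) {
      test <- ids[folds[, r] == f]
      train <- setdiff(ids, test)
      y_train <- y[match(train, ids)]
      y_test <- y[match(test, ids)]
      if (p_based) {
        kernels <- fixed_kernels
        n_sel <- fixed_size
      } else {
        g_tr <- subset_individuals(genotypes, match(train, ids))
        rr <- rrblup_effects(g_tr, y_train)
        ranked <- rank_variants(rr$effects, genotypes$map,
                                "abs_effect_descending")
        vs <- select_top(ranked, sel_spec)
        kernels <- scenario_kernels(genotypes, vs$indices, meta$beta,
                                    weight_fn, G)
        n_sel <- vs$size
      }
      for (ms in models) {
        if (ms$name == "GBLUP") {
          gb <- gblup_fold(r, f, train, test)
          add_row(sel_spec$strategy, sel_spec$proportion %||% NA_real_,
                  "GBLUP", NULL, r, f, n_sel, gb$accuracy, gb$converged)
        } else {
          fit <- fit_predict(ms, y_train, train, test, kernels)
          acc <- prediction_accuracy(y_test, fit$gebv$gebv)
          add_row(sel_spec$strategy, sel_spec$proportion %||% NA_real_,
                  ms$name, ms$omega, r, f, n_sel, acc, fit$vc$converged)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  out
}

# build the Gf/Sa/Sf kernel set for one selected-variant scenario
scenario_kernels <- function(genotypes, sel_indices, meta_beta, weight_fn, G) {
  panel <- n_variants(genotypes)
  eff <- meta_beta
  if (anyNA(eff[sel_indices])) {
    stop2("selected variants without a meta-analysis effect; cannot weight kernels")
  }
  w_all <- build_weight_vector(eff, sel_indices, panel, weight_fn)
  w_sel <- build_weight_vector(eff[sel_indices], seq_along(sel_indices),
                               length(sel_indices), weight_fn)
  list(
    G = G,
    Gf = ensure_psd(build_grm(genotypes, subset = sel_indices, label = "Gf")),
    Sa = ensure_psd(build_weighted_grm(genotypes, w_all, label = "Sa")),
    Sf = ensure_psd(build_weighted_grm(genotypes, w_sel, subset = sel_indices,
                                       label = "Sf"))
  )
}

#' Aggregate fold accuracies
#'
#' Mean and SD of per-fold accuracies for each (strategy, proportion, model,
#' omega) cell — a mean of fold accuracies, never a pooled correlation.
#'
#' @param cvres A `cv_result` from [run_cv()].
#' @return Data frame of aggregates with `n_folds` and `n_failed`.
#' @export
summarize_cv <- function(cvres) {
  key <- paste(cvres$strategy, cvres$proportion, cvres$model, cvres$omega)
  parts <- split(cvres, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- is.finite(d$accuracy) & d$converged
    data.frame(strategy = d$strategy[1], proportion = d$proportion[1],
               model = d$model[1], omega = d$omega[1],
               mean_accuracy = mean(d$accuracy[ok]),
               sd_accuracy = stats::sd(d$accuracy[ok]),
               n_folds = sum(ok), n_failed = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$strategy, out$proportion, out$model, out$omega), ]
}

#' Pairwise model comparison by paired t-tests
#'
#' Within each (strategy, proportion, omega-collapsed) cell, compares every
#' model pair by a paired t-test over fold accuracies (pairs matched by
#' repeat and fold). Stars: `*` p < 0.05, `**` p < 0.01; no multiple-testing
#' correction is applied.
#'
#' @param cvres A `cv_result` from [run_cv()].
#' @return Data frame with one row per model pair and cell: `model_a`,
#'   `model_b`, `mean_diff` (a minus b), `t`, `p`, `stars`.
#' @export
compare_models <- function(cvres) {
  key <- paste(cvres$strategy, cvres$proportion)
  out <- list()
  for (d in split(cvres, key)) {
    mods <- unique(d$model)
    if (length(mods) < 2) next
    for (i in seq_along(mods)) for (j in seq_along(mods)) {
      if (j <= i) next
      a <- d[d$model == mods[i], ]
      b <- d[d$model == mods[j], ]
      a <- a[order(a$rep, a$fold), ]
      b <- b[order(b$rep, b$fold), ]
      if (nrow(a) != nrow(b)) next
      tt <- paired_ttest(a$accuracy, b$accuracy)
      out[[length(out) + 1L]] <- data.frame(
        strategy = d$strategy[1], proportion = d$proportion[1],
        model_a = mods[i], model_b = mods[j], mean_diff = tt$mean_diff,
        t = tt$t, p = tt$p,
        stars = if (is.na(tt$p)) "" else if (tt$p < 0.01) "**"
                else if (tt$p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
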