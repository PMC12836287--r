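# Validation and statistical harness: leave-one-out cross-validation of the
# dose predictor, and the non-parametric tests used for cohort comparison
# (Fisher's exact, Mann-Whitney U, Friedman + Wilcoxon signed-rank post hocs)
# with an in-package step-down Holm-Bonferroni correction.

#' Leave-one-out cross-validation of the dose predictor
#'
#' For each case, an atlas is built from the remaining cases (reference: the
#' first remaining case in list order, unless `reference_id` pins one), the
#' held-out case's dose is predicted, and the Dice coefficient of the
#' predicted vs. actual isodose volume at `threshold_gy` is recorded.
#' Registrations between case pairs are memoized across folds. A failing
#' fold is recorded and excluded from the summary with a warning.
#'
#' @param cases list of at least 3 `patient_case`s with CT and dose.
#' @param config a `registration_config`.
#' @param threshold_gy isodose level for the Dice comparison (default 2 Gy,
#'   the low-dose envelope the complete block is built from).
#' @param p SSIM weighting exponent.
#' @param reference_id optional pinned reference id.
#' @param verbose print per-fold progress.
#' @return an object of class `loo_result`: data.frame `per_case`
#'   (id, dsc, mae_gy, seconds), `mean_dsc`, `sd_dsc`.
#' @export
leave_one_out <- function(cases, config = registration_config(),
                          threshold_gy = 2.0, p = 1, reference_id = NULL,
                          verbose = FALSE) {
  if (length(cases) < 3) stop("leave-one-out needs at least 3 cases")
  ids <- vapply(cases, function(cs) cs$id, character(1))
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    t0 <- proc.time()[["elapsed"]]
    rows[[i]] <- tryCatch({
      rest <- cases[-i]
      ref <- if (!is.null(reference_id) && reference_id %in% ids[-i])
        reference_id else rest[[1]]$id
      atl <- build_atlas(rest, ref, config, reg_cache = cache)
      pr <- predict_dose(atl, cases[[i]], p = p, reg_cache = cache)
      dsc <- dice(extract_isodose(pr$predicted_dose, threshold_gy),
                  extract_isodose(cases[[i]]$dose, threshold_gy))
      body <- cases[[i]]$structures$masks$Body
      mae <- if (is.null(body)) {
        mean(abs(pr$predicted_dose$values - cases[[i]]$dose$values))
      } else {
        mean(abs(pr$predicted_dose$values[body$values] -
                   cases[[i]]$dose$values[body$values]))
      }
      if (verbose)
        message(sprintf("fold %s: DSC %.3f, MAE %.3f Gy", ids[i], dsc, mae))
      data.frame(id = ids[i], dsc = dsc, mae_gy = mae,
                 seconds = proc.time()[["elapsed"]] - t0)
    }, error = function(e) {
      warning("fold '", ids[i], "' failed: ", conditionMessage(e))
      data.frame(id = ids[i], dsc = NA_real_, mae_gy = NA_real_,
                 seconds = proc.time()[["elapsed"]] - t0)
    })
  }
  per_case <- do.call(rbind, rows)
  ok <- !is.na(per_case$dsc)
  structure(list(per_case = per_case,
                 mean_dsc = mean(per_case$dsc[ok]),
                 sd_dsc = stats::sd(per_case$dsc[ok]),
                 mean_mae_gy = mean(per_case$mae_gy[ok]),
                 threshold_gy = threshold_gy),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d cases, DSC(%g Gy) %.3f +/- %.3f, MAE %.3f Gy\n",
              nrow(x$per_case), x$threshold_gy, x$mean_dsc, x$sd_dsc,
              x$mean_mae_gy))
  invisible(x)
}

#' Fisher's exact test (two-sided, point-probability method)
#'
#' Two-sided p as the sum over all tables with the observed margins whose
#' point hypergeometric probability does not exceed the observed one — the
#' convention that reproduces standard software output for 2 x 2 tables.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate table (zero margin); p = 1")
    return(list(p_value = 1, odds_ratio = NA_real_))
  }
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact for small samples without ties, normal approximation otherwise; the
#' method used is reported.
#'
#' @param x,y numeric samples.
#' @return list with `u`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L)
    return(list(u = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all values identical)"))
  exact <- length(x) < 50 && length(y) < 50 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(u = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Zero differences are dropped; exact for n <= 25 without tied
#' differences, normal approximation otherwise.
#'
#' @param x,y paired numeric samples.
#' @return list with `v`, `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    return(list(v = 0, p_value = 1, n_effective = 0L,
                method = "degenerate (all differences zero)"))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = exact, correct = !exact))
  list(v = unname(wt$statistic), p_value = wt$p.value,
       n_effective = length(d), method = wt$method)
}

#' Friedman test across repeated-measure conditions
#'
#' @param m subjects x conditions numeric matrix.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
friedman <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  if (all(apply(m, 1, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, df = ncol(m) - 1L, p_value = 1))
  ft <- stats::friedman.test(m)
  p <- ft$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = p)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and rejects sequentially while
#' `p_(k) <= alpha / (m - k + 1)`; adjusted p-values are the running maximum
#' of `(m - k + 1) * p_(k)`, capped at 1. Returned in the input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha family-wise error rate.
#' @return data.frame with `p`, `p_adjusted`, `reject`.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues))
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      reject = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  adj <- pmin(cummax((m - seq_len(m) + 1) * ps), 1)
  rej <- logical(m)
  for (k in seq_len(m)) {
    if (ps[k] <= alpha / (m - k + 1)) rej[k] <- TRUE else break
  }
  out <- data.frame(p = pvalues, p_adjusted = NA_real_, reject = NA)
  out$p_adjusted[ord] <- adj
  out$reject[ord] <- rej
  out
}

#' Build a cohort-comparison table
#'
#' Summarizes each metric as mean +/- SD per arm and tests the declared
#' contrasts: independent contrasts with the Mann-Whitney U test; paired
#' contrasts with a Friedman omnibus over all paired arms followed, when
#' significant, by Wilcoxon signed-rank post hocs corrected per metric with
#' Holm-Bonferroni.
#'
#' @param cohorts named list of data.frames (one per arm; rows = subjects,
#'   columns = metrics; paired arms must share subject order).
#' @param contrasts list of `list(a =, b =, paired =)` declarations.
#' @param alpha family-wise error rate for the paired family.
#' @return an object of class `comparison_table`: `summary` (metric x arm
#'   mean +/- SD strings), `tests` (tidy per-contrast results with test
#'   provenance), `friedman` (per-metric omnibus p for the paired family).
#' @export
build_comparison_table <- function(cohorts, contrasts, alpha = 0.05) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2, !is.null(names(cohorts)))
  metrics <- Reduce(intersect, lapply(cohorts, colnames))
  if (!length(metrics)) stop("cohorts share no metric columns")
  for (ct in contrasts) {
    if (!all(c(ct$a, ct$b) %in% names(cohorts)))
      stop("contrast references unknown arm")
    if (isTRUE(ct$paired) &&
        nrow(cohorts[[ct$a]]) != nrow(cohorts[[ct$b]]))
      stop("paired contrast between arms of different size")
  }
  summary <- sapply(names(cohorts), function(arm) {
    vapply(metrics, function(mt) {
      v <- cohorts[[arm]][[mt]]
      sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
    }, character(1))
  })
  rownames(summary) <- metrics
  paired_arms <- unique(unlist(lapply(
    Filter(function(ct) isTRUE(ct$paired), contrasts),
    function(ct) c(ct$a, ct$b))))
  fried <- NULL
  if (length(paired_arms) >= 2) {
    fried <- vapply(metrics, function(mt) {
      m <- sapply(paired_arms, function(arm) cohorts[[arm]][[mt]])
      friedman(m)$p_value
    }, numeric(1))
  }
  rows <- list()
  for (mt in metrics) {
    raw <- list()
    for (ci in seq_along(contrasts)) {
      ct <- contrasts[[ci]]
      a <- cohorts[[ct$a]][[mt]]; b <- cohorts[[ct$b]][[mt]]
      if (isTRUE(ct$paired)) {
        if (fried[[mt]] < alpha) {
          res <- wilcoxon_signed_rank(a, b)
          raw[[length(raw) + 1L]] <- data.frame(
            metric = mt, a = ct$a, b = ct$b, paired = TRUE,
            test = "Wilcoxon signed-rank", p = res$p_value)
        } else {
          raw[[length(raw) + 1L]] <- data.frame(
            metric = mt, a = ct$a, b = ct$b, paired = TRUE,
            test = "Friedman omnibus not significant", p = NA_real_)
        }
      } else {
        res <- mann_whitney_u(a, b)
        raw[[length(raw) + 1L]] <- data.frame(
          metric = mt, a = ct$a, b = ct$b, paired = FALSE,
          test = "Mann-Whitney U", p = res$p_value)
      }
    }
    tab <- do.call(rbind, raw)
    tab$p_adjusted <- NA_real_; tab$significant <- NA
    idx <- which(tab$paired & !is.na(tab$p))
    if (length(idx)) {
      hb <- holm_bonferroni(tab$p[idx], alpha)
      tab$p_adjusted[idx] <- hb$p_adjusted
      tab$significant[idx] <- hb$reject
    }
    idx2 <- which(!tab$paired)
    if (length(idx2)) {
      tab$p_adjusted[idx2] <- tab$p[idx2]
      tab$significant[idx2] <- tab$p[idx2] < alpha
    }
    rows[[mt]] <- tab
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  structure(list(summary = summary, tests = tests, friedman = fried,
                 alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table>\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}
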