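#' Two-group logrank chi-square statistic
#'
#' Fast kernel used inside the cross-validation permutation loop; agrees
#' with [survival::survdiff()] (rho = 0) to numerical precision. Returns 0
#' when the statistic degenerates (one group, or no events).
#'
#' @param time Survival times.
#' @param event Event indicators (0/1).
#' @param group Two-group labels coercible to 0/1.
#' @return The 1-df logrank chi-square.
#' @export
logrank_chisq <- function(time, event, group) {
  g <- as.integer(group)
  if (length(unique(g)) < 2L) return(0)
  cpp_logrank_chisq(as.numeric(time), as.integer(event), g)
}

#' Univariate Cox regression for one score
#'
#' The score is standardized (z-scored) so the hazard ratio is per
#' standard deviation. Non-identifiable or non-converged fits are flagged
#' rather than raised.
#'
#' @param score Per-sample score values, aligned with `survival_tab`.
#' @param survival_tab A [survival_table()].
#' @return List with `hr` (per SD), `p` (Wald), `ci` (95%), `coef`, `ok`
#'   and `reason` when flagged.
#' @export
univariate_cox <- function(score, survival_tab) {
  stopifnot(length(score) == nrow(survival_tab))
  if (sum(survival_tab$os_event) < 2L) stop("need at least 2 events")
  flagged <- function(reason)
    list(hr = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
         coef = NA_real_, ok = FALSE, reason = reason)
  if (stats::sd(score, na.rm = TRUE) == 0 || all(is.na(score)))
    return(flagged("constant or empty score: non-identifiable"))
  z <- as.numeric(scale(score))
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(
      survival::Surv(survival_tab$os_time, survival_tab$os_event) ~ z,
      ties = "efron"), error = function(e) NULL),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  if (is.null(fit) || is.na(stats::coef(fit)[1L]))
    return(flagged("fit failed"))
  s <- summary(fit)
  list(hr = unname(s$conf.int[1L, "exp(coef)"]),
       p = unname(s$coefficients[1L, "Pr(>|z|)"]),
       ci = unname(s$conf.int[1L, c("lower .95", "upper .95")]),
       coef = unname(stats::coef(fit)[1L]),
       ok = !warned, reason = if (warned) "convergence warning" else NULL)
}

#' Multiple Cox regression with stepwise score selection
#'
#' The clinical base covariates (any of `age`, `gender`, `grade`,
#' `avg_expression` present in the table) are forced into the model;
#' candidate spatial scores are first screened for multicollinearity with
#' the average expression (absolute Spearman correlation below
#' `rho_max`), then entered/removed by AIC-guided forward-backward
#' search starting from the base model. The final model is compared to
#' the base model by a likelihood-ratio test.
#'
#' @param scores A [score_table()] holding the candidate scores.
#' @param survival_tab A [survival_table()]; must include
#'   `avg_expression` for the multicollinearity screen.
#' @param candidates Names of candidate score columns (default: all).
#' @param rho_max Spearman screen threshold (default 0.9).
#' @return List with the final `fit`, `base_fit`, `kept` score names,
#'   `screened_out`, and `lr` (statistic, df, p; p = 1 when no candidate
#'   survives).
#' @export
multiple_cox_stepwise <- function(scores, survival_tab,
                                  candidates = NULL, rho_max = 0.9) {
  prep <- .prepare_scores(scores, survival_tab)
  m <- prep$m
  if (is.null(candidates)) candidates <- colnames(m)
  candidates <- intersect(candidates, colnames(m))
  base_vars <- intersect(c("age", "gender", "grade", "avg_expression"),
                         names(survival_tab))
  if (!"avg_expression" %in% names(survival_tab))
    stop("survival table must include avg_expression")
  screened_out <- character(0)
  keep <- character(0)
  for (cn in candidates) {
    rho <- suppressWarnings(stats::cor(m[, cn], survival_tab$avg_expression,
                                       method = "spearman"))
    if (!is.na(rho) && abs(rho) >= rho_max) screened_out <- c(screened_out, cn)
    else keep <- c(keep, cn)
  }
  dat <- data.frame(os_time = survival_tab$os_time,
                    os_event = survival_tab$os_event,
                    survival_tab[, base_vars, drop = FALSE],
                    check.names = FALSE)
  safe <- paste0("score_", seq_along(keep))
  for (i in seq_along(keep)) dat[[safe[i]]] <- m[, keep[i]]
  base_formula <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~", paste(base_vars, collapse = " + ")))
  base_fit <- survival::coxph(base_formula, data = dat, ties = "efron")
  if (length(keep) == 0L)
    return(list(fit = base_fit, base_fit = base_fit, kept = character(0),
                screened_out = screened_out,
                lr = list(stat = 0, df = 0L, p = 1)))
  upper <- stats::as.formula(paste(
    "~", paste(c(base_vars, safe), collapse = " + ")))
  lower <- stats::as.formula(paste("~", paste(base_vars, collapse = " + ")))
  step_fit <- tryCatch(
    suppressWarnings(MASS::stepAIC(base_fit,
                                   scope = list(lower = lower, upper = upper),
                                   direction = "both", trace = 0)),
    error = function(e) base_fit)
  added <- setdiff(attr(stats::terms(step_fit), "term.labels"),
                   attr(stats::terms(base_fit), "term.labels"))
  kept <- keep[match(added, safe)]
  if (length(added) == 0L)
    lr <- list(stat = 0, df = 0L, p = 1)
  else {
    lt <- lmtest::lrtest(base_fit, step_fit)
    lr <- list(stat = lt$Chisq[2L], df = lt$Df[2L], p = lt$`Pr(>Chisq)`[2L])
  }
  list(fit = step_fit, base_fit = base_fit, kept = kept,
       screened_out = screened_out, lr = lr)
}

#' Quantile-cutoff survival stratification
#'
#' Dichotomizes the cohort at each candidate quantile of the score
#' ("high" = score >= cutoff), compares the groups by the logrank test,
#' and reports all candidate results plus the best (smallest p) cutoff.
#' Cutoffs yielding an empty group are skipped.
#'
#' @param score Per-sample score values aligned with `survival_tab`.
#' @param survival_tab A [survival_table()].
#' @param quantiles Candidate cutoff quantiles (default 0.25, 0.5, 0.75).
#' @return Object of class `strat_result`: `per_cutoff` data frame
#'   (quantile, cutoff, n_high, n_low, chisq, p, median survival per
#'   group), `best` row index, `labels` for the best cutoff, and `fits`
#'   (Kaplan-Meier fits per cutoff).
#' @export
quantile_stratify <- function(score, survival_tab,
                              quantiles = c(0.25, 0.5, 0.75)) {
  stopifnot(length(score) == nrow(survival_tab))
  if (sum(survival_tab$os_event) < 2L) stop("need at least 2 events")
  if (stats::sd(score, na.rm = TRUE) == 0 || all(is.na(score))) {
    warning("constant score: no valid cutoff")
    return(structure(list(per_cutoff = NULL, best = NA_integer_,
                          labels = NULL, fits = list()),
                     class = "strat_result"))
  }
  y <- survival::Surv(survival_tab$os_time, survival_tab$os_event)
  rows <- list(); fits <- list(); labels <- list()
  for (q in quantiles) {
    cutoff <- stats::quantile(score, q, na.rm = TRUE, names = FALSE)
    hi <- score >= cutoff
    if (all(hi, na.rm = TRUE) || !any(hi, na.rm = TRUE)) next
    grp <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
    sd_ <- survival::survdiff(y ~ grp)
    p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
    fit <- survival::survfit(y ~ grp)
    med <- summary(fit)$table[, "median"]
    rows[[length(rows) + 1L]] <- data.frame(
      quantile = q, cutoff = cutoff, n_high = sum(hi), n_low = sum(!hi),
      chisq = sd_$chisq, p = p,
      median_low = med[1L], median_high = med[2L], row.names = NULL)
    fits[[length(fits) + 1L]] <- fit
    labels[[length(labels) + 1L]] <- grp
  }
  if (length(rows) == 0L) {
    warning("no quantile cutoff produced two non-empty groups")
    return(structure(list(per_cutoff = NULL, best = NA_integer_,
                          labels = NULL, fits = list()),
                     class = "strat_result"))
  }
  per_cutoff <- do.call(rbind, rows)
  best <- which.min(per_cutoff$p)
  structure(list(per_cutoff = per_cutoff, best = best,
                 labels = labels[[best]], fits = fits),
            class = "strat_result")
}

#' @export
print.strat_result <- function(x, ...) {
  if (is.null(x$per_cutoff)) {
    cat("<strat_result> no valid cutoff\n")
    return(invisible(x))
  }
  cat("<strat_result> quantile cutoffs:\n")
  print(x$per_cutoff, digits = 4)
  cat(sprintf("best cutoff: %g%% quantile (p = %.4g)\n",
              100 * x$per_cutoff$quantile[x$best], x$per_cutoff$p[x$best]))
  invisible(x)
}

#' Plot Kaplan-Meier curves for the best stratification cutoff
#' @param x A `strat_result`.
#' @param ... Passed to [plot.survfit][survival::plot.survfit].
#' @export
plot.strat_result <- function(x, ...) {
  if (is.null(x$per_cutoff)) stop("no valid cutoff to plot")
  graphics::plot(x$fits[[x$best]], col = c("#2C64AD", "#8B0000"),
                 xlab = "time (months)", ylab = "survival probability", ...)
  graphics::legend("topright", legend = c("low", "high"),
                   col = c("#2C64AD", "#8B0000"), lty = 1, bty = "n")
  invisible(x)
}

# Precompute everything about one CV repeat that does not depend on the
# survival permutation: fold membership, per-fold candidate cutoffs and
# the train/test labels they imply.
.cv_prepare <- function(score, event, k, quantiles, max_tries = 100) {
  n <- length(score)
  for (try in seq_len(max_tries)) {
    folds <- sample(rep(seq_len(k), length.out = n))
    ok <- all(vapply(seq_len(k), function(f)
      sum(event[folds != f]) >= 2L, TRUE))
    if (ok) break
    if (try == max_tries) stop("could not partition folds with events in every training set")
  }
  plan <- vector("list", k)
  for (f in seq_len(k)) {
    train <- which(folds != f); test <- which(folds == f)
    cuts <- stats::quantile(score[train], quantiles, names = FALSE)
    valid <- logical(length(cuts))
    train_lab <- test_lab <- vector("list", length(cuts))
    for (ci in seq_along(cuts)) {
      tl <- as.integer(score[train] >= cuts[ci])
      valid[ci] <- any(tl == 0L) && any(tl == 1L)
      train_lab[[ci]] <- tl
      test_lab[[ci]] <- as.integer(score[test] >= cuts[ci])
    }
    plan[[f]] <- list(train = train, test = test, valid = valid,
                      train_lab = train_lab, test_lab = test_lab)
  }
  plan
}

# Pooled cross-validated logrank statistic for one (possibly permuted)
# survival vector, given a precomputed fold plan.
.cv_stat <- function(plan, time, event) {
  n <- length(time)
  pooled <- integer(n)
  for (f in plan) {
    tt <- time[f$train]; ee <- event[f$train]
    best_ci <- 0L; best_stat <- -1
    for (ci in seq_along(f$valid)) {
      if (!f$valid[ci]) next
      s <- cpp_logrank_chisq(tt, ee, f$train_lab[[ci]])
      if (s > best_stat) { best_stat <- s; best_ci <- ci }
    }
    if (best_ci == 0L) best_ci <- which.max(lengths(f$train_lab))  # fallback
    pooled[f$test] <- f$test_lab[[best_ci]]
  }
  if (all(pooled == pooled[1L])) return(0)
  cpp_logrank_chisq(time, event, pooled)
}

#' Repeated cross-validated stratification with permutation p-values
#'
#' For each of `n` repeats, the cohort is split into `k` random folds;
#' within each fold's training set the best quantile cutoff (by training
#' logrank statistic) is learned and applied to the held-out fold, and
#' the pooled high/low labels across folds give one cross-validated
#' logrank statistic. The identical procedure is applied to `m` joint
#' permutations of the (time, event) pairs to build the null
#' distribution, giving an add-one empirical p-value per repeat.
#'
#' @param score Per-sample score values aligned with `survival_tab`.
#' @param survival_tab A [survival_table()].
#' @param n Number of CV repeats (default 20).
#' @param k Number of folds (default 10).
#' @param m Number of permutations (default 1000).
#' @param quantiles Candidate cutoff quantiles.
#' @param seed Integer seed; folds and permutations flow from it, keyed
#'   to the sample order after sorting by `sample_id` so a row
#'   permutation of the input does not change the result.
#' @return Object of class `cv_perm_result` with per-repeat observed
#'   statistics and empirical p-values, and their median.
#' @export
repeated_cv_permutation <- function(score, survival_tab, n = 20, k = 10,
                                    m = 1000, quantiles = c(0.25, 0.5, 0.75),
                                    seed = 1) {
  stopifnot(length(score) == nrow(survival_tab))
  ord <- order(survival_tab$sample_id)
  score <- score[ord]
  time <- survival_tab$os_time[ord]
  event <- as.integer(survival_tab$os_event[ord])
  nsamp <- length(score)
  if (nsamp < 2L * k) stop("need at least 2 samples per fold")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  obs <- emp_p <- numeric(n)
  for (rep_i in seq_len(n)) {
    plan <- .cv_prepare(score, event, k, quantiles)
    obs[rep_i] <- .cv_stat(plan, time, event)
    null_ge <- 0L
    for (perm in seq_len(m)) {
      pi_ <- sample.int(nsamp)
      if (.cv_stat(plan, time[pi_], event[pi_]) >= obs[rep_i])
        null_ge <- null_ge + 1L
    }
    emp_p[rep_i] <- (1 + null_ge) / (m + 1)
  }
  structure(list(n = n, k = k, m = m, observed = obs, empirical_p = emp_p,
                 median_p = stats::median(emp_p)),
            class = "cv_perm_result")
}

#' @export
print.cv_perm_result <- function(x, ...) {
  cat(sprintf("<cv_perm_result> %d x %d-fold CV, %d permutations: median empirical p = %.4g\n",
              x$n, x$k, x$m, x$median_p))
  invisible(x)
}

#' Bivariate grouping by a spatial score and average expression
#'
#' Crosses the high/low dichotomies of a spatial score and of the average
#' marker expression (using the cutoffs from the univariate analyses)
#' into four groups and reports group sizes and Kaplan-Meier median
#' survival. Empty groups are reported as such; a constant feature
#' (single-level dichotomy) triggers a warning.
#'
#' @param score Spatial score values aligned with `survival_tab`.
#' @param survival_tab A [survival_table()] with `avg_expression`.
#' @param score_cutoff,expr_cutoff Dichotomization cutoffs ("high" =
#'   value >= cutoff).
#' @return List with `groups` (factor of labels like `low/high`,
#'   score/expression order), `table` (per-group n, events, median
#'   survival) and the Kaplan-Meier `fit`.
#' @export
bivariate_group <- function(score, survival_tab, score_cutoff, expr_cutoff) {
  stopifnot("avg_expression" %in% names(survival_tab))
  s_hi <- ifelse(score >= score_cutoff, "high", "low")
  e_hi <- ifelse(survival_tab$avg_expression >= expr_cutoff, "high", "low")
  if (length(unique(s_hi)) < 2L || length(unique(e_hi)) < 2L)
    warning("a feature dichotomy is constant; fewer than 4 groups are populated")
  lev <- c("low/low", "low/high", "high/low", "high/high")
  groups <- factor(paste(s_hi, e_hi, sep = "/"), levels = lev)
  y <- survival::Surv(survival_tab$os_time, survival_tab$os_event)
  tab <- data.frame(group = lev, n = as.integer(table(groups)),
                    events = as.integer(tapply(survival_tab$os_event, groups,
                                               sum, default = 0)),
                    median_survival = NA_real_)
  present <- droplevels(groups)
  fit <- NULL
  if (nlevels(present) >= 1L) {
    fit <- survival::survfit(y ~ groups)
    st <- summary(fit)$table
    if (is.null(dim(st))) st <- t(as.matrix(st))
    med <- st[, "median"]
    grp_names <- sub("^groups=", "", rownames(st))
    tab$median_survival[match(grp_names, tab$group)] <- med
  }
  list(groups = groups, table = tab, fit = fit)
}
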