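# Internal: univariate Cox Wald p-value and HR per SD for one score.
.uni_cox <- function(z, time, event) {
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ z, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ z,
                                       ties = "efron"))
    })
  if (is.null(fit) || is.na(stats::coef(fit)[1L]))
    return(c(coef = NA_real_, p = NA_real_))
  s <- summary(fit)
  c(coef = unname(stats::coef(fit)[1L]), p = unname(s$coefficients[1L, "Pr(>|z|)"]))
}

# Internal: align a score table to the survival table and impute missing
# values; returns matrix of scores (samples x scores) plus an audit log.
.prepare_scores <- function(scores, survival_tab, max_missing = 0.2) {
  stopifnot(inherits(scores, "score_table"))
  idx <- match(survival_tab$sample_id, scores$sample_id)
  if (anyNA(idx)) stop("survival samples missing from score table: ",
                       paste(survival_tab$sample_id[is.na(idx)], collapse = ", "))
  m <- as.matrix(scores[idx, setdiff(names(scores), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  audit <- character(0)
  frac_na <- colMeans(is.na(m))
  drop <- frac_na > max_missing
  if (any(drop)) {
    audit <- c(audit, paste0("dropped (>", max_missing * 100, "% missing): ",
                             paste(colnames(m)[drop], collapse = ", ")))
    m <- m[, !drop, drop = FALSE]
  }
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) {
      m[na, j] <- stats::median(m[, j], na.rm = TRUE)
      audit <- c(audit, paste0("median-imputed ", sum(na), " value(s) in ",
                               colnames(m)[j]))
    }
  }
  const <- apply(m, 2L, stats::sd) == 0
  if (any(const)) {
    warning("constant score column(s) excluded: ",
            paste(colnames(m)[const], collapse = ", "))
    audit <- c(audit, paste0("excluded constant column(s): ",
                             paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
  }
  list(m = m, audit = audit)
}

#' Prune correlated scores, keeping the best survival association
#'
#' Greedy correlation filter: scores are ranked by ascending univariate
#' Cox p-value (ties broken by name) and accepted in order; a candidate is
#' rejected when its absolute Pearson correlation with an already accepted
#' score exceeds `r_max`. The result is deterministic and invariant to the
#' column order of the input.
#'
#' @param scores A [score_table()].
#' @param survival_tab A [survival_table()].
#' @param r_max Correlation threshold (default 0.9).
#' @return List with `scores` (the reduced `score_table`), `cox_p` (named
#'   univariate p-values), `displaced` (which accepted score displaced
#'   each rejected one) and `audit`.
#' @export
prune_correlated <- function(scores, survival_tab, r_max = 0.9) {
  if (sum(survival_tab$os_event) < 2L) stop("need at least 2 events")
  prep <- .prepare_scores(scores, survival_tab)
  m <- prep$m
  if (ncol(m) == 0L) stop("no usable score columns")
  z <- scale(m)
  pvals <- vapply(seq_len(ncol(m)), function(j)
    .uni_cox(z[, j], survival_tab$os_time, survival_tab$os_event)["p"], 0)
  names(pvals) <- colnames(m)
  pvals[is.na(pvals)] <- 1
  ord <- order(pvals, colnames(m))
  cc <- suppressWarnings(stats::cor(m))
  kept <- integer(0)
  displaced <- character(0)
  for (j in ord) {
    clash <- kept[abs(cc[j, kept]) > r_max]
    if (length(clash) == 0L) kept <- c(kept, j)
    else displaced[colnames(m)[j]] <- colnames(m)[clash[1L]]
  }
  kept_names <- sort(colnames(m)[kept])
  out <- scores[, c("sample_id", kept_names), drop = FALSE]
  class(out) <- c("score_table", "data.frame")
  list(scores = out, cox_p = pvals, displaced = displaced, audit = prep$audit)
}

#' Cox-lasso stability selection
#'
#' Repeatedly subsamples the cohort without replacement, fits an
#' l1-penalized Cox model over a fixed 25-step penalty path per subsample,
#' and records which scores enter the path before the cumulative active
#' set reaches `q` variables. Scores whose selection frequency is at least
#' `freq_min` are kept.
#'
#' @param scores A pruned [score_table()].
#' @param survival_tab A [survival_table()].
#' @param freq_min Selection-frequency threshold (default 0.20).
#' @param B Number of subsamples (default 100).
#' @param fraction Subsample fraction (default 0.5).
#' @param q Per-subsample cap on the active set; default
#'   `ceiling(sqrt(p))` for `p` candidate scores.
#' @param seed Integer seed; all subsampling flows from it.
#' @return Object of class `selection_result` with `kept`, `frequency`,
#'   `cox_p`, `freq_min` and `audit`.
#' @export
stability_select <- function(scores, survival_tab, freq_min = 0.20, B = 100,
                             fraction = 0.5, q = NULL, seed = 1) {
  prep <- .prepare_scores(scores, survival_tab)
  m <- prep$m
  p <- ncol(m)
  if (p < 2L) {
    freq <- stats::setNames(rep(1, p), colnames(m))
    return(structure(list(kept = colnames(m), frequency = freq,
                          cox_p = NULL, freq_min = freq_min,
                          audit = c(prep$audit, "fewer than 2 scores: kept as-is")),
                     class = "selection_result"))
  }
  if (is.null(q)) q <- ceiling(sqrt(p))
  time <- survival_tab$os_time
  event <- survival_tab$os_event
  y <- survival::Surv(time, event)
  x <- scale(m)
  path <- tryCatch(
    glmnet::glmnet(x, y, family = "cox", nlambda = 25,
                   lambda.min.ratio = 0.05)$lambda,
    error = function(e) NULL)
  if (is.null(path)) stop("could not establish a penalty path")
  n <- nrow(x)
  nsub <- ceiling(fraction * n)
  sel_count <- stats::setNames(numeric(p), colnames(m))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- NULL
    for (try in 1:50) {
      cand <- sample.int(n, nsub)
      if (sum(event[cand]) >= 2L) { idx <- cand; break }
    }
    if (is.null(idx)) stop("could not draw a subsample with >= 2 events")
    fit <- tryCatch(
      glmnet::glmnet(x[idx, , drop = FALSE], y[idx, ], family = "cox",
                     lambda = path),
      error = function(e) NULL)
    if (is.null(fit)) next
    beta <- as.matrix(fit$beta)  # p x n_lambda, largest lambda first
    active <- logical(p)
    for (l in seq_len(ncol(beta))) {
      active <- active | beta[, l] != 0
      if (sum(active) >= q) break
    }
    sel_count[active] <- sel_count[active] + 1
  }
  freq <- sel_count / B
  kept <- sort(names(freq)[freq >= freq_min])
  structure(list(kept = kept, frequency = freq, freq_min = freq_min,
                 B = B, fraction = fraction, q = q, audit = prep$audit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d score(s) kept at frequency >= %.2f\n",
              length(x$kept), x$freq_min))
  if (length(x$kept))
    for (k in x$kept)
      cat(sprintf("  %-35s %.2f\n", k, x$frequency[k]))
  invisible(x)
}

#' Serialize a selection result to CSV
#' @param sel A `selection_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  utils::write.csv(data.frame(score = names(sel$frequency),
                              frequency = unname(sel$frequency),
                              kept = names(sel$frequency) %in% sel$kept),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Save/restore the RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
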