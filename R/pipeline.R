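#' Pipeline run configuration
#'
#' Collects every tunable parameter of the scoring and survival pipeline
#' with the standard defaults: co-occurrence radii 10/25/50/75 µm, 250 µm
#' tiles shifted by a tenth of the tile size, at least 5 cells per tile,
#' OD thresholds 8/10/15/20/25, entropy threshold 0.61 nats, correlation
#' pruning at 0.9, stability-selection frequency 0.20 (B = 100 subsamples
#' of half the cohort), and 20 x 10-fold cross-validation with 1000
#' permutations.
#'
#' @param radii Co-occurrence neighborhood radii in µm.
#' @param tile_size Tile side in µm.
#' @param shift Grid shift in µm.
#' @param min_cells Minimum cells per retained tile.
#' @param thetas OD thresholds.
#' @param entropy_threshold Heterogeneity cutoff in nats.
#' @param r_max Pearson pruning threshold.
#' @param freq_min Stability-selection frequency threshold.
#' @param B,fraction Stability-selection subsample count and fraction.
#' @param cv_n,cv_k,cv_m CV repeats, folds and permutations.
#' @param seed Integer seed for all randomized stages.
#' @return A `run_config` list.
#' @export
run_config <- function(radii = c(10, 25, 50, 75), tile_size = 250,
                       shift = tile_size / 10, min_cells = 5,
                       thetas = c(8, 10, 15, 20, 25),
                       entropy_threshold = 0.61, r_max = 0.9,
                       freq_min = 0.20, B = 100, fraction = 0.5,
                       cv_n = 20, cv_k = 10, cv_m = 1000, seed = 1) {
  structure(list(radii = radii, tile_size = tile_size, shift = shift,
                 min_cells = min_cells, thetas = thetas,
                 entropy_threshold = entropy_threshold, r_max = r_max,
                 freq_min = freq_min, B = B, fraction = fraction,
                 cv_n = cv_n, cv_k = cv_k, cv_m = cv_m, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unset keys fall back to the defaults of [run_config()].
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) warning("ignoring unknown config key(s): ",
                               paste(unknown, collapse = ", "))
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Score every sample of a cohort
#'
#' Computes the full 53-score battery (16 co-occurrence + 37 tessellation
#' scores) per sample. Per-sample failures are isolated: the sample's row
#' is filled with missing values and the error recorded, never aborting
#' the cohort.
#'
#' @param cells Named list of [cell_table()]s, or a manifest data frame
#'   from [read_manifest()].
#' @param config A [run_config()].
#' @param verbose Print per-sample progress.
#' @return A [score_table()] with attribute `errors` (named list of
#'   per-sample failure messages, if any).
#' @export
run_scores <- function(cells, config = run_config(), verbose = FALSE) {
  if (is.data.frame(cells)) {
    manifest <- cells
    cells <- lapply(seq_len(nrow(manifest)), function(i)
      tryCatch(read_cell_table(manifest$path[i],
                               sample_id = manifest$sample_id[i]),
               error = function(e) e))
    names(cells) <- manifest$sample_id
  }
  if (length(cells) == 0L) stop("empty cohort")
  score_names <- NULL
  rows <- vector("list", length(cells))
  errors <- list()
  for (i in seq_along(cells)) {
    id <- names(cells)[i]
    res <- tryCatch({
      ct <- cells[[i]]
      if (inherits(ct, "error")) stop(conditionMessage(ct))
      c(cooccurrence_scores(ct, config$radii),
        tessellation_scores(ct, config$thetas, config$tile_size,
                            config$shift, config$min_cells,
                            config$entropy_threshold))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      rows[[i]] <- NA
    } else {
      if (is.null(score_names)) score_names <- names(res)
      rows[[i]] <- res
    }
    if (verbose) message(sprintf("[%d/%d] %s%s", i, length(cells), id,
                                 if (inherits(res, "error")) " FAILED" else ""))
  }
  if (is.null(score_names)) stop("every sample failed to score")
  rows <- lapply(rows, function(r)
    if (length(r) == 1L && is.na(r))
      stats::setNames(rep(NA_real_, length(score_names)), score_names)
    else r)
  names(rows) <- names(cells)
  out <- score_table(rows)
  attr(out, "errors") <- errors
  out
}

#' Run the survival-evaluation stage
#'
#' Given a score table and clinical outcomes: prunes correlated scores,
#' runs Cox-lasso stability selection, then for each selected score the
#' univariate Cox fit, quantile-cutoff stratification and (optionally)
#' the repeated CV permutation test; finally the multiple Cox model with
#' stepwise reduction and likelihood-ratio test against the clinical
#' base model.
#'
#' @param scores A [score_table()].
#' @param survival_tab A [survival_table()].
#' @param config A [run_config()].
#' @param run_cv Run the (expensive) CV permutation stage (default TRUE).
#' @return List with `selection`, `pruned`, `univariate` (data frame),
#'   `stratification` (list of `strat_result`), `cv` (list of
#'   `cv_perm_result`), and `multiple` (stepwise + LR test).
#' @export
run_survival <- function(scores, survival_tab, config = run_config(),
                         run_cv = TRUE) {
  missing_ids <- setdiff(survival_tab$sample_id, scores$sample_id)
  if (length(missing_ids))
    stop("samples without scores: ", paste(missing_ids, collapse = ", "))
  pruned <- prune_correlated(scores, survival_tab, config$r_max)
  sel <- stability_select(pruned$scores, survival_tab,
                          freq_min = config$freq_min, B = config$B,
                          fraction = config$fraction, seed = config$seed)
  idx <- match(survival_tab$sample_id, scores$sample_id)
  uni <- list(); strat <- list(); cv <- list()
  for (s in sel$kept) {
    v <- scores[[s]][idx]
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    u <- univariate_cox(v, survival_tab)
    uni[[s]] <- data.frame(score = s, hr_per_sd = u$hr, p = u$p,
                           ci_low = u$ci[1L], ci_high = u$ci[2L], ok = u$ok)
    strat[[s]] <- quantile_stratify(v, survival_tab)
    if (run_cv)
      cv[[s]] <- repeated_cv_permutation(v, survival_tab, n = config$cv_n,
                                         k = config$cv_k, m = config$cv_m,
                                         seed = config$seed)
  }
  multiple <- if (length(sel$kept))
    multiple_cox_stepwise(pruned$scores, survival_tab, candidates = sel$kept)
  else NULL
  list(selection = sel, pruned = pruned,
       univariate = if (length(uni)) do.call(rbind, uni) else NULL,
       stratification = strat, cv = cv, multiple = multiple)
}

#' Run the full pipeline and write reports
#'
#' Scores the cohort, evaluates survival associations and writes CSV
#' reports plus the resolved configuration to `out_dir`.
#'
#' @param cells Named list of cell tables or a manifest data frame.
#' @param survival_tab A [survival_table()].
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param run_cv Run the CV permutation stage.
#' @return Invisibly, the list from [run_survival()] plus `scores`.
#' @export
run_pipeline <- function(cells, survival_tab, config = run_config(),
                         out_dir = ".", run_cv = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- run_scores(cells, config)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  res <- run_survival(scores, survival_tab, config, run_cv = run_cv)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  write_selection(res$selection, file.path(out_dir, "selection.csv"))
  if (!is.null(res$univariate))
    utils::write.csv(res$univariate, file.path(out_dir, "univariate_cox.csv"),
                     row.names = FALSE, quote = FALSE)
  strat_rows <- lapply(names(res$stratification), function(s) {
    pc <- res$stratification[[s]]$per_cutoff
    if (is.null(pc)) return(NULL)
    cbind(score = s, pc)
  })
  strat_rows <- Filter(Negate(is.null), strat_rows)
  if (length(strat_rows))
    utils::write.csv(do.call(rbind, strat_rows),
                     file.path(out_dir, "stratification.csv"),
                     row.names = FALSE, quote = FALSE)
  if (length(res$cv)) {
    cv_tab <- do.call(rbind, lapply(names(res$cv), function(s)
      data.frame(score = s, median_empirical_p = res$cv[[s]]$median_p)))
    utils::write.csv(cv_tab, file.path(out_dir, "cv_permutation.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  res$scores <- scores
  invisible(res)
}
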