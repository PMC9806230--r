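#' Specify a synthetic tissue sample
#'
#' Defines the point process for cell positions and the marker-expression
#' field sampled at those positions. Position models: `"uniform"` (fixed
#' `n_cells`, i.i.d. uniform in the window) or `"matern"` (Matérn cluster
#' process: Poisson parents with Poisson offspring uniform in a disc;
#' `n_cells` is the expected total). Expression models:
#' \describe{
#'   \item{constant}{`od = mu + noise`.}
#'   \item{patchy}{a smooth Gaussian random field (random Fourier
#'     features with length-scale `patch_scale`) is thresholded at the
#'     area quantile giving `high_fraction` high-expression area; cells
#'     in high patches get mean `mu_high`, others `mu_low`.}
#'   \item{gradient}{mean OD rises linearly from `mu_start` at the left
#'     window edge to `mu_end` at the right.}
#' }
#' Gaussian noise with standard deviation `sd_noise` is added and the
#' result clamped to `[0, 255]`.
#'
#' @param window Length-2 numeric, window width and height in µm.
#' @param n_cells Number of cells (exact for `"uniform"`, expected for
#'   `"matern"`).
#' @param positions `"uniform"` or `"matern"`.
#' @param parent_intensity,cluster_radius Matérn parameters (parents per
#'   µm²; offspring disc radius in µm).
#' @param field `"constant"`, `"patchy"` or `"gradient"`.
#' @param mu,mu_high,mu_low,mu_start,mu_end Field means (OD units).
#' @param sd_noise Per-cell Gaussian noise SD (OD units).
#' @param patch_scale Patch length-scale in µm.
#' @param high_fraction Target high-expression area fraction.
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(window = c(2000, 2000), n_cells = 10000,
                        positions = c("uniform", "matern"),
                        parent_intensity = 5e-6, cluster_radius = 100,
                        field = c("constant", "patchy", "gradient"),
                        mu = 20, mu_high = 30, mu_low = 5,
                        mu_start = 5, mu_end = 30,
                        sd_noise = 2, patch_scale = 500,
                        high_fraction = 0.5) {
  positions <- match.arg(positions)
  field <- match.arg(field)
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0))
    stop("window must be two positive lengths in µm")
  if (n_cells < 1) stop("n_cells must be at least 1")
  if (high_fraction <= 0 || high_fraction >= 1)
    stop("high_fraction must be in (0, 1)")
  structure(list(window = window, n_cells = n_cells, positions = positions,
                 parent_intensity = parent_intensity,
                 cluster_radius = cluster_radius, field = field, mu = mu,
                 mu_high = mu_high, mu_low = mu_low, mu_start = mu_start,
                 mu_end = mu_end, sd_noise = sd_noise,
                 patch_scale = patch_scale, high_fraction = high_fraction),
            class = "tissue_spec")
}

# Smooth stationary Gaussian random field via random Fourier features of
# a squared-exponential kernel with length-scale `scale`.
.rff_field <- function(scale, n_features = 64) {
  w <- matrix(stats::rnorm(2 * n_features, sd = 1 / scale), ncol = 2L)
  b <- stats::runif(n_features, 0, 2 * pi)
  function(x, y) {
    phase <- cbind(x, y) %*% t(w) + rep(b, each = length(x))
    sqrt(2 / n_features) * rowSums(cos(phase))
  }
}

#' Generate one synthetic tissue sample
#'
#' @param spec A [tissue_spec()].
#' @param sample_id Sample identifier.
#' @param seed Optional integer seed for full reproducibility.
#' @return A [cell_table()]. For `"patchy"` fields the realized high-area
#'   fraction is attached as attribute `high_fraction`.
#' @export
generate_tissue <- function(spec, sample_id = "synthetic", seed = NULL) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  W <- spec$window
  if (spec$positions == "uniform") {
    n <- spec$n_cells
    x <- stats::runif(n, 0, W[1L]); y <- stats::runif(n, 0, W[2L])
  } else {
    R <- spec$cluster_radius
    ext <- c(W[1L] + 2 * R, W[2L] + 2 * R)
    n_par <- stats::rpois(1L, spec$parent_intensity * prod(ext))
    if (n_par == 0L) n_par <- 1L
    mu_off <- spec$n_cells / (spec$parent_intensity * prod(ext)) *
      prod(ext) / prod(W) # expected offspring per parent, window-corrected
    px <- stats::runif(n_par, -R, W[1L] + R)
    py <- stats::runif(n_par, -R, W[2L] + R)
    n_off <- stats::rpois(n_par, mu_off)
    x <- y <- numeric(0)
    for (i in seq_len(n_par)) {
      if (n_off[i] == 0L) next
      r <- R * sqrt(stats::runif(n_off[i]))
      a <- stats::runif(n_off[i], 0, 2 * pi)
      x <- c(x, px[i] + r * cos(a)); y <- c(y, py[i] + r * sin(a))
    }
    inside <- x >= 0 & x <= W[1L] & y >= 0 & y <= W[2L]
    x <- x[inside]; y <- y[inside]
    if (length(x) == 0L) { x <- stats::runif(1L, 0, W[1L]); y <- stats::runif(1L, 0, W[2L]) }
  }
  n <- length(x)
  high_frac <- NA_real_
  base <- switch(spec$field,
    constant = rep(spec$mu, n),
    gradient = spec$mu_start + (spec$mu_end - spec$mu_start) * x / W[1L],
    patchy = {
      f <- .rff_field(spec$patch_scale)
      # area-based threshold from a dense reference grid
      gx <- seq(0, W[1L], length.out = 60)
      gy <- seq(0, W[2L], length.out = 60)
      gg <- expand.grid(gx, gy)
      thr <- stats::quantile(f(gg[, 1L], gg[, 2L]), 1 - spec$high_fraction,
                             names = FALSE)
      hi <- f(x, y) >= thr
      high_frac <- mean(hi)
      ifelse(hi, spec$mu_high, spec$mu_low)
    })
  od <- pmax(0, pmin(255, base + stats::rnorm(n, 0, spec$sd_noise)))
  ct <- cell_table(x, y, od, sample_id = sample_id)
  attr(ct, "high_fraction") <- high_frac
  ct
}

#' Simulate proportional-hazards survival for a cohort
#'
#' Draws overall-survival times from an exponential baseline with
#' log-hazard `beta * z` on the standardized driver score, with
#' independent exponential censoring tuned to the target censoring rate.
#'
#' @param driver Per-sample driver score values.
#' @param beta Log hazard ratio per SD of the driver (0 = null).
#' @param baseline_median Median survival in months at the mean driver
#'   value (default 36).
#' @param censoring_rate Approximate fraction censored (default 0.3).
#' @return Data frame with `os_time` (months) and `os_event` (0/1).
#' @export
simulate_survival <- function(driver, beta, baseline_median = 36,
                              censoring_rate = 0.3) {
  n <- length(driver)
  z <- if (stats::sd(driver) > 0) as.numeric(scale(driver)) else rep(0, n)
  lambda0 <- log(2) / baseline_median
  t_event <- stats::rexp(n, rate = lambda0 * exp(beta * z))
  if (censoring_rate > 0) {
    lambda_c <- lambda0 * censoring_rate / (1 - censoring_rate)
    t_cens <- stats::rexp(n, rate = lambda_c)
  } else t_cens <- rep(Inf, n)
  data.frame(os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic cohort with linked survival
#'
#' Generates `n_samples` tissue samples as a mixture of homogeneous-high,
#' homogeneous-low and patchy types (patchy samples get high-area
#' fractions spread over `high_fraction_range`), evaluates a driver score
#' on each, and simulates proportional-hazards survival driven by it.
#' Clinical covariates (age, gender, grade) are drawn independently;
#' `avg_expression` is the per-sample mean OD.
#'
#' @param n_samples Number of samples (default 30).
#' @param fractions Length-3 numeric mixture of sample types
#'   (homogeneous-high, homogeneous-low, patchy); must sum to 1.
#' @param driver_fn Function `cell_table -> numeric` giving the score
#'   that drives survival; the default uses the realized patchy high-area
#'   fraction (0 for homogeneous samples), the generator's ground truth.
#' @param beta Log hazard ratio per SD of the driver.
#' @param n_cells Cells per sample.
#' @param censoring_rate Fraction censored.
#' @param high_fraction_range Range of patchy high-area fractions.
#' @param seed Integer seed.
#' @param spec_args Extra arguments passed to [tissue_spec()].
#' @return List with `cells` (named list of `cell_table`s), `survival`
#'   (a [survival_table()]), `driver` (the per-sample driver values) and
#'   `beta`.
#' @export
generate_cohort <- function(n_samples = 30, fractions = c(0.25, 0.25, 0.5),
                            driver_fn = NULL, beta = 0, n_cells = 2000,
                            censoring_rate = 0.3,
                            high_fraction_range = c(0.2, 0.8), seed = 1,
                            spec_args = list()) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  types <- sample(rep(c("hom_high", "hom_low", "patchy"),
                      times = round(fractions * n_samples))[seq_len(n_samples)])
  types[is.na(types)] <- "patchy"
  ids <- sprintf("s%03d", seq_len(n_samples))
  cells <- vector("list", n_samples); names(cells) <- ids
  driver <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    args <- spec_args
    if (types[i] == "patchy") {
      args$field <- "patchy"
      args$high_fraction <- stats::runif(1, high_fraction_range[1L],
                                         high_fraction_range[2L])
    } else {
      args$field <- "constant"
      args$mu <- if (types[i] == "hom_high") 30 else 5
    }
    args$n_cells <- n_cells
    ct <- generate_tissue(do.call(tissue_spec, args), sample_id = ids[i])
    cells[[i]] <- ct
    driver[i] <- if (is.null(driver_fn)) {
      hf <- attr(ct, "high_fraction")
      if (is.na(hf)) 0 else hf
    } else driver_fn(ct)
  }
  surv <- simulate_survival(driver, beta, censoring_rate = censoring_rate)
  surv_tab <- survival_table(data.frame(
    sample_id = ids, os_time = surv$os_time, os_event = surv$os_event,
    age = round(stats::rnorm(n_samples, 65, 10)),
    gender = factor(sample(c("F", "M"), n_samples, replace = TRUE)),
    grade = factor(sample(c("G1", "G2", "G3"), n_samples, replace = TRUE)),
    avg_expression = vapply(cells, function(ct) mean(ct$od), 0),
    stringsAsFactors = FALSE))
  list(cells = cells, survival = surv_tab, driver = driver, beta = beta,
       types = types)
}
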