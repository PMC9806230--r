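#' Tessellate a tissue sample into square tiles
#'
#' The relevant tissue region is the convex hull of the cell coordinates;
#' its axis-aligned bounding box is covered by square tiles of side
#' `tile_size`, optionally shifted by an origin offset. Cells are assigned
#' by half-open intervals anchored at the bounding-box minimum (a cell
#' exactly on the maximum boundary goes to the last tile), so tile
#' membership is a partition of the cells. Tiles with fewer than
#' `min_cells` cells are dropped.
#'
#' @param cells A [cell_table()].
#' @param tile_size Tile side length in µm (default 250).
#' @param offset Length-2 numeric `(dx, dy)` grid origin shift in µm.
#' @param min_cells Minimum cells for a tile to be retained (default 5).
#' @return Object of class `tile_grid`: `tile_size`, `offset`,
#'   `n_dropped` (tiles removed by the cell-count filter) and `tiles`, a
#'   data frame with tile indices `(row, col)`, bounds, `n_cells`,
#'   `mean_od`, `sd_od` plus a list column `members` of cell indices.
#' @export
tessellate <- function(cells, tile_size = 250, offset = c(0, 0),
                       min_cells = 5) {
  stopifnot(inherits(cells, "cell_table"))
  if (tile_size <= 0) stop("tile_size must be positive")
  if (nrow(cells) < min_cells) stop("sample too sparse for tessellation")
  x0 <- min(cells$x); y0 <- min(cells$y)
  xm <- max(cells$x); ym <- max(cells$y)
  cidx <- .tile_index(cells$x, x0, xm, offset[1L], tile_size)
  ridx <- .tile_index(cells$y, y0, ym, offset[2L], tile_size)
  key <- paste(ridx, cidx)
  groups <- split(seq_len(nrow(cells)), key)
  n_per <- lengths(groups)
  keep <- n_per >= min_cells
  n_dropped <- sum(!keep)
  groups <- groups[keep]
  if (length(groups) == 0L) stop("sample too sparse for tessellation")
  rc <- do.call(rbind, strsplit(names(groups), " ", fixed = TRUE))
  row <- as.integer(rc[, 1L]); col <- as.integer(rc[, 2L])
  mean_od <- vapply(groups, function(ix) mean(cells$od[ix]), 0)
  sd_od <- vapply(groups, function(ix) stats::sd(cells$od[ix]), 0)
  tiles <- data.frame(row = row, col = col,
                      xmin = x0 + offset[1L] + col * tile_size,
                      ymin = y0 + offset[2L] + row * tile_size,
                      n_cells = as.integer(n_per[keep]),
                      mean_od = mean_od, sd_od = sd_od,
                      row.names = NULL)
  tiles$members <- unname(groups)
  structure(list(tile_size = tile_size, offset = offset,
                 min_cells = min_cells, n_dropped = n_dropped,
                 tiles = tiles, od = cells$od),
            class = "tile_grid")
}

# Half-open tile assignment with the max-boundary cell folded into the
# last tile when the boundary is an exact tile edge.
.tile_index <- function(v, v0, vmax, off, s) {
  idx <- floor((v - v0 - off) / s)
  top <- (vmax - v0 - off) / s
  if (top == floor(top) && top > floor((min(v) - v0 - off) / s))
    idx[v == vmax] <- as.integer(top) - 1L
  as.integer(idx)
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d retained tiles (%d dropped), tile %g µm, offset (%g, %g)\n",
              nrow(x$tiles), x$n_dropped, x$tile_size, x$offset[1L], x$offset[2L]))
  invisible(x)
}

#' Shannon entropy of a marker-positive fraction
#'
#' `H = -p ln p - (1-p) ln(1-p)` in nats, with `0 ln 0 := 0`. On this
#' scale a 70/30 split gives 0.611, the default heterogeneity threshold,
#' and a 50/50 split gives `ln 2` (0.693), the maximum.
#'
#' @param p Numeric vector of fractions in `[0, 1]`.
#' @return Entropy in nats, in `[0, ln 2]`.
#' @export
tile_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q > 0, -q * log(q), 0)
  term(p) + term(1 - p)
}

# Per-tile positive fraction and entropy at threshold theta.
.tile_stats <- function(grid, theta) {
  pos <- vapply(grid$tiles$members,
                function(ix) mean(grid$od[ix] >= theta), 0)
  list(pos_fraction = pos, entropy = tile_entropy(pos))
}

#' Classify tiles at an OD threshold
#'
#' Decision-tree scheme: a tile whose Shannon entropy of marker-positive
#' vs marker-negative cells (cells with `od >= theta` are positive)
#' exceeds `entropy_threshold` is *heterogenous*; otherwise it is
#' *homogenous-high* when the tile mean OD is at least `theta`, else
#' *homogenous-low*.
#'
#' @param grid A `tile_grid`.
#' @param theta OD threshold.
#' @param entropy_threshold Heterogeneity cutoff in nats (default 0.61,
#'   i.e. at most 70/30 class proportions for a homogenous call).
#' @return Factor with levels `heterogenous`, `homogenous-high`,
#'   `homogenous-low`, one per retained tile.
#' @export
classify_tiles <- function(grid, theta, entropy_threshold = 0.61) {
  stopifnot(inherits(grid, "tile_grid"))
  st <- .tile_stats(grid, theta)
  cls <- ifelse(st$entropy > entropy_threshold, "heterogenous",
                ifelse(grid$tiles$mean_od >= theta,
                       "homogenous-high", "homogenous-low"))
  factor(cls, levels = c("heterogenous", "homogenous-high", "homogenous-low"))
}

#' Fraction of high-expression tiles
#'
#' The binary spatial-expression-map score: the fraction of retained tiles
#' whose mean OD is at least `theta`.
#' @param grid A `tile_grid`.
#' @param theta OD threshold.
#' @return Fraction in `[0, 1]`.
#' @export
expression_class_ratio <- function(grid, theta) {
  stopifnot(inherits(grid, "tile_grid"))
  mean(grid$tiles$mean_od >= theta)
}

#' Three-class tile composition
#'
#' Fractions of heterogenous, homogenous-high and homogenous-low tiles
#' (summing to 1) under [classify_tiles()].
#' @inheritParams classify_tiles
#' @return Named numeric vector of three fractions.
#' @export
three_class_ratios <- function(grid, theta, entropy_threshold = 0.61) {
  cls <- classify_tiles(grid, theta, entropy_threshold)
  tab <- table(cls) / length(cls)
  c(frac_heterogenous = unname(tab["heterogenous"]),
    frac_homogenous_high = unname(tab["homogenous-high"]),
    frac_homogenous_low = unname(tab["homogenous-low"]))
}

#' Grid-shift averaged score
#'
#' Evaluates `score_fn` on grids shifted by `shift` µm in each of the four
#' axis directions and returns the mean, making tile-based scores robust
#' to the grid placement. Shifts where no tile survives the cell-count
#' filter are skipped with a warning.
#'
#' @param cells A [cell_table()].
#' @param score_fn Function mapping a `tile_grid` to one number.
#' @param tile_size Tile side in µm.
#' @param shift Shift magnitude in µm; defaults to a tenth of the tile
#'   size (25 µm at the default 250 µm tile).
#' @param min_cells Minimum cells per retained tile.
#' @param include_origin Also average the unshifted grid (default FALSE).
#' @return Mean of the per-shift scores.
#' @export
shifted_score <- function(cells, score_fn, tile_size = 250,
                          shift = tile_size / 10, min_cells = 5,
                          include_origin = FALSE) {
  offsets <- list(c(shift, 0), c(-shift, 0), c(0, shift), c(0, -shift))
  if (include_origin) offsets <- c(list(c(0, 0)), offsets)
  vals <- numeric(0)
  for (off in offsets) {
    v <- tryCatch(score_fn(tessellate(cells, tile_size, off, min_cells)),
                  error = function(e) NA_real_)
    if (is.na(v)) warning("grid shift produced no retained tiles; skipped")
    else vals <- c(vals, v)
  }
  if (length(vals) == 0L) stop("no grid shift produced a usable tessellation")
  mean(vals)
}

#' Ecosystem Diversity Index
#'
#' Fits one-dimensional Gaussian mixture models with 1..`max_components`
#' components to `values` and returns the component count of the best fit
#' by the Bayesian information criterion; ties favor fewer components.
#' With fewer than `2 * max_components` values the component range is
#' reduced to `floor(n/2)` (at least 1). A constant vector has EDI 1 by
#' definition.
#'
#' @param values Numeric vector (per-tile entropies, means or SDs).
#' @param max_components Largest component count tried (default 5).
#' @return Object of class `edi_fit` with `edi`, `bic` (per component
#'   count, conventional smaller-is-better scale) and `values`.
#' @export
edi <- function(values, max_components = 5) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("no finite values for EDI")
  gmax <- max(1L, min(max_components, floor(n / 2)))
  if (stats::sd(values) == 0 || n < 2L)
    return(structure(list(edi = 1L, bic = stats::setNames(NA_real_, "1"),
                          values = values), class = "edi_fit"))
  fit <- tryCatch(
    mclust::mclustBIC(values, G = 1:gmax, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  bic <- rep(NA_real_, gmax)
  if (!is.null(fit)) bic[seq_len(nrow(fit))] <- fit[, "V"]
  if (all(is.na(bic))) {
    fit <- tryCatch(
      mclust::mclustBIC(values, G = 1:gmax, modelNames = "E", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) bic[seq_len(nrow(fit))] <- fit[, "E"]
  }
  # mclust reports BIC on a larger-is-better scale; convert to the
  # conventional -2 logLik + k log n so the EDI is the argmin.
  bic <- -bic
  names(bic) <- as.character(1:gmax)
  if (all(is.na(bic)))
    return(structure(list(edi = NA_integer_, bic = bic, values = values),
                     class = "edi_fit"))
  best <- which(bic == min(bic, na.rm = TRUE))[1L]
  structure(list(edi = as.integer(best), bic = bic, values = values),
            class = "edi_fit")
}

#' @export
print.edi_fit <- function(x, ...) {
  cat(sprintf("<edi_fit> EDI = %s over %d values (components tried: %s)\n",
              x$edi, length(x$values), paste(names(x$bic), collapse = ",")))
  invisible(x)
}

#' The tessellation score battery
#'
#' Computes the 37 tessellation scores of a sample at the default
#' settings: per OD threshold (5 thresholds), the shift-averaged fraction
#' of high-expression tiles, the mean per-tile entropy, the EDI of the
#' per-tile entropies, the three tile-class fractions and the global
#' marker-positive cell fraction; plus the EDI of the per-tile mean OD and
#' of the per-tile OD standard deviation. EDI-type scores and the class
#' fractions are computed on the unshifted grid.
#'
#' @param cells A [cell_table()].
#' @param thetas OD thresholds (default `c(8, 10, 15, 20, 25)`).
#' @param tile_size Tile side in µm (default 250).
#' @param shift Grid shift in µm (default `tile_size / 10`).
#' @param min_cells Minimum cells per tile (default 5).
#' @param entropy_threshold Heterogeneity cutoff in nats (default 0.61).
#' @return Named numeric vector of 37 scores.
#' @export
tessellation_scores <- function(cells, thetas = c(8, 10, 15, 20, 25),
                                tile_size = 250, shift = tile_size / 10,
                                min_cells = 5, entropy_threshold = 0.61) {
  stopifnot(inherits(cells, "cell_table"))
  grid <- tessellate(cells, tile_size, c(0, 0), min_cells)
  out <- numeric(0)
  for (th in thetas) {
    ratio <- tryCatch(
      shifted_score(cells, function(g) expression_class_ratio(g, th),
                    tile_size, shift, min_cells),
      error = function(e) NA_real_)
    st <- .tile_stats(grid, th)
    ent_edi <- edi(st$entropy)$edi
    ratios3 <- three_class_ratios(grid, th, entropy_threshold)
    vals <- c(ratio, mean(st$entropy), as.numeric(ent_edi),
              unname(ratios3), mean(cells$od >= th))
    names(vals) <- paste0(
      c("ratio_high", "mean_entropy", "edi_entropy",
        "frac_heterogenous", "frac_homogenous_high", "frac_homogenous_low",
        "pos_cell_fraction"), "_od", th)
    out <- c(out, vals)
  }
  out <- c(out,
           edi_mean_od = as.numeric(edi(grid$tiles$mean_od)$edi),
           edi_sd_od = as.numeric(edi(grid$tiles$sd_od)$edi))
  out
}

#' Export per-tile records for map rendering
#'
#' Writes one row per retained tile with bounds in µm, summary statistics
#' and the class label at each OD threshold.
#' @param grid A `tile_grid`.
#' @param path Output CSV path.
#' @param thetas OD thresholds for class labels.
#' @param entropy_threshold Heterogeneity cutoff in nats.
#' @return `path`, invisibly.
#' @export
write_tile_map <- function(grid, path, thetas = c(8, 10, 15, 20, 25),
                           entropy_threshold = 0.61) {
  df <- grid$tiles[, c("row", "col", "xmin", "ymin", "n_cells",
                       "mean_od", "sd_od")]
  df$xmax <- df$xmin + grid$tile_size
  df$ymax <- df$ymin + grid$tile_size
  for (th in thetas)
    df[[paste0("class_od", th)]] <-
      as.character(classify_tiles(grid, th, entropy_threshold))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a tile class map
#'
#' Draws the retained tiles colored by class at one OD threshold, the
#' spatial-expression-map analogue of a stained-slide overlay.
#' @param x A `tile_grid`.
#' @param theta OD threshold (default 15).
#' @param entropy_threshold Heterogeneity cutoff in nats.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tile_grid <- function(x, theta = 15, entropy_threshold = 0.61, ...) {
  cls <- classify_tiles(x, theta, entropy_threshold)
  cols <- c(heterogenous = "#BFA300", `homogenous-high` = "#8B0000",
            `homogenous-low` = "#2C64AD")
  t <- x$tiles
  graphics::plot(NA, xlim = range(c(t$xmin, t$xmin + x$tile_size)),
                 ylim = range(c(t$ymin, t$ymin + x$tile_size)),
                 xlab = "x (µm)", ylab = "y (µm)", asp = 1, ...)
  graphics::rect(t$xmin, t$ymin, t$xmin + x$tile_size, t$ymin + x$tile_size,
                 col = cols[as.character(cls)], border = "grey40")
  graphics::legend("topright", legend = names(cols), fill = cols, bty = "n",
                   cex = 0.8)
  invisible(x)
}
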