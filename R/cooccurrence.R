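#' Map a continuous OD value to a co-occurrence level
#'
#' OD values on the 0--255 stain scale are rounded half-up to the nearest
#' integer and clamped to the 255 levels 0..254 used by the co-occurrence
#' matrix.
#'
#' @param od Numeric vector of OD values (finite, non-negative).
#' @return Integer vector of levels in 0..254.
#' @export
map_od_to_level <- function(od) {
  if (any(!is.finite(od))) stop("od must be finite")
  if (any(od < 0)) stop("od must be non-negative")
  pmin(as.integer(floor(od + 0.5)), 254L)
}

#' Build the object-based co-occurrence matrix
#'
#' A 255x255 joint histogram of mapped OD levels over all pairs of cells
#' sharing an edge in the neighborhood graph. Counting is symmetric: each
#' undirected edge contributes both ordered level pairs, so the matrix is
#' exactly symmetric and its marginals coincide. The matrix is normalized
#' to sum to 1.
#'
#' @param cells A [cell_table()].
#' @param graph A `nbhd_graph` built on the same cells.
#' @return Object of class `cooc_matrix`: `p` (255x255 matrix, levels
#'   0..254), `mu` and `sigma` (the common marginal mean and standard
#'   deviation) and `n_pairs` (2 x number of edges).
#' @export
build_cooccurrence <- function(cells, graph) {
  stopifnot(inherits(cells, "cell_table"), inherits(graph, "nbhd_graph"))
  if (graph$n_cells != nrow(cells))
    stop("graph was built on a different number of cells")
  if (nrow(graph$edges) == 0L)
    stop("empty graph: co-occurrence undefined at this radius")
  lev <- map_od_to_level(cells$od)
  a <- lev[graph$edges[, 1L]]
  b <- lev[graph$edges[, 2L]]
  # both orders -> symmetric integer counts before normalization
  idx <- c(a * 255L + b, b * 255L + a) + 1L
  counts <- tabulate(idx, nbins = 255L * 255L)
  p <- matrix(counts / sum(counts), nrow = 255L, ncol = 255L, byrow = TRUE,
              dimnames = list(0:254, 0:254))
  marg <- rowSums(p)
  levels <- 0:254
  mu <- sum(levels * marg)
  sigma <- sqrt(sum((levels - mu)^2 * marg))
  structure(list(p = p, mu = mu, sigma = sigma,
                 n_pairs = 2L * nrow(graph$edges)),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> 255x255, %d ordered pairs, marginal mean %.2f (sd %.2f)\n",
              x$n_pairs, x$mu, x$sigma))
  invisible(x)
}

# Level-difference helpers shared by the features; D[i,j] = i - j on levels.
.level_diff2 <- function() {
  levels <- 0:254
  outer(levels, levels, function(i, j) (i - j)^2)
}

#' Co-occurrence Homogeneity
#'
#' `sum_ij p(i,j) / (1 + (i - j)^2)`: large when neighboring cells share
#' similar OD values; equals 1 iff all mass lies on the diagonal.
#' @param m A `cooc_matrix`.
#' @return Value in (0, 1].
#' @export
cooc_homogeneity <- function(m) {
  stopifnot(inherits(m, "cooc_matrix"))
  sum(m$p / (1 + .level_diff2()))
}

#' Co-occurrence Contrast
#'
#' `sum_ij (i - j)^2 p(i,j)`: increases when neighboring cells have
#' distinct OD values; 0 iff all mass lies on the diagonal.
#' @param m A `cooc_matrix`.
#' @return Value in `[0, 254^2]`.
#' @export
cooc_contrast <- function(m) {
  stopifnot(inherits(m, "cooc_matrix"))
  sum(.level_diff2() * m$p)
}

#' Co-occurrence Correlation
#'
#' `(sum_ij i j p(i,j) - mu_x mu_y) / (sigma_x sigma_y)`, the Pearson-type
#' linear dependency of neighboring-cell OD levels. Undefined (returned as
#' `NA`) when all neighboring cells share a single level (zero marginal
#' variance).
#' @param m A `cooc_matrix`.
#' @return Value in `[-1, 1]`, or `NA` when degenerate.
#' @export
cooc_correlation <- function(m) {
  stopifnot(inherits(m, "cooc_matrix"))
  if (m$sigma == 0) return(NA_real_)
  levels <- 0:254
  e_ij <- sum(outer(levels, levels) * m$p)
  (e_ij - m$mu^2) / m$sigma^2
}

#' Co-occurrence Angular Second Moment
#'
#' `sum_ij p(i,j)^2`, a measure of the general uniformity of OD values;
#' equals 1 iff all mass sits in a single entry.
#' @param m A `cooc_matrix`.
#' @return Value in (0, 1].
#' @export
cooc_asm <- function(m) {
  stopifnot(inherits(m, "cooc_matrix"))
  sum(m$p^2)
}

#' The co-occurrence score battery
#'
#' For each neighborhood radius, builds the cell graph and co-occurrence
#' matrix and computes the four texture features (Homogeneity, Contrast,
#' Correlation, Angular second moment), yielding 16 named scores at the
#' default radii. Radii with no edges yield missing values with a warning;
#' a degenerate Correlation (single shared level) is returned as `NA`.
#'
#' @param cells A [cell_table()].
#' @param radii Neighborhood radii in µm (default `c(10, 25, 50, 75)`).
#' @return Named numeric vector, e.g. `homogeneity_r10 ... asm_r75`.
#' @export
cooccurrence_scores <- function(cells, radii = c(10, 25, 50, 75)) {
  stopifnot(inherits(cells, "cell_table"))
  out <- numeric(0)
  for (r in radii) {
    g <- build_graph(cells, r)
    if (nrow(g$edges) == 0L) {
      warning(sprintf("no edges at radius %g µm; co-occurrence scores missing", r))
      vals <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      m <- build_cooccurrence(cells, g)
      vals <- c(cooc_homogeneity(m), cooc_contrast(m),
                cooc_correlation(m), cooc_asm(m))
    }
    names(vals) <- paste0(c("homogeneity", "contrast", "correlation", "asm"),
                          "_r", r)
    out <- c(out, vals)
  }
  out
}

#' Export a co-occurrence matrix in sparse triplet form
#' @param m A `cooc_matrix`.
#' @param path Output CSV path (columns level_i, level_j, p).
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(m, path) {
  nz <- which(m$p > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(level_i = nz[, 1L] - 1L,
                              level_j = nz[, 2L] - 1L,
                              p = m$p[nz]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
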