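# Independent brute-force oracles used across the suite. These stay
# deliberately naive: correctness over speed, and no shared code with the
# implementation paths they check.

# All-pairs distance-threshold edge list (i < j), closed ball.
bf_edges <- function(x, y, r) {
  n <- length(x)
  out <- NULL
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= r^2)
        out <- rbind(out, c(i, j))
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

edge_key <- function(e) sort(paste(e[, 1L], e[, 2L]))

# Brute-force symmetric co-occurrence histogram from an edge list.
bf_cooc_matrix <- function(levels, edges) {
  p <- matrix(0, 255L, 255L)
  for (k in seq_len(nrow(edges))) {
    a <- levels[edges[k, 1L]] + 1L
    b <- levels[edges[k, 2L]] + 1L
    p[a, b] <- p[a, b] + 1
    p[b, a] <- p[b, a] + 1
  }
  p / sum(p)
}

# Direct double-loop evaluation of the four co-occurrence features.
bf_features <- function(p) {
  hom <- 0; con <- 0; asm <- 0; eij <- 0
  mx <- 0
  for (i in 0:254) for (j in 0:254) {
    pij <- p[i + 1L, j + 1L]
    hom <- hom + pij / (1 + (i - j)^2)
    con <- con + (i - j)^2 * pij
    asm <- asm + pij^2
    eij <- eij + i * j * pij
    mx <- mx + i * pij
  }
  sx2 <- 0
  for (i in 0:254) for (j in 0:254) sx2 <- sx2 + (i - mx)^2 * p[i + 1L, j + 1L]
  corr <- if (sx2 == 0) NA_real_ else (eij - mx^2) / sx2
  list(homogeneity = hom, contrast = con, asm = asm, correlation = corr)
}

# Build a cooc_matrix object directly from sparse (level_i, level_j, mass)
# triplets; marginals computed from scratch.
make_cooc <- function(i, j, mass) {
  p <- matrix(0, 255L, 255L)
  for (k in seq_along(i)) p[i[k] + 1L, j[k] + 1L] <- mass[k]
  stopifnot(abs(sum(p) - 1) < 1e-12)
  marg <- rowSums(p)
  lv <- 0:254
  mu <- sum(lv * marg)
  structure(list(p = p, mu = mu,
                 sigma = sqrt(sum((lv - mu)^2 * marg)),
                 n_pairs = NA_integer_),
            class = "cooc_matrix")
}

# Floor-division tile assignment (no boundary folding; callers avoid
# exact-boundary points).
bf_tile_keys <- function(x, y, x0, y0, s, dx = 0, dy = 0) {
  paste(floor((y - y0 - dy) / s), floor((x - x0 - dx) / s))
}

# Convex hull area by the one-sided-line test: a directed pair (i, j) is a
# hull edge iff every point lies on or left of the line i -> j.
bf_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  verts <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cross <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
             (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cross >= -1e-9)) { verts[i] <- TRUE; verts[j] <- TRUE }
  }
  hx <- pts[verts, 1]; hy <- pts[verts, 2]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]; hy <- hy[o]
  nxt <- c(seq_along(hx)[-1L], 1L)
  abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
}

# Small deterministic cell tables.
toy_cells <- function(od = c(10, 20, 30), spacing = 10, id = "toy") {
  n <- length(od)
  cell_table(x = (seq_len(n) - 1L) * spacing, y = rep(0, n), od = od,
             sample_id = id)
}

# Cohort of synthetic survival records around a given score vector.
toy_survival <- function(score, beta = 0, seed = 1, censoring = 0.3) {
  set.seed(seed)
  sv <- simulate_survival(score, beta, censoring_rate = censoring)
  survival_table(data.frame(
    sample_id = sprintf("s%03d", seq_along(score)),
    os_time = sv$os_time, os_event = sv$os_event,
    age = rnorm(length(score), 65, 10),
    gender = factor(sample(c("F", "M"), length(score), TRUE)),
    grade = factor(sample(c("G1", "G2", "G3"), length(score), TRUE)),
    avg_expression = rnorm(length(score), 15, 3)))
}

# Score table from a samples x scores matrix.
as_score_table <- function(m, ids = sprintf("s%03d", seq_len(nrow(m)))) {
  rows <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    names(v) <- colnames(m)
    v
  })
  names(rows) <- ids
  score_table(rows)
}
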