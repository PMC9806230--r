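#' Construct a validated cell table
#'
#' A cell table holds one tissue sample's segmented tumor cells: planar
#' center coordinates in micrometers and the membrane mean optical density
#' (OD) of the marker stain on a 0--255 scale, one row per cell.
#'
#' @param x,y Numeric vectors of cell center coordinates in µm.
#' @param od Numeric vector of membrane mean OD values on `[0, 255]`.
#'   Values above 255 are clamped with a warning; negative values are an
#'   error.
#' @param sample_id Single non-empty string identifying the sample.
#' @return A data frame of class `cell_table` with columns `x`, `y`, `od`
#'   and attribute `sample_id`.
#' @examples
#' ct <- cell_table(c(0, 10, 0), c(0, 0, 10), c(10, 20, 30), "s1")
#' summarize_sample(ct)
#' @export
cell_table <- function(x, y, od, sample_id = "sample") {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a single non-empty string")
  x <- as.numeric(x); y <- as.numeric(y); od <- as.numeric(od)
  n <- length(x)
  if (n < 1L) stop("cell table must contain at least one cell")
  if (length(y) != n || length(od) != n)
    stop("x, y and od must have equal length")
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(od))
  if (length(bad))
    stop("non-finite coordinates or od in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  neg <- which(od < 0)
  if (length(neg))
    stop("negative od in rows: ", paste(utils::head(neg, 10L), collapse = ", "))
  if (any(od > 255)) {
    warning("od values above 255 clamped to 255")
    od <- pmin(od, 255)
  }
  out <- data.frame(x = x, y = y, od = od)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("cell_table", "data.frame")
  out
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> sample '%s': %d cells, od in [%.2f, %.2f]\n",
              sample_id(x), nrow(x), min(x$od), max(x$od)))
  invisible(x)
}

#' Sample identifier of a cell table
#' @param cells A `cell_table`.
#' @return The sample id string.
#' @export
sample_id <- function(cells) attr(cells, "sample_id")

#' Read a per-sample cell table from delimited text
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the required fields to
#'   file column names, e.g. `c(x = "x", y = "y", od = "od")`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param sep Field delimiter (default comma).
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, columns = c(x = "x", y = "y", od = "od"),
                            sample_id = NULL, sep = ",") {
  need <- c("x", "y", "od")
  if (!all(need %in% names(columns)))
    stop("column mapping must name x, y and od")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  xs <- suppressWarnings(as.numeric(df[[columns[["x"]]]]))
  ys <- suppressWarnings(as.numeric(df[[columns[["y"]]]]))
  ods <- suppressWarnings(as.numeric(df[[columns[["od"]]]]))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(ods) | ods < 0)
  if (length(bad))
    stop("invalid rows in ", path, " (non-numeric, NaN or negative od): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  cell_table(xs, ys, ods, sample_id = sample_id)
}

#' Write a cell table to CSV
#' @param cells A `cell_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells)[, c("x", "y", "od")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `sample_id` and `path` mapping each
#' sample to its cell-table file. Relative paths are resolved against the
#' manifest's directory.
#' @param path Manifest CSV path.
#' @return Data frame with columns `sample_id`, `path`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "path") %in% names(m)))
    stop("manifest must have columns sample_id and path")
  if (nrow(m) == 0L) stop("empty manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

# Polygon area by the shoelace formula on a convex-hull vertex cycle.
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(h) < 3L) return(0)
  hx <- pts[h, 1L]; hy <- pts[h, 2L]
  nxt <- c(seq_along(h)[-1L], 1L)
  abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
}

#' Per-sample summary statistics
#'
#' @param cells A `cell_table`.
#' @return A list with `n_cells`, `mean_od`, `sd_od` and `tissue_area`
#'   (area of the convex hull of the cell coordinates, in µm²; 0 with a
#'   `degenerate_hull` flag when fewer than 3 non-collinear cells exist).
#' @export
summarize_sample <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  area <- hull_area(cells$x, cells$y)
  degenerate <- area == 0
  if (degenerate)
    warning("degenerate convex hull (fewer than 3 non-collinear cells); area set to 0")
  list(n_cells = nrow(cells),
       mean_od = mean(cells$od),
       sd_od = stats::sd(cells$od),
       tissue_area = area,
       degenerate_hull = degenerate)
}

#' Assemble a per-sample score table
#'
#' @param rows Named list: one named numeric vector of scores per sample
#'   (names are score names; list names are sample ids).
#' @return Data frame of class `score_table`, one row per sample, with a
#'   `sample_id` column followed by score columns.
#' @export
score_table <- function(rows) {
  ids <- names(rows)
  if (is.null(ids) || anyDuplicated(ids))
    stop("rows must be a named list with unique sample ids")
  cols <- names(rows[[1L]])
  if (anyDuplicated(cols)) stop("duplicated score names")
  mat <- do.call(rbind, lapply(rows, function(r) r[cols]))
  out <- data.frame(sample_id = ids, mat, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Validate a clinical/survival table
#'
#' @param df Data frame with columns `sample_id`, `os_time` (months, > 0),
#'   `os_event` (0/1) and optionally `age`, `gender`, `grade`,
#'   `pathologist_score`, `avg_expression`.
#' @return The validated data frame with class `survival_table`.
#' @export
survival_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$os_time) | df$os_time <= 0))
    stop("os_time must be positive and finite")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  class(df) <- unique(c("survival_table", class(df)))
  df
}
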