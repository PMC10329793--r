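#' Categorical landcover grids
#'
#' A landcover grid is an integer matrix of pixel classes at a fixed
#' resolution in metres per pixel. Classes: `0` non-urban, `1` other urban
#' (urban but not under tree canopy), `2` tree canopy, `3` cloud or image
#' distortion. Coordinates are 0-based and row-major; cell indexing is
#' half-open.
#'
#' @param codes integer matrix of pixel classes (values 0-3).
#' @param res_m resolution, metres per pixel.
#' @return object of class `landcover_grid`.
#' @export
landcover_grid <- function(codes, res_m) {
  stopifnot(is.matrix(codes), res_m > 0)
  storage.mode(codes) <- "integer"
  if (anyNA(codes) || !all(codes %in% 0:3)) {
    stop("every pixel must be classified with a code in 0:3", call. = FALSE)
  }
  structure(list(codes = codes, res_m = res_m), class = "landcover_grid")
}

LANDCOVER_LEVELS <- c("non_urban", "other_urban", "canopy", "cloud")

#' @export
print.landcover_grid <- function(x, ...) {
  cat("landcover_grid:", nrow(x$codes), "x", ncol(x$codes), "px at",
      x$res_m, "m/px\n")
  print(round(prop.table(table(factor(LANDCOVER_LEVELS[x$codes + 1L],
                                      levels = LANDCOVER_LEVELS))), 3))
  invisible(x)
}

#' Read / write a landcover grid as plain text
#'
#' The text format is a whitespace-separated integer matrix, optionally
#' preceded by a `# res_m: <metres>` header line. `res_m` given as an
#' argument overrides the header.
#'
#' @param path file path.
#' @param res_m resolution in metres per pixel (required if no header).
#' @return [read_landcover_grid()] returns a `landcover_grid`.
#' @export
read_landcover_grid <- function(path, res_m = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  res_line <- grep("res_m:", hdr, value = TRUE)
  if (is.null(res_m)) {
    if (!length(res_line)) stop("no resolution header and no res_m given",
                                call. = FALSE)
    res_m <- as.numeric(sub(".*res_m:\\s*", "", res_line[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.integer)
  if (length(unique(lengths(rows))) != 1L) {
    stop("ragged grid: rows differ in length", call. = FALSE)
  }
  landcover_grid(do.call(rbind, rows), res_m)
}

#' @rdname read_landcover_grid
#' @param grid a `landcover_grid`.
#' @export
write_landcover_grid <- function(grid, path) {
  stopifnot(inherits(grid, "landcover_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# res_m: %g", grid$res_m), con)
  utils::write.table(grid$codes, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select sample cells from a landcover grid
#'
#' Overlays a square cell grid (default 1 km) on the landcover raster,
#' draws a simple random sample of cells at the given sampling rate
#' (without replacement), and applies the urban-content quality rule: any
#' selected cell with 25% or less of its classified area urban (canopy plus
#' other urban, against non-urban) is discarded. Partial cells at the
#' raster margin are not sampled.
#'
#' @param grid a [landcover_grid()].
#' @param cell_size_km cell edge, km.
#' @param sampling_rate fraction of cells to select, in (0, 1].
#' @param seed integer seed for reproducible selection.
#' @param min_urban_frac discard threshold: cells with urban fraction less
#'   than or equal to this are dropped.
#' @return data frame of retained cells: `cell_row`, `cell_col` (0-based),
#'   `row0`, `col0`, `px` (pixel offsets and edge length), `urban_frac`;
#'   attributes `n_cells`, `n_selected`, `n_discarded`.
#' @export
select_cells <- function(grid, cell_size_km = 1, sampling_rate = 0.25,
                         seed = NULL, min_urban_frac = 0.25) {
  stopifnot(inherits(grid, "landcover_grid"),
            sampling_rate > 0, sampling_rate <= 1)
  px <- as.integer(round(cell_size_km * 1000 / grid$res_m))
  ncr <- nrow(grid$codes) %/% px
  ncc <- ncol(grid$codes) %/% px
  n_cells <- ncr * ncc
  if (n_cells < 1L) stop("grid smaller than one sample cell", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_sel <- max(1L, as.integer(round(sampling_rate * n_cells)))
  picked <- sort(sample.int(n_cells, n_sel))
  cell_row <- (picked - 1L) %/% ncc
  cell_col <- (picked - 1L) %% ncc
  urban_frac <- vapply(seq_along(picked), function(k) {
    block <- grid$codes[cell_row[k] * px + seq_len(px),
                        cell_col[k] * px + seq_len(px)]
    n_urban <- sum(block == 1L | block == 2L)
    n_classified <- n_urban + sum(block == 0L)  # clouds excluded
    if (n_classified == 0L) return(NaN)
    n_urban / n_classified
  }, numeric(1))
  keep <- !is.nan(urban_frac) & urban_frac > min_urban_frac
  out <- data.frame(cell_row = cell_row[keep], cell_col = cell_col[keep],
                    row0 = cell_row[keep] * px, col0 = cell_col[keep] * px,
                    px = rep.int(px, sum(keep)), urban_frac = urban_frac[keep])
  attr(out, "n_cells") <- n_cells
  attr(out, "n_selected") <- n_sel
  attr(out, "n_discarded") <- n_sel - nrow(out)
  out
}

# factor pair (rows x cols) closest to square, rows <= cols
lattice_shape <- function(n) {
  r <- max(Filter(function(d) n %% d == 0L, seq_len(floor(sqrt(n)))))
  c(r, n %/% r)
}

#' Place evenly spaced sample points in a cell
#'
#' Points sit on a regular rows-by-columns lattice, the factorization of
#' `n_points` closest to square (55 points give 5 x 11), centred in the
#' cell with half-spacing margins. Deterministic given the cell.
#'
#' @param cell one row of a [select_cells()] result.
#' @param n_points points per cell (default 55, the survey design density
#'   per square kilometre).
#' @return data frame of point positions `x`, `y` in pixel coordinates
#'   (fractional, 0-based) plus the originating cell indices.
#' @export
place_points <- function(cell, n_points = 55) {
  stopifnot(n_points >= 1)
  rc <- lattice_shape(n_points)
  ri <- rep(seq_len(rc[1]), each = rc[2])
  ci <- rep(seq_len(rc[2]), times = rc[1])
  data.frame(
    cell_row = cell$cell_row, cell_col = cell$cell_col,
    y = cell$row0 + (ri - 0.5) / rc[1] * cell$px,
    x = cell$col0 + (ci - 0.5) / rc[2] * cell$px
  )
}

#' Classify sample points against the landcover grid
#'
#' Each point takes the class of the pixel containing it. Points that fall
#' on cloud or image distortion are marked discarded (the survey's
#' quality-control removal); all other points are retained.
#'
#' @param grid a [landcover_grid()].
#' @param points data frame from [place_points()].
#' @return `points` with `label`, `discarded`, `reason` columns.
#' @export
classify_points <- function(grid, points) {
  pr <- floor(points$y) + 1L
  pc <- floor(points$x) + 1L
  code <- grid$codes[cbind(pr, pc)]
  points$label <- LANDCOVER_LEVELS[code + 1L]
  points$discarded <- points$label == "cloud"
  points$reason <- ifelse(points$discarded, "cloud_or_distortion", NA_character_)
  points
}

#' Estimate canopy cover from classified points
#'
#' The estimate is the share of retained (non-discarded) points classified
#' as canopy. Two standard errors are reported: the binomial SE
#' `sqrt(p(1-p)/n)`, which treats points as independent draws, and a
#' cluster-level SE from the spread of per-cell canopy means, which
#' respects the within-cell spatial clustering of the design. When every
#' point has been discarded the result is no-data (`NA`), never zero.
#'
#' @param points classified points ([classify_points()]).
#' @return list with `estimate`, `se` (binomial), `se_cluster`, `n_used`,
#'   `n_discarded`, `n_cells`.
#' @examples
#' g <- generate_raster(0.3, extent = c(100, 100), res_m = 10, seed = 1)
#' cells <- select_cells(g, cell_size_km = 0.5, sampling_rate = 1, seed = 1)
#' pts <- classify_points(g, do.call(rbind, lapply(split(cells, seq_len(nrow(cells))), place_points)))
#' estimate_canopy(pts)
#' @export
estimate_canopy <- function(points) {
  kept <- points[!points$discarded, , drop = FALSE]
  n <- nrow(kept)
  if (n == 0L) {
    return(list(estimate = NA_real_, se = NA_real_, se_cluster = NA_real_,
                n_used = 0L, n_discarded = sum(points$discarded),
                n_cells = 0L))
  }
  p <- mean(kept$label == "canopy")
  cell_id <- interaction(kept$cell_row, kept$cell_col, drop = TRUE)
  cell_means <- tapply(kept$label == "canopy", cell_id, mean)
  k <- length(cell_means)
  list(
    estimate = p,
    se = sqrt(p * (1 - p) / n),
    se_cluster = if (k > 1) stats::sd(cell_means) / sqrt(k) else NA_real_,
    n_used = n,
    n_discarded = sum(points$discarded),
    n_cells = k
  )
}

#' End-to-end point-grid canopy survey
#'
#' Runs the full survey design on a landcover grid: cell selection at the
#' sampling rate, the urban-content discard rule, point placement, cloud
#' removal, and estimation.
#'
#' @inheritParams select_cells
#' @param n_points points per cell.
#' @return the [estimate_canopy()] list, plus `cells` and `points`.
#' @export
canopy_survey <- function(grid, cell_size_km = 1, sampling_rate = 0.25,
                          n_points = 55, seed = NULL) {
  cells <- select_cells(grid, cell_size_km, sampling_rate, seed)
  if (nrow(cells) == 0L) {
    return(list(estimate = NA_real_, se = NA_real_, se_cluster = NA_real_,
                n_used = 0L, n_discarded = 0L, n_cells = 0L,
                cells = cells, points = NULL))
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    place_points(cells[i, , drop = FALSE], n_points)
  }))
  pts <- classify_points(grid, pts)
  out <- estimate_canopy(pts)
  out$cells <- cells
  out$points <- pts
  out
}
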