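#' Point cloud container
#'
#' A light container for n sensor-space points with optional per-point
#' intensity and grid indices (row/col of the range-camera pixel each point
#' came from).  Most functions also accept a bare n x 3 matrix.
#'
#' @param xyz n x 3 numeric matrix (x, y, z in meters) or a data frame with
#'   three numeric columns.
#' @param intensity Optional numeric vector of length n (non-negative).
#' @param grid Optional n x 2 integer matrix of (row, col) pixel indices.
#' @return An object of class `egg_cloud`.
#' @export
egg_cloud <- function(xyz, intensity = NULL, grid = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(ncol(xyz) == 3L)
  colnames(xyz) <- c("x", "y", "z")
  if (!is.null(intensity)) {
    stopifnot(length(intensity) == nrow(xyz), all(intensity >= 0))
  }
  if (!is.null(grid)) {
    grid <- as.matrix(grid)
    stopifnot(nrow(grid) == nrow(xyz), ncol(grid) == 2L)
  }
  structure(list(xyz = xyz, intensity = intensity, grid = grid),
            class = "egg_cloud")
}

#' @export
print.egg_cloud <- function(x, ...) {
  cat(sprintf("<egg_cloud> %d points%s%s\n", nrow(x$xyz),
              if (!is.null(x$intensity)) ", with intensity" else "",
              if (!is.null(x$grid)) ", gridded" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud An [egg_cloud()] or n x 3 matrix.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud_xyz(cloud))

# Coerce cloud-like input to a plain n x 3 double matrix.
cloud_xyz <- function(cloud) {
  if (inherits(cloud, "egg_cloud")) return(cloud$xyz)
  m <- as.matrix(cloud)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 3L)
  m
}

# Subset a cloud by a logical or integer index, preserving side columns.
cloud_subset <- function(cloud, idx) {
  if (!inherits(cloud, "egg_cloud")) return(cloud_xyz(cloud)[idx, , drop = FALSE])
  egg_cloud(cloud$xyz[idx, , drop = FALSE],
            intensity = if (!is.null(cloud$intensity)) cloud$intensity[idx],
            grid = if (!is.null(cloud$grid)) cloud$grid[idx, , drop = FALSE])
}
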