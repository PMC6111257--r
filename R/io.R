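# File I/O: whitespace-delimited .xyz point clouds, PNG intensity images,
# and JSON/CSV result records.

#' Read a .xyz point cloud
#'
#' Parses whitespace-delimited lines of 3 or 4 numeric fields
#' (`x y z [intensity]`, meters).  Blank lines and `#` comments are
#' skipped.  A malformed line raises an error naming its line number.
#'
#' @param path File path.
#' @return An [egg_cloud()]; the source line number of each point is kept
#'   as attribute `"line"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no data lines in ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  bad <- which(!(nf %in% c(3L, 4L)))
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected 3 or 4 fields, got %d",
                 keep[bad[1]], path, nf[bad[1]]))
  }
  if (length(unique(nf)) > 1L) {
    odd <- which(nf != nf[1])[1]
    stop(sprintf("malformed line %d in %s: %d fields where earlier lines have %d",
                 keep[odd], path, nf[odd], nf[1]))
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  badnum <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(badnum)) {
    stop(sprintf("malformed line %d in %s: non-numeric field",
                 keep[badnum[1]], path))
  }
  m <- do.call(rbind, vals)
  cl <- egg_cloud(m[, 1:3, drop = FALSE],
                  intensity = if (ncol(m) == 4L) m[, 4] else NULL)
  attr(cl, "line") <- keep
  cl
}

#' Write a .xyz point cloud
#'
#' One point per line, `x y z [intensity]`, full double precision.
#'
#' @param cloud An [egg_cloud()] or n x 3 matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  xyz <- cloud_xyz(cloud)
  intensity <- if (inherits(cloud, "egg_cloud")) cloud$intensity
  lines <- if (is.null(intensity)) {
    sprintf("%.9f %.9f %.9f", xyz[, 1], xyz[, 2], xyz[, 3])
  } else {
    sprintf("%.9f %.9f %.9f %g", xyz[, 1], xyz[, 2], xyz[, 3], intensity)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-channel PNG intensity image
#'
#' @param path PNG file path (8- or 16-bit, single channel; the first
#'   channel is used if more are present).
#' @param bit_depth Bit depth used to rescale to integer gray levels.
#' @return Integer matrix of intensities.
#' @export
read_intensity_png <- function(path, bit_depth = 8L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * (2^bit_depth - 1))), nrow(img), ncol(img))
}

#' Write an intensity image as PNG
#'
#' Written at 8 bits per pixel (the writer does not support 16-bit
#' output; [read_intensity_png()] reads both depths).
#'
#' @param intensity Integer matrix of gray levels in 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_png <- function(intensity, path) {
  stopifnot(all(intensity >= 0), all(intensity <= 255))
  png::writePNG(intensity / 255, path)
  invisible(path)
}

# Flat named list describing a fit, in reporting units (cm, mL, degrees).
result_record <- function(fit) {
  rec <- list(
    tool = "eggfit",
    version = as.character(utils::packageVersion("eggfit")),
    model = fit$variant$axis,
    with_shear = isTRUE(fit$variant$with_shear),
    converged = isTRUE(fit$converged),
    iterations = fit$iterations,
    n_points = fit$n,
    sse = fit$sse,
    dof = fit$dof)
  if (isTRUE(fit$converged)) {
    rec$a_cm <- fit$shape$a * 100
    rec$b_cm <- fit$shape$b * 100
    rec$tip_m <- c(fit$pose$xc, fit$pose$yc, fit$pose$zc)
    rec$omega_deg <- fit$pose$omega * 180 / pi
    rec$psi_deg <- fit$pose$psi * 180 / pi
    rec$phi_deg <- fit$pose$phi * 180 / pi
    if (!is.null(fit$shear)) {
      rec$sh_x <- fit$shear$sh_x
      rec$sh_y <- fit$shear$sh_y
    }
    vol <- if (is.null(fit$volume)) fit_volume(fit) else fit$volume
    rec$volume_ml <- vol$V * 1e6
    rec$sigma_volume_ml <- vol$sigma_V * 1e6
  } else {
    rec$note <- fit$note
  }
  rec
}

#' Write a fit result to JSON
#'
#' Reporting units: shape in cm, angles in degrees, tip in meters, volume
#' in mL.  An unconverged fit is written with `converged = false` and no
#' volume fields.  Numbers are stored at full precision so a read-back
#' reproduces them exactly.
#'
#' @param fit An `egg_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result <- function(fit, path) {
  jsonlite::write_json(result_record(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a batch of fit results to CSV
#'
#' One row per fit, scalar fields only (tip coordinates expanded).
#'
#' @param fits List of `egg_fit` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    rec <- result_record(f)
    tip <- rec$tip_m
    rec$tip_m <- NULL
    if (!is.null(tip)) {
      rec$xc_m <- tip[1]; rec$yc_m <- tip[2]; rec$zc_m <- tip[3]
    }
    rec
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    r[miss] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
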