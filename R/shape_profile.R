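#' Station-wise digitized shape of a fish body or swimbladder
#'
#' A `shape_profile` stores the digitized outline of a structure (fish body
#' or swimbladder) as stations along the snout-to-tail axis. At each axial
#' position `u` (mm) it records the upper and lower sagittal boundaries
#' `z_upper`, `z_lower` (mm, lateral radiograph) and the dorsal-view width
#' `w` (mm). `u` increases snout to tail and `z` increases ventral to
#' dorsal; all geometry is kept in millimetres (conversion to metres
#' happens only inside the scattering engine).
#'
#' @param u Axial station positions (mm), strictly increasing.
#' @param z_upper Upper sagittal boundary (mm) at each station.
#' @param z_lower Lower sagittal boundary (mm) at each station.
#' @param w Dorsal-view width (mm) at each station, non-negative.
#'
#' @return An object of class `shape_profile`: a data frame with columns
#'   `u`, `z_upper`, `z_lower`, `w` and attribute `du` (the common station
#'   spacing in mm, or `NA` if the spacing is non-uniform).
#' @examples
#' p <- shape_profile(u = 0:10, z_upper = rep(2, 11),
#'                    z_lower = rep(-2, 11), w = rep(3, 11))
#' attr(p, "du")
#' @export
shape_profile <- function(u, z_upper, z_lower, w) {
  n <- length(u)
  if (n < 2) stop("invalid shape: a profile needs at least 2 stations", call. = FALSE)
  if (length(z_upper) != n || length(z_lower) != n || length(w) != n) {
    stop("u, z_upper, z_lower and w must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(u, z_upper, z_lower, w)))) {
    stop("invalid shape: non-finite coordinates", call. = FALSE)
  }
  if (any(diff(u) <= 0)) {
    stop("invalid shape: u must be strictly increasing", call. = FALSE)
  }
  if (any(z_upper < z_lower - 1e-9)) {
    stop("invalid shape: z_upper must be >= z_lower at every station", call. = FALSE)
  }
  if (any(w < 0)) stop("invalid shape: widths must be non-negative", call. = FALSE)
  out <- data.frame(u = as.numeric(u), z_upper = as.numeric(z_upper),
                    z_lower = as.numeric(z_lower), w = as.numeric(w))
  attr(out, "du") <- profile_spacing(out$u)
  class(out) <- c("shape_profile", "data.frame")
  out
}

# Common spacing if uniform to 1e-9 mm, else NA.
profile_spacing <- function(u) {
  d <- diff(u)
  if (max(d) - min(d) <= 1e-9) mean(d) else NA_real_
}

#' @export
print.shape_profile <- function(x, ...) {
  du <- attr(x, "du")
  cat(sprintf("<shape_profile> %d stations, u in [%.2f, %.2f] mm, spacing %s\n",
              nrow(x), min(x$u), max(x$u),
              if (is.na(du)) "non-uniform" else sprintf("%.4g mm", du)))
  invisible(x)
}

#' Resample a shape profile to uniform station spacing
#'
#' Linearly interpolates the three boundary curves onto a uniform axial
#' grid of spacing `du` spanning the original extent. Both endpoints are
#' preserved; when the extent is not an exact multiple of `du` the last
#' interval is shortened so the posterior endpoint is kept. Digitization
#' workflows typically record coarse stations (10 mm body / 5 mm bladder)
#' and resample to 1 mm before scattering computations.
#'
#' @param profile A [shape_profile()].
#' @param du Target station spacing in mm (> 0).
#' @return A `shape_profile` with uniform spacing (the terminal interval
#'   may be shorter to preserve the posterior endpoint).
#' @examples
#' p <- shape_profile(u = c(0, 10), z_upper = c(0, 10),
#'                    z_lower = c(-1, -1), w = c(1, 1))
#' resample_profile(p, 1)
#' @export
resample_profile <- function(profile, du) {
  stopifnot(inherits(profile, "shape_profile"))
  if (!is.numeric(du) || length(du) != 1 || !is.finite(du) || du <= 0) {
    stop("du must be a single positive number", call. = FALSE)
  }
  u0 <- min(profile$u)
  u1 <- max(profile$u)
  u_new <- seq(u0, u1, by = du)
  if (u1 - u_new[length(u_new)] > 1e-9) u_new <- c(u_new, u1)
  interp <- function(y) stats::approx(profile$u, y, xout = u_new)$y
  shape_profile(u_new, interp(profile$z_upper), interp(profile$z_lower),
                interp(profile$w))
}

#' Translate a shape profile
#'
#' Rigid translation along the axial (`du_mm`) and dorso-ventral (`dz_mm`)
#' directions. Morphometric areas and volumes are invariant under
#' translation.
#'
#' @param profile A [shape_profile()].
#' @param du_mm,dz_mm Offsets in mm.
#' @return A translated `shape_profile`.
#' @export
translate_profile <- function(profile, du_mm = 0, dz_mm = 0) {
  stopifnot(inherits(profile, "shape_profile"))
  shape_profile(profile$u + du_mm, profile$z_upper + dz_mm,
                profile$z_lower + dz_mm, profile$w)
}

#' Read and write shape station tables
#'
#' The on-disk dialect is delimited text with one row per station and
#' columns `u_mm`, `z_upper_mm`, `z_lower_mm`, `w_mm`. `write_shape()`
#' emits tab-separated values with exactly this header;  `read_shape()`
#' accepts comma- or tab-separated files.
#'
#' @param path File path.
#' @param profile A [shape_profile()] (for the writer).
#' @return `read_shape()` returns a `shape_profile`; `write_shape()`
#'   returns `path` invisibly.
#' @export
read_shape <- function(path) {
  if (!file.exists(path)) stop("shape file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           strip.white = TRUE, stringsAsFactors = FALSE)
  need <- c("u_mm", "z_upper_mm", "z_lower_mm", "w_mm")
  if (!all(need %in% names(tab))) {
    stop("malformed shape file ", path, ": expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(tab[need]) |
                 !apply(tab[need], 1L, function(r) all(is.finite(as.numeric(r)))))
  if (length(bad)) {
    stop("malformed shape file ", path, ": non-numeric or missing value at row ",
         bad[1], call. = FALSE)
  }
  shape_profile(tab$u_mm, tab$z_upper_mm, tab$z_lower_mm, tab$w_mm)
}

#' @rdname read_shape
#' @export
write_shape <- function(profile, path) {
  stopifnot(inherits(profile, "shape_profile"))
  tab <- data.frame(u_mm = profile$u, z_upper_mm = profile$z_upper,
                    z_lower_mm = profile$z_lower, w_mm = profile$w)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
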