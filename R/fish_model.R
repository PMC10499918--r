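#' A digitized fish: body and (optional) swimbladder profiles
#'
#' Couples the digitized body outline with the swimbladder outline and the
#' specimen metadata. Specimens whose swimbladder was deflated at
#' radiography carry `bladder = NULL`; they are kept for morphometric
#' bookkeeping but are excluded from acoustic computations, which raise a
#' deflated-specimen error.
#'
#' @param species Species label (character scalar).
#' @param TL_cm Total length in cm (> 0). This is the length `L` of the
#'   TS-length regressions.
#' @param body A [shape_profile()] for the fish body.
#' @param bladder A [shape_profile()] for the swimbladder, or `NULL` for a
#'   deflated specimen.
#' @param note Free-text provenance note.
#' @return An object of class `fish_model`.
#' @export
fish_model <- function(species, TL_cm, body, bladder = NULL, note = "") {
  stopifnot(inherits(body, "shape_profile"))
  if (!is.numeric(TL_cm) || length(TL_cm) != 1 || !is.finite(TL_cm) || TL_cm <= 0) {
    stop("TL_cm must be a single positive number", call. = FALSE)
  }
  if (!is.null(bladder)) {
    stopifnot(inherits(bladder, "shape_profile"))
    if (min(bladder$u) < min(body$u) - 1e-6 ||
        max(bladder$u) > max(body$u) + 1e-6) {
      stop("geometry error: bladder extends beyond the body's axial extent",
           call. = FALSE)
    }
  }
  structure(list(species = as.character(species)[1], TL_cm = TL_cm,
                 body = body, bladder = bladder, note = as.character(note)[1]),
            class = "fish_model")
}

#' @export
print.fish_model <- function(x, ...) {
  cat(sprintf("<fish_model> %s, TL = %.1f cm, body %d stations, %s\n",
              x$species, x$TL_cm, nrow(x$body),
              if (is.null(x$bladder)) "swimbladder DEFLATED"
              else sprintf("bladder %d stations", nrow(x$bladder))))
  invisible(x)
}

#' Has the fish an inflated swimbladder?
#' @param fish A [fish_model()].
#' @return Logical scalar.
#' @export
has_bladder <- function(fish) !is.null(fish$bladder)

#' Ellipsoid volume from the three swimbladder dimensions
#'
#' \deqn{V = \frac{4\pi}{3}\,\frac{sbl}{2}\,\frac{sbh}{2}\,\frac{sbw}{2}}
#'
#' @param sbl,sbh,sbw Swimbladder length, maximum height and maximum width
#'   in mm (>= 0).
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(2, 2, 2)  # unit-radius sphere, 4*pi/3
#' @export
ellipsoid_volume <- function(sbl, sbh, sbw) {
  if (any(c(sbl, sbh, sbw) < 0)) {
    stop("swimbladder dimensions must be non-negative", call. = FALSE)
  }
  (4 * pi / 3) * (sbl / 2) * (sbh / 2) * (sbw / 2)
}

# Signed inclination (deg) of the line joining the anterior and posterior
# midline points of a profile, positive when the anterior end is higher.
profile_midline_angle <- function(profile) {
  n <- nrow(profile)
  z_ant <- (profile$z_upper[1] + profile$z_lower[1]) / 2
  z_post <- (profile$z_upper[n] + profile$z_lower[n]) / 2
  atan2(z_ant - z_post, profile$u[n] - profile$u[1]) * 180 / pi
}

#' Swimbladder morphometrics from a digitized fish
#'
#' Measures the six quantities used throughout swimbladder morphometry:
#' * `sbl` - swimbladder length, the axial distance between the anterior
#'   and posterior margins (mm);
#' * `sbh` - maximum thickness in the lateral aspect,
#'   \eqn{\max(z_{upper} - z_{lower})} (mm);
#' * `sbw` - maximum thickness in the dorsal aspect, \eqn{\max(w)} (mm);
#' * `sb_theta` - inclination of the bladder axis to the body centreline
#'   (degrees, positive when the anterior end sits higher), measured
#'   between the line through the body's anterior/posterior mid-height
#'   points and the line through the bladder's anterior/posterior midline
#'   points;
#' * `dorsal_area` - area of the traced dorsal surface,
#'   \eqn{\int w(u)\,du} by the trapezoid rule (mm^2);
#' * `volume` - the ellipsoid volume of the three dimensions via
#'   [ellipsoid_volume()] (mm^3).
#'
#' @param fish A [fish_model()] with an inflated swimbladder.
#' @return A one-row data frame of class `morphometrics` with columns
#'   `species`, `TL_cm`, `sbl`, `sbh`, `sbw`, `sb_theta`, `dorsal_area`,
#'   `volume`.
#' @export
measure_morphometrics <- function(fish) {
  stopifnot(inherits(fish, "fish_model"))
  if (!has_bladder(fish)) {
    stop("deflated specimen: no inflated swimbladder to measure (excluded ",
         "from analysis)", call. = FALSE)
  }
  b <- fish$bladder
  sbl <- max(b$u) - min(b$u)
  sbh <- max(b$z_upper - b$z_lower)
  sbw <- max(b$w)
  n <- nrow(b)
  dorsal_area <- sum(diff(b$u) * (b$w[-1] + b$w[-n]) / 2)
  sb_theta <- profile_midline_angle(b) - profile_midline_angle(fish$body)
  out <- data.frame(species = fish$species, TL_cm = fish$TL_cm,
                    sbl = sbl, sbh = sbh, sbw = sbw, sb_theta = sb_theta,
                    dorsal_area = dorsal_area,
                    volume = ellipsoid_volume(sbl, sbh, sbw))
  class(out) <- c("morphometrics", "data.frame")
  out
}

#' Write and read a fish (shape files plus a JSON metadata record)
#'
#' `write_fish()` writes `<stem>_body.tsv`, `<stem>_bladder.tsv` (when
#' inflated) and `<stem>_meta.json` (species, TL_cm, note, deflated flag).
#' `read_fish()` reads them back.
#'
#' @param fish A [fish_model()].
#' @param stem Path stem (directory plus file prefix).
#' @return `read_fish()` returns a `fish_model`; `write_fish()` returns
#'   `stem` invisibly.
#' @export
write_fish <- function(fish, stem) {
  stopifnot(inherits(fish, "fish_model"))
  write_shape(fish$body, paste0(stem, "_body.tsv"))
  if (has_bladder(fish)) write_shape(fish$bladder, paste0(stem, "_bladder.tsv"))
  meta <- list(species = fish$species, TL_cm = fish$TL_cm, note = fish$note,
               deflated = !has_bladder(fish))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_fish
#' @export
read_fish <- function(stem) {
  meta_path <- paste0(stem, "_meta.json")
  if (!file.exists(meta_path)) stop("fish metadata not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  body <- read_shape(paste0(stem, "_body.tsv"))
  bladder <- if (isTRUE(meta$deflated)) NULL else read_shape(paste0(stem, "_bladder.tsv"))
  fish_model(meta$species, meta$TL_cm, body, bladder,
             note = if (is.null(meta$note)) "" else meta$note)
}
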