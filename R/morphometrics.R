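#' Morphometric estimators
#'
#' Rediae are treated as cylinders (length x width) and their pharynges as
#' spheres (diameter), giving simple volume estimates from two-dimensional
#' photo measurements. The relative pharynx size (pharynx volume / body
#' volume) is the key caste morphometric: soldier-like small rediae carry
#' disproportionately large mouthparts. The standard linear size (SLS) is
#' the cube root of body volume, a linearized size measure.
#'
#' All functions are vectorized and propagate `NA` (a missing measurement
#' stays missing); nonpositive measurements are domain errors.
#'
#' @param length_um body length in micrometres (positive).
#' @param width_um body width at the widest point in micrometres (positive).
#' @return `body_volume()`: cylinder volume pi * (width/2)^2 * length in
#'   cubic micrometres.
#' @examples
#' body_volume(100, 20)           # 31415.93
#' pharynx_volume(10)             # 523.60
#' relative_pharynx(523.6, 31415.93)
#' standard_linear_size(27)       # 3
#' @export
body_volume <- function(length_um, width_um) {
  check_positive(length_um, "length_um")
  check_positive(width_um, "width_um")
  pi * (width_um / 2)^2 * length_um
}

#' @rdname body_volume
#' @param pharynx_um pharynx diameter (longest dimension) in micrometres.
#' @export
pharynx_volume <- function(pharynx_um) {
  check_positive(pharynx_um, "pharynx_um")
  (4 / 3) * pi * (pharynx_um / 2)^3
}

#' @rdname body_volume
#' @param pharynx_volume_um3 pharynx volume in cubic micrometres.
#' @param body_volume_um3 body volume in cubic micrometres (positive).
#' @return `relative_pharynx()`: dimensionless ratio, with attribute
#'   `implausible` marking ratios above 1 (a pharynx cannot truly exceed
#'   its body; such values indicate a measurement problem but are kept).
#' @export
relative_pharynx <- function(pharynx_volume_um3, body_volume_um3) {
  if (any(!is.na(body_volume_um3) & body_volume_um3 <= 0)) {
    stop("body_volume_um3 must be positive")
  }
  if (any(!is.na(pharynx_volume_um3) & pharynx_volume_um3 < 0)) {
    stop("pharynx_volume_um3 must be nonnegative")
  }
  ratio <- pharynx_volume_um3 / body_volume_um3
  attr(ratio, "implausible") <- !is.na(ratio) & ratio > 1
  ratio
}

#' @rdname body_volume
#' @return `standard_linear_size()`: cube root of body volume (um).
#' @export
standard_linear_size <- function(body_volume_um3) {
  check_positive(body_volume_um3, "body_volume_um3")
  body_volume_um3^(1 / 3)
}

check_positive <- function(x, what) {
  if (any(!is.na(x) & x <= 0)) {
    stop(what, " must be positive (got ",
         x[!is.na(x) & x <= 0][1], ")")
  }
  invisible(x)
}

#' Enrich colony records with derived morphometrics
#'
#' Adds `body_volume_um3`, `sls_um`, `pharynx_volume_um3`,
#' `relative_pharynx` and `rel_pharynx_implausible` columns to a colony's
#' record table. Missing pharynx diameters yield missing pharynx-derived
#' fields; excluded records are carried through untouched but keep `NA`
#' derived values.
#'
#' @param colony a [redia_colony()].
#' @return The colony with enriched `records`.
#' @export
add_morphometrics <- function(colony) {
  stopifnot(inherits(colony, "redia_colony"))
  r <- colony$records
  usable <- !r$excluded & !is.na(r$length_um) & !is.na(r$width_um)
  r$body_volume_um3 <- NA_real_
  r$body_volume_um3[usable] <- body_volume(r$length_um[usable], r$width_um[usable])
  r$sls_um <- NA_real_
  r$sls_um[usable] <- standard_linear_size(r$body_volume_um3[usable])
  has_ph <- usable & !is.na(r$pharynx_um)
  r$pharynx_volume_um3 <- NA_real_
  r$pharynx_volume_um3[has_ph] <- pharynx_volume(r$pharynx_um[has_ph])
  rel <- rep(NA_real_, nrow(r))
  rel[has_ph] <- as.numeric(relative_pharynx(r$pharynx_volume_um3[has_ph],
                                             r$body_volume_um3[has_ph]))
  r$relative_pharynx <- rel
  r$rel_pharynx_implausible <- !is.na(rel) & rel > 1
  colony$records <- r
  colony
}
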