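#' Piecewise GFP-to-OD600 calibration
#'
#' The fluorescence calibration used to deconvolve two-species cocultures
#' in which one species carries a constitutive GFP reporter. Fluorescence
#' \code{F} maps to the reporter strain's OD600 via a two-branch curve:
#' linear below a branch threshold, and a square-root branch above it,
#' \deqn{OD = s (F + o) \; (F < \theta), \qquad
#'       OD = -a + \sqrt{a^2 - b},\; b = b_s (b_o - F) \; (F \ge \theta).}
#' The defaults are the published constants for sGFP \emph{S. aureus}
#' (s = 2.97e-5, o = 200, \eqn{\theta} = 3000, a = 0.0283, b_s = 5.20e-6,
#' b_o = 100). With these constants the curve is strictly increasing on
#' each branch and jumps by about 2.8% across the threshold, leaving a
#' small unreachable OD gap (~0.0950 to ~0.0977) that the inverse flags.
#'
#' @param linear_scale OD600 per fluorescence unit on the linear branch.
#' @param linear_offset fluorescence-unit offset of the linear branch.
#' @param branch_threshold fluorescence value where the branch switches.
#' @param a,b_scale,b_offset constants of the upper (square-root) branch.
#'
#' @return An object of class \code{"gfp_calibration"}.
#' @seealso [gfp_to_od()], [invert_gfp_calibration()]
#' @export
gfp_calibration <- function(linear_scale = 2.97e-5, linear_offset = 200,
                            branch_threshold = 3000, a = 0.0283,
                            b_scale = 5.20e-6, b_offset = 100) {
  if (linear_scale <= 0 || b_scale <= 0 || a <= 0)
    stop("'linear_scale', 'b_scale' and 'a' must be > 0")
  if (branch_threshold <= b_offset)
    stop("'branch_threshold' must exceed 'b_offset'")
  cal <- structure(list(linear_scale = linear_scale,
                        linear_offset = linear_offset,
                        branch_threshold = branch_threshold,
                        a = a, b_scale = b_scale, b_offset = b_offset),
                   class = "gfp_calibration")
  # codomain edges of the two branches (the open interval between them is
  # the calibration's unreachable gap)
  cal$od_linear_max <- linear_scale * (branch_threshold + linear_offset)
  cal$od_sqrt_min <- -a + sqrt(a^2 - b_scale * (b_offset - branch_threshold))
  if (cal$od_sqrt_min < cal$od_linear_max)
    stop("calibration branches overlap; conversion would not be invertible")
  cal
}

#' @export
print.gfp_calibration <- function(x, ...) {
  cat(sprintf(
    "GFP calibration: OD = %.3g*(F + %g) for F < %g; -a + sqrt(a^2 - b) above\n",
    x$linear_scale, x$linear_offset, x$branch_threshold))
  cat(sprintf("  a = %.4g, b = %.3g*(%g - F); unreachable OD gap [%.5f, %.5f)\n",
              x$a, x$b_scale, x$b_offset, x$od_linear_max, x$od_sqrt_min))
  invisible(x)
}

#' Convert fluorescence readings to reporter-strain OD600
#'
#' Applies the piecewise [gfp_calibration]. Blank-subtracted fluorescence
#' slightly below zero is accepted down to \code{-linear_offset} (where the
#' linear branch reaches OD 0); more negative readings are an error.
#'
#' @param F fluorescence readings (vectorized).
#' @param cal a [gfp_calibration].
#'
#' @return OD600 of the reporter strain.
#' @examples
#' gfp_to_od(c(0, 2999, 3000))  # 0.00594, 0.09501, 0.09772
#' @export
gfp_to_od <- function(F, cal = gfp_calibration()) {
  stopifnot(inherits(cal, "gfp_calibration"), is.numeric(F))
  F <- as.vector(F)
  if (any(!is.finite(F))) stop("'F' must be finite")
  if (any(F < -cal$linear_offset))
    stop(sprintf("fluorescence below -%g is outside the calibration domain",
                 cal$linear_offset))
  upper <- F >= cal$branch_threshold
  od <- cal$linear_scale * (F + cal$linear_offset)
  if (any(upper)) {
    disc <- cal$a^2 - cal$b_scale * (cal$b_offset - F[upper])
    if (any(disc < 0))
      stop("negative discriminant on the upper calibration branch")
    od[upper] <- -cal$a + sqrt(disc)
  }
  od
}

#' Invert the GFP calibration
#'
#' Exact algebraic inverse of [gfp_to_od()], branch chosen by comparing the
#' OD to the branch codomain edges. ODs inside the calibration's
#' unreachable gap are mapped to the branch threshold and flagged via the
#' \code{"gap"} attribute. ODs below \code{gfp_to_od(0)} are an error
#' unless \code{extrapolate = TRUE}, in which case the linear branch is
#' extended through blank-subtracted negative fluorescence down to OD 0
#' (needed to synthesize fluorescence for inocula below the calibration's
#' zero-fluorescence OD).
#'
#' @param od reporter-strain OD600 (vectorized), >= 0.
#' @param cal a [gfp_calibration].
#' @param extrapolate allow ODs in \code{[0, gfp_to_od(0))} by linear
#'   extrapolation to negative fluorescence.
#'
#' @return Fluorescence readings with logical attribute \code{"gap"}
#'   marking ODs that fell in the unreachable gap.
#' @examples
#' invert_gfp_calibration(0.00594)   # 0
#' gfp_to_od(invert_gfp_calibration(0.05))  # round trip
#' @export
invert_gfp_calibration <- function(od, cal = gfp_calibration(),
                                   extrapolate = FALSE) {
  stopifnot(inherits(cal, "gfp_calibration"), is.numeric(od))
  if (any(!is.finite(od)) || any(od < 0)) stop("'od' must be finite and >= 0")
  od0 <- cal$linear_scale * cal$linear_offset  # gfp_to_od(0)
  if (!extrapolate && any(od < od0))
    stop(sprintf("OD below gfp_to_od(0) = %.5g is outside the calibration range; %s",
                 od0, "use extrapolate = TRUE to extend the linear branch"))
  F <- od / cal$linear_scale - cal$linear_offset
  gap <- od >= cal$od_linear_max & od < cal$od_sqrt_min
  F[gap] <- cal$branch_threshold
  upper <- od >= cal$od_sqrt_min
  if (any(upper))
    F[upper] <- cal$b_offset -
      (cal$a^2 - (od[upper] + cal$a)^2) / cal$b_scale
  structure(F, gap = gap)
}
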