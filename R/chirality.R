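#' Section line across an AFM image
#'
#' @param p1,p2 endpoints, numeric (x, y) in nm.
#' @param role `"AB"` or `"CD"`.  By convention the lines are chosen so
#'   that the bundle along A-B lies underneath the other when the helix is
#'   right-handed, and the bundle along C-D lies underneath when it is
#'   left-handed.
#' @param n number of samples along the line, >= 10.
#' @return an object of class `section_line`.
#' @export
section_line <- function(p1, p2, role = c("AB", "CD"), n = 100) {
  role <- match.arg(role)
  if (all(p1 == p2)) stop("endpoints must be distinct")
  if (n < 10) stop("need at least 10 samples")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), role = role,
                 n = as.integer(n)),
            class = "section_line")
}

# bilinear interpolation of image heights at (x, y) nm positions
bilinear_height <- function(img, x, y) {
  ps <- img$pixel_size
  H <- img$heights
  cx <- x / ps; ry <- y / ps            # 0-based fractional pixel coords
  if (any(cx < 0 | cx > ncol(H) - 1 | ry < 0 | ry > nrow(H) - 1))
    stop("section line leaves the image bounds")
  c0 <- pmin(floor(cx), ncol(H) - 2); r0 <- pmin(floor(ry), nrow(H) - 2)
  fx <- cx - c0; fy <- ry - r0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  H[i00] * (1 - fx) * (1 - fy) + H[i01] * fx * (1 - fy) +
    H[i10] * (1 - fx) * fy + H[i11] * fx * fy
}

#' Height profile along a section line
#'
#' Samples the image by bilinear interpolation at uniform spacing along the
#' line.
#'
#' @param img an [afm_image()].
#' @param line a [section_line()] lying inside the image bounds.
#' @return a `data.frame` with columns `distance_nm` (from `p1`) and
#'   `height_nm`.
#' @export
section_profile <- function(img, line) {
  stopifnot(inherits(img, "afm_image"), inherits(line, "section_line"))
  tt <- seq(0, 1, length.out = line$n)
  x <- line$p1[1] + tt * (line$p2[1] - line$p1[1])
  y <- line$p1[2] + tt * (line$p2[2] - line$p1[2])
  len <- sqrt(sum((line$p2 - line$p1)^2))
  data.frame(distance_nm = tt * len,
             height_nm = bilinear_height(img, x, y))
}

#' Uphill slope of a section profile
#'
#' Least-squares slope of height versus distance over the ascending flank
#' of the profile's main peak, restricted to samples between 20 and 80
#' percent of the peak height measured from the flank's base.  Only uphill
#' flanks are surveyed because high-speed AFM cannot image downhill regions
#' reliably (tip parachuting).
#'
#' @param profile a data frame from [section_profile()] (columns
#'   `distance_nm`, `height_nm`).
#' @param frac window on the ascending flank as fractions of the peak
#'   height above the base, default `c(0.2, 0.8)`.
#' @return slope (nm height per nm lateral distance).
#' @export
uphill_slope <- function(profile, frac = c(0.2, 0.8)) {
  h <- profile$height_nm
  d <- profile$distance_nm
  m <- which.max(h)
  if (m == 1) stop("profile has no uphill flank (maximum at first sample)")
  base <- min(h[1:m])
  if (h[m] - base <= 0) stop("profile has no uphill flank (flat)")
  lo <- base + frac[1] * (h[m] - base)
  hi <- base + frac[2] * (h[m] - base)
  inband <- which(h[1:m] >= lo & h[1:m] <= hi)
  if (length(inband) < 2) stop("too few samples on the ascending flank")
  # keep the contiguous run adjacent to the peak
  brk <- which(diff(inband) > 1)
  if (length(brk) > 0) inband <- inband[(max(brk) + 1):length(inband)]
  if (length(inband) < 2) stop("too few samples on the ascending flank")
  stats::coef(stats::lm(h[inband] ~ d[inband]))[[2]]
}

#' Chirality call from crossing-point uphill slopes
#'
#' The handedness statistic is `delta = slope_AB - slope_CD`.  A larger
#' uphill slope along a section line indicates that the bundle lying along
#' that line passes underneath the other at the crossing; with the section
#' line convention of [section_line()], a positive `delta` indicates a
#' right-handed structure and a negative one a left-handed structure.
#'
#' @param slope_AB,slope_CD uphill slopes (nm/nm) along the A-B and C-D
#'   section lines.
#' @param tolerance calls within `tolerance` of zero are `"indeterminate"`;
#'   default 1e-3.
#' @return an object of class `chirality_result`: list with `slope_AB`,
#'   `slope_CD`, `delta`, `call`.
#' @export
chirality_from_slopes <- function(slope_AB, slope_CD, tolerance = 1e-3) {
  if (!is.finite(slope_AB) || !is.finite(slope_CD))
    stop("slopes must be finite")
  delta <- slope_AB - slope_CD
  call <- if (delta > tolerance) "right"
          else if (delta < -tolerance) "left"
          else "indeterminate"
  structure(list(slope_AB = slope_AB, slope_CD = slope_CD, delta = delta,
                 call = call),
            class = "chirality_result")
}

#' @export
print.chirality_result <- function(x, ...) {
  cat(sprintf(
    "Chirality: slope_AB = %.4g, slope_CD = %.4g, delta = %.4g -> %s\n",
    x$slope_AB, x$slope_CD, x$delta, x$call))
  invisible(x)
}

#' Locate the crossing point of two bundles in an AFM image
#'
#' Helper returning the position of the global height maximum after a light
#' box smoothing; at a crossing the overpassing bundle rides on top of the
#' other, so the crossing is the tallest feature.
#'
#' @param img an [afm_image()].
#' @param smooth half-width of the smoothing box in pixels, default 1.
#' @return numeric (x, y) position in nm.
#' @export
find_crossing <- function(img, smooth = 1) {
  stopifnot(inherits(img, "afm_image"))
  H <- img$heights
  if (smooth > 0) {
    k <- 2 * smooth + 1
    H <- t(apply(apply(H, 2, stats::filter, rep(1 / k, k)), 1,
                 stats::filter, rep(1 / k, k)))
    H[is.na(H)] <- -Inf
  }
  ij <- which(H == max(H), arr.ind = TRUE)[1, ]
  c(x = (ij[[2]] - 1) * img$pixel_size, y = (ij[[1]] - 1) * img$pixel_size)
}

#' End-to-end chirality call on an AFM image
#'
#' Convenience pipeline: sample the two section profiles, measure both
#' uphill slopes, and call the handedness.
#'
#' @param img an [afm_image()].
#' @param line_ab,line_cd [section_line()] objects with roles AB and CD.
#' @param tolerance passed to [chirality_from_slopes()].
#' @return a `chirality_result`.
#' @export
afm_chirality <- function(img, line_ab, line_cd, tolerance = 1e-3) {
  if (line_ab$role != "AB" || line_cd$role != "CD")
    stop("section line roles must be AB and CD respectively")
  sA <- uphill_slope(section_profile(img, line_ab))
  sC <- uphill_slope(section_profile(img, line_cd))
  chirality_from_slopes(sA, sC, tolerance)
}
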