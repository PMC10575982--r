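# orthonormal basis completing a unit axis vector to a right-handed frame
axis_basis <- function(n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

# helix parameters and residual for a fixed axis direction
helix_for_axis <- function(pts, n) {
  b <- axis_basis(n)
  u <- pts %*% b$e1
  v <- pts %*% b$e2
  z <- pts %*% b$n
  circ <- taubin_circle(as.numeric(u), as.numeric(v))
  du <- u - circ["cx"]; dv <- v - circ["cy"]
  rho <- sqrt(du^2 + dv^2)
  phi_raw <- atan2(dv, du)
  dphi <- diff(phi_raw)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))   # unwrap
  phi <- cumsum(c(phi_raw[1], dphi))
  fit <- stats::lm(z ~ phi)
  zres <- stats::residuals(fit)
  slope <- stats::coef(fit)[[2]]
  rms <- sqrt(mean((rho - circ["r"])^2 + zres^2))
  list(radius = unname(circ["r"]), slope = slope, phi = phi, z = z,
       rms = rms, center2d = circ[c("cx", "cy")], basis = b)
}

#' Total-least-squares helix fit of ordered 3D points
#'
#' Fits an axis, radius and pitch to an ordered 3D polyline in the spirit of
#' the HELFIT approach: an initial axis estimate from the mean cross product
#' of successive chords is refined by direct search, where for each
#' candidate axis the points are projected onto the axis-normal plane, a
#' least-squares circle gives radius and centre, and a linear fit of axial
#' displacement against unwrapped phase gives the pitch.  The objective is
#' the combined radial-plus-axial point residual.  Handedness is taken from
#' the sign of the mean triple product `(t_k x t_{k+1}) . axis` over
#' consecutive chord tangents, with the axis oriented along the point
#' ordering; it is reported `"indeterminate"` when the residual RMS is not
#' smaller than the radius.
#'
#' @param points matrix `n x 3` of ordered coordinates (nm), `n >= 4`, not
#'   collinear.
#' @param tol convergence tolerance of the axis search, default 1e-10.
#' @return an object of class `helix_fit`: list with `axis_point`,
#'   `axis_direction` (unit vector), `radius` (nm), `pitch` (nm per turn),
#'   `turns`, `handedness` (`"right"`, `"left"` or `"indeterminate"`),
#'   `rms` (nm).
#' @export
fit_helix <- function(points, tol = 1e-10) {
  pts <- as.matrix(points)
  if (nrow(pts) < 4) stop("need at least 4 points for a helix fit")
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  sv <- svd(pc)$d
  if (sv[2] < 1e-9 * sv[1])
    stop("degenerate geometry: points are (near-)collinear")
  # initial axis: mean cross product of successive chords
  ch <- diff(pts)
  cr <- t(vapply(seq_len(nrow(ch) - 1), function(k) {
    a <- ch[k, ]; b <- ch[k + 1, ]
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }, numeric(3)))
  n0 <- colMeans(cr)
  if (sqrt(sum(n0^2)) < 1e-12 * max(abs(ch))) n0 <- svd(pc)$v[, 3]
  n0 <- n0 / sqrt(sum(n0^2))
  obj <- function(ang) {
    n <- rotate_axis(n0, ang[1], ang[2])
    helix_for_axis(pc, n)$rms
  }
  op <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                     control = list(reltol = tol, maxit = 2000))
  n <- rotate_axis(n0, op$par[1], op$par[2])
  h <- helix_for_axis(pc, n)
  # orient the axis along the point ordering (axial coordinate increasing)
  idx <- seq_len(nrow(pts))
  if (stats::coef(stats::lm(h$z ~ idx))[[2]] < 0) {
    n <- -n
    h <- helix_for_axis(pc, n)
  }
  pitch <- 2 * pi * abs(h$slope)
  turns <- abs(h$phi[length(h$phi)] - h$phi[1]) / (2 * pi)
  # handedness from chord-tangent triple products against the oriented axis
  tp <- cr %*% n
  hand <- if (h$rms >= h$radius) "indeterminate"
          else if (mean(tp) > 0) "right" else "left"
  axis_point <- ctr + h$basis$e1 * h$center2d[["cx"]] +
    h$basis$e2 * h$center2d[["cy"]]
  structure(list(axis_point = axis_point, axis_direction = n,
                 radius = h$radius, pitch = pitch, turns = turns,
                 handedness = hand, rms = h$rms),
            class = "helix_fit")
}

# rotate unit vector n0 by small angles about two perpendicular directions
rotate_axis <- function(n0, a, b) {
  bb <- axis_basis(n0)
  n <- n0 + a * bb$e1 + b * bb$e2
  n / sqrt(sum(n^2))
}

#' @export
print.helix_fit <- function(x, ...) {
  cat(sprintf(
    "Helix fit: radius %.4g nm, pitch %.4g nm/turn, %.3g turns, %s-handed (RMS %.3g nm)\n",
    x$radius, x$pitch, x$turns, x$handedness, x$rms))
  invisible(x)
}

#' Compare backbone and pier helix radii
#'
#' The sign of `r_pier - r_backbone` tells whether the origami backbone
#' runs inside the coil (positive difference, the over-extended-junction
#' case) or outside it (negative difference, the contracted-junction case).
#'
#' @param fit_b,fit_p [fit_helix()] results for the backbone and pier guide
#'   points of the same structure.  Their axes must agree within
#'   `max_axis_angle` degrees.
#' @param max_axis_angle maximum allowed angle between the two fitted axes
#'   (degrees), default 30.
#' @return an object of class `radius_comparison`: list with `r_backbone`,
#'   `r_pier`, `difference` (nm) and `call` (`"backbone-inside"`,
#'   `"backbone-outside"` or `"indeterminate"` at zero difference).
#' @export
compare_backbone_pier <- function(fit_b, fit_p, max_axis_angle = 30) {
  stopifnot(inherits(fit_b, "helix_fit"), inherits(fit_p, "helix_fit"))
  cosang <- abs(sum(fit_b$axis_direction * fit_p$axis_direction))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  if (ang >= max_axis_angle)
    stop(sprintf("incompatible helix axes: %.1f degrees apart", ang))
  diff <- fit_p$radius - fit_b$radius
  call <- if (diff > 0) "backbone-inside"
          else if (diff < 0) "backbone-outside"
          else "indeterminate"
  structure(list(r_backbone = fit_b$radius, r_pier = fit_p$radius,
                 difference = diff, call = call),
            class = "radius_comparison")
}
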