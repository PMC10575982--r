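# run fn with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, fn) {
  if (is.null(seed)) stop("a seed is mandatory for synthetic generators")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic stretch / relax force-extension pair
#'
#' Extension follows the combined construct model plus iid Gaussian noise.
#' Optional unfolding "rips" emulate junction G-quadruplex unfolding: each
#' rip adds a contour increment to the stretch curve only above its rip
#' force, while on the relax curve the refolding force of rip `i` is
#' `refold_fraction * rip_force_i`, so the increment persists to lower
#' forces and the pair shows hysteresis.  `refold_fraction = 0` means no
#' refolding during relaxation (slow refolder, maximal hysteresis);
#' `refold_fraction = 1` reproduces the stretch curve (fast refolder, no
#' hysteresis).
#'
#' @param m a [construct_model()].
#' @param force_grid forces (pN) at which to sample, all `>= m$F0`.
#' @param noise_sigma extension noise SD (nm).
#' @param seed RNG seed (mandatory).
#' @param rips optional 2-column matrix / data.frame of
#'   `(rip force pN, added contour nm)`.
#' @param refold_fraction relaxation refolding-force fraction in [0, 1],
#'   default 0.
#' @return list with elements `stretch` and `relax`, both [fe_trace()]s.
#' @export
gen_force_extension <- function(m, force_grid, noise_sigma = 0, seed,
                                rips = NULL, refold_fraction = 0) {
  stopifnot(inherits(m, "construct_model"))
  if (any(force_grid < m$F0)) stop("force grid extends below F0")
  base <- construct_extension(force_grid, m)
  rip_offset <- function(thresholds) {
    off <- numeric(length(force_grid))
    if (is.null(rips)) return(off)
    r <- as.matrix(rips)
    for (i in seq_len(nrow(r)))
      off <- off + r[i, 2] * (force_grid >= thresholds[i])
    off
  }
  thr <- if (is.null(rips)) NULL else as.matrix(rips)[, 1]
  x_st <- base + rip_offset(thr)
  x_rx <- base + rip_offset(refold_fraction * thr)
  with_seed(seed, function() {
    list(stretch = fe_trace(force_grid,
                            x_st + stats::rnorm(length(x_st), 0, noise_sigma),
                            direction = "stretch"),
         relax = fe_trace(rev(force_grid),
                          rev(x_rx + stats::rnorm(length(x_rx), 0,
                                                  noise_sigma)),
                          direction = "relax"))
  })
}

#' Force grid of a constant-velocity ramp
#'
#' Builds a force grid whose points are uniform in *extension* of the model
#' (the sampling a constant-velocity optical-tweezers pull produces), so
#' low forces — where extension changes fastest — are densely sampled.
#'
#' @param m a [construct_model()].
#' @param force_range `c(lo, hi)` (pN), `lo > m$F0`.
#' @param n number of points.
#' @return increasing force vector of length `n` (pN).
#' @export
ramp_force_grid <- function(m, force_range = c(0.1, 8.2), n = 500) {
  stopifnot(inherits(m, "construct_model"))
  if (force_range[1] <= m$F0) stop("force range must start above F0")
  xs <- seq(construct_extension(force_range[1], m),
            construct_extension(force_range[2], m), length.out = n)
  vapply(xs, function(x)
    stats::uniroot(function(F) construct_extension(F, m) - x,
                   c(force_range[1] * 0.999, force_range[2] * 1.001),
                   tol = 1e-10)$root,
    numeric(1))
}

# equilibrium spring extension under a bilinear (entropic/enthalpic) law
bilinear_spring_ext <- function(F, k_low, k_high, breakpoint, x0 = 0) {
  ifelse(F <= breakpoint,
         x0 + F / k_low,
         x0 + breakpoint / k_low + (F - breakpoint) / k_high)
}

#' Generate a synthetic force-jump temporal trace
#'
#' At each setpoint change the dsDNA handles re-equilibrate instantly while
#' the nanospring extension relaxes exponentially (time constant `tau`)
#' from its previous value to the new equilibrium implied by the bilinear
#' spring law.  Gaussian noise is added to both channels.
#'
#' @param schedule data.frame with columns `t_s` (setpoint start times, s,
#'   first must be 0) and `force_pN`.
#' @param handles a [wlc_params()] for the instantaneous handle response.
#' @param k_low,k_high,breakpoint bilinear spring law (pN/nm, pN/nm, pN).
#' @param x0 zero-force spring length (nm), default 189.
#' @param tau relaxation time constant (s), > 0.
#' @param dt sampling interval (s), default 0.005.
#' @param t_end total duration (s); default the last setpoint time plus 4 s.
#' @param noise_sigma extension noise SD (nm).
#' @param force_noise force channel noise SD (pN), default 0.05.
#' @param seed RNG seed (mandatory).
#' @return an [fj_trace()].
#' @export
gen_force_jump_trace <- function(schedule, handles, k_low, k_high,
                                 breakpoint = 2, x0 = 189, tau = 0.5,
                                 dt = 0.005, t_end = NULL, noise_sigma = 0,
                                 force_noise = 0.05, seed) {
  stopifnot(inherits(handles, "wlc_params"))
  if (tau <= 0) stop("tau must be > 0")
  if (k_low <= 0 || k_high <= 0 || breakpoint <= 0)
    stop("invalid bilinear spring law")
  if (!is.data.frame(schedule) || nrow(schedule) == 0 ||
      !all(c("t_s", "force_pN") %in% names(schedule)))
    stop("schedule needs columns t_s and force_pN")
  if (is.null(t_end)) t_end <- schedule$t_s[nrow(schedule)] + 4
  tt <- seq(0, t_end, by = dt)
  f_set <- schedule$force_pN[findInterval(tt, schedule$t_s)]
  spring_eq <- bilinear_spring_ext(schedule$force_pN, k_low, k_high,
                                   breakpoint, x0)
  handle_x <- wlc_extension_at_force(schedule$force_pN, handles)
  # piecewise exponential relaxation of the spring component
  spring_x <- numeric(length(tt))
  prev <- spring_eq[1]
  for (j in seq_len(nrow(schedule))) {
    t0 <- schedule$t_s[j]
    t1 <- if (j < nrow(schedule)) schedule$t_s[j + 1] else t_end + dt
    sel <- tt >= t0 & tt < t1
    spring_x[sel] <- spring_eq[j] +
      (prev - spring_eq[j]) * exp(-(tt[sel] - t0) / tau)
    prev <- spring_eq[j] + (prev - spring_eq[j]) * exp(-(t1 - t0) / tau)
  }
  ext <- spring_x + handle_x[findInterval(tt, schedule$t_s)]
  with_seed(seed, function() {
    fj_trace(tt,
             f_set + stats::rnorm(length(tt), 0, force_noise),
             ext + stats::rnorm(length(tt), 0, noise_sigma),
             dt = dt)
  })
}

#' Standard force-jump setpoint schedule
#'
#' Builds the protocol used in the force-jump experiments: recoils from a
#' 30 pN hold to each low force in turn, then uncoils from a 0.5 pN hold to
#' each test force in turn.
#'
#' @param recoil_to final forces of the recoil jumps (pN).
#' @param uncoil_to final forces of the uncoil jumps (pN).
#' @param hold_high,hold_low holding forces (pN), defaults 30 and 0.5.
#' @param dwell seconds spent at each setpoint, default 4.
#' @return a schedule data.frame for [gen_force_jump_trace()].
#' @export
jump_schedule <- function(recoil_to = c(0.5, 1, 2, 4, 6, 8, 10),
                          uncoil_to = c(1, 2, 4, 6, 8, 10),
                          hold_high = 30, hold_low = 0.5, dwell = 4) {
  forces <- c(rbind(hold_high, recoil_to))
  forces <- c(forces, c(rbind(hold_low, uncoil_to)))
  data.frame(t_s = (seq_along(forces) - 1) * dwell, force_pN = forces)
}

#' Read / write a force-jump setpoint schedule as TSV
#'
#' Sidecar format for [gen_force_jump_trace()]: tab-separated columns
#' `t_s`, `force_pN`.
#'
#' @param path file path.
#' @return `read_jump_schedule`: a schedule data.frame.
#' @export
read_jump_schedule <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("t_s", "force_pN") %in% names(df)))
    stop("schedule file must have columns t_s and force_pN")
  df[c("t_s", "force_pN")]
}

#' @param schedule a schedule data.frame (`t_s`, `force_pN`).
#' @rdname read_jump_schedule
#' @export
write_jump_schedule <- function(schedule, path) {
  utils::write.table(schedule[c("t_s", "force_pN")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a synthetic AFM image of two crossing bundles
#'
#' Two straight bundle segments with Gaussian height cross-sections cross
#' at the canvas centre.  The overpassing bundle is elevated near the
#' crossing by a ramp of width `bend_factor` times the bundle width
#' (emulating its gradual mechanical climb over the other), while the
#' underlying bundle is occluded by a pointwise height maximum.  Because the
#' climbing ramp is broader than a bundle width, the uphill slope measured
#' along the underneath bundle exceeds the one along the overpassing
#' bundle.  The A-B section line always lies along the bundle oriented
#' lower-left to upper-right; for a right-handed coil that bundle is the
#' one underneath.
#'
#' @param helix_radius coil radius (nm); sets the canvas size.
#' @param handedness `"right"` or `"left"`.
#' @param bundle_height ridge height (nm), default 2.
#' @param bundle_width Gaussian ridge SD (nm), default 4.
#' @param pixel_size nm per pixel, default 1.
#' @param tip_broadening Gaussian tip blur SD (nm), default 0.
#' @param noise_sigma height noise SD (nm), default 0.
#' @param bend_factor ratio of climbing-ramp width to bundle width,
#'   default 2.
#' @param seed RNG seed (mandatory).
#' @return list with `image` (an [afm_image()]), `line_ab`, `line_cd`
#'   ([section_line()]s through the crossing) and `handedness` (the ground
#'   truth).
#' @export
gen_afm_crossing_image <- function(helix_radius, handedness = c("right",
                                                                "left"),
                                   bundle_height = 2, bundle_width = 4,
                                   pixel_size = 1, tip_broadening = 0,
                                   noise_sigma = 0, bend_factor = 2,
                                   seed) {
  handedness <- match.arg(handedness)
  if (helix_radius <= bundle_width)
    stop("helix radius must exceed the bundle width")
  half <- max(3 * helix_radius, 12 * bundle_width)
  n <- 2 * floor(half / pixel_size) + 1
  coord <- (seq_len(n) - 1) * pixel_size - (n - 1) * pixel_size / 2
  X <- matrix(coord, n, n, byrow = TRUE)   # x along columns
  Y <- matrix(coord, n, n)                  # y along rows (downward)
  # bundle 1 runs lower-left to upper-right (direction (1, -1) in image
  # coords since y points down); bundle 2 is its mirror
  d1 <- abs(X + Y) / sqrt(2)   # distance to the (1,-1) line
  d2 <- abs(X - Y) / sqrt(2)   # distance to the (1, 1) line
  under_d <- if (handedness == "right") d1 else d2
  over_d <- if (handedness == "right") d2 else d1
  h_under <- bundle_height * exp(-under_d^2 / (2 * bundle_width^2))
  ramp <- exp(-under_d^2 / (2 * (bend_factor * bundle_width)^2))
  h_over <- bundle_height * exp(-over_d^2 / (2 * bundle_width^2)) *
    (1 + ramp)
  H <- pmax(h_under, h_over)
  if (tip_broadening > 0) H <- gauss_blur(H, tip_broadening / pixel_size)
  H <- with_seed(seed, function()
    H + matrix(stats::rnorm(length(H), 0, noise_sigma), n, n))
  img <- afm_image(H, pixel_size)
  ctr <- (n - 1) * pixel_size / 2
  span <- min(ctr - pixel_size,
              (2 + 3 * bend_factor) * bundle_width)
  mk <- function(dirx, diry, role)
    section_line(c(ctr - span * dirx, ctr - span * diry),
                 c(ctr + span * dirx, ctr + span * diry), role = role,
                 n = max(50, round(4 * span / pixel_size)))
  list(image = img,
       line_ab = mk(1 / sqrt(2), -1 / sqrt(2), "AB"),
       line_cd = mk(1 / sqrt(2), 1 / sqrt(2), "CD"),
       handedness = handedness)
}

# separable Gaussian blur with reflected edges, sigma in pixels
gauss_blur <- function(H, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- c(rev(v[2:(r + 1)]), v, rev(v[(n - r):(n - 1)]))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  H2 <- apply(H, 2, smooth1)
  t(apply(H2, 1, smooth1))
}

#' Generate points on an ideal helix
#'
#' Ordered points on a circular helix of given radius, pitch and turn
#' count, plus isotropic Gaussian noise.  A right-handed helix advances
#' along its axis with counterclockwise phase (right-hand rule).
#'
#' @param radius helix radius (nm).
#' @param pitch axial rise per turn (nm).
#' @param turns number of turns, > 0.
#' @param n number of points, >= 4.
#' @param handedness `"right"` or `"left"`.
#' @param noise_sigma isotropic noise SD per coordinate (nm), default 0.
#' @param seed RNG seed (mandatory).
#' @return matrix `n x 3` of coordinates (nm).
#' @export
gen_helix_points <- function(radius, pitch, turns, n = 13,
                             handedness = c("right", "left"),
                             noise_sigma = 0, seed) {
  handedness <- match.arg(handedness)
  if (n < 4) stop("need at least 4 points")
  if (turns <= 0) stop("turns must be > 0")
  theta <- seq(0, 2 * pi * turns, length.out = n)
  sgn <- if (handedness == "right") 1 else -1
  pts <- cbind(radius * cos(theta),
               sgn * radius * sin(theta),
               pitch * theta / (2 * pi))
  with_seed(seed, function()
    pts + matrix(stats::rnorm(3 * n, 0, noise_sigma), n, 3))
}

#' Generate a fluctuating pseudo-trajectory
#'
#' Each frame is the base conformation plus iid Gaussian displacement per
#' entity (optionally with a linear drift), emulating thermal fluctuation
#' about a relaxed structure.
#'
#' @param base matrix `entities x 3` of base coordinates (nm).
#' @param fluct_sigma per-axis fluctuation SD (nm); scalar or one value per
#'   entity.
#' @param n_frames number of frames, >= 2.
#' @param frame_spacing_ns time between frames (ns), default 10.
#' @param drift optional length-3 displacement added per frame (nm).
#' @param seed RNG seed (mandatory).
#' @return a [cg_trajectory()].
#' @export
gen_trajectory <- function(base, fluct_sigma, n_frames,
                           frame_spacing_ns = 10, drift = c(0, 0, 0),
                           seed) {
  base <- as.matrix(base)
  if (n_frames < 2) stop("need at least 2 frames")
  ne <- nrow(base)
  sig <- rep_len(fluct_sigma, ne)
  pos <- array(0, dim = c(n_frames, ne, 3))
  with_seed(seed, function() {
    for (k in seq_len(n_frames)) {
      noise <- matrix(stats::rnorm(3 * ne, 0, rep(sig, 3)), ne, 3)
      pos[k, , ] <<- base + noise +
        matrix(drift * (k - 1), ne, 3, byrow = TRUE)
    }
    cg_trajectory(pos, time_ps = (seq_len(n_frames) - 1) *
                    frame_spacing_ns * 1e3)
  })
}
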