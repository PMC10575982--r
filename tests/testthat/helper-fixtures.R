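# Shared fixtures: the GQ-NS parameter set used as generator truth
# (fitted column: Lp 50 nm, L0 1244 nm, K0 1298 pN, k 0.04 pN/nm, x0 189 nm)
gqns_handles <- function() wlc_params(Lp = 50, L0 = 1244, K0 = 1298)
gqns_spring <- function() spring_params(k = 0.04, x0 = 189)
gqns_model <- function(F0 = 0)
  construct_model(gqns_handles(), gqns_spring(), F0 = F0)

# Independent bisection oracle for the extensible WLC force balance:
# solves Eq-2-style balance for F at extension x by plain interval halving,
# sharing no code with wlc_force_at_extension.
oracle_wlc_force <- function(x, Lp, L0, K0, kBT = 4.114, tol = 1e-12) {
  g <- function(F)
    (kBT / Lp) * (1 / (4 * (1 - x / L0 + F / K0)^2) - 0.25 + x / L0 -
                    F / K0) - F
  lo <- max(0, K0 * (x / L0 - 1)) + 1e-9
  hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# closed-form inextensible Marko-Siggia force at fractional extension u
oracle_marko_siggia <- function(u, Lp, kBT = 4.114)
  (kBT / Lp) * (1 / (4 * (1 - u)^2) - 0.25 + u)

# closed-form bilinear spring equilibrium (GQ-NS-like regime constants)
bilinear_ext_oracle <- function(F, k_low = 0.02, k_high = 0.41, bp = 2,
                                x0 = 189) {
  ifelse(F <= bp, x0 + F / k_low,
         x0 + bp / k_low + (F - bp) / k_high)
}

# closed-form least-squares slope of y on x
oracle_ls_slope <- function(x, y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)

# brute-force double-loop RMSD/RMSF oracles on a [frame, entity, 3] array
oracle_rmsd <- function(pos) {
  nf <- dim(pos)[1]; ne <- dim(pos)[2]
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    s <- 0
    for (i in seq_len(ne))
      s <- s + sum((pos[k, i, ] - pos[1, i, ])^2)
    out[k] <- sqrt(s / ne)
  }
  out
}

oracle_rmsf <- function(pos) {
  nf <- dim(pos)[1]; ne <- dim(pos)[2]
  out <- numeric(ne)
  for (i in seq_len(ne)) {
    ref <- colMeans(pos[, i, , drop = FALSE][, 1, ])
    s <- 0
    for (k in seq_len(nf)) s <- s + sum((pos[k, i, ] - ref)^2)
    out[i] <- sqrt(s / nf)
  }
  out
}

# render a Gaussian-profile ridge along a circular arc into an afm_image
render_arc_image <- function(radius, arc_frac = 0.75, width = 2,
                             height = 2, pixel_size = 1, canvas = NULL) {
  if (is.null(canvas)) canvas <- ceiling(3 * radius)
  n <- 2 * canvas + 1
  coord <- (seq_len(n) - 1) * pixel_size
  ctr <- canvas * pixel_size
  th <- seq(0, 2 * pi * arc_frac, length.out = 3000)
  cx <- ctr + radius * cos(th)
  cy <- ctr + radius * sin(th)
  X <- matrix(coord, n, n, byrow = TRUE)
  Y <- matrix(coord, n, n)
  d2 <- matrix(Inf, n, n)
  for (i in seq(1, length(th), by = 5))
    d2 <- pmin(d2, (X - cx[i])^2 + (Y - cy[i])^2)
  afm_image(height * exp(-d2 / (2 * width^2)), pixel_size)
}

# exact points on a circle, optionally traversed multiple turns
circle_points <- function(radius, n = 100, turns = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi * turns, length.out = n)
  cbind(x = cx + radius * cos(th), y = cy + radius * sin(th))
}

# the repeated recoil-only force-jump schedule used in recovery tests
recoil_schedule <- function(repeats = 6, dwell = 6) {
  one <- jump_schedule(recoil_to = c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9,
                                     10),
                       uncoil_to = numeric(0), dwell = dwell)
  sch <- do.call(rbind, lapply(seq_len(repeats), function(r) one))
  sch$t_s <- (seq_len(nrow(sch)) - 1) * dwell
  sch
}
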