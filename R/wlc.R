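#' Thermal energy at 298.15 K
#'
#' Default value of kBT used throughout the package, in pN nm.
#' @export
KBT_ROOM <- 4.114

#' Worm-like chain parameters
#'
#' Parameter set for the extensible (stretch-modulus corrected) worm-like
#' chain describing the dsDNA handles of a nanospring construct.
#'
#' @param Lp persistence length (nm).
#' @param L0 contour length (nm).
#' @param K0 stretch (elastic) modulus (pN).
#' @param kBT thermal energy (pN nm); default 4.114 corresponds to 298.15 K.
#' @return An object of class `wlc_params`.
#' @examples
#' wlc_params(Lp = 50, L0 = 1244, K0 = 1298)
#' @export
wlc_params <- function(Lp, L0, K0, kBT = KBT_ROOM) {
  stopifnot(is.numeric(Lp), is.numeric(L0), is.numeric(K0), is.numeric(kBT))
  if (Lp <= 0) stop("Lp must be > 0")
  if (L0 <= 0) stop("L0 must be > 0")
  if (K0 <= 0) stop("K0 must be > 0")
  if (kBT <= 0) stop("kBT must be > 0")
  structure(list(Lp = Lp, L0 = L0, K0 = K0, kBT = kBT),
            class = "wlc_params")
}

#' Hooke spring parameters
#'
#' Linear spring law for the nanospring itself: `x_s(F) = x0 + F / k`, so
#' `x0` is the spring length at zero force and `k` the spring constant.
#'
#' @param k spring constant (pN nm^-1).
#' @param x0 zero-force spring length (nm).
#' @return An object of class `spring_params`.
#' @export
spring_params <- function(k, x0) {
  stopifnot(is.numeric(k), is.numeric(x0))
  if (k <= 0) stop("spring constant k must be > 0")
  if (x0 < 0) stop("zero-force length x0 must be >= 0")
  structure(list(k = k, x0 = x0), class = "spring_params")
}

#' Combined construct model
#'
#' The full optical-tweezers construct: worm-like-chain dsDNA handles in
#' series with the Hooke nanospring, plus a force-calibration offset `F0`
#' absorbing instrumental deviation near zero force.  Total extension is
#' `x(F) = f_WLC(F - F0) + (F - F0)/k + x0`.
#'
#' @param handles a [wlc_params()] object for the dsDNA handles.
#' @param spring a [spring_params()] object for the nanospring.
#' @param F0 force-calibration offset (pN), default 0.
#' @return An object of class `construct_model`.
#' @export
construct_model <- function(handles, spring, F0 = 0) {
  stopifnot(inherits(handles, "wlc_params"), inherits(spring, "spring_params"))
  if (!is.finite(F0)) stop("F0 must be finite")
  structure(list(handles = handles, spring = spring, F0 = F0),
            class = "construct_model")
}

#' @export
print.construct_model <- function(x, ...) {
  cat("Nanospring construct model\n")
  cat(sprintf("  handles: Lp = %.4g nm, L0 = %.5g nm, K0 = %.5g pN (kBT = %.4g pN nm)\n",
              x$handles$Lp, x$handles$L0, x$handles$K0, x$handles$kBT))
  cat(sprintf("  spring : k = %.4g pN/nm, x0 = %.5g nm\n",
              x$spring$k, x$spring$x0))
  cat(sprintf("  F0     : %.4g pN\n", x$F0))
  invisible(x)
}

#' Junction geometry for chemo-mechanical force estimates
#'
#' Geometric and mechanical constants of one nanospring junction: the
#' single-stranded inter-base distance, the G-quadruplex end-to-end span,
#' the per-GQ rupture force, and the number of GQs / bridge duplexes per
#' junction.
#'
#' @param nt_spacing ssDNA inter-base distance (nm), default 0.68.
#' @param gq_span_lo,gq_span_hi GQ end-to-end range (nm), defaults 2 and 3.
#' @param gq_rupture_force per-GQ mechanical stability (pN), default 20.
#' @param n_gq_per_junction number of G-quadruplexes per junction, default 2.
#' @param n_duplex_per_junction number of bridge duplexes per junction,
#'   default 2.
#' @return An object of class `junction_geometry`.
#' @export
junction_geometry <- function(nt_spacing = 0.68, gq_span_lo = 2,
                              gq_span_hi = 3, gq_rupture_force = 20,
                              n_gq_per_junction = 2,
                              n_duplex_per_junction = 2) {
  vals <- c(nt_spacing, gq_span_lo, gq_span_hi, gq_rupture_force,
            n_gq_per_junction, n_duplex_per_junction)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("junction geometry values must be finite and non-negative")
  if (gq_span_lo > gq_span_hi) stop("gq_span_lo must be <= gq_span_hi")
  structure(list(nt_spacing = nt_spacing, gq_span_lo = gq_span_lo,
                 gq_span_hi = gq_span_hi,
                 gq_rupture_force = gq_rupture_force,
                 n_gq_per_junction = n_gq_per_junction,
                 n_duplex_per_junction = n_duplex_per_junction),
            class = "junction_geometry")
}

# RHS of the extensible WLC force balance at extension x and trial force F.
wlc_rhs <- function(F, x, p) {
  d <- 1 - x / p$L0 + F / p$K0
  (p$kBT / p$Lp) * (1 / (4 * d^2) - 0.25 + x / p$L0 - F / p$K0)
}

#' Force of an extensible worm-like chain at a given extension
#'
#' Solves the extensible Marko-Siggia force balance
#' \deqn{F = (k_BT/L_p)\left[\frac{1}{4(1 - x/L_0 + F/K_0)^2} - \frac14 +
#'   \frac{x}{L_0} - \frac{F}{K_0}\right]}
#' self-consistently for F (the force appears on both sides).  The solution
#' is unique because the right-hand side is strictly decreasing in F.
#'
#' @param x extension (nm); may be a vector.  Extensions at or beyond the
#'   contour length are admissible thanks to the enthalpic `F/K0` term.
#' @param p a [wlc_params()] object.
#' @param rel_tol relative tolerance of the root, default 1e-9.
#' @return force (pN), same length as `x`.
#' @export
wlc_force_at_extension <- function(x, p, rel_tol = 1e-9) {
  stopifnot(inherits(p, "wlc_params"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("extension must be finite and >= 0")
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    # denominator 1 - x/L0 + F/K0 must stay positive
    lo <- max(0, p$K0 * (xi / p$L0 - 1))
    eps <- max(1e-12, lo * 1e-12)
    lo <- lo + eps
    g <- function(F) wlc_rhs(F, xi, p) - F
    hi <- max(1, 2 * lo)
    it <- 0
    while (g(hi) > 0) {
      hi <- hi * 4
      it <- it + 1
      if (it > 60) stop("extension beyond admissible WLC range: no bracket")
    }
    if (g(lo) < 0) {
      # x below contour length and already relaxed at F -> 0+
      return(0)
    }
    r <- stats::uniroot(g, c(lo, hi), tol = 1e-13, maxiter = 2000)$root
    # polish to the requested relative tolerance by a few Newton-like steps
    for (i in 1:5) {
      gr <- g(r)
      if (abs(gr) <= rel_tol * max(r, 1e-6)) break
      h <- max(1e-8, abs(r) * 1e-8)
      r <- r - gr / ((g(r + h) - gr) / h)
    }
    r
  }, numeric(1))
}

#' Extension of an extensible worm-like chain at a given force
#'
#' Numerical inversion of the extensible worm-like chain: for each force the
#' force balance is solved for the fractional extension.  Writing
#' `u = x/L0 - F/K0` and `c = F Lp / kBT`, the balance reduces to the cubic
#' `4 v^3 + (4c - 3) v^2 - 1 = 0` in `v = 1 - u`, which has exactly one
#' positive root; it is found by a safeguarded Newton iteration started at
#' `v = 1` (the exact zero-force solution).
#'
#' @param F force (pN); may be a vector, all entries >= 0.
#' @param p a [wlc_params()] object.
#' @return extension (nm), same length as `F`; strictly increasing in `F`
#'   and always below `L0 * (1 + F/K0)`.
#' @export
wlc_extension_at_force <- function(F, p) {
  stopifnot(inherits(p, "wlc_params"))
  if (any(!is.finite(F)) || any(F < 0))
    stop("force must be finite and >= 0")
  cc <- F * p$Lp / p$kBT
  a <- 4 * cc - 3
  v <- rep(1, length(F))            # exact root at F = 0
  f <- 4 * v^3 + a * v^2 - 1
  for (i in seq_len(100)) {
    df <- 12 * v^2 + 2 * a * v
    step <- f / df
    v <- pmin(pmax(v - step, 1e-12), 1)
    f <- 4 * v^3 + a * v^2 - 1
    if (max(abs(f)) < 1e-13) break
  }
  bad <- abs(f) > 1e-9
  if (any(bad)) {                   # fall back to bisection, rarely needed
    v[bad] <- vapply(which(bad), function(j) {
      stats::uniroot(function(z) 4 * z^3 + a[j] * z^2 - 1,
                     c(1e-14, 1), tol = 1e-14)$root
    }, numeric(1))
  }
  p$L0 * (1 - v + F / p$K0)
}

#' Hooke spring extension at a given force
#'
#' Extension of the nanospring under its linear spring law,
#' `x_s(F) = x0 + F/k`.
#'
#' @param F force (pN), vectorised.
#' @param s a [spring_params()] object.
#' @return extension (nm).
#' @export
spring_extension <- function(F, s) {
  stopifnot(inherits(s, "spring_params"))
  if (any(!is.finite(F)) || any(F < 0)) stop("force must be finite and >= 0")
  s$x0 + F / s$k
}

#' Extension of the full construct at a given force
#'
#' Series combination of handles and nanospring after force calibration:
#' `x(F) = f_WLC(F - F0) + (F - F0)/k + x0`.
#'
#' @param F force (pN), vectorised; every entry must be >= `m$F0`.
#' @param m a [construct_model()] object.
#' @return extension (nm).
#' @export
construct_extension <- function(F, m) {
  stopifnot(inherits(m, "construct_model"))
  if (any(F < m$F0)) stop("force below the calibration offset F0")
  Fc <- F - m$F0
  wlc_extension_at_force(Fc, m$handles) + spring_extension(Fc, m$spring)
}

#' Pushing force exerted by bridge duplexes at full extension
#'
#' Tension in `n_strands` bridge duplexes whose end-to-end distance equals
#' the duplex contour length, obtained by solving the extensible worm-like
#' chain self-consistently at `x = L0`.  At that extension the force depends
#' only on `Lp`, `K0` and `kBT` (not on `L0`).
#'
#' @param p a [wlc_params()] object; defaults to dsDNA with `Lp` = 50 nm and
#'   `K0` = 1200 pN (midpoint of the 1000-1500 pN theoretical range).
#' @param n_strands number of duplexes per junction (>= 0).
#' @return force (pN).
#' @examples
#' duplex_push_force()              # ~31 pN for a single duplex
#' duplex_push_force(n_strands = 2) # ~62 pN per junction
#' @export
duplex_push_force <- function(p = wlc_params(Lp = 50, L0 = 100, K0 = 1200),
                              n_strands = 1) {
  if (n_strands < 0) stop("n_strands must be >= 0")
  if (n_strands == 0) return(0)
  n_strands * wlc_force_at_extension(p$L0, p)
}

#' Bending force available from junction G-quadruplex formation
#'
#' Total mechanical stability of the G-quadruplexes in one junction,
#' `n_gq_per_junction * gq_rupture_force`.
#'
#' @param g a [junction_geometry()] object.
#' @return force (pN).
#' @export
gq_bend_force <- function(g = junction_geometry()) {
  stopifnot(inherits(g, "junction_geometry"))
  g$n_gq_per_junction * g$gq_rupture_force
}

#' End-to-end length of a single-stranded linker
#'
#' Length of an `n_nt`-nucleotide single-stranded linker at the standard
#' inter-base spacing, with a flag reporting whether it falls inside the
#' G-quadruplex end-to-end span (so that a poly-T linker can mimic a GQ).
#'
#' @param n_nt number of nucleotides (>= 0).
#' @param g a [junction_geometry()] object.
#' @return list with `length_nm` and logical `within_gq_span`.
#' @export
linker_end_to_end <- function(n_nt, g = junction_geometry()) {
  stopifnot(inherits(g, "junction_geometry"))
  if (n_nt < 0) stop("n_nt must be >= 0")
  len <- n_nt * g$nt_spacing
  list(length_nm = len,
       within_gq_span = len >= g$gq_span_lo && len <= g$gq_span_hi)
}

#' Helical pitch from zero-force length and turn count
#'
#' Pitch of a coiled nanospring as its zero-force length divided by the
#' number of turns counted from AFM images.
#'
#' @param length_nm zero-force spring length (nm).
#' @param turns number of coil turns.
#' @return pitch (nm per turn).
#' @export
coil_pitch <- function(length_nm, turns) {
  if (turns <= 0) stop("turns must be > 0")
  if (length_nm < 0) stop("length must be >= 0")
  length_nm / turns
}
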