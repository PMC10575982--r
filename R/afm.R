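#' AFM height map
#'
#' A 2D grid of heights with physical pixel size.  Coordinates follow image
#' convention: origin at the top-left pixel centre, x rightward along
#' columns, y downward along rows, both in nm (`(col - 1) * pixel_size`,
#' `(row - 1) * pixel_size`); heights in nm.
#'
#' @param heights numeric matrix of heights (nm), rows = y, cols = x.
#' @param pixel_size nm per pixel, > 0.
#' @param scan_direction `"left-to-right"` or `"right-to-left"`.
#' @return an object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_size,
                      scan_direction = c("left-to-right", "right-to-left")) {
  scan_direction <- match.arg(scan_direction)
  if (!is.matrix(heights) || length(heights) == 0)
    stop("heights must be a nonempty matrix")
  if (any(!is.finite(heights))) stop("heights must be finite")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(heights = heights, pixel_size = pixel_size,
                 scan_direction = scan_direction),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("AFM image: %d x %d px, %.3g nm/px, heights %.3g-%.3g nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Read / write AFM height maps as whitespace-delimited text matrices
#'
#' One image row per line, heights in nm.  The pixel size is stored in a
#' `# pixel_size_nm = <value>` comment on the first line.
#'
#' @param path file path.
#' @param pixel_size nm per pixel; for `read_afm_txt`, overrides the value
#'   in the file header if given.
#' @return `read_afm_txt`: an [afm_image()].
#' @export
read_afm_txt <- function(path, pixel_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(pixel_size)) {
    m <- regmatches(hdr, regexpr("pixel_size_nm\\s*=\\s*[0-9.eE+-]+", hdr))
    if (length(m) == 0)
      stop("no pixel_size_nm header in file and none supplied")
    pixel_size <- as.numeric(sub(".*=\\s*", "", m[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) stop("ragged height matrix")
  afm_image(do.call(rbind, rows), pixel_size)
}

#' @param img an [afm_image()].
#' @rdname read_afm_txt
#' @export
write_afm_txt <- function(img, path) {
  stopifnot(inherits(img, "afm_image"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm = %.10g", img$pixel_size), con)
  utils::write.table(img$heights, con, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

# Zhang-Suen thinning of a logical matrix (TRUE = object pixel).
thin_mask <- function(mask) {
  pad <- function(m) {
    out <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out
  }
  m <- pad(mask)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P2 <- sh(m, 1, 0); P3 <- sh(m, 1, -1); P4 <- sh(m, 0, -1)
      P5 <- sh(m, -1, -1); P6 <- sh(m, -1, 0); P7 <- sh(m, -1, 1)
      P8 <- sh(m, 0, 1); P9 <- sh(m, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (pass == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nr - 1), 2:(nc - 1)]
}

# Largest 8-connected component of a logical matrix, as a logical matrix.
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask & lab == 0L, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  while (nrow(idx) > 0) {
    cur <- cur + 1L
    queue <- idx[1, , drop = FALSE]
    lab[queue] <- cur
    while (nrow(queue) > 0) {
      nxt <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- queue[, 1] + dr; c <- queue[, 2] + dc
        ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
        r <- r[ok]; c <- c[ok]
        ii <- cbind(r, c)
        hit <- mask[ii] & lab[ii] == 0L
        if (any(hit)) {
          ii <- ii[hit, , drop = FALSE]
          lab[ii] <- cur
          nxt <- rbind(nxt, ii)
        }
      }
      queue <- if (is.null(nxt)) matrix(0L, 0, 2) else unique(nxt)
    }
    idx <- which(mask & lab == 0L, arr.ind = TRUE)
  }
  if (cur == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Longest path through the 8-connected skeleton pixel graph (two BFS sweeps).
skeleton_path <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  key <- px[, 1] + (px[, 2] - 1) * nrow(mask)
  lookup <- stats::setNames(seq_len(n), key)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    r <- px[i, 1]; c <- px[i, 2]
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- as.character(r + dr + (c + dc - 1) * nrow(mask))
      j <- lookup[k]
      if (!is.na(j)) nb <- c(nb, j)
    }
    adj[[i]] <- nb
  }
  bfs <- function(start) {
    dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
    dist[start] <- 0L
    q <- start
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        parent[w] <- v
        q <- c(q, w)
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- b
  while (!is.na(b2$parent[path[1]])) path <- c(b2$parent[path[1]], path)
  px[path, , drop = FALSE]
}

#' Trace the backbone centerline of a ridge in an AFM image
#'
#' Thresholds the image, keeps the largest connected above-threshold
#' region, thins it to a one-pixel skeleton and orders the skeleton pixels
#' along the longest path through it (branches are dropped with a warning).
#'
#' @param img an [afm_image()].
#' @param height_threshold heights above this value (nm) belong to the
#'   ridge.
#' @return an object of class `backbone_trace`: a matrix of ordered (x, y)
#'   points in nm along the ridge centerline.
#' @export
trace_backbone <- function(img, height_threshold) {
  stopifnot(inherits(img, "afm_image"))
  mask <- img$heights > height_threshold
  if (!any(mask)) stop("no pixels above the height threshold")
  mask <- largest_component(mask)
  skel <- thin_mask(mask)
  if (!any(skel)) skel <- mask  # degenerate: ridge thinner than one pixel
  deg <- degree_count(skel)
  if (any(deg[skel] > 2))
    warning("branched skeleton: taking the longest path")
  path <- skeleton_path(skel)
  pts <- cbind(x = (path[, 2] - 1) * img$pixel_size,
               y = (path[, 1] - 1) * img$pixel_size)
  backbone_trace(pts)
}

degree_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  deg <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    deg[rs, cs] <- deg[rs, cs] + mask[rs - dr, cs - dc]
  }
  deg
}

#' Backbone trace constructor
#'
#' @param points matrix with columns x, y (nm), at least 3 rows,
#'   consecutive points distinct.
#' @return an object of class `backbone_trace`.
#' @export
backbone_trace <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("a backbone trace needs at least 3 points")
  if (any(rowSums(abs(diff(points))) == 0))
    stop("consecutive trace points must be distinct")
  structure(points, class = c("backbone_trace", class(points)))
}

# Taubin algebraic circle fit (Chernov's Newton form).
taubin_circle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  z <- u^2 + v^2
  Zm <- mean(z)
  Muu <- mean(u * u); Mvv <- mean(v * v); Muv <- mean(u * v)
  Muz <- mean(u * z); Mvz <- mean(v * z); Mzz <- mean(z * z)
  cov_xy <- Muu * Mvv - Muv^2
  A3 <- 4 * Zm
  A2 <- -3 * Zm^2 - Mzz
  A1 <- Mzz * Zm + 4 * cov_xy * Zm - Muz^2 - Mvz^2 - Zm^3
  A0 <- Muz^2 * Mvv + Mvz^2 * Muu - Mzz * cov_xy -
    2 * Muz * Mvz * Muv + Zm^2 * cov_xy
  # Newton from eta = 0
  eta <- 0
  for (i in 1:50) {
    p <- A0 + eta * (A1 + eta * (A2 + eta * A3))
    dp <- A1 + eta * (2 * A2 + 3 * A3 * eta)
    step <- p / dp
    eta <- eta - step
    if (!is.finite(eta)) { eta <- 0; break }
    if (abs(step) < 1e-14 * max(1, abs(eta))) break
  }
  det <- (Muu - eta) * (Mvv - eta) - Muv^2
  cx <- (Muz * (Mvv - eta) - Mvz * Muv) / det / 2
  cy <- (Mvz * (Muu - eta) - Muz * Muv) / det / 2
  r <- sqrt(cx^2 + cy^2 + Zm)
  c(cx = cx + mx, cy = cy + my, r = r)
}

#' Least-squares circle fit of a backbone trace
#'
#' Algebraic (Taubin) circle fit refined by geometric least squares
#' (minimising the variance of point-to-centre distances).  Collinear
#' traces are rejected: a circle through them would have infinite radius.
#'
#' @param traced a [backbone_trace()] (or 2-column matrix) with at least 3
#'   non-collinear points.
#' @return an object of class `curvature_result`: list with `radius` (nm),
#'   `center` (x, y nm), `rms` (radial residual RMS, nm).
#' @export
curvature_radius <- function(traced) {
  pts <- as.matrix(traced)
  if (nrow(pts) < 3) stop("need at least 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  # collinearity guard via covariance condition number
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-16 ||
      sqrt(ev[1] / max(ev[2], .Machine$double.xmin)) > 1e8)
    stop("degenerate geometry: points are (near-)collinear")
  init <- taubin_circle(x, y)
  obj <- function(ctr) {
    d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    sum((d - mean(d))^2)
  }
  op <- stats::optim(init[c("cx", "cy")], obj, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 500))
  d <- sqrt((x - op$par[1])^2 + (y - op$par[2])^2)
  structure(list(radius = mean(d), center = unname(op$par),
                 rms = sqrt(mean((d - mean(d))^2))),
            class = "curvature_result")
}

#' Number of coil turns from a traced backbone
#'
#' Polyline arclength divided by the circumference at the fitted curvature
#' radius, `turns = arclength / (2 * pi * radius)`.
#'
#' @param traced a [backbone_trace()] (or 2-column matrix).
#' @param radius curvature radius (nm), e.g. from [curvature_radius()].
#' @return number of turns (dimensionless).
#' @export
turns_from_trace <- function(traced, radius) {
  if (radius <= 0) stop("radius must be > 0")
  pts <- as.matrix(traced)
  len <- sum(sqrt(rowSums(diff(pts)^2)))
  if (len == 0) stop("zero-length polyline")
  len / (2 * pi * radius)
}
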