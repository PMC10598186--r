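## Lumen diameter measurement: centreline splines, perpendicular
## cross-sections, and the FWHM edge-cued ellipse caliper.

#' Centreline sampling interval
#'
#' The measurement interval along airway centrelines is set dynamically to
#' half the smallest voxel dimension of the image, e.g. 0.4 mm for
#' 0.8 x 0.8 x 1.0 mm voxels.
#'
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return Interval in mm.
#' @export
sampling_interval <- function(spacing) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  min(spacing) / 2
}

#' Fit a smooth centreline spline to a segment path
#'
#' Fits a smoothing cubic spline per coordinate, parameterised by cumulative
#' chord length, through the segment's skeleton voxels in world mm. The
#' smoothing (generalised cross-validation) suppresses the sub-voxel
#' staircase of the discrete skeleton so that straight airways recover an
#' arc-to-chord ratio of 1. Arc length is computed by fine quadrature along
#' the fitted curve; Euclidean length is the straight-line distance between
#' the curve's endpoints.
#'
#' @param path_voxels m x 3 matrix of 0-based voxel indices (proximal first).
#' @param spacing,origin grid geometry (mm).
#' @param quadrature_step quadrature step in mm for the arc length
#'   (default: a tenth of [sampling_interval()]).
#' @return An object of class \code{segment_spline} with fields
#'   \code{eval(t)} and \code{tangent(t)} (t in \[0, 1\]),
#'   \code{arc_length_mm}, \code{euclidean_length_mm}.
#' @export
fit_spline <- function(path_voxels, spacing, origin = c(0, 0, 0),
                       quadrature_step = sampling_interval(spacing) / 10) {
  pts <- .voxel_to_world(path_voxels, spacing, origin)
  m <- nrow(pts)
  if (m < 2L) stop("segment path must contain at least 2 voxels")
  chord <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- chord[m]
  if (total <= 0) stop("degenerate (zero-length) segment path")
  u <- chord / total  # unit parameter

  # Smoothing strength is chosen deterministically: the stiffest spline
  # (smallest equivalent df) whose maximum 3D deviation from the voxel path
  # stays within one voxel. Straight airways therefore collapse to a line
  # (arc/chord ratio 1) while genuine curvature above the voxel scale is
  # retained.
  tol <- max(spacing)
  make_fits <- function(df) {
    lapply(1:3, function(ax) {
      f <- tryCatch(suppressWarnings(
        stats::smooth.spline(u, pts[, ax], df = df)),
        error = function(e) NULL)
      if (is.null(f)) return(NULL)
      list(ev = function(t) stats::predict(f, t)$y,
           dv = function(t) stats::predict(f, t, deriv = 1)$y)
    })
  }
  fits <- NULL
  if (m >= 5L) {
    df_seq <- c(2, 3, 4, 6, 8, 12, 16, 24, 32)
    df_seq <- df_seq[df_seq <= m - 1L]
    pick <- length(df_seq)
    for (i in seq_along(df_seq)) {
      cand <- make_fits(df_seq[i])
      if (any(vapply(cand, is.null, TRUE))) next
      fit_at_u <- cbind(cand[[1]]$ev(u), cand[[2]]$ev(u), cand[[3]]$ev(u))
      maxres <- sqrt(max(rowSums((fit_at_u - pts)^2)))
      fits <- cand
      if (maxres <= tol) { pick <- i; break }
    }
    # one step finer than the acceptance threshold: halves the amplitude
    # attenuation of genuine curvature at negligible staircase cost
    if (!is.null(fits) && pick < length(df_seq)) {
      cand <- make_fits(df_seq[pick + 1L])
      if (!any(vapply(cand, is.null, TRUE))) fits <- cand
    }
  }
  if (is.null(fits)) {
    fits <- lapply(1:3, function(ax) {
      y <- pts[, ax]
      if (m >= 4L) {
        f <- stats::splinefun(u, y, method = "natural")
        return(list(ev = function(t) f(t), dv = function(t) f(t, deriv = 1)))
      }
      f <- stats::approxfun(u, y, rule = 2)
      h <- 1e-4
      list(ev = f, dv = function(t) (f(pmin(t + h, 1)) - f(pmax(t - h, 0))) /
             (pmin(t + h, 1) - pmax(t - h, 0)))
    })
  }

  eval_fun <- function(t) cbind(fits[[1]]$ev(t), fits[[2]]$ev(t),
                                fits[[3]]$ev(t))
  tangent_fun <- function(t) {
    d <- cbind(fits[[1]]$dv(t), fits[[2]]$dv(t), fits[[3]]$dv(t))
    n <- sqrt(rowSums(d^2))
    n[n < 1e-12] <- 1
    d / n
  }

  nq <- max(64L, ceiling(total / quadrature_step))
  tq <- seq(0, 1, length.out = nq + 1L)
  pq <- eval_fun(tq)
  arc <- sum(sqrt(rowSums(diff(pq)^2)))
  eucl <- sqrt(sum((pq[nq + 1L, ] - pq[1L, ])^2))
  structure(list(eval = eval_fun, tangent = tangent_fun,
                 arc_length_mm = arc, euclidean_length_mm = eucl,
                 n_points = m, chord_mm = total),
            class = "segment_spline")
}

#' @export
print.segment_spline <- function(x, ...) {
  cat(sprintf("segment_spline: %d voxels, L_a = %.2f mm, L_e = %.2f mm\n",
              x$n_points, x$arc_length_mm, x$euclidean_length_mm))
  invisible(x)
}

#' Extract a perpendicular CT patch
#'
#' Resamples the CT on a square grid in the plane normal to the local
#' centreline tangent, by trilinear interpolation. The in-plane basis is
#' deterministic: the first axis is the normalised cross product of the
#' tangent with the global z axis (global x when the tangent is parallel to
#' z), the second completes the right-handed frame. The physical extent is
#' capped at \code{max_extent} mm per side (default 40, enough to frame any
#' airway). Samples falling outside the volume are filled with -1000 HU and
#' flagged.
#'
#' @param volume an [image_volume()].
#' @param point world mm position of the patch centre (on the centreline).
#' @param tangent unit tangent vector at \code{point}.
#' @param pitch in-plane pixel pitch in mm (default: [sampling_interval()]).
#' @param max_extent maximum physical extent per side in mm.
#' @return An object of class \code{perpendicular_patch}: \code{hu} matrix,
#'   \code{inside} logical matrix, \code{pitch_mm}, \code{extent_mm},
#'   \code{centre}, basis vectors \code{u}, \code{v}.
#' @export
extract_patch <- function(volume, point, tangent,
                          pitch = sampling_interval(volume$spacing),
                          max_extent = 40) {
  stopifnot(inherits(volume, "image_volume"))
  tangent <- tangent / sqrt(sum(tangent^2))
  dims <- dim(volume$data)
  lo <- volume$origin
  hi <- volume$origin + (dims - 1) * volume$spacing
  if (any(point < lo) || any(point > hi))
    stop("patch centre (", paste(round(point, 2), collapse = ", "),
         ") lies outside the volume")
  u <- c(tangent[2] * 1 - tangent[3] * 0,
         tangent[3] * 0 - tangent[1] * 1,
         tangent[1] * 0 - tangent[2] * 0)  # tangent x (0,0,1)
  if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
  u <- u / sqrt(sum(u^2))
  v <- c(tangent[2] * u[3] - tangent[3] * u[2],
         tangent[3] * u[1] - tangent[1] * u[3],
         tangent[1] * u[2] - tangent[2] * u[1])
  v <- v / sqrt(sum(v^2))

  hn <- floor((max_extent / 2) / pitch)
  g <- seq(-hn, hn) * pitch
  ab <- as.matrix(expand.grid(a = g, b = g))
  pts <- cbind(point[1] + ab[, 1] * u[1] + ab[, 2] * v[1],
               point[2] + ab[, 1] * u[2] + ab[, 2] * v[2],
               point[3] + ab[, 1] * u[3] + ab[, 2] * v[3])
  smp <- cpp_trilinear(as.numeric(volume$data), dims, volume$spacing,
                       volume$origin, pts, -1000)
  np <- 2L * hn + 1L
  structure(list(hu = matrix(smp$values, np, np),
                 inside = matrix(smp$inside, np, np),
                 pitch_mm = pitch, extent_mm = 2 * hn * pitch,
                 centre = point, u = u, v = v, tangent = tangent,
                 source_spacing = volume$spacing),
            class = "perpendicular_patch")
}

# vectorised bilinear interpolation on a patch; a, b in patch mm coordinates
# (0 at the centre pixel)
.patch_bilinear <- function(patch, a, b) {
  np <- nrow(patch$hu)
  hn <- (np - 1) / 2
  x <- a / patch$pitch_mm + hn  # 0-based pixel coords
  y <- b / patch$pitch_mm + hn
  x <- pmin(pmax(x, 0), np - 1 - 1e-9)
  y <- pmin(pmax(y, 0), np - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0 + 1, y0 + 1); i10 <- cbind(x0 + 2, y0 + 1)
  i01 <- cbind(x0 + 1, y0 + 2); i11 <- cbind(x0 + 2, y0 + 2)
  h <- patch$hu
  h[i00] * (1 - fx) * (1 - fy) + h[i10] * fx * (1 - fy) +
    h[i01] * (1 - fx) * fy + h[i11] * fx * fy
}

# closed-form Gaussian fit (log-parabola / Caruana): y = b + a exp(-(r-mu)^2
# / (2 s^2)); returns NULL when the fit is degenerate
.fit_gaussian_peak <- function(r, y, baseline) {
  z <- y - baseline
  keep <- z > 0.1 * max(z)
  if (sum(keep) < 3L) return(NULL)
  r <- r[keep]; z <- z[keep]
  # intensity-weighted log-parabola fit (Caruana/Guo): weighting by z^2
  # keeps the resampling-blurred tails from inflating sigma
  X <- cbind(1, r, r * r) * z
  cf <- tryCatch(solve(crossprod(X), crossprod(X, z * log(z))),
                 error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) return(NULL)
  s2 <- -1 / (2 * cf[3])
  mu <- cf[2] * s2
  s <- sqrt(s2)
  if (!is.finite(mu) || s < 0.05 || s > 5) return(NULL)
  list(mu = mu, sigma = s)
}

# direct least-squares ellipse fit (Fitzgibbon et al.): returns
# list(centre, r_major, r_minor) or NULL
.fit_ellipse_dls <- function(x, y) {
  if (length(x) < 5L) return(NULL)
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-6)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- evec[, ok[1]]
  coefs <- c(a1, T1 %*% a1)  # A B C D E F in scaled frame
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  q <- A * E^2 + C * D^2 - B * D * E + den * F
  s <- sqrt((A - C)^2 + B^2)
  q1 <- 2 * q * ((A + C) + s)
  q2 <- 2 * q * ((A + C) - s)
  if (!is.finite(q1) || !is.finite(q2) || q1 <= 0 || q2 <= 0) return(NULL)
  radii <- c(-sqrt(q1) / den, -sqrt(q2) / den) * sc
  if (any(radii <= 0)) return(NULL)
  list(centre = c(cx * sc + mx, cy * sc + my),
       r_major = max(radii), r_minor = min(radii))
}

#' Measure lumen diameter on a perpendicular patch
#'
#' Implements the full-width half-maximum edge-cued ellipse caliper. From
#' the patch centre (optionally re-centred on the centroid of the connected
#' low-HU lumen region) an intensity profile is cast outwards at
#' \code{n_rays} equally spaced angles, sampled every half pixel. On each
#' ray the airway wall is located as the HU maximum beyond a dead zone, the
#' wall is modelled as a Gaussian in radius, and the lumen boundary is
#' placed at the inner radius where the fitted Gaussian crosses halfway
#' between the wall peak and the lumen baseline (the minimum HU between
#' centre and peak). Rays with an insufficiently prominent wall or a failed
#' fit are rejected; boundary radii more than 3 scaled MADs from the median
#' are discarded; a direct least-squares ellipse is fitted to the surviving
#' boundary points. The reported diameter is the geometric-mean diameter
#' \code{2 * sqrt(r_minor * r_major)}.
#'
#' @param patch a [extract_patch()] result.
#' @param n_rays number of ray angles (default 60).
#' @param dead_zone_mm inner radius excluded from the wall-peak search.
#' @param min_prominence_hu required wall peak height above the lumen
#'   baseline.
#' @param gauss_window_mm half-width of the profile window around the peak
#'   used for the Gaussian fit.
#' @param refine_centre re-centre on the low-HU (< -800) lumen region before
#'   casting rays.
#' @param min_valid_frac fraction of rays that must survive for a valid fit.
#' @param centre_max_hu maximum HU allowed at the (refined) centre: the
#'   edge-cue model requires a resolvably dark lumen core, so brighter
#'   centres (sub-resolution airways, mis-centred patches) are invalid.
#' @return An object of class \code{ellipse_fit}: \code{diameter_mm},
#'   \code{minor_radius_mm}, \code{major_radius_mm}, \code{valid},
#'   \code{n_rays_used}, \code{boundary} (accepted points, patch mm coords).
#' @export
measure_fwhm_ellipse <- function(patch, n_rays = 60, dead_zone_mm = 0.5,
                                 min_prominence_hu = 100,
                                 gauss_window_mm = 2,
                                 refine_centre = TRUE,
                                 min_valid_frac = 0.6,
                                 centre_max_hu = -800) {
  stopifnot(inherits(patch, "perpendicular_patch"))
  np <- nrow(patch$hu)
  hn <- (np - 1) / 2
  c0 <- c(0, 0)
  if (refine_centre) {
    low <- patch$hu < -800
    if (low[hn + 1, hn + 1]) {
      lab <- cpp_label_components(as.logical(low), c(np, np, 1L))
      lab <- matrix(lab, np, np)
      reg <- which(lab == lab[hn + 1, hn + 1], arr.ind = TRUE)
      c0 <- (colMeans(reg) - (hn + 1)) * patch$pitch_mm
    }
  }

  invalid <- structure(list(diameter_mm = NA_real_,
                            minor_radius_mm = NA_real_,
                            major_radius_mm = NA_real_,
                            valid = FALSE, n_rays_used = 0L,
                            n_rays = n_rays, boundary = NULL,
                            centre_offset = c0),
                       class = "ellipse_fit")
  if (.patch_bilinear(patch, c0[1], c0[2]) > centre_max_hu)
    return(invalid)

  step <- patch$pitch_mm / 2
  rmax <- (hn - 1) * patch$pitch_mm - max(abs(c0))
  if (rmax <= dead_zone_mm + step) rmax <- dead_zone_mm + 2 * step
  rr <- seq(0, rmax, by = step)
  ang <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  aa <- outer(cos(ang), rr)  # n_rays x n_r offsets
  bb <- outer(sin(ang), rr)
  prof <- matrix(.patch_bilinear(patch, c0[1] + as.numeric(aa),
                                 c0[2] + as.numeric(bb)),
                 nrow = n_rays)

  # measured wall widths include the known variance of the resampling
  # kernels (trilinear volume->patch, linear patch->profile); subtract it
  # when converting the fitted width to the half-maximum offset so the
  # boundary is placed by the wall's own width, not the interpolation's.
  # (Scanner PSF / partial-volume blur is unknown and is not corrected.)
  sp2 <- patch$source_spacing^2 / 6
  dir3 <- outer(cos(ang), patch$u) + outer(sin(ang), patch$v)  # n_rays x 3
  samp_var <- as.numeric(dir3^2 %*% sp2) + patch$pitch_mm^2 / 6

  search <- which(rr > dead_zone_mm)
  bpts <- NULL
  for (i in seq_len(n_rays)) {
    p <- prof[i, ]
    ipk <- search[which.max(p[search])]
    base <- min(p[seq_len(ipk)])
    pk <- p[ipk]
    if (pk < base + min_prominence_hu) next
    # fit window: full inner flank, but only ~one wall half-width outward,
    # because the outer flank sits on the parenchymal baseline, not the
    # lumen baseline the half-maximum refers to
    win <- which(rr >= rr[ipk] - gauss_window_mm &
                   rr <= rr[ipk] + min(gauss_window_mm, 0.75))
    r_in <- NA_real_
    gf <- .fit_gaussian_peak(rr[win], p[win], base)
    if (!is.null(gf)) {
      s_wall <- sqrt(max(gf$sigma^2 - samp_var[i], (0.3 * gf$sigma)^2))
      r_in <- gf$mu - s_wall * sqrt(2 * log(2))
    } else {
      half <- (pk + base) / 2
      below <- which(p[seq_len(ipk)] <= half)
      if (length(below)) {
        j <- max(below)
        if (j < ipk) {
          f <- (half - p[j]) / (p[j + 1] - p[j])
          r_in <- rr[j] + f * step
        }
      }
    }
    if (is.finite(r_in) && r_in > 0 && r_in < rr[ipk])
      bpts <- rbind(bpts, c(r_in, ang[i]))
  }

  if (is.null(bpts)) return(invalid)

  rad <- bpts[, 1]
  med <- stats::median(rad)
  md <- stats::mad(rad)
  keep <- if (md > 1e-9) abs(rad - med) <= 3 * md else rep(TRUE, length(rad))
  bpts <- bpts[keep, , drop = FALSE]
  n_used <- nrow(bpts)
  if (n_used < max(5L, ceiling(min_valid_frac * n_rays))) {
    invalid$n_rays_used <- n_used
    return(invalid)
  }
  bx <- c0[1] + bpts[, 1] * cos(bpts[, 2])
  by <- c0[2] + bpts[, 1] * sin(bpts[, 2])
  ef <- .fit_ellipse_dls(bx, by)
  if (is.null(ef)) { invalid$n_rays_used <- n_used; return(invalid) }
  structure(list(diameter_mm = 2 * sqrt(ef$r_minor * ef$r_major),
                 minor_radius_mm = ef$r_minor,
                 major_radius_mm = ef$r_major,
                 valid = TRUE, n_rays_used = n_used, n_rays = n_rays,
                 boundary = cbind(x = bx, y = by), centre_offset = c0),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("ellipse_fit: d = %.2f mm (r %.2f x %.2f), %d/%d rays\n",
                x$diameter_mm, x$minor_radius_mm, x$major_radius_mm,
                x$n_rays_used, x$n_rays))
  else cat("ellipse_fit: invalid (", x$n_rays_used, "rays )\n")
  invisible(x)
}

#' Measure a segment's diameter series
#'
#' Samples the centreline spline at the measurement interval, extracts a
#' perpendicular patch at each sample and applies the FWHM ellipse caliper.
#' The segment's mean diameter is the mean over valid samples; the segment
#' is flagged invalid when fewer than half of its samples yield a valid fit.
#'
#' @param volume an [image_volume()].
#' @param spline a [fit_spline()] result.
#' @param interval sampling interval in mm (default:
#'   [sampling_interval()] of the volume spacing).
#' @param pitch patch pixel pitch (default: same as \code{interval}).
#' @param max_extent maximum patch extent per side (mm).
#' @param ... further arguments passed to [measure_fwhm_ellipse()].
#' @return An object of class \code{segment_measurement}: per-sample data
#'   frame \code{samples} (arc position, diameter, validity, patch extent),
#'   \code{mean_diameter_mm}, \code{valid}, \code{interval_mm}.
#' @export
measure_segment <- function(volume, spline,
                            interval = sampling_interval(volume$spacing),
                            pitch = interval, max_extent = 40, ...) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(spline, "segment_spline"))
  nsmp <- max(2L, floor(spline$arc_length_mm / interval) + 1L)
  tt <- seq(0, 1, length.out = nsmp)
  ctr <- spline$eval(tt)
  tg <- spline$tangent(tt)
  lo <- volume$origin
  hi <- volume$origin + (dim(volume$data) - 1) * volume$spacing
  res <- vector("list", nsmp)
  for (i in seq_len(nsmp)) {
    p <- ctr[i, ]
    if (any(p < lo) || any(p > hi)) {
      res[[i]] <- data.frame(pos_mm = tt[i] * spline$arc_length_mm,
                             diameter_mm = NA_real_, minor_mm = NA_real_,
                             major_mm = NA_real_, valid = FALSE,
                             n_rays_used = 0L, extent_mm = NA_real_,
                             in_volume = FALSE)
      next
    }
    patch <- extract_patch(volume, p, tg[i, ], pitch = pitch,
                           max_extent = max_extent)
    fit <- measure_fwhm_ellipse(patch, ...)
    res[[i]] <- data.frame(pos_mm = tt[i] * spline$arc_length_mm,
                           diameter_mm = fit$diameter_mm,
                           minor_mm = fit$minor_radius_mm,
                           major_mm = fit$major_radius_mm,
                           valid = fit$valid,
                           n_rays_used = fit$n_rays_used,
                           extent_mm = patch$extent_mm, in_volume = TRUE)
  }
  samples <- do.call(rbind, res)
  ok <- samples$valid
  # consistency filter: where the lumen opens into a parent or child at a
  # junction (or shrinks into a rounded tip) the ellipse is no longer a
  # cross-section of this segment; such samples stand far off the segment's
  # median diameter and are flagged invalid
  if (sum(ok) >= 3L) {
    d <- samples$diameter_mm[ok]
    med <- stats::median(d)
    thr <- max(4 * stats::mad(d), 0.25 * med)
    bad <- abs(samples$diameter_mm - med) > thr
    samples$valid[bad %in% TRUE] <- FALSE
    ok <- samples$valid
  }
  structure(list(samples = samples,
                 mean_diameter_mm = if (any(ok))
                   mean(samples$diameter_mm[ok]) else NA_real_,
                 valid = mean(ok) >= 0.5,
                 interval_mm = interval),
            class = "segment_measurement")
}

#' @export
print.segment_measurement <- function(x, ...) {
  cat(sprintf(
    "segment_measurement: %d samples every %.2f mm, mean d = %s mm%s\n",
    nrow(x$samples), x$interval_mm,
    ifelse(is.na(x$mean_diameter_mm), "NA",
           sprintf("%.2f", x$mean_diameter_mm)),
    if (x$valid) "" else " [INVALID]"))
  invisible(x)
}
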