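#' Procrustes similarity fit between landmark sets
#'
#' Finds the least-squares similarity transform (translation, rotation,
#' isotropic scale; reflection forbidden) mapping `source` landmarks onto
#' `template` landmarks, in closed form.  Because a face's relative landmark
#' geometry differs from trial to trial, the fit is not exact; the residual
#' root-mean-square landmark distance after transformation is returned.
#'
#' @param source n x 2 matrix of source landmarks (n >= 2), in the canonical
#'   row order.
#' @param template n x 2 matrix of template landmarks in the same order.
#' @return Object of class `zg_similarity`: list with `rotation_deg`,
#'   `scale` (> 0), `translation` (`c(tx, ty)`), `residual_rms`.
#' @seealso [map_endpoints()], [invert_transform()]
#' @export
#' @examples
#' tpl <- template_face()$landmarks
#' fit <- procrustes_fit(tpl, tpl)
#' fit$residual_rms  # 0: identity
procrustes_fit <- function(source, template) {
  source <- as.matrix(source); template <- as.matrix(template)
  stopifnot(ncol(source) == 2, ncol(template) == 2,
            nrow(source) == nrow(template), nrow(source) >= 2)
  if (anyNA(source) || anyNA(template)) stop("landmarks contain NA")
  ms <- colMeans(source); mt <- colMeans(template)
  xs <- sweep(source, 2, ms); xt <- sweep(template, 2, mt)
  ss <- sum(xs^2)
  if (ss < 1e-12) stop("degenerate source landmarks (coincident points)")
  ## collinearity check: rank of the centered configuration
  ev <- eigen(crossprod(xs), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] / ev[1] < 1e-10) stop("degenerate source landmarks (collinear)")
  a <- sum(xs * xt)                         # Sum xs . xt
  b <- sum(xs[, 1] * xt[, 2] - xs[, 2] * xt[, 1])
  theta <- atan2(b, a)
  scale <- sqrt(a^2 + b^2) / ss
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  translation <- mt - scale * as.vector(R %*% ms)
  tf <- structure(list(rotation_deg = theta * 180 / pi, scale = scale,
                       translation = translation),
                  class = "zg_similarity")
  resid <- map_endpoints(tf, source) - template
  tf$residual_rms <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' @export
print.zg_similarity <- function(x, ...) {
  cat(sprintf(
    "<zg_similarity> rotation %.2f deg, scale %.4f, translation (%.3f, %.3f)",
    x$rotation_deg, x$scale, x$translation[1], x$translation[2]))
  if (!is.null(x$residual_rms)) cat(sprintf(", residual %.4g", x$residual_rms))
  cat("\n")
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform A `zg_similarity` from [procrustes_fit()].
#' @param points n x 2 matrix (or length-2 vector) of points.
#' @return Transformed points, same shape as the input.
#' @export
map_endpoints <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 2) else as.matrix(points)
  th <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- transform$scale * p %*% t(R)
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  if (vec) as.vector(out) else out
}

#' Invert a similarity transform
#'
#' @param transform A `zg_similarity`.
#' @return The inverse `zg_similarity`.
#' @export
invert_transform <- function(transform) {
  th <- -transform$rotation_deg * pi / 180
  s <- 1 / transform$scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  structure(list(rotation_deg = -transform$rotation_deg, scale = s,
                 translation = as.vector(-s * R %*% transform$translation)),
            class = "zg_similarity")
}

#' Select events mappable onto the template face
#'
#' Applies the inclusion filters for endpoint mapping: saccades are kept if
#' their endpoint lies inside the 3x3-degree window centered on the trial's
#' target; microsaccades are kept only if both their start and end lie
#' inside the window.  The boundary is closed (points exactly on the edge
#' are included).
#'
#' @param trial One trial row (with `target_x`, `target_y`) or a trial log;
#'   with a log, events are matched to trials by `trial_id`.
#' @param events Event table with `x_start`, `y_start`, `x_end`, `y_end`,
#'   `class`, and `trial_id` when `trial` is a log.
#' @param target_window Window side, degrees.
#' @return The filtered event table.
#' @export
select_mappable_events <- function(trial, events, target_window = 3) {
  half <- target_window / 2 + 1e-9
  if (nrow(trial) == 1 && !"trial_id" %in% names(events)) {
    tx <- rep(trial$target_x, nrow(events))
    ty <- rep(trial$target_y, nrow(events))
  } else {
    m <- match(events$trial_id, trial$trial_id)
    tx <- trial$target_x[m]; ty <- trial$target_y[m]
  }
  end_in <- abs(events$x_end - tx) <= half & abs(events$y_end - ty) <= half
  start_in <- abs(events$x_start - tx) <= half & abs(events$y_start - ty) <= half
  keep <- ifelse(events$class == "microsaccade", end_in & start_in, end_in)
  keep[is.na(keep)] <- FALSE
  events[keep, , drop = FALSE]
}

## the 13-cell discrete disk within a 5x5 window (Euclidean radius <= 2)
zg_disk_kernel <- function(radius_px = 2) {
  o <- expand.grid(dx = -radius_px:radius_px, dy = -radius_px:radius_px)
  o <- o[o$dx^2 + o$dy^2 <= radius_px^2, ]
  o$w <- 1 / nrow(o)
  o
}

#' Template-space grid
#'
#' Pixel grid covering the template face, at the template pixel pitch
#' (22 deg / 1440 px by default, so a 5-pixel kernel subtends ~0.076 deg).
#'
#' @param xlim,ylim Grid extents in degrees.
#' @param pitch_deg Degrees per pixel.
#' @return List `xlim`, `ylim`, `pitch_deg`, `nx`, `ny` (class `zg_grid`).
#' @export
heatmap_grid <- function(xlim = c(-1.8, 1.8), ylim = c(-1.8, 1.8),
                         pitch_deg = 22 / 1440) {
  nx <- as.integer(ceiling(diff(xlim) / pitch_deg))
  ny <- as.integer(ceiling(diff(ylim) / pitch_deg))
  structure(list(xlim = xlim, ylim = ylim, pitch_deg = pitch_deg,
                 nx = nx, ny = ny), class = "zg_grid")
}

#' Smoothed endpoint-frequency map
#'
#' Bins points on a template-space pixel grid and convolves the counts with
#' a normalized 5x5-pixel disk kernel (the 13 cells within Euclidean radius
#' 2, each weighted 1/13).  Under zero padding the map mass equals the
#' number of binned points minus the mass smoothed across the grid edge,
#' which is reported.
#'
#' @param points n x 2 matrix of template-space points (degrees).
#' @param grid A [heatmap_grid()].
#' @param disk_radius_px Kernel radius in pixels.
#' @return Object of class `zg_heatmap`: list with `density` (ny x nx
#'   matrix; rows indexed by y from `ylim[1]` upward), `grid`, `n_points`
#'   (points falling on the grid), `boundary_loss` (kernel mass lost over
#'   the edge), `n_outside` (points off the grid).
#' @export
endpoint_heatmap <- function(points, grid = heatmap_grid(),
                             disk_radius_px = 2) {
  p <- as.matrix(points)
  if (length(p) == 0) p <- matrix(numeric(0), 0, 2)
  ix <- floor((p[, 1] - grid$xlim[1]) / grid$pitch_deg) + 1L
  iy <- floor((p[, 2] - grid$ylim[1]) / grid$pitch_deg) + 1L
  ok <- which(ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny)
  counts <- matrix(0, grid$ny, grid$nx)
  if (length(ok)) {
    tb <- table(factor(iy[ok], levels = seq_len(grid$ny)),
                factor(ix[ok], levels = seq_len(grid$nx)))
    counts <- matrix(as.numeric(tb), grid$ny, grid$nx)
  }
  ker <- zg_disk_kernel(disk_radius_px)
  sm <- matrix(0, grid$ny, grid$nx)
  for (k in seq_len(nrow(ker))) {
    dx <- ker$dx[k]; dy <- ker$dy[k]
    sx <- max(1, 1 + dx):min(grid$nx, grid$nx + dx)
    sy <- max(1, 1 + dy):min(grid$ny, grid$ny + dy)
    sm[sy, sx] <- sm[sy, sx] + ker$w[k] * counts[sy - dy, sx - dx]
  }
  structure(list(density = sm, grid = grid, n_points = length(ok),
                 boundary_loss = length(ok) - sum(sm),
                 n_outside = nrow(p) - length(ok)),
            class = "zg_heatmap")
}

#' @export
print.zg_heatmap <- function(x, ...) {
  cat(sprintf(
    "<zg_heatmap> %d x %d px, %d points (%d off-grid), boundary loss %.4g\n",
    x$grid$ny, x$grid$nx, x$n_points, x$n_outside, x$boundary_loss))
  invisible(x)
}

#' @export
plot.zg_heatmap <- function(x, template = NULL, ...) {
  gx <- x$grid$xlim[1] + (seq_len(x$grid$nx) - 0.5) * x$grid$pitch_deg
  gy <- x$grid$ylim[1] + (seq_len(x$grid$ny) - 0.5) * x$grid$pitch_deg
  image(gx, gy, t(x$density), col = hcl.colors(64, "viridis"),
        xlab = "x (deg)", ylab = "y (deg)", asp = 1, ...)
  if (!is.null(template)) {
    points(template$landmarks[, 1], template$landmarks[, 2], pch = 3,
           col = "white")
  }
  invisible(x)
}

#' Fit a 2D Gaussian to endpoints
#'
#' Maximum-likelihood mean and covariance of raw endpoint data, with a
#' normalized density evaluable on a grid.
#'
#' @param points n x 2 matrix, n >= 3 and not collinear.
#' @return Object of class `zg_gauss2d`: list with `mean`, `cov`, `n`, and
#'   `density(x, y)` - a vectorized bivariate normal density function.
#' @export
fit_endpoint_gaussian <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3) stop("need at least 3 points for a 2D Gaussian fit")
  mu <- colMeans(p)
  S <- cov(p) * (nrow(p) - 1) / nrow(p)      # ML covariance
  dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(dt) || dt < 1e-12) {
    stop("singular endpoint covariance (collinear points); ",
         "consider jittering the points")
  }
  Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / dt
  dens <- function(x, y) {
    dx <- x - mu[1]; dy <- y - mu[2]
    q <- Sinv[1, 1] * dx^2 + 2 * Sinv[1, 2] * dx * dy + Sinv[2, 2] * dy^2
    exp(-q / 2) / (2 * pi * sqrt(dt))
  }
  structure(list(mean = mu, cov = S, n = nrow(p), density = dens),
            class = "zg_gauss2d")
}

#' @export
print.zg_gauss2d <- function(x, ...) {
  cat(sprintf("<zg_gauss2d> n = %d, mean (%.3f, %.3f), sd (%.3f, %.3f), cor %.3f\n",
              x$n, x$mean[1], x$mean[2], sqrt(x$cov[1, 1]), sqrt(x$cov[2, 2]),
              x$cov[1, 2] / sqrt(x$cov[1, 1] * x$cov[2, 2])))
  invisible(x)
}

#' Compare two landing-distribution maps
#'
#' Normalizes both maps to unit mass and reports their cosine similarity
#' ("normalized correlation": 1 for identical shapes, 0 for disjoint
#' support) and the L1 (total-variation style) distance between the
#' unit-mass maps, in `[0, 1]`.  Symmetric in its arguments.
#'
#' @param map_a,map_b `zg_heatmap` objects (or matrices) on a common grid.
#' @return List `correlation`, `l1_distance`.
#' @export
compare_landing_distributions <- function(map_a, map_b) {
  a <- if (inherits(map_a, "zg_heatmap")) map_a$density else as.matrix(map_a)
  b <- if (inherits(map_b, "zg_heatmap")) map_b$density else as.matrix(map_b)
  if (!all(dim(a) == dim(b))) stop("maps must share a common grid")
  if (sum(a) <= 0 || sum(b) <= 0) stop("zero-mass map")
  a <- a / sum(a); b <- b / sum(b)
  list(correlation = sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
       l1_distance = sum(abs(a - b)) / 2)
}

#' Map a session's endpoints into template-face space
#'
#' For each trial, fits the Procrustes similarity transform from the trial's
#' 7 landmarks to the template matching the trial's orientation, filters
#' events with [select_mappable_events()], and maps saccade endpoints and
#' microsaccade endpoints into template space.
#'
#' @param trials Trial log with landmark coordinate columns (`hair_top_x`,
#'   ..., `chin_bottom_y`) and `orientation`.
#' @param events Event table with `trial_id` assigned (ground truth carries
#'   it; for detected events use [assign_events_to_trials()]).
#' @param face_height Face height in degrees (template geometry).
#' @param target_window Window side for the inclusion filters.
#' @param feature_frame When `TRUE`, inverted-trial endpoints are flipped
#'   vertically after mapping so that all points share the canonical upright
#'   template's feature coordinates (eyes up) - the convention needed to
#'   compare landing distributions across orientations, and the one used to
#'   display inverted-face maps.
#' @return List of class `zg_mapped`: data frames `saccades` and
#'   `microsaccades` (`trial_id`, `x`, `y` in template degrees,
#'   `orientation`), per-trial `residuals` (Procrustes RMS), and the
#'   templates used.
#' @export
map_session_endpoints <- function(trials, events, face_height = 3,
                                  target_window = 3, feature_frame = FALSE) {
  tpl <- list(upright = template_face(face_height, "upright"),
              inverted = template_face(face_height, "inverted"))
  ev <- select_mappable_events(trials, events, target_window)
  sac_rows <- list(); mic_rows <- list()
  resid <- numeric(nrow(trials))
  lm_cols_x <- paste0(zg_landmark_names, "_x")
  lm_cols_y <- paste0(zg_landmark_names, "_y")
  for (i in seq_len(nrow(trials))) {
    tid <- trials$trial_id[i]
    evi <- ev[ev$trial_id == tid, , drop = FALSE]
    ori <- trials$orientation[i]
    src <- cbind(as.numeric(trials[i, lm_cols_x]),
                 as.numeric(trials[i, lm_cols_y]))
    tf <- procrustes_fit(src, tpl[[ori]]$landmarks)
    resid[i] <- tf$residual_rms
    if (nrow(evi) == 0) next
    pts <- map_endpoints(tf, cbind(evi$x_end, evi$y_end))
    if (feature_frame && ori == "inverted") pts[, 2] <- -pts[, 2]
    d <- data.frame(trial_id = tid, x = pts[, 1], y = pts[, 2],
                    orientation = ori)
    sac_rows[[length(sac_rows) + 1L]] <- d[evi$class == "saccade", ]
    mic_rows[[length(mic_rows) + 1L]] <- d[evi$class == "microsaccade", ]
  }
  empty <- data.frame(trial_id = integer(0), x = numeric(0), y = numeric(0),
                      orientation = character(0))
  structure(list(
    saccades = if (length(sac_rows)) do.call(rbind, sac_rows) else empty,
    microsaccades = if (length(mic_rows)) do.call(rbind, mic_rows) else empty,
    residuals = data.frame(trial_id = trials$trial_id, residual_rms = resid),
    templates = tpl), class = "zg_mapped")
}

#' Assign detected events to trials
#'
#' Labels each event with the trial whose `[onset, next onset)` interval
#' (within the same subject and block) contains the event onset.
#'
#' @param trials Trial log.
#' @param events Event table without `trial_id`.
#' @return `events` with a `trial_id` column (`NA` for events before the
#'   first trial of a block).
#' @export
assign_events_to_trials <- function(trials, events) {
  tsub <- zg_subject_of(trials); esub <- zg_subject_of(events)
  events$trial_id <- NA_integer_
  for (s in unique(tsub)) {
    for (b in unique(trials$block[tsub == s])) {
      trs <- which(tsub == s & trials$block == b)
      trs <- trs[order(trials$onset_ms[trs])]
      evs <- which(esub == s &
                     (if ("block" %in% names(events)) events$block == b else TRUE))
      if (!length(evs)) next
      k <- findInterval(events$onset_ms[evs], trials$onset_ms[trs])
      ok <- k >= 1
      events$trial_id[evs[ok]] <- trials$trial_id[trs[k[ok]]]
    }
  }
  events
}
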