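## Canonical face geometry and the template face.
##
## Seven named landmarks on a face of height `face_height` degrees, expressed
## relative to the face center (x rightward, y upward).  The proportions are a
## stylized frontal face; any 7-point template can be supplied instead.

zg_landmark_names <- c("hair_top", "forehead_top", "eye_left", "eye_right",
                       "nose_tip", "mouth_center", "chin_bottom")

## landmark positions for a face of height 3 deg, face center at origin
zg_canonical_landmarks <- function(face_height = 3) {
  s <- face_height / 3
  m <- rbind(
    hair_top     = c(0.00,  1.50),
    forehead_top = c(0.00,  1.05),
    eye_left     = c(-0.45, 0.45),
    eye_right    = c(0.45,  0.45),
    nose_tip     = c(0.00, -0.15),
    mouth_center = c(0.00, -0.70),
    chin_bottom  = c(0.00, -1.50)
  ) * s
  colnames(m) <- c("x", "y")
  m
}

## endpoint-anchor mixture weights over the 7 landmarks; upright gazes favor
## the eyes/forehead, inverted gazes the nose/mouth/chin (weights sum to 1)
zg_landmark_weights <- function(orientation = c("upright", "inverted")) {
  orientation <- match.arg(orientation)
  w <- if (orientation == "upright") {
    c(0.02, 0.18, 0.27, 0.27, 0.16, 0.07, 0.03)
  } else {
    ## nose/mouth-heavy: the chin sits on the window edge, so weight there
    ## would largely be cut away by the inclusion filter
    c(0.02, 0.05, 0.09, 0.09, 0.30, 0.35, 0.10)
  }
  names(w) <- zg_landmark_names
  w
}

#' Template face
#'
#' The canonical 7-landmark template onto which movement endpoints are mapped.
#' Landmarks are expressed in degrees relative to the face center.  For the
#' inverted condition the template is flipped vertically: a similarity
#' transform without reflection cannot map an upside-down face onto the
#' upright template, so each trial is mapped onto the template matching its
#' orientation.
#'
#' @param face_height Face height in degrees.
#' @param orientation `"upright"` or `"inverted"`.
#' @return An object of class `zg_template_face`: a list with `landmarks`
#'   (7 x 2 matrix, rows named `hair_top`, `forehead_top`, `eye_left`,
#'   `eye_right`, `nose_tip`, `mouth_center`, `chin_bottom`), `pitch_deg`
#'   (degrees per template pixel, default 22/1440), `face_height` and
#'   `orientation`.
#' @export
#' @examples
#' template_face()$landmarks
template_face <- function(face_height = 3,
                          orientation = c("upright", "inverted")) {
  orientation <- match.arg(orientation)
  lm <- zg_canonical_landmarks(face_height)
  if (orientation == "inverted") lm[, "y"] <- -lm[, "y"]
  structure(list(landmarks = lm,
                 pitch_deg = 22 / 1440,
                 face_height = face_height,
                 orientation = orientation),
            class = "zg_template_face")
}

#' @export
print.zg_template_face <- function(x, ...) {
  cat(sprintf("<zg_template_face> %s, height %g deg, pitch %.5f deg/px\n",
              x$orientation, x$face_height, x$pitch_deg))
  print(round(x$landmarks, 3))
  invisible(x)
}

## trial-specific landmark set: canonical geometry (flipped when inverted),
## slightly scaled/rotated/jittered per trial, centered on the target;
## clamped so all landmarks stay inside the face bounding box
zg_trial_landmarks <- function(center, orientation, face_height = 3,
                               scale_range = c(0.9, 1.0),
                               rot_sd_deg = 2, jitter_sd = 0.03) {
  lm <- zg_canonical_landmarks(face_height)
  if (orientation == "inverted") lm[, 2] <- -lm[, 2]
  sc <- runif(1, scale_range[1], scale_range[2])
  th <- rnorm(1, 0, rot_sd_deg) * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lm <- sc * lm %*% t(R)
  lm <- lm + matrix(rnorm(length(lm), 0, jitter_sd), ncol = 2)
  half <- face_height / 2
  lm[] <- pmin(pmax(lm, -half), half)
  lm[, 1] <- lm[, 1] + center[1]
  lm[, 2] <- lm[, 2] + center[2]
  colnames(lm) <- c("x", "y")
  rownames(lm) <- zg_landmark_names
  lm
}

#' Counterbalance orderings of the four conditions
#'
#' All orderings of the 4 task conditions (scene/no-scene crossed with
#' upright/inverted), used to counterbalance block order across subjects:
#' subject s runs ordering `((s - 1) mod 24) + 1`, repeated over the second
#' half of the session's blocks.
#'
#' @return A 24 x 4 integer matrix; entries index the rows of the internal
#'   condition table (scene/upright, scene/inverted, no-scene/upright,
#'   no-scene/inverted).
#' @export
#' @examples
#' nrow(condition_orderings())  # 4! = 24
condition_orderings <- function() {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perms(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  perms(1:4)
}

zg_conditions <- function() {
  data.frame(condition = rep(c("scene", "no_scene"), each = 2),
             orientation = rep(c("upright", "inverted"), 2),
             stringsAsFactors = FALSE)
}
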