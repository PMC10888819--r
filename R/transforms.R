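# 2D rigid/affine transform algebra and image resampling.
#
# Coordinate convention: pixel indices are 0-based (x = column, y = row),
# with y increasing down the image. A transform acts on points as
#   p' = R(theta) (p - c) + c + t
# where c is the rotation centre (default: image centre), t = (tx, ty) in
# pixels and R(theta) rotates counterclockwise in the (x, y) frame by
# `rotation` degrees. Physical coordinates are index * spacing.

#' Rigid 2D transform
#'
#' @slot rotation rotation angle in degrees (counterclockwise).
#' @slot tx,ty translation in pixels.
#' @slot center rotation centre, numeric length 2 (x, y), 0-based pixels.
#' @export
setClass("RigidTransform2D",
  representation(rotation = "numeric", tx = "numeric", ty = "numeric",
                 center = "numeric"),
  prototype(rotation = 0, tx = 0, ty = 0, center = c(0, 0)),
  validity = function(object) {
    if (length(object@center) != 2L) return("center must have length 2")
    if (anyNA(c(object@rotation, object@tx, object@ty, object@center)))
      return("transform parameters must be finite")
    TRUE
  })

#' Construct a rigid 2D transform
#'
#' @param rotation Rotation in degrees, counterclockwise about `center`.
#' @param tx,ty Translation in pixels (x = column, y = row).
#' @param center Rotation centre `(x, y)` in 0-based pixel coordinates.
#' @return A [RigidTransform2D-class] object.
#' @export
rigidTransform <- function(rotation = 0, tx = 0, ty = 0, center = c(0, 0)) {
  methods::new("RigidTransform2D", rotation = rotation, tx = tx, ty = ty,
               center = as.numeric(center))
}

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: rotation %.3f deg, t = (%.2f, %.2f) px, centre (%.1f, %.1f)\n",
              object@rotation, object@tx, object@ty,
              object@center[1], object@center[2]))
})

rotationMatrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# General form p' = R p + b of a centred rigid transform.
.rigidGeneral <- function(tf) {
  R <- rotationMatrix(tf@rotation)
  b <- tf@center - R %*% tf@center + c(tf@tx, tf@ty)
  list(R = R, b = as.numeric(b))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `inner` first, then
#' `outer`. The result is expressed about the centre of `outer`.
#'
#' @param outer,inner [RigidTransform2D-class] objects.
#' @return A [RigidTransform2D-class].
#' @export
composeTransform <- function(outer, inner) {
  go <- .rigidGeneral(outer); gi <- .rigidGeneral(inner)
  R <- go$R %*% gi$R
  b <- as.numeric(go$R %*% gi$b + go$b)
  rot <- outer@rotation + inner@rotation
  cen <- outer@center
  t <- b - cen + as.numeric(R %*% cen)
  rigidTransform(rot, t[1], t[2], cen)
}

#' Invert a rigid transform
#'
#' @param tf A [RigidTransform2D-class].
#' @return The inverse transform, about the same centre.
#' @export
invertTransform <- function(tf) {
  g <- .rigidGeneral(tf)
  Ri <- t(g$R)
  bi <- as.numeric(-Ri %*% g$b)
  cen <- tf@center
  t <- bi - cen + as.numeric(Ri %*% cen)
  rigidTransform(-tf@rotation, t[1], t[2], cen)
}

#' Apply a rigid transform to points
#'
#' @param tf A [RigidTransform2D-class].
#' @param pts Numeric matrix with columns (x, y), 0-based pixels.
#' @return Transformed point matrix of the same shape.
#' @export
transformPoints <- function(tf, pts) {
  pts <- rbind(pts)  # accept a bare length-2 vector
  g <- .rigidGeneral(tf)
  out <- t(g$R %*% t(pts)) + matrix(g$b, nrow(pts), 2, byrow = TRUE)
  dimnames(out) <- dimnames(pts)
  out
}

#' Image centre in 0-based pixel coordinates
#'
#' @param img matrix or array.
#' @return Numeric `(x, y)` centre.
#' @export
imageCenter <- function(img) {
  d <- dim(img)
  c((d[2] - 1) / 2, (d[1] - 1) / 2)  # (x, y)
}

# Bilinear / nearest-neighbour sampling of `img` (matrix) at fractional
# 0-based coordinates. Out-of-frame positions take `background`.
.sampleAt <- function(img, xs, ys, interp, background) {
  H <- nrow(img); W <- ncol(img)
  if (interp == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    out <- rep(background, length(xs))
    out[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    return(out)
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- rep(as.numeric(background), length(xs))
  ok <- x0 >= -1 & x0 <= W - 1 & y0 >= -1 & y0 <= H - 1
  gx0 <- pmin(pmax(x0, 0), W - 1); gx1 <- pmin(pmax(x0 + 1, 0), W - 1)
  gy0 <- pmin(pmax(y0, 0), H - 1); gy1 <- pmin(pmax(y0 + 1, 0), H - 1)
  # clamp-at-border sampling; fully outside handled by `ok`
  v00 <- img[cbind(gy0 + 1, gx0 + 1)]
  v01 <- img[cbind(gy0 + 1, gx1 + 1)]
  v10 <- img[cbind(gy1 + 1, gx0 + 1)]
  v11 <- img[cbind(gy1 + 1, gx1 + 1)]
  vals <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  strictly <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
  out[ok & strictly] <- vals[ok & strictly]
  out
}

#' Resample an image under a rigid transform
#'
#' Produces the image whose content has been moved by `tf`: output pixel
#' p takes the value of the input at `invertTransform(tf)` applied to p.
#' RGB arrays are resampled per channel; label rasters should use
#' `interp = "nearest"` so the label vocabulary is preserved exactly.
#'
#' @param img Matrix (grayscale/labels) or H x W x C array.
#' @param tf A [RigidTransform2D-class].
#' @param interp `"bilinear"` or `"nearest"`.
#' @param background Fill value for out-of-frame pixels.
#' @return Resampled image, same shape as `img`.
#' @export
resampleRigid <- function(img, tf, interp = c("bilinear", "nearest"),
                          background = 0) {
  interp <- match.arg(interp)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  inv <- invertTransform(tf)
  g <- .rigidGeneral(inv)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  sx <- g$R[1, 1] * xs + g$R[1, 2] * ys + g$b[1]
  sy <- g$R[2, 1] * xs + g$R[2, 2] * ys + g$b[2]
  if (length(d) == 2L) {
    out <- matrix(.sampleAt(img, sx, sy, interp, background), H, W)
  } else {
    out <- array(0, d)
    for (ch in seq_len(d[3]))
      out[, , ch] <- matrix(.sampleAt(img[, , ch], sx, sy, interp, background), H, W)
  }
  out
}

#' Resample an image under a 6-parameter affine transform
#'
#' The transform acts about a centre: `p' = A (p - c) + c + t`, with
#' `par = (a11, a12, a21, a22, tx, ty)`.
#'
#' @param img matrix or H x W x C array.
#' @param par numeric length 6.
#' @param center transform centre (x, y), 0-based pixels.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param background fill value outside the frame.
#' @return Resampled image.
#' @export
resampleAffine <- function(img, par, center = imageCenter(img),
                           interp = "bilinear", background = 0) {
  A <- matrix(par[1:4], 2, 2, byrow = TRUE)
  t <- par[5:6]
  Ai <- solve(A)
  d <- dim(img); H <- d[1]; W <- d[2]
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  # inverse map: p = Ai (p' - c - t) + c
  dx <- xs - center[1] - t[1]
  dy <- ys - center[2] - t[2]
  sx <- Ai[1, 1] * dx + Ai[1, 2] * dy + center[1]
  sy <- Ai[2, 1] * dx + Ai[2, 2] * dy + center[2]
  if (length(d) == 2L) {
    matrix(.sampleAt(img, sx, sy, interp, background), H, W)
  } else {
    out <- array(0, d)
    for (ch in seq_len(d[3]))
      out[, , ch] <- matrix(.sampleAt(img[, , ch], sx, sy, interp, background), H, W)
    out
  }
}

# Compose two affine parameter vectors (about a shared centre):
# result applies `inner` first, then `outer`.
composeAffinePar <- function(outer, inner) {
  Ao <- matrix(outer[1:4], 2, 2, byrow = TRUE)
  Ai <- matrix(inner[1:4], 2, 2, byrow = TRUE)
  A <- Ao %*% Ai
  t <- as.numeric(Ao %*% inner[5:6]) + outer[5:6]
  c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t)
}
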