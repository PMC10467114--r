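#' Elementary rotation matrices
#'
#' Right-handed rotations about the x, y and z axes, taking angles in
#' degrees. The composed convention used throughout the package is
#' Tait-Bryan Z-Y-X: `R = Rz(phi) %*% Ry(theta) %*% Rx(psi)`, so that
#' `R[3,1] = -sin(theta)`, `R[3,2] = cos(theta) sin(psi)` and
#' `R[3,3] = cos(theta) cos(psi)`.
#'
#' @param deg angle in degrees
#' @return 3x3 rotation matrix
#' @export
rot_x <- function(deg) {
  r <- deg * pi / 180; c_ <- cos(r); s <- sin(r)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  r <- deg * pi / 180; c_ <- cos(r); s <- sin(r)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  r <- deg * pi / 180; c_ <- cos(r); s <- sin(r)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

.is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' Least-squares (Kabsch) superposition of one point set onto another
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (weighted) RMSD of `R x + t` over paired points, via SVD of the
#' cross-covariance matrix with the reflection branch corrected to
#' `det(R) = +1`.
#'
#' @param mobile `n x 3` matrix of coordinates to move (nm)
#' @param reference `n x 3` matrix of target coordinates (nm)
#' @param weights optional non-negative per-point weights
#' @return list of class `kabsch_fit` with elements `R` (3x3 rotation
#'   acting on column vectors), `t` (length-3 translation, nm) and `rmsd`
#'   (minimised value, nm). `R %*% t(mobile) + t` approximates
#'   `t(reference)`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("pairing error: mobile and reference must have equal dimensions")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate body: need >= 3 paired atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  P <- sweep(reference, 2, cr)
  if (qr(M)$rank < 2 || qr(P)$rank < 2)
    stop("degenerate body: collinear point set, rotation underdetermined")
  H <- t(M * w) %*% P              # 3x3 cross-covariance (mobile -> reference)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- M %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - P)^2)))
  structure(list(R = R, t = t_vec, rmsd = rmsd), class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat("Kabsch superposition: rmsd =", format(x$rmsd, digits = 6), "nm\n")
  invisible(x)
}

#' Euler (Tait-Bryan) angles from a rotation matrix
#'
#' Decomposes a proper rotation under the Z-Y-X convention
#' `R = Rz(phi) %*% Ry(theta) %*% Rx(psi)` and reports only the tilt pair:
#' `theta = -asin(R31)` (rotation about y, degrees in \[-90, 90\]) and
#' `psi = atan2(R32 / cos(theta), R33 / cos(theta))` (rotation about x,
#' degrees in (-180, 180\]). The rotation about z is deliberately not
#' reported: for a membrane-tethered body it is rotation about the membrane
#' normal and carries no orientational information. At gimbal lock
#' (`|cos(theta)| < gimbal_tol`, i.e. theta near +/-90 deg) psi and phi are
#' not separable; psi is set to 0 and the pose flagged.
#'
#' @param R 3x3 proper rotation matrix
#' @param gimbal_tol tolerance on `|cos(theta)|` below which the pose is
#'   flagged as gimbal-locked (default 1e-6)
#' @return list with `theta`, `psi` (degrees) and logical `gimbal`
#' @export
euler_from_rotation <- function(R, gimbal_tol = 1e-6) {
  if (!.is_rotation(R))
    stop("invariant violation: input is not a proper rotation matrix")
  s <- min(1, max(-1, R[3, 1]))
  theta <- -asin(s)
  ct <- cos(theta)
  if (abs(ct) < gimbal_tol) {
    return(list(theta = theta * 180 / pi, psi = 0, gimbal = TRUE))
  }
  psi <- atan2(R[3, 2] / ct, R[3, 3] / ct)
  list(theta = theta * 180 / pi, psi = psi * 180 / pi, gimbal = FALSE)
}
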