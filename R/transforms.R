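# Rigid resampling of images and volumes. The forward map
#   T(p) = R(theta) (p - c) + c + t
# moves anatomy; resampling produces out(q) = in(T^{-1}(q)) so that
# apply_rigid_2d(img, tf) is the image of the anatomy *after* the motion tf.

#' Apply an in-plane rigid transform to a planar image
#'
#' Resamples with bilinear interpolation; pixels mapping outside the input
#' grid receive `fill`.
#'
#' @param img a [planar_image].
#' @param tf a [rigid2d]. Its `center_mm` is the rotation center.
#' @param fill intensity for out-of-grid pixels.
#' @return A [planar_image] of the moved anatomy.
#' @export
apply_rigid_2d <- function(img, tf, fill = 0) {
  stopifnot(inherits(img, "planar_image"), inherits(tf, "rigid2d"))
  px <- cpp_resample2d(img$pixels, tf$dx_mm, tf$dy_mm,
                       tf$theta_deg * pi / 180,
                       tf$center_mm[1], tf$center_mm[2],
                       img$spacing_mm[1], img$spacing_mm[2], fill)
  planar_image(px, img$spacing_mm, img$plane_label)
}

#' Apply a 6-DOF rigid transform to a volume
#'
#' Trilinear resampling about `center_mm` (defaults to the volume's physical
#' center). Rotations are applied extrinsically in the order yaw (SI axis),
#' pitch (lateral axis), roll (AP axis).
#'
#' @param vol a [volume_image].
#' @param tf a [rigid3d].
#' @param center_mm rotation center (x, y, z) in mm; default volume center.
#' @param fill intensity for out-of-grid voxels.
#' @return A [volume_image] of the moved anatomy.
#' @export
apply_rigid_3d <- function(vol, tf, center_mm = NULL, fill = 0) {
  stopifnot(inherits(vol, "volume_image"), inherits(tf, "rigid3d"))
  d <- dim(vol$voxels)
  if (is.null(center_mm)) center_mm <- (d - 1) / 2 * vol$spacing_mm
  params <- c(tf$lat_mm, tf$ap_mm, tf$si_mm,
              tf$roll_deg * pi / 180, tf$pitch_deg * pi / 180,
              tf$yaw_deg * pi / 180)
  vx <- cpp_resample3d(vol$voxels, as.integer(d), vol$spacing_mm, params,
                       as.numeric(center_mm), fill)
  volume_image(array(vx, d), vol$spacing_mm, vol$modality)
}

#' Invert a rigid transform
#'
#' @param tf a [rigid2d] or [rigid3d].
#' @return The inverse transform (same class, same rotation center for 2D).
#' @export
invert_rigid <- function(tf) {
  if (inherits(tf, "rigid2d")) {
    th <- -tf$theta_deg * pi / 180
    # T^{-1}: rotation -theta about c, translation -R(-theta) t
    dx <- -(cos(th) * tf$dx_mm - sin(th) * tf$dy_mm)
    dy <- -(sin(th) * tf$dx_mm + cos(th) * tf$dy_mm)
    return(rigid2d(dx, dy, -tf$theta_deg, tf$center_mm))
  }
  stopifnot(inherits(tf, "rigid3d"))
  R <- rotation_matrix_3d(tf$roll_deg, tf$pitch_deg, tf$yaw_deg)
  t_inv <- -t(R) %*% c(tf$lat_mm, tf$ap_mm, tf$si_mm)
  ang <- angles_from_rotation_3d(t(R))
  rigid3d(t_inv[1], t_inv[2], t_inv[3], ang[1], ang[2], ang[3])
}

#' Compose two rigid 3D transforms (apply `a` first, then `b`)
#'
#' Both transforms must share the same rotation center for the composition
#' to be exact; the package always rotates volumes about their center.
#'
#' @param a,b [rigid3d] transforms.
#' @return A [rigid3d] equal to `b` after `a`.
#' @export
compose_rigid_3d <- function(a, b) {
  Ra <- rotation_matrix_3d(a$roll_deg, a$pitch_deg, a$yaw_deg)
  Rb <- rotation_matrix_3d(b$roll_deg, b$pitch_deg, b$yaw_deg)
  R <- Rb %*% Ra
  t_ab <- Rb %*% c(a$lat_mm, a$ap_mm, a$si_mm) +
    c(b$lat_mm, b$ap_mm, b$si_mm)
  ang <- angles_from_rotation_3d(R)
  rigid3d(t_ab[1], t_ab[2], t_ab[3], ang[1], ang[2], ang[3])
}

# Rotation matrix on patient axes x = lateral, y = AP, z = SI:
# R = Ry(roll) %*% Rx(pitch) %*% Rz(yaw), angles in degrees.
rotation_matrix_3d <- function(roll_deg, pitch_deg, yaw_deg) {
  r <- roll_deg * pi / 180
  p <- pitch_deg * pi / 180
  y <- yaw_deg * pi / 180
  Ry <- matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(p), sin(p), 0, -sin(p), cos(p)), 3, 3)
  Rz <- matrix(c(cos(y), sin(y), 0, -sin(y), cos(y), 0, 0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

# Recover (roll, pitch, yaw) degrees from R = Ry(roll) Rx(pitch) Rz(yaw).
# R[2,3] = -sin(pitch); R[1,3]/R[3,3] -> roll; R[2,1]/R[2,2] -> yaw.
angles_from_rotation_3d <- function(R) {
  pitch <- asin(max(-1, min(1, -R[2, 3])))
  if (abs(cos(pitch)) > 1e-9) {
    roll <- atan2(R[1, 3], R[3, 3])
    yaw <- atan2(R[2, 1], R[2, 2])
  } else {
    # gimbal: fold roll into yaw
    roll <- 0
    yaw <- atan2(-R[1, 2], R[1, 1])
  }
  c(roll, pitch, yaw) * 180 / pi
}
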