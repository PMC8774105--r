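## met_frame: canonical Met-centered frame via a two-quaternion
## construction. Convention: right-handed axes, scalar-first unit
## quaternions (w, x, y, z), active rotations; the composed rotation is
## Q2 * Q1 (Q1 applied first).

quat_axis_angle <- function(axis, angle) {
  axis <- vunit(axis)
  c(cos(angle / 2), axis * sin(angle / 2))
}

quat_identity <- function() c(1, 0, 0, 0)

quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

quat_to_rotmat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

quat_rotate <- function(q, v) {
  R <- quat_to_rotmat(q)
  if (is.matrix(v)) v %*% t(R) else as.numeric(R %*% v)
}

#' Canonical Met-frame transform
#'
#' Constructs the rigid motion that canonicalizes a methionine
#' thioether: SD is translated to the origin; a first quaternion (Q1)
#' rotates about the cross product of SD-CE and the x-axis by the angle
#' alpha between them, rendering the SD-CE bond colinear with +x; a
#' second quaternion (Q2) rotates about the x-axis by -beta, bringing
#' CG into the x,y-plane with non-negative y (the CH2 arm along +y).
#' Aromatic centroids are mapped with the composition Q2 * Q1.
#'
#' @param met A `MetSite` with non-collinear CG, SD, CE.
#' @return A `FrameTransform`: `translation` (equal to -SD),
#'   `alpha_rad`, `beta_rad`, unit quaternions `q1`, `q2`, `composed`,
#'   and the 3 x 3 `rotation` matrix of the composition.
#' @export
met_frame_transform <- function(met) {
  stopifnot(inherits(met, "MetSite"))
  v <- met$ce - met$sd
  g <- met$cg - met$sd
  wedge <- vangle(v, g)
  if (wedge < pi / 180 || wedge > pi - pi / 180)
    stop("degenerate CG-SD-CE geometry (collinear) in ",
         residue_label(met$ref$chain_id, met$ref$residue_number,
                       met$ref$insertion_code, met$ref$residue_name),
         " of ", met$structure_id)

  xhat <- c(1, 0, 0)
  alpha <- vangle(v, xhat)
  axis1 <- vcross(v, xhat)
  if (vnorm(axis1) < 1e-12) {
    # SD-CE already along +/- x: identity, or a fixed half-turn about z
    q1 <- if (v[1L] > 0) quat_identity() else quat_axis_angle(c(0, 0, 1), pi)
  } else {
    q1 <- quat_axis_angle(axis1, alpha)
  }

  g1 <- quat_rotate(q1, g)
  beta <- atan2(g1[3L], g1[2L])
  q2 <- quat_axis_angle(xhat, -beta)
  composed <- quat_multiply(q2, q1)

  tf <- list(translation = -met$sd, alpha_rad = alpha, beta_rad = beta,
             q1 = q1, q2 = q2, composed = composed,
             rotation = quat_to_rotmat(composed))
  class(tf) <- "FrameTransform"
  tf
}

#' Apply a frame transform to points
#'
#' Each point is translated (SD to the origin) and then rotated by the
#' composed quaternion. Rigid: all pairwise distances are preserved.
#'
#' @param transform A `FrameTransform`.
#' @param points A 3-vector or an n x 3 matrix.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_frame <- function(transform, points) {
  stopifnot(inherits(transform, "FrameTransform"))
  R <- transform$rotation
  if (is.matrix(points)) {
    sweep(points, 2L, -transform$translation) %*% t(R)
  } else {
    as.numeric(R %*% (points + transform$translation))
  }
}

#' Map a bridge cluster into the canonical Met frame
#'
#' Applies the cluster Met's frame transform to every partner centroid.
#' The Met atoms themselves are not emitted: in the canonical frame
#' they are implicit (SD at the origin, CE on +x, CG in the x,y-plane).
#'
#' @param cluster A `BridgeCluster`.
#' @return A data frame of local-frame points: `residue_type`, `x`,
#'   `y`, `z`, plus source identifiers (`structure_id`, Met and
#'   aromatic residue identities).
#' @export
cluster_to_local_frame <- function(cluster) {
  stopifnot(inherits(cluster, "BridgeCluster"))
  tf <- tryCatch(met_frame_transform(cluster$met), error = function(e)
    stop("cluster on Met ",
         residue_label(cluster$met$ref$chain_id,
                       cluster$met$ref$residue_number,
                       cluster$met$ref$insertion_code),
         " of ", cluster$structure_id, ": ", conditionMessage(e),
         call. = FALSE))
  centroids <- do.call(rbind, lapply(cluster$partners, `[[`, "centroid"))
  local <- apply_frame(tf, centroids)
  data.frame(
    residue_type = vapply(cluster$partners, `[[`, character(1L), "resname"),
    x = local[, 1L], y = local[, 2L], z = local[, 3L],
    structure_id = cluster$structure_id,
    met_chain = cluster$met$ref$chain_id,
    met_number = cluster$met$ref$residue_number,
    aromatic_chain = vapply(cluster$partners, function(p) p$ref$chain_id,
                            character(1L)),
    aromatic_number = vapply(cluster$partners, function(p)
      p$ref$residue_number, integer(1L)),
    stringsAsFactors = FALSE
  )
}

#' Local-frame table for many clusters
#'
#' Row-binds [cluster_to_local_frame()] over a cluster list; clusters
#' with degenerate Met geometry are dropped with a warning.
#'
#' @param clusters List of `BridgeCluster`.
#' @return A data frame (possibly zero rows).
#' @export
local_frame_table <- function(clusters) {
  rows <- lapply(clusters, function(cl)
    tryCatch(cluster_to_local_frame(cl), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    }))
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(residue_type = character(), x = numeric(),
                      y = numeric(), z = numeric(),
                      structure_id = character(), met_chain = character(),
                      met_number = integer(), aromatic_chain = character(),
                      aromatic_number = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
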