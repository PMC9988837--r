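# Per-landmark effect summaries: surface normals, signed normal
# displacement (magnitude of inward/outward shape change), angle differences
# (direction of shape change), the maximum ancestry shift across
# individuals, and the comparison of genetic-PC versus consensus correction.

#' Area-weighted vertex normals of a landmark surface
#'
#' Averages the (area-weighted) normals of the triangles incident to each
#' vertex and normalizes. With the template's counter-clockwise winding the
#' normals point outward (+z for the synthetic template).
#'
#' @param face `L x 3` configuration.
#' @param triangulation Integer `F x 3` matrix of 1-based vertex triples.
#' @return `L x 3` matrix of unit normals.
#' @export
vertex_normals <- function(face, triangulation) {
  L <- nrow(face)
  tr <- triangulation
  v1 <- face[tr[, 2L], , drop = FALSE] - face[tr[, 1L], , drop = FALSE]
  v2 <- face[tr[, 3L], , drop = FALSE] - face[tr[, 1L], , drop = FALSE]
  # cross product rows: length = 2 * triangle area (area weighting built in)
  fn <- cbind(v1[, 2L] * v2[, 3L] - v1[, 3L] * v2[, 2L],
              v1[, 3L] * v2[, 1L] - v1[, 1L] * v2[, 3L],
              v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L])
  areas <- sqrt(rowSums(fn^2))
  if (any(areas == 0)) {
    warning(sum(areas == 0), " zero-area triangle(s) skipped")
    fn <- fn[areas > 0, , drop = FALSE]
    tr <- tr[areas > 0, , drop = FALSE]
  }
  normals <- matrix(0, L, 3L)
  for (corner in 1:3) {
    idx <- tr[, corner]
    for (d in 1:3)
      normals[, d] <- normals[, d] +
        unname(tapply(fn[, d], factor(idx, levels = seq_len(L)),
                      sum, default = 0))
  }
  normals[is.na(normals)] <- 0
  nrm <- sqrt(rowSums(normals^2))
  if (any(nrm == 0))
    stop("isolated vertex (no incident triangles with area): index ",
         which(nrm == 0)[1L])
  normals / nrm
}

#' Signed normal displacement between two faces
#'
#' Per landmark, the component of `face_b - face_a` along the supplied unit
#' normal: positive values are outward movement, negative inward.
#'
#' @param face_a,face_b `L x 3` configurations.
#' @param normals `L x 3` unit normals (typically of the base face).
#' @return Numeric vector of L signed displacements.
#' @export
normal_displacement <- function(face_a, face_b, normals) {
  if (!isTRUE(all.equal(rowSums(normals^2), rep(1, nrow(normals)),
                        tolerance = 1e-8)))
    stop("normals must be unit length")
  if (nrow(face_a) != nrow(face_b) || nrow(face_a) != nrow(normals))
    stop("landmark counts differ")
  rowSums((face_b - face_a) * normals)
}

#' Angle between two displacement fields, per landmark
#'
#' Arc-cosine of the cosine similarity of the two displacement vectors at
#' each landmark, in degrees within \[0, 180\]. Landmarks where either
#' vector is shorter than `eps` get angle 0 (direction undefined on static
#' landmarks).
#'
#' @param effect_a,effect_b `L x 3` displacement fields.
#' @param eps Length threshold below which a direction is undefined
#'   (default 1e-9 length units).
#' @return Numeric vector of L angles in degrees.
#' @export
angle_difference <- function(effect_a, effect_b, eps = 1e-9) {
  if (nrow(effect_a) != nrow(effect_b)) stop("landmark counts differ")
  na <- sqrt(rowSums(effect_a^2))
  nb <- sqrt(rowSums(effect_b^2))
  cosv <- rowSums(effect_a * effect_b) / (na * nb)
  cosv <- pmin(1, pmax(-1, cosv))
  ang <- acos(cosv) * 180 / pi
  ang[na < eps | nb < eps] <- 0
  ang
}

#' Maximum ancestry shift per landmark
#'
#' For matched cohorts before and after an ancestry correction, computes the
#' Euclidean distance moved by each landmark of each individual and returns
#' the per-landmark maximum over individuals.
#'
#' @param before,after `n x L x 3` arrays with matching individuals.
#' @return Numeric vector of L maximal shifts.
#' @export
max_ancestry_shift <- function(before, after) {
  if (!identical(dim(before), dim(after)))
    stop("cohorts have mismatched dimensions")
  d2 <- (before - after)^2
  dist <- sqrt(d2[, , 1L] + d2[, , 2L] + d2[, , 3L])  # n x L
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1L)
  apply(dist, 2L, max)
}

#' Compare genetic-PC and consensus correction methods per region
#'
#' For each region, expresses the genetic-PC-derived face and the
#' consensus-derived face as displacements from a shared base face and
#' summarizes their disagreement as a signed normal displacement map
#' (magnitude differences) and an angle-difference map (direction
#' differences).
#'
#' @param pc_faces Named list of `L x 3` regional faces from the genetic-PC
#'   route.
#' @param consensus_faces Named list of `L x 3` regional faces from the
#'   consensus route (same region names).
#' @param base_face `L x 3` shared reference (average) face.
#' @param triangulation Template triangulation for base-face normals.
#' @param eps Angle threshold, see [angle_difference()].
#' @return Named list per region, each with `normal_displacement` (L values,
#'   consensus minus PC along the base normals) and `angle_difference`
#'   (L degrees between the two displacement fields).
#' @export
compare_correction_methods <- function(pc_faces, consensus_faces, base_face,
                                       triangulation, eps = 1e-9) {
  if (!setequal(names(pc_faces), names(consensus_faces)))
    stop("region sets differ between the two methods")
  normals <- vertex_normals(base_face, triangulation)
  out <- lapply(names(pc_faces), function(r) {
    list(normal_displacement = normal_displacement(pc_faces[[r]],
                                                   consensus_faces[[r]],
                                                   normals),
         angle_difference = angle_difference(
           consensus_faces[[r]] - base_face,
           pc_faces[[r]] - base_face, eps = eps))
  })
  names(out) <- names(pc_faces)
  out
}
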