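#' Rigid pose of a geometry in image space
#'
#' Maps canonical-pose coordinates x to image coordinates `R x + translation`.
#'
#' @param translation Length-3 numeric, mm.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  translation <- as.numeric(translation)
  rotation <- as.matrix(rotation)
  if (length(translation) != 3) stop("rigid_pose: translation must be length 3")
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rigid_pose: rotation must be orthonormal with determinant +1")
  structure(list(translation = translation, rotation = rotation),
            class = "rigid_pose")
}

#' Rotation taking the canonical long axis (+z) to a given direction
#'
#' @param axis Target direction (length-3, need not be unit).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_to_axis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ez <- c(0, 0, 1)
  v <- c(ez[2] * a[3] - ez[3] * a[2],
         ez[3] * a[1] - ez[1] * a[3],
         ez[1] * a[2] - ez[2] * a[1])
  c_ <- sum(ez * a)
  if (c_ < -1 + 1e-12) {  # antiparallel: rotate pi about x
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Labeled voxel image
#'
#' Container for 3-D label images with labels 0 (background), 1 (cavity),
#' 2 (wall). `origin` is the position of the center of voxel (1, 1, 1).
#'
#' @param voxels 3-D integer array with values in \{0, 1, 2\}.
#' @param spacing Voxel spacing per axis, mm.
#' @param origin Center of the first voxel, mm.
#' @return An object of class `label_image`.
#' @export
label_image <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3) stop("label_image: voxels must be a 3-D array")
  if (!all(voxels %in% 0:2)) stop("label_image: labels must be in {0, 1, 2}")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("label_image: spacing must be positive")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_image %d x %d x %d, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- tabulate(x$voxels + 1L, 3)
  cat(sprintf("  background %d, cavity %d, wall %d voxels\n", tab[1], tab[2], tab[3]))
  invisible(x)
}

# classify canonical-pose points into 0/1/2 labels (vectorized)
classify_points <- function(geom, x, y, z) {
  zb <- basal_height(geom)
  rho <- sqrt(x^2 + y^2)
  lab <- integer(length(rho))
  inside_z <- z >= 0 & z <= zb
  if (any(inside_z)) {
    r_epi <- epi_radius_at_height(geom, z[inside_z])
    in_epi <- rho[inside_z] <= r_epi
    idx <- which(inside_z)[in_epi]
    lab[idx] <- 2L
    r_cav <- cavity_radius_at_height(geom, z[idx])
    cav <- !is.na(r_cav) & rho[idx] < r_cav
    lab[idx[cav]] <- 1L
  }
  lab
}

# canonical-pose bounding box (matrix 2 x 3: min row, max row)
canonical_bbox <- function(geom) {
  psi <- seq(geom$psi0, pi / 2, length.out = 257)
  rmax <- max(geom$R_b * profile_shape(geom$e, psi))
  rbind(c(-rmax, -rmax, 0), c(rmax, rmax, basal_height(geom)))
}

#' Voxelize an LV geometry into a label image
#'
#' Each voxel is assigned by the membership of its center: 0 background,
#' 1 cavity, 2 wall.
#'
#' @param geom An `lv_geometry`.
#' @param pose A `rigid_pose` mapping canonical to image coordinates
#'   (default identity).
#' @param spacing Voxel spacing per axis, mm.
#' @param margin Padding added around the geometry when building the default
#'   grid, mm.
#' @param grid Optional explicit grid: list with `dim`, `spacing`, `origin`.
#'   When supplied, an error is raised if the geometry is only partially
#'   contained; a grid that misses the geometry entirely yields all zeros.
#' @return A `label_image`.
#' @export
voxelize <- function(geom, pose = NULL, spacing = c(1, 1, 1), margin = 4,
                     grid = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("voxelize: spacing must be positive")
  if (is.null(pose)) pose <- rigid_pose()
  bb <- canonical_bbox(geom)
  corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  corners_img <- t(pose$rotation %*% t(corners) + pose$translation)
  lo <- apply(corners_img, 2, min); hi <- apply(corners_img, 2, max)
  if (is.null(grid)) {
    origin <- lo - margin + spacing / 2
    dim_ <- pmax(1L, as.integer(ceiling((hi - lo + 2 * margin) / spacing)))
  } else {
    spacing <- rep_len(as.numeric(grid$spacing), 3)
    origin <- rep_len(as.numeric(grid$origin), 3)
    dim_ <- as.integer(grid$dim)
    gmax <- origin + (dim_ - 1) * spacing
    overlap_lo <- pmax(lo, origin - spacing / 2)
    overlap_hi <- pmin(hi, gmax + spacing / 2)
    if (any(overlap_hi < overlap_lo)) {
      return(label_image(array(0L, dim_), spacing, origin))
    }
    if (any(lo < origin - spacing) || any(hi > gmax + spacing))
      stop("voxelize: grid extent too small to contain the geometry")
  }
  xs <- origin[1] + (seq_len(dim_[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim_[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim_[3]) - 1) * spacing[3]
  # image -> canonical: xc = R^T (x - t)
  n <- prod(dim_)
  X <- rep(xs, times = dim_[2] * dim_[3]) - pose$translation[1]
  Y <- rep(rep(ys, each = dim_[1]), times = dim_[3]) - pose$translation[2]
  Z <- rep(zs, each = dim_[1] * dim_[2]) - pose$translation[3]
  R <- pose$rotation
  xc <- R[1, 1] * X + R[2, 1] * Y + R[3, 1] * Z
  yc <- R[1, 2] * X + R[2, 2] * Y + R[3, 2] * Z
  zc <- R[1, 3] * X + R[2, 3] * Y + R[3, 3] * Z
  lab <- classify_points(geom, xc, yc, zc)
  label_image(array(lab, dim_), spacing, origin)
}

#' Read / write label images as NIfTI
#'
#' @param img A `label_image`.
#' @param path Output (input) file path, `.nii` or `.nii.gz`.
#' @return `write_label_image` returns `path` invisibly; `read_label_image`
#'   returns a `label_image`.
#' @export
write_label_image <- function(img, path) {
  xform <- diag(4)
  diag(xform)[1:3] <- img$spacing
  xform[1:3, 4] <- img$origin
  nii <- RNifti::asNifti(img$voxels, datatype = "int16")
  nii <- RNifti::`sform<-`(nii, structure(xform, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  nii <- RNifti::readNifti(path)
  xf <- RNifti::xform(nii)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  label_image(array(as.integer(round(as.array(nii))), dim(nii)),
              spacing = spacing,
              origin = xf[1:3, 4])
}

#' Export an LV surface as an ASCII PLY triangulation
#'
#' @param geom An `lv_geometry`.
#' @param path Output `.ply` path.
#' @param surface `"epi"` or `"endo"`.
#' @param n_psi,n_theta Sampling resolution.
#' @param pose Optional `rigid_pose`.
#' @return `path`, invisibly.
#' @export
write_surface_ply <- function(geom, path, surface = c("epi", "endo"),
                              n_psi = 40, n_theta = 48, pose = NULL) {
  surface <- match.arg(surface)
  if (is.null(pose)) pose <- rigid_pose()
  t_ <- if (surface == "epi") 1 else 0
  psi <- seq(geom$psi0, pi / 2, length.out = n_psi)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  gr <- expand.grid(psi = psi, theta = th)
  pts <- lv_point(geom, gr$psi, rep(t_, nrow(gr)), gr$theta)
  pts <- t(pose$rotation %*% t(pts) + pose$translation)
  vid <- function(ip, ith) (((ith - 1) %% n_theta)) * n_psi + ip - 1  # 0-based
  faces <- NULL
  for (ith in seq_len(n_theta)) {
    for (ip in seq_len(n_psi - 1)) {
      a <- vid(ip, ith); b <- vid(ip + 1, ith)
      c_ <- vid(ip + 1, ith + 1); d <- vid(ip, ith + 1)
      faces <- rbind(faces, c(a, b, c_), c(a, c_, d))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}
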