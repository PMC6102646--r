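# Fitting the idealized shape family to labeled images and to surface
# samples, and the overlap metrics used to compare shapes.

# classify a geometry onto an explicit grid without containment checks
classify_grid <- function(geom, pose, dim_, spacing, origin) {
  xs <- origin[1] + (seq_len(dim_[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim_[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim_[3]) - 1) * spacing[3]
  X <- rep(xs, times = dim_[2] * dim_[3]) - pose$translation[1]
  Y <- rep(rep(ys, each = dim_[1]), times = dim_[3]) - pose$translation[2]
  Z <- rep(zs, each = dim_[1] * dim_[2]) - pose$translation[3]
  R <- pose$rotation
  xc <- R[1, 1] * X + R[2, 1] * Y + R[3, 1] * Z
  yc <- R[1, 2] * X + R[2, 2] * Y + R[3, 2] * Z
  zc <- R[1, 3] * X + R[2, 3] * Y + R[3, 3] * Z
  array(classify_points(geom, xc, yc, zc), dim_)
}

same_grid <- function(a, b) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-6
}

#' Cavity-and-wall similarity functional between two label images
#'
#' \deqn{J = 1 - \frac12\left(\frac{|C_a \cap C_b|}{|C_a \cup C_b|} +
#'   \frac{|W_a \cap W_b|}{|W_a \cup W_b|}\right)}
#' where C and W are the cavity and wall voxel sets. 0 means identical
#' segmentations, 1 fully disjoint ones.
#'
#' @param img_a,img_b `label_image`s on the same grid.
#' @return Similarity score in \[0, 1\].
#' @export
similarity_j <- function(img_a, img_b) {
  if (!same_grid(img_a, img_b))
    stop("similarity_j: images must share spacing, dimensions and origin")
  jacc <- function(lab) {
    a <- img_a$voxels == lab; b <- img_b$voxels == lab
    u <- sum(a | b)
    if (u == 0) {
      warning(sprintf("similarity_j: empty union for label %d; Jaccard set to 0", lab))
      return(0)
    }
    sum(a & b) / u
  }
  1 - (jacc(1L) + jacc(2L)) / 2
}

# grid covering the canonical bounding boxes of a set of geometries
common_grid <- function(geoms, spacing, margin = 3) {
  spacing <- rep_len(spacing, 3)
  bbs <- lapply(geoms, canonical_bbox)
  lo <- Reduce(pmin, lapply(bbs, function(b) b[1, ])) - margin
  hi <- Reduce(pmax, lapply(bbs, function(b) b[2, ])) + margin
  list(dim = pmax(1L, as.integer(ceiling((hi - lo) / spacing))),
       spacing = spacing, origin = lo + spacing / 2)
}

#' Wall Dice score between two geometries
#'
#' Both geometries are voxelized in canonical pose on a common grid and the
#' Dice coefficient 2|A n B| / (|A| + |B|) of the wall label is returned.
#'
#' @param geom_a,geom_b `lv_geometry`s.
#' @param spacing Voxel spacing, mm (default 1 mm isotropic).
#' @return Dice score in \[0, 1\].
#' @export
dice_score <- function(geom_a, geom_b, spacing = 1) {
  gr <- common_grid(list(geom_a, geom_b), spacing)
  id <- rigid_pose()
  wa <- classify_grid(geom_a, id, gr$dim, gr$spacing, gr$origin) == 2L
  wb <- classify_grid(geom_b, id, gr$dim, gr$spacing, gr$origin) == 2L
  na <- sum(wa); nb <- sum(wb)
  if (na == 0 || nb == 0) stop("dice_score: empty wall region")
  2 * sum(wa & wb) / (na + nb)
}

#' Estimate the long axis of a segmented ventricle
#'
#' Starts from the total-least-squares line through the per-axial-slice
#' centers of gravity of the labeled region (cavity plus wall) and then
#' refines it by re-slicing the volume perpendicular to the current axis
#' estimate: for an axisymmetric ventricle, slices normal to the true axis
#' have their centroids exactly on the axis, so the iteration removes the
#' obliquity bias of fixed axial slices. The direction is oriented base to
#' apex by the slice-area gradient (cross sections shrink toward the apex).
#'
#' @param img A `label_image`.
#' @param n_iter Cap on re-slicing refinements after the axial-slice
#'   initialization (the loop stops once the direction change drops below
#'   0.05 degrees).
#' @return List with `direction` (unit 3-vector, base -> apex), `centroid`
#'   (mm) of the labeled region, and the final per-slab centroid table.
#' @export
estimate_long_axis <- function(img, n_iter = 40) {
  d <- dim(img$voxels)
  n_axial <- sum(apply(img$voxels > 0, 3, any))
  if (n_axial < 2)
    stop("estimate_long_axis: need at least 2 non-empty axial slices")
  vox <- which(img$voxels > 0, arr.ind = TRUE)
  P <- cbind(img$origin[1] + (vox[, 1] - 1) * img$spacing[1],
             img$origin[2] + (vox[, 2] - 1) * img$spacing[2],
             img$origin[3] + (vox[, 3] - 1) * img$spacing[3])
  cog <- colMeans(P)
  Pc <- sweep(P, 2, cog)
  slab_fit <- function(dir, width) {
    proj <- as.numeric(Pc %*% dir)
    bins <- floor((proj - min(proj)) / width)
    counts <- as.numeric(table(bins))
    ctr <- rowsum(Pc, bins) / counts
    # partial end slabs have biased centroids; weight the line fit by count
    keep <- counts > 0.1 * max(counts)
    ctr <- ctr[keep, , drop = FALSE]
    w <- counts[keep]
    wm <- colSums(ctr * w) / sum(w)
    new_dir <- svd(sqrt(w) * sweep(ctr, 2, wm))$v[, 1]
    cproj <- as.numeric(sweep(ctr, 2, wm) %*% new_dir)
    if (stats::coef(stats::lm(w ~ cproj))[2] > 0)
      new_dir <- -new_dir
    list(dir = new_dir,
         slices = data.frame(x = ctr[, 1] + cog[1], y = ctr[, 2] + cog[2],
                             z = ctr[, 3] + cog[3],
                             area = w * img$spacing[1] * img$spacing[2]))
  }
  width <- max(img$spacing)
  fit <- slab_fit(c(0, 0, 1), width)
  for (k in seq_len(n_iter)) {
    prev <- fit$dir
    fit <- slab_fit(fit$dir, width)
    if (abs(sum(prev * fit$dir)) > cos(0.05 * pi / 180)) break
  }
  list(direction = fit$dir, centroid = cog, slices = fit$slices)
}

# rigid pre-alignment of a candidate geometry to a target image: match long
# axes and centers of gravity
align_pose <- function(geom, target_axis, target_centroid) {
  R <- rotation_to_axis(-target_axis)  # canonical +z points apex -> base
  zc <- lv_centroid_height(geom, n = 48)
  tr <- target_centroid - as.numeric(R %*% c(0, 0, zc))
  rigid_pose(tr, R)
}

fit_objective <- function(par, img, target_axis, target_centroid, counts) {
  geom <- tryCatch(
    lv_geometry(par[1], par[2], par[3], par[4], par[5], par[6]),
    error = function(e) NULL)
  if (is.null(geom) || geom$R_b - geom$L < 2 || geom$Z - geom$H < 2)
    return(2)
  pose <- align_pose(geom, target_axis, target_centroid)
  lab <- classify_grid(geom, pose, dim(img$voxels), img$spacing, img$origin)
  jacc <- function(cand, ref_n, ref_idx) {
    inter <- sum(cand[ref_idx])
    u <- sum(cand) + ref_n - inter
    if (u == 0) 0 else inter / u
  }
  jc <- jacc(lab == 1L, counts$n_cav, counts$idx_cav)
  jw <- jacc(lab == 2L, counts$n_wall, counts$idx_wall)
  1 - (jc + jw) / 2
}

# decimate an image by integer strides (voxel centers are preserved)
stride_image <- function(img, stride) {
  d <- dim(img$voxels)
  ix <- seq(1, d[1], by = stride[1])
  iy <- seq(1, d[2], by = stride[2])
  iz <- seq(1, d[3], by = stride[3])
  label_image(img$voxels[ix, iy, iz, drop = FALSE],
              img$spacing * stride, img$origin)
}

#' Fit the six-parameter model to a label image
#'
#' Minimizes the cavity-and-wall similarity functional over the six shape
#' parameters with Nelder-Mead. Every objective evaluation is preceded by a
#' rigid alignment matching the candidate's long axis and center of gravity
#' to those estimated from the target image. For fine grids a coarse
#' (strided) pass precedes refinement on the full grid.
#'
#' @param img Target `label_image` containing cavity and wall labels.
#' @param init Initial `lv_geometry`; default is the population-mean BoD
#'   shape.
#' @param restarts Number of perturbed restarts after the first attempt.
#' @param maxit Nelder-Mead iteration cap per attempt.
#' @return List with `geometry` (fitted `lv_geometry`), `pose`
#'   (`rigid_pose`), `J` (final similarity), and `converged` flag.
#' @export
fit_to_image <- function(img, init = NULL, restarts = 3, maxit = 400) {
  if (!any(img$voxels == 1L) || !any(img$voxels == 2L))
    stop("fit_to_image: image must contain both cavity and wall labels")
  if (is.null(init)) {
    st <- population_stats("BoD")
    init <- lv_geometry_from_vector(st$mean)
  }
  ax <- estimate_long_axis(img)
  stride <- pmax(1L, as.integer(floor(2 / img$spacing)))
  coarse <- if (any(stride > 1L)) stride_image(img, stride) else NULL
  run <- function(im, par0, maxit_) {
    counts <- list(idx_cav = im$voxels == 1L, idx_wall = im$voxels == 2L)
    counts$n_cav <- sum(counts$idx_cav); counts$n_wall <- sum(counts$idx_wall)
    parscale <- c(3, 5, 1.5, 1.5, 0.08, 0.1)
    stats::optim(par0, fit_objective, img = im, target_axis = ax$direction,
                 target_centroid = ax$centroid, counts = counts,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit_, parscale = parscale,
                                reltol = 1e-4))
  }
  par0 <- as.numeric(init)
  best <- NULL
  perturb <- rbind(rep(0, 6),
                   c(2, 3, 1, 0.8, 0.05, 0.06),
                   c(-2, -3, -1, -0.8, -0.05, -0.06),
                   c(3, -2, -1.2, 1, 0.08, -0.08))
  for (r in seq_len(min(restarts + 1, nrow(perturb)))) {
    p0 <- par0 + perturb[r, ]
    if (!is.null(coarse)) {
      res_c <- run(coarse, p0, maxit)
      p0 <- res_c$par
    }
    res <- run(img, p0, maxit)
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < 0.02) break
  }
  geom <- lv_geometry(best$par[1], best$par[2], best$par[3], best$par[4],
                      min(1, max(0, best$par[5])), best$par[6])
  converged <- best$convergence == 0 || best$value < 0.05
  if (!converged)
    warning("fit_to_image: optimizer did not converge; returning best so far")
  list(geometry = geom,
       pose = align_pose(geom, ax$direction, ax$centroid),
       J = best$value, converged = converged)
}

# mean distance from points (rho, zeta) to a sampled profile curve
profile_cloud_distance <- function(geom, rho, zeta, surface, n_samp = 512) {
  psi <- seq(geom$psi0, pi / 2, length.out = n_samp)
  pr <- evaluate_profile(geom, psi)
  cr <- if (surface == "epi") pr$rho_epi else pr$rho_end
  cz <- if (surface == "epi") pr$zeta_epi else pr$zeta_end
  d <- vapply(seq_along(rho), function(i)
    min((cr - rho[i])^2 + (cz - zeta[i])^2), numeric(1))
  mean(sqrt(d))
}

#' Fit the shape family to epicardial/endocardial surface samples
#'
#' Two-block alternating fit in canonical pose: first R_b, Z, e, psi0 are
#' adjusted to the epicardial cloud, then L, H to the endocardial cloud; the
#' two steps are repeated until the parameters stop changing. A monolithic
#' six-parameter variant is available for comparison.
#'
#' @param epi_points,endo_points Point clouds (n x 3 matrices, mm) in
#'   canonical pose; `endo_points` may be NULL (block 2 is skipped and L, H
#'   keep their initial values).
#' @param init Initial `lv_geometry`.
#' @param max_alternations Cap on block alternations.
#' @param tol Relative parameter-change tolerance for convergence.
#' @param monolithic Optimize all six parameters jointly instead.
#' @return Fitted `lv_geometry` with attribute `"alternations"`.
#' @export
fit_to_surfaces <- function(epi_points, endo_points = NULL, init,
                            max_alternations = 20, tol = 1e-3,
                            monolithic = FALSE) {
  if (is.null(epi_points) || nrow(epi_points) == 0)
    stop("fit_to_surfaces: empty epicardial cloud")
  re <- sqrt(epi_points[, 1]^2 + epi_points[, 2]^2); ze <- epi_points[, 3]
  rn <- zn <- NULL
  if (!is.null(endo_points) && nrow(endo_points) > 0) {
    rn <- sqrt(endo_points[, 1]^2 + endo_points[, 2]^2); zn <- endo_points[, 3]
  }
  par <- as.numeric(init)  # R_b, Z, L, H, e, psi0
  make <- function(p) tryCatch(
    lv_geometry(p[1], p[2], p[3], p[4], p[5], p[6]), error = function(e) NULL)
  obj_all <- function(p) {
    g <- make(p)
    if (is.null(g)) return(1e6)
    d <- profile_cloud_distance(g, re, ze, "epi")
    if (!is.null(rn)) d <- d + profile_cloud_distance(g, rn, zn, "endo")
    d
  }
  if (monolithic) {
    res <- stats::optim(par, obj_all, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10,
                                       parscale = c(3, 5, 1.5, 1.5, 0.08, 0.1)))
    out <- make(res$par)
    attr(out, "alternations") <- NA_integer_
    return(out)
  }
  alt <- 0
  repeat {
    old <- par
    # block 1: outer surface parameters on the epicardial cloud
    o1 <- function(q) {
      g <- make(c(q[1], q[2], par[3], par[4], q[3], q[4]))
      if (is.null(g)) return(1e6)
      profile_cloud_distance(g, re, ze, "epi")
    }
    r1 <- stats::optim(par[c(1, 2, 5, 6)], o1, method = "Nelder-Mead",
                       control = list(maxit = 800, reltol = 1e-10,
                                      parscale = c(3, 5, 0.08, 0.1)))
    par[c(1, 2, 5, 6)] <- r1$par
    # block 2: wall thicknesses on the endocardial cloud
    if (!is.null(rn)) {
      o2 <- function(q) {
        g <- make(c(par[1], par[2], q[1], q[2], par[5], par[6]))
        if (is.null(g)) return(1e6)
        profile_cloud_distance(g, rn, zn, "endo")
      }
      r2 <- stats::optim(par[3:4], o2, method = "Nelder-Mead",
                         control = list(maxit = 600, reltol = 1e-10,
                                        parscale = c(1.5, 1.5)))
      par[3:4] <- r2$par
    }
    alt <- alt + 1
    delta <- max(abs(par - old) / pmax(abs(old), 1e-6))
    if (delta < tol || alt >= max_alternations) break
  }
  if (alt >= max_alternations)
    warning("fit_to_surfaces: alternation cap reached; returning best so far")
  out <- make(par)
  attr(out, "alternations") <- alt
  out
}

#' Sample points on a geometry's surfaces
#'
#' @param geom An `lv_geometry`.
#' @param n_psi,n_theta Sampling resolution.
#' @param surface `"epi"` or `"endo"`.
#' @return n x 3 matrix of points in canonical pose, mm.
#' @export
sample_surface <- function(geom, surface = c("epi", "endo"),
                           n_psi = 30, n_theta = 12) {
  surface <- match.arg(surface)
  t_ <- if (surface == "epi") 1 else 0
  psi <- seq(geom$psi0, pi / 2 - 1e-6, length.out = n_psi)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  gr <- expand.grid(psi = psi, theta = th)
  lv_point(geom, gr$psi, rep(t_, nrow(gr)), gr$theta)
}

#' Synthetic segmentation of a known geometry
#'
#' Voxelizes the geometry and then flips boundary-adjacent labels (voxels
#' with at least one differently-labeled 6-neighbor) independently at the
#' given rate, each flipped voxel taking the label of a random 6-neighbor.
#' Emulates segmentation uncertainty concentrated at tissue boundaries.
#'
#' @param xi_true True `lv_geometry`.
#' @param pose A `rigid_pose` (default identity).
#' @param spacing Voxel spacing, mm; the anisotropic cine-MRI default is
#'   `c(1.36, 1.36, 8.8)`.
#' @param label_noise_rate Flip probability for boundary voxels, in \[0, 1\].
#' @param seed Integer seed; output is reproducible.
#' @return A `label_image`.
#' @export
generate_label_image <- function(xi_true, pose = NULL,
                                 spacing = c(1.36, 1.36, 8.8),
                                 label_noise_rate = 0, seed = 1) {
  if (label_noise_rate < 0 || label_noise_rate > 1)
    stop("generate_label_image: label_noise_rate must be in [0, 1]")
  img <- voxelize(xi_true, pose = pose, spacing = spacing)
  if (label_noise_rate == 0) return(img)
  v <- img$voxels
  d <- dim(v)
  shift <- function(a, ax, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    idx[[ax]] <- src
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  neigh <- list(shift(v, 1, 1L), shift(v, 1, -1L), shift(v, 2, 1L),
                shift(v, 2, -1L), shift(v, 3, 1L), shift(v, 3, -1L))
  boundary <- Reduce(`|`, lapply(neigh, function(nb) nb != v))
  with_seed(seed, {
    flip <- boundary & (array(stats::runif(length(v)), d) < label_noise_rate)
    pick <- array(sample.int(6, length(v), replace = TRUE), d)
    for (k in 1:6) {
      sel <- flip & pick == k
      v[sel] <- neigh[[k]][sel]
    }
  })
  label_image(v, img$spacing, img$origin)
}
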