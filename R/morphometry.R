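#' Fit an ellipsoid to a nucleus voxel cloud by second moments
#'
#' Centre = centroid; principal axes = eigenvectors of the point covariance;
#' semi-axis lengths follow the uniform-solid-ellipsoid relation
#' `semi-axis = sqrt(5 * eigenvalue)`. When a frame is supplied, Sheppard's
#' grid correction (`voxelSize^2 / 12` per axis) is subtracted from the
#' eigenvalues first, removing the voxelisation bias of sampling a solid at
#' voxel centres.
#'
#' @param points n x 3 matrix of physical coordinates (micrometres), e.g.
#'   voxel centres of one segmented nucleus; at least 4 non-coplanar points.
#' @param frame optional [EmbryoFrame-class]; enables the grid correction.
#' @return an [EllipsoidFit-class] with ascending semi-axes and matching
#'   principal-axis columns (minor, middle, major).
#' @examples
#' g <- as.matrix(expand.grid(x = -4:4, y = -4:4, z = -4:4))
#' sphere <- g[rowSums(g^2) <= 9, ]
#' semiAxes(fitEllipsoid(sphere, embryoFrame()))
#' @export
fitEllipsoid <- function(points, frame = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  centre <- colMeans(points)
  d <- sweep(points, 2, centre, "-")
  S <- crossprod(d) / nrow(points)   # population covariance
  e <- eigen(S, symmetric = TRUE)
  lambda <- rev(e$values)            # ascending
  vectors <- e$vectors[, 3:1, drop = FALSE]
  if (!is.null(frame)) {
    corr <- mean(frame@voxelSize^2) / 12
    lambda <- pmax(lambda - corr, min(frame@voxelSize)^2 / 400)
  }
  if (lambda[1] <= 1e-12)
    stop("degenerate point set: covariance is rank-deficient ",
         "(coplanar or collinear points)")
  new("EllipsoidFit", centre = centre, semiAxes = sqrt(5 * lambda),
      principalAxes = vectors)
}

#' Shape descriptors of a fitted ellipsoid
#'
#' With ascending semi-axes a <= b <= c:
#' prolate ellipticity = 2(c - b)/(b + c) (0 for a sphere, towards 2 for a
#' needle), oblate ellipticity = 2(b - a)/(a + b), and sphericity =
#' `pi^(1/3) (6V)^(2/3) / A` where V is the object volume (voxel count times
#' voxel volume when available, else the fitted ellipsoid volume) and A the
#' ellipsoid surface area by the Knud Thomsen approximation (p = 1.6075).
#'
#' @param fit an [EllipsoidFit-class].
#' @param voxelCount optional measured voxel count of the object.
#' @param frame optional [EmbryoFrame-class] (needed to convert the voxel
#'   count to a volume).
#' @return named numeric: `prolate`, `oblate`, `sphericity`.
#' @examples
#' f <- new("EllipsoidFit", centre = c(0, 0, 0), semiAxes = c(1, 1, 1.5),
#'          principalAxes = diag(3))
#' shapeMetrics(f)[["prolate"]]  # 0.4
#' @export
shapeMetrics <- function(fit, voxelCount = NULL, frame = NULL) {
  s <- fit@semiAxes
  a <- s[1]; b <- s[2]; cc <- s[3]
  prolate <- 2 * (cc - b) / (b + cc)
  oblate <- 2 * (b - a) / (a + b)
  V <- if (!is.null(voxelCount) && !is.null(frame))
    voxelCount * prod(frame@voxelSize) else (4 / 3) * pi * a * b * cc
  p <- 1.6075
  A <- 4 * pi * (((a * b)^p + (a * cc)^p + (b * cc)^p) / 3)^(1 / p)
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  c(prolate = prolate, oblate = oblate, sphericity = sphericity)
}

#' Orientation of a nuclear major axis in embryo polar coordinates
#'
#' The axis is sign-folded so its medial-lateral (x) component is
#' non-negative (ties: fold so y >= 0, then z >= 0), making the angles
#' invariant under `v -> -v`. Theta is the deviation from the dorso-ventral
#' z axis (`acos(v_z)`, 0-180 degrees); phi the azimuth within the
#' medial-lateral / antero-posterior plane (`atan2(v_y, v_x)`, (-90, 90]
#' degrees, 0 = medial-lateral).
#'
#' @param v major-axis vector (any nonzero length; normalised internally).
#' @param frame optional [EmbryoFrame-class]; the embryo axes are the array
#'   axes, so only kept for interface symmetry.
#' @return named numeric: `theta`, `phi` (degrees).
#' @examples
#' orientationAngles(c(1, 0, 0))  # theta 90, phi 0
#' @export
orientationAngles <- function(v, frame = NULL) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero vector has no orientation")
  v <- v / n
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0) ||
      (v[1] == 0 && v[2] == 0 && v[3] < 0))
    v <- -v
  theta <- acos(pmin(1, pmax(-1, v[3]))) * 180 / pi
  phi <- atan2(v[2], v[1]) * 180 / pi
  c(theta = theta, phi = phi)
}
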