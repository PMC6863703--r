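# Rigid-body geometry, hydrogen-bond criteria and grid quantization.
#
# All coordinates are in Angstrom; all angles in degrees at the API surface.
# Internally everything is vectorized over rows of n x 3 matrices so that the
# placement enumeration can process hundreds of thousands of candidate poses.

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("hbnetforge geometry error: zero-length vector cannot be normalised")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# rowwise helpers for n x 3 matrices ------------------------------------------

row_norm <- function(m) sqrt(rowSums(m * m))

row_unit <- function(m) m / row_norm(m)

row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_dot <- function(a, b) rowSums(a * b)

as_row3 <- function(x, n) {
  if (is.matrix(x)) {
    if (nrow(x) == n) return(x)
    if (nrow(x) == 1L) return(matrix(x, n, 3L, byrow = TRUE))
    stop("row count mismatch")
  }
  matrix(x, n, 3L, byrow = TRUE)
}

# rows represented by x: 1 for a plain xyz vector, nrow for a matrix
nrow3 <- function(x) if (is.matrix(x)) nrow(x) else 1L

#' Interior angle at b formed by points a-b-c, in degrees
#' @param a,b,c numeric xyz vectors
#' @return angle in degrees in [0, 180]
#' @export
angle_deg <- function(a, b, c) {
  u <- unit_vec(a - b); v <- unit_vec(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle a-b-c-d about the b-c axis, in degrees
#' @param a,b,c,d numeric xyz vectors
#' @return signed dihedral in (-180, 180]
#' @export
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit_vec(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# rowwise angle at H: angle(D, H, A) given matrices
row_angle_deg <- function(a, b, c) {
  u <- row_unit(a - b); v <- row_unit(c - b)
  d <- pmin(1, pmax(-1, row_dot(u, v)))
  rad2deg(acos(d))
}

## Rigid transforms -----------------------------------------------------------

#' Construct a rigid-body transform
#'
#' A rotation (proper, orthonormal) plus a translation, applied as
#' \code{x -> R x + t}.
#'
#' @param rotation 3x3 rotation matrix (orthonormal within 1e-8, det +1)
#' @param translation length-3 numeric translation (Angstrom)
#' @return object of class \code{rigid_transform}
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("hbnetforge contract error: rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("hbnetforge contract error: rotation is a reflection (det < 0)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' Identity transform
#' @return a \code{rigid_transform}
#' @export
transform_identity <- function() rigid_transform()

#' Apply a rigid transform to points
#' @param transform a \code{rigid_transform}
#' @param points length-3 vector or n x 3 matrix
#' @return object of the same shape as \code{points}
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.matrix(points)) {
    out <- points %*% t(transform$R)
    out[, 1L] <- out[, 1L] + transform$t[1L]
    out[, 2L] <- out[, 2L] + transform$t[2L]
    out[, 3L] <- out[, 3L] + transform$t[3L]
    rownames(out) <- rownames(points)
    out
  } else {
    as.numeric(transform$R %*% points + transform$t)
  }
}

#' Compose two rigid transforms (\code{a} applied after \code{b})
#' @param a,b \code{rigid_transform} objects
#' @return \code{rigid_transform} equivalent to applying \code{b} then \code{a}
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#' @param transform a \code{rigid_transform}
#' @return the inverse \code{rigid_transform}
#' @export
transform_inverse <- function(transform) {
  rigid_transform(t(transform$R), as.numeric(-t(transform$R) %*% transform$t))
}

# orthonormal frame (rotation matrix columns) from a point triple
frame_axes <- function(p1, p2, p3) {
  e1 <- unit_vec(p2 - p1)
  w <- p3 - p1
  w <- w - sum(w * e1) * e1
  if (vnorm(w) < 1e-9) stop("hbnetforge geometry error: collinear points define no frame")
  e2 <- unit_vec(w)
  cbind(e1, e2, vcross(e1, e2))
}

#' Rigid transform superposing one point triple onto another
#'
#' The two triples must be congruent (same pairwise distances within 0.05 A);
#' the returned transform maps \code{src} onto \code{dst} exactly for exactly
#' congruent triples.
#'
#' @param src,dst 3 x 3 matrices, one point per row
#' @return a \code{rigid_transform} with \code{apply_transform(out, src) == dst}
#'   within 1e-6 A for congruent input
#' @export
superpose_frames <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(identical(dim(src), c(3L, 3L)), identical(dim(dst), c(3L, 3L)))
  ds <- stats::dist(src); dd <- stats::dist(dst)
  if (max(abs(ds - dd)) > 0.05)
    stop("hbnetforge geometry error: point triples are not congruent (tolerance 0.05 A)")
  Fs <- frame_axes(src[1L, ], src[2L, ], src[3L, ])
  Fd <- frame_axes(dst[1L, ], dst[2L, ], dst[3L, ])
  R <- Fd %*% t(Fs)
  # re-orthonormalise to keep the rigid_transform contract tight
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  rigid_transform(R, dst[1L, ] - as.numeric(R %*% src[1L, ]))
}

## NeRF-style atom placement --------------------------------------------------

#' Place an atom from internal coordinates
#'
#' Places atom \code{d} bonded to \code{c}, with bond length
#' \code{|d - c| = bond}, bond angle \code{angle(b, c, d)} and dihedral
#' \code{dihedral(a, b, c, d)} about the b-c axis.
#'
#' @param a,b,c reference xyz vectors (must not be collinear)
#' @param bond bond length (Angstrom)
#' @param angle bond angle (degrees)
#' @param dihedral dihedral angle (degrees)
#' @return xyz of the placed atom
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  as.numeric(place_atoms_n(matrix(a, 1L), matrix(b, 1L), matrix(c, 1L),
                           bond, angle, dihedral))
}

# vectorized NeRF: a, b, c recycled n x 3; bond/angle/dihedral recycled length n
place_atoms_n <- function(a, b, c, bond, angle, dihedral) {
  n <- max(nrow3(a), nrow3(b), nrow3(c), length(bond), length(angle), length(dihedral))
  a <- as_row3(a, n); b <- as_row3(b, n); c <- as_row3(c, n)
  bond <- rep_len(bond, n); th <- deg2rad(rep_len(angle, n)); ph <- deg2rad(rep_len(dihedral, n))
  bc <- row_unit(c - b)
  n1 <- row_cross(b - a, bc)
  nn <- row_norm(n1)
  if (any(nn < 1e-9)) stop("hbnetforge geometry error: collinear reference atoms in place_atom")
  n1 <- n1 / nn
  m1 <- row_cross(n1, bc)
  d2x <- -bond * cos(th)
  d2y <- bond * sin(th) * cos(ph)
  d2z <- -bond * sin(th) * sin(ph)
  c + bc * d2x + m1 * d2y + n1 * d2z
}

# Like place_atoms_n, but rows whose (a, b, c) reference triple is collinear
# (e.g. a 180-degree bond angle upstream makes the torsion degenerate) get a
# deterministic perpendicular substitute for `a` instead of an error.
place_atoms_safe <- function(a, b, c, bond, angle, dihedral) {
  n <- max(nrow3(a), nrow3(b), nrow3(c), length(bond), length(angle), length(dihedral))
  a <- as_row3(a, n); b <- as_row3(b, n); c <- as_row3(c, n)
  cr <- row_cross(b - a, c - b)
  bad <- row_norm(cr) < 1e-8
  if (any(bad)) {
    perp <- arbitrary_perp(c[bad, , drop = FALSE] - b[bad, , drop = FALSE])
    a[bad, ] <- b[bad, , drop = FALSE] + perp
  }
  place_atoms_n(a, b, c, bond, angle, dihedral)
}

# a deterministic unit vector perpendicular to v (rowwise for matrices)
arbitrary_perp <- function(v) {
  if (!is.matrix(v)) v <- matrix(v, 1L)
  ax <- abs(v)
  pick <- max.col(-ax, ties.method = "first")  # index of smallest |component|
  e <- matrix(0, nrow(v), 3L)
  e[cbind(seq_len(nrow(v)), pick)] <- 1
  row_unit(row_cross(v, e))
}

# Rodrigues rotation of points p about unit axes u by angle (deg), rowwise
rotate_rows <- function(p, u, angle) {
  th <- deg2rad(rep_len(angle, nrow(p)))
  cth <- cos(th); sth <- sin(th)
  p * cth + row_cross(u, p) * sth + u * row_dot(u, p) * (1 - cth)
}

#' Rotate points about an axis
#' @param points n x 3 matrix or xyz vector
#' @param origin point on the axis
#' @param axis axis direction (normalised internally)
#' @param angle rotation angle, degrees
#' @return rotated points, same shape as input
#' @export
rotate_about_axis <- function(points, origin, axis, angle) {
  vec <- !is.matrix(points)
  if (vec) points <- matrix(points, 1L)
  u <- matrix(unit_vec(axis), nrow(points), 3L, byrow = TRUE)
  shifted <- sweep(points, 2L, origin)
  out <- sweep(rotate_rows(shifted, u, angle), 2L, origin, `+`)
  if (vec) as.numeric(out) else out
}

## Grid quantization ----------------------------------------------------------

# round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Snap points to an integer grid
#'
#' Each coordinate is divided by the grid spacing and rounded to the nearest
#' integer with the half-away-from-zero tie rule, so grid keys are
#' bit-reproducible.
#'
#' @param points xyz vector or n x 3 matrix (ligand-local frame)
#' @param spacing grid spacing in Angstrom (> 0)
#' @return integer triple (or n x 3 integer matrix)
#' @export
snap_to_grid <- function(points, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("hbnetforge value error: grid spacing must be a positive number")
  vec <- !is.matrix(points)
  if (vec) points <- matrix(points, 1L)
  k <- round_half_away(points / spacing)
  storage.mode(k) <- "integer"
  if (vec) as.integer(k) else k
}

# flatten integer key matrix rows into strings for hashing
key_string <- function(keys) {
  if (!is.matrix(keys)) keys <- matrix(keys, 1L)
  do.call(paste, c(lapply(seq_len(ncol(keys)), function(j) keys[, j]), list(sep = ",")))
}

## Hydrogen-bond geometry -----------------------------------------------------

#' Hydrogen-bond geometric criteria
#'
#' Distance and angle windows defining when a donor/acceptor pair counts as
#' hydrogen bonded, plus the ideal values at which the score ramp peaks.
#' Defaults follow common structural-biology practice and every value can be
#' overridden.
#'
#' @param d_min,d_max donor-heavy to acceptor-heavy distance window (Angstrom)
#' @param theta_min minimum donor angle D-H...A (degrees)
#' @param psi_min minimum acceptor angle base-A...H (degrees)
#' @param ideal_d ideal heavy-heavy distance (Angstrom)
#' @param ideal_theta ideal donor angle (degrees)
#' @param weight score weight w (score = -w * f(d) * f(theta))
#' @return object of class \code{hbond_params}
#' @export
hbond_params <- function(d_min = 2.6, d_max = 3.2, theta_min = 120, psi_min = 90,
                         ideal_d = 2.8, ideal_theta = 180, weight = 1) {
  stopifnot(0 < d_min, d_min < ideal_d, ideal_d < d_max,
            0 < theta_min, theta_min <= 180, theta_min < ideal_theta || ideal_theta == 180)
  structure(list(d_min = d_min, d_max = d_max, theta_min = theta_min,
                 psi_min = psi_min, ideal_d = ideal_d, ideal_theta = ideal_theta,
                 weight = weight), class = "hbond_params")
}

# linear ramp: 0 at lo and hi, 1 at peak
ramp01 <- function(x, lo, peak, hi) {
  up <- (x - lo) / (peak - lo)
  dn <- if (hi > peak) (hi - x) / (hi - peak) else rep(1, length(x))
  pmax(0, pmin(up, dn, 1))
}

# Vectorized core: D, H, A are n x 3 (recycled); bases is a list of n x 3
# matrices (alternative acceptor base atoms; the most favourable base is used).
hbond_geom_n <- function(D, H, A, bases, params, overlap = c("error", "reject")) {
  overlap <- match.arg(overlap)
  n <- max(nrow3(D), nrow3(H), nrow3(A), vapply(bases, nrow3, 1L))
  D <- as_row3(D, n); H <- as_row3(H, n); A <- as_row3(A, n)
  d <- row_norm(A - D)
  dHA <- row_norm(A - H)
  bad <- d < 0.5 | dHA < 0.5
  if (any(bad)) {
    if (overlap == "error")
      stop("hbnetforge geometry error: overlapping atoms in hbond_eval (distance < 0.5 A)")
    # push the offending rows far out of the window instead of dividing by ~0
    D[bad, ] <- matrix(c(1e6, 0, 0), sum(bad), 3L, byrow = TRUE)
    H[bad, ] <- matrix(c(1e6 + 1, 0, 0), sum(bad), 3L, byrow = TRUE)
    d[bad] <- 1e6
  }
  theta <- row_angle_deg(D, H, A)
  psi <- rep(-Inf, n)
  for (b in bases) {
    b <- as_row3(b, n)
    psi <- pmax(psi, row_angle_deg(b, A, H))
  }
  # window comparisons carry a 1e-6 numerical tolerance so geometry sampled
  # exactly on a boundary survives rigid-motion round-trips
  eps <- 1e-6
  ok <- d >= params$d_min - eps & d <= params$d_max + eps &
        theta >= params$theta_min - eps & psi >= params$psi_min - eps
  fd <- ramp01(d, params$d_min, params$ideal_d, params$d_max)
  ft <- ramp01(theta, params$theta_min, params$ideal_theta, 360)
  score <- ifelse(ok, -params$weight * fd * ft, 0)
  list(ok = ok, score = score, d = d, theta = theta, psi = psi)
}

#' Evaluate hydrogen-bond geometry between a donor and an acceptor
#'
#' A hydrogen bond is accepted when the donor-heavy to acceptor-heavy distance
#' lies inside \code{[d_min, d_max]}, the donor angle D-H...A is at least
#' \code{theta_min} and the acceptor angle base-A...H is at least
#' \code{psi_min}. When several equivalent base atoms are supplied (e.g. the
#' two lone-pair-defining neighbours of a carbonyl oxygen) the most favourable
#' one is used, so the evaluation is symmetric under base relabeling. The
#' score is \code{-w * f(d) * f(theta)} with linear ramps peaking at
#' \code{ideal_d}/\code{ideal_theta} and vanishing on the window boundary;
#' it is 0 when the bond is not accepted.
#'
#' @param donor_heavy,donor_h,acceptor_heavy xyz vectors
#' @param acceptor_base xyz vector or matrix of alternative base atoms (rows)
#' @param params an \code{\link{hbond_params}} object
#' @param overlap what to do when atoms overlap (distance < 0.5 A): raise a
#'   geometry error (default) or reject the bond
#' @return list with \code{ok} (logical), \code{score} (<= 0), and the
#'   measured \code{d}, \code{theta}, \code{psi}
#' @export
hbond_eval <- function(donor_heavy, donor_h, acceptor_heavy, acceptor_base,
                       params = hbond_params(), overlap = c("error", "reject")) {
  if (!is.matrix(acceptor_base)) acceptor_base <- matrix(acceptor_base, 1L)
  bases <- lapply(seq_len(nrow(acceptor_base)), function(i) acceptor_base[i, , drop = FALSE])
  g <- hbond_geom_n(matrix(donor_heavy, 1L), matrix(donor_h, 1L),
                    matrix(acceptor_heavy, 1L), bases, params, overlap = overlap)
  list(ok = g$ok[1L], score = g$score[1L], d = g$d[1L], theta = g$theta[1L], psi = g$psi[1L])
}

# quaternion (w, x, y, z) from rotation matrix, canonical sign
quat_from_rotation <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q * q))
  nz <- which(abs(q) > 1e-9)
  if (length(nz) && q[nz[1L]] < 0) q <- -q
  q
}
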