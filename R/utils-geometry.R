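# Small geometry helpers shared by the orientation, descriptor and msm code.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Angle between two vectors in degrees
#' @param u,v numeric 3-vectors
#' @return angle in [0, 180] degrees
#' @keywords internal
angle_deg <- function(u, v) {
  ct <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# Signed torsion of vector v relative to vector u about unit axis b
# (right-handed about b), degrees in (-180, 180].
signed_torsion_deg <- function(u, v, b) {
  b <- unit_vec(b)
  up <- u - sum(u * b) * b
  vp <- v - sum(v * b) * b
  if (vec_norm(up) < 1e-10 || vec_norm(vp) < 1e-10)
    stop("torsion undefined: vector parallel to the axis")
  x <- sum(up * vp)
  y <- sum(b * c(up[2] * vp[3] - up[3] * vp[2],
                 up[3] * vp[1] - up[1] * vp[3],
                 up[1] * vp[2] - up[2] * vp[1]))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# smallest circular difference a-b in degrees, result in (-180, 180]
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# circular standard deviation (degrees) via resultant length
circ_sd_deg <- function(x_deg) {
  th <- x_deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  R <- min(1, R)
  sqrt(pmax(0, -2 * log(R))) * 180 / pi
}

#' Optimal least-squares (Kabsch) rotation
#'
#' Returns the proper rotation matrix `R` such that the centred rows of `A`
#' map onto the centred rows of `B`: `(A - centroid_A) %*% R ~ (B - centroid_B)`.
#'
#' @param A,B n x 3 coordinate matrices with matching rows
#' @return 3 x 3 rotation matrix with determinant +1
#' @export
kabsch_rotation <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# rotation matrix for angle deg about unit axis (Rodrigues)
rotation_about_axis <- function(axis, deg) {
  a <- unit_vec(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# apply rotation about a point: rows of X
rotate_coords <- function(X, R, center) {
  sweep(sweep(X, 2, center) %*% t(R), 2, center, `+`)
}

# atomic masses (u) and Bondi van der Waals radii (Angstrom) by element
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

element_mass <- function(elem) {
  m <- .atomic_mass[elem]
  if (anyNA(m))
    stop("unknown element(s): ", paste(unique(elem[is.na(m)]), collapse = ", "))
  unname(m)
}

element_vdw <- function(elem) {
  r <- .vdw_radius[elem]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elem[is.na(r)]), collapse = ", "))
  unname(r)
}

# infer element from a PDB atom name (protein heavy atoms + hydrogens)
element_from_name <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  first <- substr(e, 1, 1)
  ifelse(first %in% c("H", "C", "N", "O", "S", "P"), first, first)
}
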