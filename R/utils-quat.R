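# Quaternion helpers. Convention: scalar-first (w, x, y, z), unit
# quaternions encode right-handed rotations taking body axes to the lab
# frame. Body axes: e1 = chain tangent, e2 = minor-groove patch direction,
# e3 = e1 x e2.

quat_identity <- function(n = 1L) {
  matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
}

quat_normalize <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  q / sqrt(rowSums(q^2))
}

quat_multiply <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 4)
  if (is.null(dim(b))) b <- matrix(b, ncol = 4)
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

quat_conjugate <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

# Rotate body-frame vector(s) v by quaternion(s) q (both vectorized over rows).
quat_rotate <- function(q, v) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3, nrow = nrow(q), byrow = TRUE)
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + (y * tz - z * ty),
        vy + w * ty + (z * tx - x * tz),
        vz + w * tz + (x * ty - y * tx))
}

# Quaternion from axis-angle rotation vector(s).
quat_from_rotvec <- function(w) {
  if (is.null(dim(w))) w <- matrix(w, ncol = 3)
  th <- sqrt(rowSums(w^2))
  s <- ifelse(th < 1e-14, 0.5, sin(th / 2) / th)
  quat_normalize(cbind(cos(th / 2), s * w[, 1], s * w[, 2], s * w[, 3]))
}

# Quaternion from a single 3x3 rotation matrix (columns = body axes in lab).
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Minimal rotation matrix taking unit vector a to unit vector b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
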