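# Independent oracles and fixture builders used across test files.

# Horn's quaternion method for optimal rigid superposition RMSD.
# Independent of the Kabsch/SVD implementation under test: the optimal
# proper rotation is found as the largest eigenvalue of the 4x4 key
# matrix built from the cross-covariance of the centered coordinates,
# and RMSD follows from the residual identity
#   n * rmsd^2 = Ga + Gb - 2 * lambda_max.
quaternion_rmsd <- function(xa, xb) {
  stopifnot(nrow(xa) == nrow(xb))
  n <- nrow(xa)
  ya <- sweep(xa, 2, colMeans(xa))
  yb <- sweep(xb, 2, colMeans(xb))
  m <- crossprod(yb, ya)   # sum over atoms of yb_i %o% ya_i
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    nrow = 4, byrow = TRUE)
  lambda <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  ga <- sum(ya^2); gb <- sum(yb^2)
  sqrt(max(ga + gb - 2 * lambda, 0) / n)
}

# wrap a plain coordinate matrix as a structure_model (CA trace)
as_ca_model <- function(xyz, residues = seq_len(nrow(xyz)), index = 1L) {
  structure(
    data.frame(residue = as.integer(residues), aa = "A", atom = "CA",
               chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    model_index = index, class = c("structure_model", "data.frame"))
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

apply_rigid <- function(model, rot, trans) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, trans, `+`)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# minimal in-code peak list: one ok peak per residue at given positions
toy_peaks <- function(residue, h, n, intensity = 1e6, status = "ok",
                      aa = "X") {
  peak_list(data.frame(residue = residue, aa = aa, h_ppm = h, n_ppm = n,
                       intensity = intensity, status = status))
}
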