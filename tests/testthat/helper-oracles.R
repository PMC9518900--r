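## Independent oracle implementations used to check the package's
## computations.  These deliberately share no code with the package
## internals.

## praxeolitic dihedral (IUPAC convention), degrees
oracle_dihedral <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1
  b1 <- p2 - p1; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p3 - p2
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

## dihedral by brute-force rotation fit: rotate the last atom about the
## central bond until it lies in the reference half-plane, the rotation
## angle (sign per right-hand rule about b2) is minus the dihedral
oracle_dihedral_rotfit <- function(p0, p1, p2, p3) {
  axis <- p3 - p2
  axis <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  rod <- function(u, ang) {
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  f <- function(ang) {
    p3r <- p2 + as.vector(rod(axis, ang) %*% (p3 - p2))
    ## distance of rotated p3 from the plane spanned by (p0, p1, p2) on
    ## the p0 side
    v <- p3r - p2
    vperp <- v - sum(v * axis) * axis
    u0 <- (p0 - p1) - sum((p0 - p1) * axis) * axis
    -sum(vperp * u0) / sqrt(sum(vperp^2) * sum(u0^2))
  }
  opt <- optimize(f, c(-pi, pi), tol = 1e-14)
  ang <- opt$minimum
  ## resolve sign ambiguity of the optimizer near +-pi
  cand <- c(ang, -ang)
  err <- vapply(cand, function(a) abs(f(a) + 1), 1)
  -cand[which.min(err)] * 180 / pi
}

## chain construction via explicit Rodrigues rotation matrices
oracle_build_chain <- function(bonds, angles, dihedrals) {
  ## bonds[k]: |x_k - x_{k-1}|; angles[k]: angle at x_{k-1} (degrees);
  ## dihedrals[k]: dihedral of (x_{k-3}, x_{k-2}, x_{k-1}, x_k)
  rod <- function(u, ang) {
    u <- u / sqrt(sum(u^2))
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  n <- length(bonds) + 3
  X <- matrix(0, n, 3)
  X[1, ] <- c(0, 0, 0)
  X[2, ] <- c(bonds[1], 0, 0) * 0   # placeholder, overwritten below
  ## first three atoms in a canonical frame
  X[2, ] <- c(1, 0, 0) * attr(bonds, "b12")
  th <- attr(bonds, "a123") * pi / 180
  X[3, ] <- X[2, ] + attr(bonds, "b23") *
    c(-cos(th), sin(th), 0) * -1
  for (k in seq_along(bonds)) {
    A <- X[k, ]; B <- X[k + 1, ]; C <- X[k + 2, ]
    d <- (C - B) / sqrt(sum((C - B)^2))
    nrm <- c((B - A)[2] * d[3] - (B - A)[3] * d[2],
             (B - A)[3] * d[1] - (B - A)[1] * d[3],
             (B - A)[1] * d[2] - (B - A)[2] * d[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    ## start from the in-plane position at the ideal bond angle (dihedral
    ## 180) and rotate about the bond axis to the target dihedral
    th <- angles[k] * pi / 180
    D0 <- C + as.vector(rod(nrm, pi - th) %*% (d * bonds[k]))
    dih0 <- oracle_dihedral(A, B, C, D0)
    D <- C + as.vector(rod(d, (dihedrals[k] - dih0) * pi / 180) %*% (D0 - C))
    X[k + 3, ] <- D
  }
  X
}

## brute-force optimal superposition: coarse Euler-angle grid plus
## numeric refinement, translation optimal at centroids
oracle_superpose_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(a) {
    Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
                   0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                   sin(a[2]), 0, cos(a[2])), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]),
                   0, -sin(a[3]), cos(a[3])), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) mean(rowSums((Pc %*% t(rotmat(a)) - Qc)^2))
  grid <- seq(-pi, pi, length.out = 13)
  best <- NULL; bestv <- Inf
  for (a1 in grid) for (a2 in grid[grid >= -pi / 2 & grid <= pi / 2])
    for (a3 in grid) {
      v <- obj(c(a1, a2, a3))
      if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
    }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  sqrt(opt$value)
}

## exhaustive-seed TM-score oracle: every fragment of lengths L, L/2 and
## L/4, subset iteration to a fixed point, best TM kept
oracle_tm_score <- function(P, Q) {
  L <- nrow(P)
  d0 <- max(1.24 * (max(L - 15, 0))^(1 / 3) - 1.8, 0.5)
  d_cut <- max(d0, 4.5)
  kab <- function(A, B) {
    ca <- colMeans(A); cb <- colMeans(B)
    H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
    sv <- svd(H)
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    function(X) sweep(sweep(X, 2, ca) %*% t(R), 2, cb, "+")
  }
  best <- -Inf
  for (fl in unique(pmax(c(L, floor(L / 2), floor(L / 4)), 4))) {
    if (fl > L) next
    for (s in 1:(L - fl + 1)) {
      idx <- s:(s + fl - 1)
      for (it in 1:30) {
        tr <- kab(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
        d <- sqrt(rowSums((tr(P) - Q)^2))
        tm <- sum(1 / (1 + (d / d0)^2)) / L
        if (tm > best) best <- tm
        nidx <- which(d <= d_cut)
        if (length(nidx) < 4) nidx <- order(d)[1:4]
        nidx <- sort(nidx)
        if (identical(nidx, idx)) break
        idx <- nidx
      }
    }
  }
  best
}

## dense inverse-Hessian accumulation of the BFGS update; the initial
## matrix is gamma * I with gamma from the newest pair, matching the
## limited-memory two-loop scaling
oracle_dense_direction <- function(g, S, Y) {
  d <- length(g)
  k <- length(S)
  ylast <- Y[[k]]
  gamma <- sum(S[[k]] * ylast) / sum(ylast * ylast)
  H <- diag(gamma, d)
  for (i in seq_len(k)) {
    s <- S[[i]]; y <- Y[[i]]
    rho <- 1 / sum(y * s)
    V <- diag(d) - rho * y %*% t(s)
    H <- t(V) %*% H %*% V + rho * s %*% t(s)
  }
  as.vector(-H %*% g)
}

## random curvature history with positive y's (so no pairs are discarded)
random_history <- function(dim, npairs, seed) {
  set.seed(seed)
  ## draw (s, y) from a random SPD quadratic so y = A s
  A <- crossprod(matrix(rnorm(dim * dim), dim))
  A <- A + diag(dim) * 0.5
  S <- list(); Y <- list()
  for (i in seq_len(npairs)) {
    s <- rnorm(dim)
    S[[i]] <- s
    Y[[i]] <- as.vector(A %*% s)
  }
  g <- rnorm(dim)
  list(g = g, S = S, Y = Y,
       rho = vapply(seq_len(npairs),
                    function(i) 1 / sum(Y[[i]] * S[[i]]), 1))
}
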