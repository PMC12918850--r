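# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary data.

# quick CA-only chain from a coordinate matrix
make_chain <- function(coords, resno = seq_len(nrow(coords)) + 100L,
                       aa = rep("A", nrow(coords)), chain_id = "A") {
  residue_chain(chain_id, resno, aa, list(CA = as.matrix(coords)))
}

# reproducible random CA chain (coordinates roughly protein-scaled)
random_chain <- function(n, seed, chain_id = "A", first_resno = 101L) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * n, sd = 2.2), n, 3)
  make_chain(apply(steps, 2, cumsum), resno = first_resno + seq_len(n) - 1L,
             chain_id = chain_id)
}

rotation_about <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rigidly move a chain: rotate (column-action matrix R) then translate
transform_chain <- function(chain, R, t) {
  xyz <- lapply(chain$xyz, function(m) sweep(m %*% t(R), 2, t, `+`))
  residue_chain(chain$chain_id, chain$resno, chain$aa, xyz)
}

# --- independent superposed-RMSD oracles -------------------------------

# Horn's closed-form quaternion solution: maximal eigenvalue of the 4x4
# profile matrix gives the optimal proper-rotation residual directly.
# Entirely independent of the SVD route used by kabsch_superpose.
oracle_rmsd_quaternion <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  M <- crossprod(Yc, Xc)  # M[a,b] = sum_i y_ia x_ib
  S <- function(a, b) M[a, b]
  K <- matrix(c(
    S(1,1)+S(2,2)+S(3,3), S(2,3)-S(3,2), S(3,1)-S(1,3), S(1,2)-S(2,1),
    S(2,3)-S(3,2), S(1,1)-S(2,2)-S(3,3), S(1,2)+S(2,1), S(3,1)+S(1,3),
    S(3,1)-S(1,3), S(1,2)+S(2,1), -S(1,1)+S(2,2)-S(3,3), S(2,3)+S(3,2),
    S(1,2)-S(2,1), S(3,1)+S(1,3), S(2,3)+S(3,2), -S(1,1)-S(2,2)+S(3,3)),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# brute force: sample unit quaternions on a seeded grid, score the residual
# of each proper rotation, refine the best few by Nelder-Mead over the
# quaternion components. Slow but assumption-free.
oracle_rmsd_grid <- function(X, Y, n_grid = 4000, seed = 42) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  quat_to_R <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
             2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
             2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  }
  resid <- function(q) {
    R <- quat_to_R(q)                 # column-action rotation
    sqrt(sum((Xc - Yc %*% t(R))^2) / n)
  }
  set.seed(seed)
  qs <- matrix(rnorm(4 * n_grid), n_grid, 4)
  vals <- apply(qs, 1, resid)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(i) {
    stats::optim(qs[i, ], resid, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(refined)
}

# --- sequence-alignment DP oracle --------------------------------------

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# global Needleman-Wunsch score with affine-like gap cost
# (gap of length L costs open + L * extend), plain O(n*m*L) enumeration
# over gap lengths so it stays independent of any library routine.
oracle_nw_score <- function(sa, sb, open, extend, submat) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  gapcost <- function(L) if (L == 0) 0 else open + L * extend
  F <- matrix(-Inf, n + 1, m + 1)
  F[1, 1] <- 0
  for (j in seq_len(m)) F[1, j + 1] <- -gapcost(j)
  for (i in seq_len(n)) F[i + 1, 1] <- -gapcost(i)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- F[i, j] + submat[a[i], b[j]]
    for (L in seq_len(j)) best <- max(best, F[i + 1, j + 1 - L] - gapcost(L))
    for (L in seq_len(i)) best <- max(best, F[i + 1 - L, j + 1] - gapcost(L))
    F[i + 1, j + 1] <- best
  }
  F[n + 1, m + 1]
}

# naive per-window recomputation used as the matrix oracle
oracle_window_matrix <- function(chainA, chainB, corr, min_window) {
  rows <- list()
  for (seg in seq_len(max(corr$segment))) {
    sidx <- which(corr$segment == seg)
    L <- length(sidx)
    if (L < min_window) next
    for (s in seq_len(L - min_window + 1)) {
      for (len in min_window:(L - s + 1)) {
        idx <- sidx[s:(s + len - 1)]
        X <- chainA$xyz$CA[corr$pairs[idx, 1], , drop = FALSE]
        Y <- chainB$xyz$CA[corr$pairs[idx, 2], , drop = FALSE]
        rows[[length(rows) + 1]] <- c(corr$resnoA[idx[1]], len,
                                      oracle_rmsd_quaternion(X, Y))
      }
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("start_res", "length", "rmsd")
  m
}

# hand-written 3-residue PDB fixture
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   GLY A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A  10       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A  10       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   ALA A  11       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A  11       4.031   2.803   0.200  1.00  0.00           C",
    "ATOM      6  C   ALA A  11       5.500   2.600   0.500  1.00  0.00           C",
    "ATOM      7  CA  SER A  12       6.800   4.000   1.000  1.00  0.00           C",
    "END"), path)
  path
}

# noiseless Gompertz curve as a tht_curve (raw, with baseline)
gompertz_curve <- function(A = 100, t_i = 10, B = 2, baseline = 0,
                           n_points = 289, dt = 5 / 60, well = "W1",
                           condition = "sim", subtracted = FALSE) {
  tt <- (seq_len(n_points) - 1) * dt
  tht_curve(well, tt, baseline + A * exp(-exp(-(tt - t_i) / B)), condition,
            background_subtracted = subtracted)
}
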