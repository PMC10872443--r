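# Cluster-robust (CR2) sandwich covariance and Satterthwaite degrees of
# freedom for random-intercept GLS fits.
#
# Working model: y = X beta + u, Var(u) = Omega = blockdiag over clusters j of
# sigma_eps2 * (I + theta * J_nj), theta = sigma_lambda2 / sigma_eps2.
# beta-hat = M X' W y with W = Omega^-1, M = (X' W X)^-1. The CR2 adjustment
# A_j is the symmetric matrix satisfying A_j S_j A_j = Omega_j where
# S_j = Var(e_j) = Omega_j - X_j M X_j' under the working model, so the meat
# is unbiased when the working model holds. Satterthwaite df for a contrast c
# use q_j' Omega q_k, with (I - H) Omega (I - H)' blocks
# Omega_j - X_j M X_j' (diagonal) and -X_j M X_k' (off-diagonal).

# symmetric matrix power via eigendecomposition; pseudo-inverts tiny
# eigenvalues (rank deficiency from residual constraints)
.symPower <- function(S, pow) {
  eg <- eigen(S, symmetric = TRUE)
  vals <- eg$values
  tol <- max(vals) * 1e-10
  out <- ifelse(vals > tol, vals^pow, 0)
  eg$vectors %*% (out * t(eg$vectors))
}

# Per-cluster CR2 pieces for working correlation V_j = I + theta * J.
# Returns, for each cluster: zMat (n_j x p, column k = z_j for coefficient k),
# plus a_j (p x p: X_j' z_j per coefficient) and b_j per coefficient.
.cr2Pieces <- function(X, blocks, theta) {
  p <- ncol(X)
  XtWX <- matrix(0, p, p)
  Vinv <- vector("list", length(blocks))
  for (j in seq_along(blocks)) {
    b <- blocks[[j]]
    nj <- length(b)
    Vi <- diag(nj) - (theta / (1 + nj * theta)) * matrix(1, nj, nj)
    Vinv[[j]] <- Vi
    XtWX <- XtWX + crossprod(X[b, , drop = FALSE], Vi %*% X[b, , drop = FALSE])
  }
  M <- solve(XtWX)
  pieces <- vector("list", length(blocks))
  for (j in seq_along(blocks)) {
    b <- blocks[[j]]
    nj <- length(b)
    Xj <- X[b, , drop = FALSE]
    Vj <- diag(nj) + theta * matrix(1, nj, nj)
    Sj <- Vj - Xj %*% M %*% t(Xj)
    Vh <- .symPower(Vj, 0.5)
    Aj <- Vh %*% .symPower(Vh %*% Sj %*% Vh, -0.5) %*% Vh
    # z_j for all unit contrasts at once: columns are coefficients;
    # the meat term is M X_j' W_j (A_j e_j), so z_j = A_j W_j X_j M c
    Zj <- Aj %*% Vinv[[j]] %*% Xj %*% M
    pieces[[j]] <- list(block = b, Z = Zj, XtZ = crossprod(Xj, Zj),
                        ZtVZ = crossprod(Zj, Vj %*% Zj))
  }
  list(M = M, pieces = pieces)
}

# CR2 covariance of beta-hat and Satterthwaite df per coefficient.
# e: working residuals y - X beta-hat. Returns list(vcov, df).
.crVcovDf <- function(X, blocks, theta, e) {
  p <- ncol(X)
  cp <- .cr2Pieces(X, blocks, theta)
  M <- cp$M
  J <- length(blocks)
  U <- matrix(0, J, p)            # U[j, k] = z_{jk}' e_j
  aArr <- array(0, c(p, p, J))     # a_{jk} = X_j' z_{jk}
  bMat <- matrix(0, J, p)          # b_{jk} = z_{jk}' V_j z_{jk}
  for (j in seq_len(J)) {
    pc <- cp$pieces[[j]]
    U[j, ] <- crossprod(pc$Z, e[pc$block])
    aArr[, , j] <- pc$XtZ
    bMat[j, ] <- diag(pc$ZtVZ)
  }
  vc <- crossprod(U)               # sum_j u_j u_j' (already includes M via Z)
  df <- numeric(p)
  for (k in seq_len(p)) {
    A <- matrix(aArr[, k, ], nrow = p)        # p x J, columns a_{jk}
    G <- crossprod(A, M %*% A)                # J x J
    dj <- bMat[, k] - diag(G)
    num <- sum(dj)^2
    den <- sum(dj^2) + sum(G^2) - sum(diag(G)^2)
    df[k] <- num / max(den, .Machine$double.xmin)
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(df) <- colnames(X)
  list(vcov = vc, df = df)
}
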