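# Independent reference implementations used as oracles. These are written
# directly from the textbook definitions with dense matrices and no shared
# code with the package internals.

# symmetric matrix power via eigendecomposition (pseudo-inverse for
# singular matrices)
oracleSymPower <- function(S, pow) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- eg$values
  tol <- max(abs(lam)) * 1e-10
  lp <- ifelse(lam > tol, lam^pow, 0)
  eg$vectors %*% (lp * t(eg$vectors))
}

# dense CR2 cluster-robust covariance with Satterthwaite df for one
# coefficient, for the random-intercept GLS model with variance ratio theta
# (sigma_lambda2 / sigma_eps2, error variance normalized to 1).
# Definitions: W = Omega^-1, M = (X'WX)^-1, H = X M X' W,
# S_j = [(I - H) Omega (I - H)']_jj, A_j with A_j S_j A_j' = Omega_j,
# meat_j = M X_j' W_j A_j e_j; Satterthwaite df from the distribution of
# sum_j z_j' e_j with z_j = A_j' W_j X_j M c.
oracleCR2 <- function(X, cluster, theta, e) {
  cluster <- as.factor(cluster)
  n <- nrow(X)
  p <- ncol(X)
  Omega <- diag(n)
  for (lev in levels(cluster)) {
    id <- which(cluster == lev)
    Omega[id, id] <- Omega[id, id] + theta
  }
  W <- solve(Omega)
  M <- solve(t(X) %*% W %*% X)
  H <- X %*% M %*% t(X) %*% W
  IH <- diag(n) - H
  Smat <- IH %*% Omega %*% t(IH)
  levs <- levels(cluster)
  J <- length(levs)
  meat <- matrix(0, p, J)
  zlist <- vector("list", J)
  for (j in seq_len(J)) {
    id <- which(cluster == levs[j])
    Sj <- Smat[id, id, drop = FALSE]
    Oj <- Omega[id, id, drop = FALSE]
    Vh <- oracleSymPower(Oj, 0.5)
    inner <- Vh %*% Sj %*% Vh
    Aj <- Vh %*% oracleSymPower(inner, -0.5) %*% Vh
    Wj <- W[id, id, drop = FALSE]
    Xj <- X[id, , drop = FALSE]
    meat[, j] <- M %*% t(Xj) %*% Wj %*% Aj %*% e[id]
    zlist[[j]] <- list(id = id, z = t(Aj) %*% Wj %*% Xj %*% M)
  }
  vcov <- meat %*% t(meat)
  # Satterthwaite df per coefficient: statistic sum_j (z_j' e_j) with
  # E under homoskedastic working model; df = (sum d)^2 / Var where
  # Var = 2 sum_j d_j^2 + 2 sum_{j != k} (z_j' Omega_{jk} z_k)^2 with
  # Omega block-diagonal so cross terms use G_jk = z_j' X_j M X_k' z_k signs
  df <- numeric(p)
  for (ci in seq_len(p)) {
    zs <- lapply(zlist, function(l) {
      zz <- numeric(n)
      zz[l$id] <- l$z[, ci]
      zz
    })
    Gm <- matrix(0, J, J)
    b <- numeric(J)
    for (j in seq_len(J)) {
      for (k in seq_len(J)) {
        # Cov(z_j' e, z_k' e) under the working model: z_j' (I-H) Omega
        # (I-H)' z_k
        Gm[j, k] <- t(zs[[j]]) %*% IH %*% Omega %*% t(IH) %*% zs[[k]]
      }
      b[j] <- t(zs[[j]]) %*% Omega %*% zs[[j]]
    }
    ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
    df[ci] <- sum(ev)^2 / sum(ev^2)
  }
  list(vcov = vcov, df = df)
}

# brute-force discrete sphere voxel count: integer offsets with
# squared distance <= r^2
oracleSphereCount <- function(r) {
  g <- seq(-ceiling(r), ceiling(r))
  idx <- expand.grid(g, g, g)
  sum(idx[, 1]^2 + idx[, 2]^2 + idx[, 3]^2 <= r^2 + 1e-9)
}

# flood-fill 6-connected components of a logical 3-D array (recursive BFS,
# no shared code with the package's union-find)
oracleComponents6 <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      if (!mask[i, j, k] || lab[i, j, k] != 0L) next
      cur <- cur + 1L
      queue <- matrix(c(i, j, k), 1)
      lab[i, j, k] <- cur
      while (nrow(queue) > 0) {
        v <- queue[1, ]
        queue <- queue[-1, , drop = FALSE]
        for (o in seq_len(6)) {
          w <- v + offs[o, ]
          if (any(w < 1) || any(w > dims)) next
          if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
            lab[w[1], w[2], w[3]] <- cur
            queue <- rbind(queue, w)
          }
        }
      }
    }
  lab
}

# balanced one-way ANOVA ICC(1,1) via explicit mean squares
oracleICC11 <- function(values, groups) {
  k <- length(unique(table(groups)))
  stopifnot(k == 1)  # balanced only
  ni <- as.numeric(table(groups)[1])
  a <- length(unique(groups))
  gm <- tapply(values, groups, mean)
  msb <- ni * sum((gm - mean(values))^2) / (a - 1)
  msw <- sum((values - gm[as.character(groups)])^2) / (a * (ni - 1))
  s2b <- max((msb - msw) / ni, 0)
  s2b / (s2b + msw)
}

# simple simulated panel helpers shared across tests
makeTestPredictor <- function(n = 30, s = 10, seed = 1) {
  generatePredictorPanel(sqrt(0.44), sqrt(0.56), n, s, seed = seed)
}
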