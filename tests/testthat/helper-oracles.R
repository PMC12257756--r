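# Independent oracles used across the suite. These deliberately avoid the
# package's sparse mixed-model-equation machinery: dense V-matrix algebra,
# gene dropping, and recursive kinship recursions.

# restricted -2 log-likelihood from dense V (independent of the MME path)
dense_n2ll <- function(v, design, ped) {
  n <- design$n
  A <- relationship_matrix(ped)
  X <- design$X
  y <- design$Y[, 1L]
  V <- v[length(v)] * diag(n)
  for (k in seq_along(design$Zlist)) {
    Z <- as.matrix(design$Zlist[[k]])
    K <- if (names(design$Zlist)[k] == "animal") A else diag(ncol(Z))
    V <- V + v[k] * Z %*% K %*% t(Z)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric((n - ncol(X)) * log(2 * pi) + determinant(V)$modulus +
               determinant(XtViX)$modulus + t(y) %*% P %*% y)
}

# dense generalized-least-squares fixed effects and BLUP breeding values
dense_gls <- function(v, design, ped) {
  n <- design$n
  A <- relationship_matrix(ped)
  X <- design$X
  y <- design$Y[, 1L]
  V <- v[length(v)] * diag(n)
  for (k in seq_along(design$Zlist)) {
    Z <- as.matrix(design$Zlist[[k]])
    K <- if (names(design$Zlist)[k] == "animal") A else diag(ncol(Z))
    V <- V + v[k] * Z %*% K %*% t(Z)
  }
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ka <- match("animal", names(design$Zlist))
  Za <- as.matrix(design$Zlist[[ka]])
  u <- v[ka] * A %*% t(Za) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b), ebv = as.numeric(u))
}

# gene-dropping estimate of additive relationships for a set of id pairs;
# founders receive unique alleles, relationships are twice the IBD
# probability of randomly drawn alleles
gene_drop_a <- function(ped, pairs, ndrop = 2e5, seed = 99) {
  set.seed(seed)
  n <- length(ped$id)
  M <- matrix(0L, ndrop, n)
  P <- matrix(0L, ndrop, n)
  aid <- 0L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L) {
      aid <- aid + 1L
      M[, i] <- aid
    } else {
      pick <- stats::runif(ndrop) < 0.5
      M[, i] <- ifelse(pick, M[, s], P[, s])
    }
    if (d == 0L) {
      aid <- aid + 1L
      P[, i] <- aid
    } else {
      pick <- stats::runif(ndrop) < 0.5
      P[, i] <- ifelse(pick, M[, d], P[, d])
    }
  }
  t(apply(pairs, 1L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    phi <- ((M[, i] == M[, j]) + (M[, i] == P[, j]) +
              (P[, i] == M[, j]) + (P[, i] == P[, j])) / 4
    c(est = 2 * mean(phi), se = 2 * stats::sd(phi) / sqrt(ndrop))
  }))
}

# recursive kinship (and hence inbreeding) oracle
kinship_oracle <- function(ped) {
  n <- length(ped$id)
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    for (j in seq_len(i - 1L)) {
      v <- 0
      if (s > 0L) v <- v + 0.5 * phi[s, j]
      if (d > 0L) v <- v + 0.5 * phi[d, j]
      phi[i, j] <- phi[j, i] <- v
    }
    phi[i, i] <- 0.5 + 0.5 * (if (s > 0L && d > 0L) phi[s, d] else 0)
  }
  phi
}

# random pedigree with complete parentage for non-founders
random_pedigree <- function(n_founders = 14, n_offspring = 36, seed = 7) {
  set.seed(seed)
  id <- sprintf("F%02d", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  sire <- dam <- rep(NA_character_, n_founders)
  for (k in seq_len(n_offspring)) {
    males <- id[sex == "M"]
    females <- id[sex == "F"]
    id <- c(id, sprintf("O%02d", k))
    sire <- c(sire, sample(males, 1L))
    dam <- c(dam, sample(females, 1L))
    sex <- c(sex, sample(c("M", "F"), 1L))
  }
  new_pedigree(id, sire, dam)
}

# small simulated dataset used by several model tests
small_dataset <- function(seed = 3, dams = 10, frac = 0.5) {
  cfg <- sim_config(n_lines = 1, generations = 3, sires_per_gen = 3,
                    dams_per_gen = dams, phenotyped_fraction = frac,
                    seed = seed)
  simulate_dataset(cfg)
}
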