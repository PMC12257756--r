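# ---- average-information REML engine ---------------------------------------
#
# Shared by the univariate (d = 1) and bivariate (d = 2) fits. The state is
# one d x d covariance block per random term plus the residual. Each
# iteration: (1) assemble the mixed-model-equation coefficient matrix on its
# fixed sparsity pattern, permuted once by a fill-reducing ordering; (2)
# factorize it as L D L' (compiled kernel); (3) exact first derivatives of
# the restricted log-likelihood from the Takahashi selected inverse (traces
# of the inverse coefficient matrix against the sparse inverse-covariance
# blocks); (4) average-information matrix from working variates (one
# multi-RHS solve); (5) Newton step with step halving, variance floors and
# projection of non-PSD blocks. Convergence: relative component change below
# `tol_comp` and -2logL change below `tol_logl`.

.reml_ai <- function(prep, design, d, t_idx = 1L, start_blocks, fix_term = NA,
                     fixed_r = NA_real_, floor_, maxit = 60L,
                     tol_comp = 1e-6, tol_logl = 1e-8) {
  terms_all <- c(prep$terms, "residual")
  nt <- length(terms_all)
  nk <- nt - 1L
  m <- prep$m
  mm <- d * m
  n <- prep$n

  if (d == 1L) {
    tmpl <- prep$Ctmpl
    assemble_x <- function(blocks) {
      coef <- c(1 / blocks[[nt]][1, 1],
                vapply(blocks[seq_len(nk)], function(b) 1 / b[1, 1], 0))
      .assemble_uni_x(prep, coef)
    }
  } else {
    asmb <- .biv_assembler(prep)
    tmpl <- asmb$tmpl
    assemble_x <- function(blocks) {
      coefs <- c(list(solve(blocks[[nt]])),
                 lapply(blocks[seq_len(nk)], solve))
      .assemble_biv_x(asmb, coefs)
    }
  }

  # fill-reducing ordering from one CHOLMOD analysis of the template
  x0 <- assemble_x(start_blocks)
  C0 <- tmpl; C0@x <- x0
  ch0 <- Matrix::Cholesky(C0, LDL = TRUE, super = FALSE, perm = TRUE)
  perm <- ch0@perm + 1L
  ipos <- integer(mm); ipos[perm] <- seq_len(mm)
  Tt <- as(tmpl, "TsparseMatrix")
  bi <- ipos[Tt@i + 1L]; bj <- ipos[Tt@j + 1L]
  i2 <- pmin(bi, bj); j2 <- pmax(bi, bj)
  ptmpl <- as(Matrix::sparseMatrix(i = i2, j = j2, x = 1, dims = c(mm, mm),
                                   symmetric = TRUE), "CsparseMatrix")
  pT <- as(ptmpl, "TsparseMatrix")
  posmap <- match((i2 - 1L) + mm * as.double(j2 - 1L),
                  pT@i + mm * as.double(pT@j))
  Ap <- ptmpl@p; Aip <- ptmpl@i
  sym <- ldl_symbolic(mm, Ap, Aip)

  Yd <- prep$Y[, if (d == 1L) t_idx else seq_len(d), drop = FALSE]
  TtYd <- prep$TtY[, if (d == 1L) t_idx else seq_len(d), drop = FALSE]
  YtYd <- prep$YtY[if (d == 1L) t_idx else seq_len(d),
                   if (d == 1L) t_idx else seq_len(d), drop = FALSE]

  solve_perm <- function(fac, B) {
    Bp <- B[perm, , drop = FALSE]
    X <- ldl_solve(mm, sym$Lp, fac$Li, fac$Lx, fac$D, Bp)
    out <- matrix(0, mm, ncol(B))
    out[perm, ] <- X
    out
  }

  eval_state <- function(blocks) {
    xx <- tryCatch(assemble_x(blocks), error = function(e) NULL)
    if (is.null(xx)) return(NULL)
    xp <- numeric(length(xx)); xp[posmap] <- xx
    fac <- ldl_numeric(mm, Ap, Aip, xp, sym$Lp, sym$Parent)
    if (!fac$ok) return(NULL)
    R0 <- blocks[[nt]]
    R0i <- tryCatch(solve(R0), error = function(e) NULL)
    if (is.null(R0i)) return(NULL)
    rhs <- as.numeric(TtYd %*% R0i)      # stacks trait blocks column-wise
    s <- solve_perm(fac, matrix(rhs, mm, 1L))[, 1L]
    yPy <- sum(R0i * YtYd) - sum(s * rhs)
    ldG <- 0
    for (k in seq_len(nk)) {
      ldG <- ldG + prep$q[k] * as.numeric(determinant(blocks[[k]])$modulus)
      if (prep$terms[k] == "animal") ldG <- ldG + d * prep$logdetA
    }
    val <- unname(d * (n - prep$p) * log(2 * pi) +
      n * as.numeric(determinant(R0)$modulus) + ldG +
      sum(log(fac$D)) + yPy)
    list(fac = fac, s = s, val = val, R0i = R0i)
  }

  # free-parameter layout per term: d=1 -> (v); d=2 -> (v1, c, v2) or
  # (v1, v2) when the correlation is frozen
  is_fixed <- !is.na(fix_term) & terms_all == fix_term
  par_index <- list(); pos <- 0L
  for (k in seq_len(nt)) {
    npk <- if (d == 1L) 1L else if (is_fixed[k]) 2L else 3L
    par_index[[k]] <- pos + seq_len(npk)
    pos <- pos + npk
  }
  npar <- pos
  blocks_to_theta <- function(blocks) {
    th <- numeric(npar)
    for (k in seq_len(nt)) {
      b <- blocks[[k]]
      th[par_index[[k]]] <- if (d == 1L) b[1, 1]
        else if (is_fixed[k]) c(b[1, 1], b[2, 2])
        else c(b[1, 1], b[1, 2], b[2, 2])
    }
    th
  }
  theta_to_blocks <- function(th) {
    blocks <- vector("list", nt)
    for (k in seq_len(nt)) {
      tk <- th[par_index[[k]]]
      if (d == 1L) {
        blocks[[k]] <- matrix(max(tk, floor_), 1L, 1L)
      } else if (is_fixed[k]) {
        v <- pmax(tk, floor_)
        cc <- fixed_r * sqrt(v[1L] * v[2L])
        blocks[[k]] <- matrix(c(v[1L], cc, cc, v[2L]), 2L)
      } else {
        v1 <- max(tk[1L], floor_); v2 <- max(tk[3L], floor_)
        b <- matrix(c(v1, tk[2L], tk[2L], v2), 2L)
        ev <- eigen(b, symmetric = TRUE)
        evmin <- max(floor_ * 1e-2, 1e-7 * abs(ev$values[1L]))
        if (ev$values[2L] < evmin) {   # project to nearest invertible PSD
          b <- ev$vectors %*% diag(pmax(ev$values, evmin)) %*% t(ev$vectors)
          attr(b, "projected") <- TRUE
        }
        blocks[[k]] <- b
      }
    }
    blocks
  }

  # derivative bases dSigma/dtheta per term
  e_bases <- function(k, blocks) {
    if (d == 1L) return(list(matrix(1, 1L, 1L)))
    if (is_fixed[k]) {
      b <- blocks[[k]]
      r <- fixed_r
      list(matrix(c(1, r / 2 * sqrt(b[2, 2] / b[1, 1]),
                    r / 2 * sqrt(b[2, 2] / b[1, 1]), 0), 2L),
           matrix(c(0, r / 2 * sqrt(b[1, 1] / b[2, 2]),
                    r / 2 * sqrt(b[1, 1] / b[2, 2]), 1), 2L))
    } else {
      list(matrix(c(1, 0, 0, 0), 2L),
           matrix(c(0, 1, 1, 0), 2L),
           matrix(c(0, 0, 0, 1), 2L))
    }
  }

  # positions in the Takahashi output needed for the trace terms, built once
  pos_env <- new.env(parent = emptyenv())
  build_positions <- function(Z) {
    full_trip <- function(M) {
      Mt <- as(as(as(M, "CsparseMatrix"), "generalMatrix"), "TsparseMatrix")
      list(i = Mt@i, j = Mt@j, x = Mt@x)
    }
    sets <- vector("list", nt)
    for (k in seq_len(nt)) {
      if (terms_all[k] == "residual") {
        G <- full_trip(prep$TtT); off <- 0L
      } else if (terms_all[k] == "animal") {
        G <- full_trip(prep$Ainv); off <- prep$offsets[k]
      } else {
        q <- prep$q[k]; off <- prep$offsets[k]
        G <- list(i = seq_len(q) - 1L, j = seq_len(q) - 1L, x = rep(1, q))
      }
      pairs <- list()
      for (a in seq_len(d)) for (b in seq_len(d)) {
        if (b < a) next
        pi_ <- ipos[G$i + 1L + off + (a - 1L) * m]
        pj_ <- ipos[G$j + 1L + off + (b - 1L) * m]
        idx <- z_positions(Z$Zp, Z$Zi, pmax(pi_, pj_) - 1L, pmin(pi_, pj_) - 1L)
        if (any(idx == 0L))
          stop("internal error: inverse entry outside the factor pattern")
        pairs[[paste(a, b)]] <- list(idx = idx, w = G$x)
      }
      sets[[k]] <- pairs
    }
    pos_env$sets <- sets
  }
  trace_mats <- function(Z) {
    if (is.null(pos_env$sets)) build_positions(Z)
    lapply(pos_env$sets, function(pairs) {
      M <- matrix(0, d, d)
      for (nm in names(pairs)) {
        ab <- as.integer(strsplit(nm, " ")[[1L]])
        v <- sum(pairs[[nm]]$w * Z$Zx[pairs[[nm]]$idx])
        M[ab[1L], ab[2L]] <- v
        M[ab[2L], ab[1L]] <- v
      }
      M
    })
  }

  grad_ai <- function(st, blocks, TR) {
    R0i <- st$R0i
    E <- Yd - matrix(as.numeric(prep$T %*% matrix(st$s, m, d)), n, d)
    Py <- E %*% R0i
    # working variates W[, i] is a (n x d) matrix flattened column-major
    W <- list(); EB <- list(); termof <- integer(0)
    for (k in seq_len(nt)) {
      if (terms_all[k] == "residual") {
        base <- Py
      } else {
        Zk <- design$Zlist[[k]]
        Tk <- crossprod(Zk, Py)
        if (terms_all[k] == "animal") Tk <- solve(prep$Ainv, Tk)
        base <- as.matrix(Zk %*% Tk)
      }
      for (Ei in e_bases(k, blocks)) {
        W[[length(W) + 1L]] <- base %*% Ei
        EB[[length(EB) + 1L]] <- Ei
        termof <- c(termof, k)
      }
    }
    # gradients
    g <- numeric(npar)
    yPVPy <- vapply(W, function(w) sum(w * Py), 0)
    for (i in seq_along(W)) {
      k <- termof[i]; Ei <- EB[[i]]
      if (terms_all[k] == "residual") {
        Mi <- R0i %*% Ei %*% R0i
        trPV <- n * sum(R0i * Ei) - sum(Mi * TR[[k]])
      } else {
        Si <- solve(blocks[[k]])
        Mi <- Si %*% Ei %*% Si
        trPV <- prep$q[k] * sum(Si * Ei) - sum(Mi * TR[[k]])
      }
      g[i] <- -0.5 * (trPV - yPVPy[i])
    }
    # average information via one multi-RHS solve
    RHS <- matrix(0, mm, length(W))
    for (i in seq_along(W))
      RHS[, i] <- as.numeric(crossprod(prep$T, W[[i]] %*% R0i))
    SW <- solve_perm(st$fac, RHS)
    AI <- matrix(0, length(W), length(W))
    PW <- vector("list", length(W))
    for (i in seq_along(W)) {
      Dw <- W[[i]] - matrix(as.numeric(prep$T %*% matrix(SW[, i], m, d)), n, d)
      PW[[i]] <- Dw %*% R0i
    }
    for (i in seq_along(W)) for (j in i:length(W)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(W[[i]] * PW[[j]])
    }
    list(g = g, AI = AI)
  }

  # expectation-maximization update (monotone; used when the AI step fails)
  em_step <- function(st, blocks, TR) {
    out <- blocks
    Smat <- matrix(st$s, m, d)
    for (k in seq_len(nk)) {
      ix <- prep$offsets[k] + seq_len(prep$q[k])
      U <- Smat[ix, , drop = FALSE]
      UKU <- if (prep$terms[k] == "animal")
        crossprod(U, as.matrix(solve(prep$Ainv, U))) else crossprod(U)
      out[[k]] <- (UKU + TR[[k]]) / prep$q[k]
    }
    E <- Yd - matrix(as.numeric(prep$T %*% Smat), n, d)
    out[[nt]] <- (crossprod(E, Yd) + crossprod(Yd, E)) / (2 * (n - prep$p))
    theta_to_blocks(blocks_to_theta(out))   # apply floors / fixed correlation
  }

  # ---- iterations: AI steps with halving, EM fallback ----
  blocks <- start_blocks
  st <- eval_state(blocks)
  if (is.null(st)) stop("starting values give a singular coefficient matrix")
  converged <- FALSE
  iter <- 0L
  projected <- FALSE
  varp <- mean(diag(YtYd)) / n
  TR <- NULL
  repeat {
    if (maxit == 0L) { converged <- NA; break }
    iter <- iter + 1L
    Z <- ldl_takahashi(mm, sym$Lp, st$fac$Li, st$fac$Lx, st$fac$D)
    TR <- trace_mats(Z)
    ga <- grad_ai(st, blocks, TR)
    step <- as.numeric(.safe_inv(ga$AI) %*% ga$g)
    th <- blocks_to_theta(blocks)
    scale <- 1
    accepted <- FALSE
    for (h in seq_len(15L)) {
      th_new <- th + scale * step
      blocks_new <- theta_to_blocks(th_new)
      st_new <- eval_state(blocks_new)
      if (!is.null(st_new) && st_new$val < st$val - 1e-11) {
        accepted <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!accepted) {
      blocks_new <- em_step(st, blocks, TR)
      st_new <- eval_state(blocks_new)
      if (!is.null(st_new) && st_new$val < st$val - 1e-11) {
        accepted <- TRUE
      }
    }
    if (!accepted) { converged <- TRUE; break }  # numerical optimum
    th_acc <- blocks_to_theta(blocks_new)
    relchg <- max(abs(th_acc - th) / pmax(abs(th), 1e-3 * varp))
    dval <- st$val - st_new$val
    projected <- any(vapply(blocks_new, function(b)
      isTRUE(attr(b, "projected")), TRUE))
    blocks <- blocks_new
    st <- st_new
    if (relchg < tol_comp && dval < tol_logl) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  Z <- ldl_takahashi(mm, sym$Lp, st$fac$Li, st$fac$Lx, st$fac$D)
  ga <- grad_ai(st, blocks, trace_mats(Z))
  varcov <- .safe_inv(ga$AI)

  # prediction error variances of all animals from the selected inverse
  pev_all <- NULL
  if ("animal" %in% prep$terms) {
    Z <- ldl_takahashi(mm, sym$Lp, st$fac$Li, st$fac$Lx, st$fac$D)
    ka <- match("animal", prep$terms)
    cols <- prep$offsets[ka] + seq_len(prep$q[ka])
    pev_all <- matrix(0, prep$q[ka], d)
    for (a in seq_len(d)) {
      p_ <- ipos[cols + (a - 1L) * m]
      pev_all[, a] <- Z$Zx[Z$Zp[p_] + 1L]
    }
    rownames(pev_all) <- design$levels[["animal"]]
  }

  names(blocks) <- terms_all
  list(blocks = blocks, s = st$s, val = st$val, logLik = -st$val / 2,
       converged = converged, iterations = iter, gradient = ga$g,
       AI = ga$AI, varcov = varcov, par_index = par_index,
       projected = projected, pev = pev_all)
}
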