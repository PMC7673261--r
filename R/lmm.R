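# Gene-wise linear mixed models with a single random intercept.
#
# Model per gene g:  y_g = X beta_g + Z b_g + e_g,
#   b_g ~ N(0, sigma_b^2 I_q) over subjects, e_g ~ N(0, sigma_e^2 I_n).
# Because X and the subject grouping Z are shared across genes, the profiled
# REML criterion in the variance ratio lambda = sigma_b^2 / sigma_e^2 reduces
# to per-subject shrinkage weights:
#   V^-1 = I - Z diag(lambda / (1 + lambda n_s)) Z',
#   log|V| = sum_s log(1 + lambda n_s),
# so one lambda evaluation for ALL genes costs a handful of small matrix
# products. A shared lambda grid is evaluated in bulk, then each gene's
# optimum is refined by Brent search in its bracketing interval. lme4 is the
# independent oracle for this fitter in the test suite.

#' Fit a random-intercept linear model to every gene at once
#'
#' @param y Matrix genes x samples of continuous values.
#' @param x Fixed-effect design matrix (samples x p), full column rank.
#' @param subject Factor/character of subject IDs, one per sample.
#' @param lambda_max Upper bound for the variance ratio search.
#' @param n_grid Size of the shared log-spaced lambda grid.
#' @param reml_keep_threshold A gene's random intercept is retained only
#'   when it improves the -2 restricted log-likelihood by more than this
#'   (restricted LRT against the boundary; the null is the
#'   half-and-half chi-square mixture, so the default `qchisq(0.95, 1)`
#'   keeps ~2.5 percent of genes under a truly zero donor variance).
#'   Fits below the threshold are classed singular, exactly like
#'   boundary estimates. Set to 0 for raw boundary behaviour (lme4
#'   semantics).
#' @return List with per-gene `beta` (genes x p), `sigma2`, `lambda`,
#'   `singular` (boundary or unsupported fit, lambda = 0),
#'   `zero_variance`, the per-gene unscaled coefficient covariance
#'   `cov_unscaled` (p x p x genes), BLUP ingredients and the design
#'   bookkeeping.
#' @keywords internal
lmm_fit_genes <- function(y, x, subject, lambda_max = 1e6, n_grid = 41L,
                          reml_keep_threshold = stats::qchisq(0.95, 1)) {
  stopifnot(is.matrix(y), nrow(x) == ncol(y))
  subject <- factor(subject)
  n <- ncol(y)
  p <- ncol(x)
  g <- nrow(y)
  q <- nlevels(subject)
  z_idx <- as.integer(subject)
  ns <- tabulate(z_idx, q)

  yt <- t(y)                                   # n x g
  zty <- rowsum(yt, z_idx, reorder = TRUE)     # q x g group sums
  ztx <- rowsum(x, z_idx, reorder = TRUE)      # q x p
  xtx <- crossprod(x)                          # p x p
  xty <- crossprod(x, yt)                      # p x g
  yty <- colSums(yt^2)

  zero_variance <- unname(apply(y, 1, function(v) var(v) < 1e-12))

  # -2 * restricted log-likelihood (up to constants), all genes at one lambda
  crit_all <- function(lambda) {
    w <- lambda / (1 + lambda * ns)
    a <- xtx - crossprod(ztx, ztx * w)               # X' V^-1 X
    b <- xty - crossprod(ztx, zty * w)               # X' V^-1 Y
    yy <- yty - colSums(zty^2 * w)                   # diag Y' V^-1 Y
    beta <- solve(a, b)
    rss <- pmax(yy - colSums(b * beta), 1e-300)
    (n - p) * log(rss) + sum(log1p(lambda * ns)) +
      determinant(a, logarithm = TRUE)$modulus[1]
  }

  grid <- c(0, 10^seq(-6, log10(lambda_max), length.out = n_grid - 1L))
  crit_mat <- matrix(vapply(grid, crit_all, numeric(g)), nrow = g)
  best_j <- max.col(-crit_mat, ties.method = "first")

  lambda_hat <- numeric(g)
  crit_one <- function(lambda, gi) {
    w <- lambda / (1 + lambda * ns)
    a <- xtx - crossprod(ztx, ztx * w)
    b <- xty[, gi] - crossprod(ztx, zty[, gi] * w)[, 1]
    yy <- yty[gi] - sum(zty[, gi]^2 * w)
    beta <- solve(a, b)
    rss <- max(yy - sum(b * beta), 1e-300)
    (n - p) * log(rss) + sum(log1p(lambda * ns)) +
      determinant(a, logarithm = TRUE)$modulus[1]
  }
  crit_best <- crit_mat[cbind(seq_len(g), best_j)]
  interior <- which(best_j > 1L & best_j < length(grid) & !zero_variance)
  for (gi in interior) {
    j <- best_j[gi]
    opt <- optimize(crit_one, gi = gi,
                    interval = c(grid[j - 1L], grid[j + 1L]))
    # keep the boundary if it is at least as good (numerical safety)
    if (crit_mat[gi, 1] <= opt$objective) {
      lambda_hat[gi] <- 0
      crit_best[gi] <- crit_mat[gi, 1]
    } else {
      lambda_hat[gi] <- opt$minimum
      crit_best[gi] <- opt$objective
    }
  }
  at_top <- which(best_j == length(grid) & !zero_variance)
  lambda_hat[at_top] <- grid[length(grid)]
  # restricted LRT against the boundary: random intercept kept only when
  # it improves -2 lR by more than the threshold
  reml_improvement <- unname(pmax(crit_mat[, 1] - crit_best, 0))
  singular <- lambda_hat <= 1e-10 | zero_variance |
    reml_improvement <= reml_keep_threshold
  lambda_hat[singular] <- 0

  # final per-gene quantities; genes sharing lambda = 0 are batched
  beta <- matrix(NA_real_, g, p,
                 dimnames = list(rownames(y), colnames(x)))
  sigma2 <- numeric(g)
  cov_unscaled <- array(NA_real_, c(p, p, g))
  finalize <- function(idx, lambda) {
    w <- lambda / (1 + lambda * ns)
    a <- xtx - crossprod(ztx, ztx * w)
    ai <- solve(a)
    b <- xty[, idx, drop = FALSE] - crossprod(ztx, zty[, idx, drop = FALSE] * w)
    bet <- ai %*% b
    yy <- yty[idx] - colSums(zty[, idx, drop = FALSE]^2 * w)
    rss <- pmax(yy - colSums(b * bet), 0)
    list(beta = t(bet), sigma2 = rss / (n - p), ai = ai)
  }
  sing_idx <- which(singular)
  if (length(sing_idx) > 0) {
    fin <- finalize(sing_idx, 0)
    beta[sing_idx, ] <- fin$beta
    sigma2[sing_idx] <- fin$sigma2
    cov_unscaled[, , sing_idx] <- fin$ai
  }
  for (gi in which(!singular)) {
    fin <- finalize(gi, lambda_hat[gi])
    beta[gi, ] <- fin$beta
    sigma2[gi] <- fin$sigma2
    cov_unscaled[, , gi] <- fin$ai
  }

  list(
    beta = beta, sigma2 = sigma2, lambda = lambda_hat,
    singular = singular, zero_variance = zero_variance,
    reml_improvement = reml_improvement,
    cov_unscaled = cov_unscaled,
    n = n, p = p, df_resid = n - p,
    subject = subject, ns = ns, z_idx = z_idx,
    x = x, zty = zty, xty = xty, ztx = ztx, xtx = xtx, yty = yty,
    gene_ids = rownames(y)
  )
}

# Per-subject BLUPs b_hat = lambda Z'V^-1 (y - X beta) for one fit.
# Returns genes x q matrix.
lmm_blups <- function(fit, y) {
  g <- nrow(y)
  q <- length(fit$ns)
  blup <- matrix(0, g, q)
  # Z'(y - X beta) = Z'y - (Z'X) beta'
  ztr <- fit$zty - fit$ztx %*% t(fit$beta)             # q x g
  for (gi in seq_len(g)) {
    lam <- fit$lambda[gi]
    if (lam > 0) {
      blup[gi, ] <- lam * ztr[, gi] / (1 + lam * fit$ns)
    }
  }
  blup
}

# ---- Satterthwaite denominator degrees of freedom ------------------------
#
# For a non-singular gene the Satterthwaite df of a contrast c is
#   nu = 2 (c' Vbeta c)^2 / (g' W g),
# where g is the gradient of c' Vbeta(eta) c in the variance parameters
# eta = (sigma_b^2, sigma_e^2) and W the asymptotic covariance of eta_hat
# (twice the inverse Hessian of the -2 restricted log-likelihood). Multi-df
# F tests combine the eigencontrast dfs as 2E/(E - q) with
# E = sum nu_m/(nu_m - 2). Singular fits are exact OLS: df = n - p.

# -2 restricted log-likelihood (up to constants) at eta for one gene
reml_m2ll_eta <- function(fit, gi, eta) {
  sb2 <- eta[1]; se2 <- eta[2]
  lambda <- sb2 / se2
  ns <- fit$ns
  w <- lambda / (1 + lambda * ns)
  a <- fit$xtx - crossprod(fit$ztx, fit$ztx * w)
  b <- fit$xty[, gi] - crossprod(fit$ztx, fit$zty[, gi] * w)[, 1]
  yy <- fit$yty[gi] - sum(fit$zty[, gi]^2 * w)
  beta <- solve(a, b)
  rss <- max(yy - sum(b * beta), 1e-300)
  (fit$n - fit$p) * log(se2) + sum(log1p(lambda * ns)) +
    determinant(a, logarithm = TRUE)$modulus[1] + rss / se2
}

# coefficient covariance sigma_e^2 * (X' V^-1 X)^-1 at eta
vbeta_eta <- function(fit, eta) {
  lambda <- eta[1] / eta[2]
  w <- lambda / (1 + lambda * fit$ns)
  a <- fit$xtx - crossprod(fit$ztx, fit$ztx * w)
  eta[2] * solve(a)
}

# Per-gene cache: covariance of the variance parameters and the Jacobians
# of Vbeta in each; NULL for singular / zero-variance genes.
satt_gene_cache <- function(fit, gi) {
  if (fit$singular[gi]) return(NULL)
  eta <- c(fit$lambda[gi] * fit$sigma2[gi], fit$sigma2[gi])
  h <- pmax(1e-8, 1e-4 * eta)
  f <- function(e) reml_m2ll_eta(fit, gi, pmax(e, 1e-12))
  # central-difference 2x2 Hessian
  hess <- matrix(0, 2, 2)
  f0 <- f(eta)
  for (j in 1:2) {
    ej <- numeric(2); ej[j] <- h[j]
    hess[j, j] <- (f(eta + ej) - 2 * f0 + f(eta - ej)) / h[j]^2
  }
  e1 <- c(h[1], 0); e2 <- c(0, h[2])
  hess[1, 2] <- hess[2, 1] <-
    (f(eta + e1 + e2) - f(eta + e1 - e2) -
       f(eta - e1 + e2) + f(eta - e1 - e2)) / (4 * h[1] * h[2])
  w_cov <- tryCatch(2 * solve(hess), error = function(e) NULL)
  if (is.null(w_cov)) return(NULL)
  jac <- lapply(1:2, function(j) {
    ej <- numeric(2); ej[j] <- h[j]
    (vbeta_eta(fit, eta + ej) - vbeta_eta(fit, pmax(eta - ej, 1e-12))) /
      (2 * h[j])
  })
  list(w = w_cov, jac = jac)
}

# attach per-gene Satterthwaite caches (computed once per fit)
ensure_satt_cache <- function(fit) {
  if (!is.null(fit$satt)) return(fit)
  fit$satt <- lapply(seq_along(fit$sigma2), function(gi) {
    satt_gene_cache(fit, gi)
  })
  fit
}

quad_form <- function(v, m) drop(crossprod(v, m %*% v))

# Satterthwaite df for a single contrast vector (in coefficient space)
satt_contrast_df <- function(fit, gi, cv) {
  cache <- fit$satt[[gi]]
  if (is.null(cache)) return(fit$df_resid)
  v <- fit$sigma2[gi] * quad_form(cv, fit$cov_unscaled[, , gi])
  g <- c(quad_form(cv, cache$jac[[1]]), quad_form(cv, cache$jac[[2]]))
  denom <- quad_form(g, cache$w)
  if (!is.finite(denom) || denom <= 0) return(fit$df_resid)
  max(2 * v^2 / denom, 1)
}

# Satterthwaite denominator df for the multi-df test L beta = 0
satt_f_ddf <- function(fit, gi, l_rows) {
  cache <- fit$satt[[gi]]
  if (is.null(cache)) return(fit$df_resid)
  vb <- fit$sigma2[gi] * fit$cov_unscaled[, , gi]
  vl <- l_rows %*% vb %*% t(l_rows)
  eig <- eigen(vl, symmetric = TRUE)
  pos <- eig$values > max(sqrt(.Machine$double.eps) * eig$values[1], 0)
  q <- sum(pos)
  if (q == 0) return(fit$df_resid)
  nu <- vapply(seq_len(q), function(m) {
    cv <- drop(crossprod(l_rows, eig$vectors[, m]))
    satt_contrast_df(fit, gi, cv)
  }, numeric(1))
  if (q == 1) return(nu)
  if (all(abs(diff(nu)) < 1e-8)) return(mean(nu))
  if (any(nu <= 2)) return(2)
  e <- sum(nu / (nu - 2))
  2 * e / (e - q)
}

# ---- Kenward-Roger small-sample F-test -----------------------------------
#
# Plugging the REML variance estimates into the GLS covariance understates
# Var(beta_hat); with few samples this inflates Wald F-tests even with
# Satterthwaite df. The Kenward-Roger correction adds the Kackar-Harville
# term (Phi_A = Phi + 2 Lambda) and rescales the F statistic with matched
# moments. All ingredient matrices have closed forms here because
# V^-1 = I - Z diag(w) Z' with w_s = lambda/(1 + lambda n_s):
#   X'V^-1 Z Z'V^-1 X   = ZtX' diag(u^2) ZtX,        u_s = 1/(1+lambda n_s)
#   X'V^-2 X            = XtX - ZtX' diag(2w - w^2 n) ZtX
#   X'V^-1 ZZ'V^-1 ZZ'V^-1 X = ZtX' diag(u^3 n) ZtX
#   X'V^-1 ZZ'V^-2 X    = ZtX' diag(u^3) ZtX
#   X'V^-3 X            = XtX - ZtX' diag(3w - 3w^2 n + w^3 n^2) ZtX
# Singular fits are exact OLS and skip the correction.

# per-gene KR ingredients (Phi, dPhi/dtheta building blocks, Phi_adj)
kr_gene_cache <- function(fit, gi) {
  if (fit$singular[gi]) return(NULL)
  sc <- fit$satt[[gi]]
  if (is.null(sc)) return(NULL)
  lambda <- fit$lambda[gi]
  se2 <- fit$sigma2[gi]
  ns <- fit$ns
  u <- 1 / (1 + lambda * ns)
  w <- lambda * u
  ztx <- fit$ztx
  xtx <- fit$xtx
  m1 <- crossprod(ztx, ztx * u^2)
  m2 <- xtx - crossprod(ztx, ztx * (2 * w - w^2 * ns))
  m3 <- crossprod(ztx, ztx * (u^3 * ns))
  m4 <- crossprod(ztx, ztx * u^3)
  m5 <- xtx - crossprod(ztx, ztx * (3 * w - 3 * w^2 * ns + w^3 * ns^2))
  phi <- se2 * fit$cov_unscaled[, , gi]
  p_list <- list(-m1 / se2^2, -m2 / se2^2)
  q_list <- list(list(m3 / se2^3, m4 / se2^3),
                 list(m4 / se2^3, m5 / se2^3))
  w_cov <- sc$w
  kh <- matrix(0, fit$p, fit$p)
  for (i in 1:2) {
    for (j in 1:2) {
      kh <- kh + w_cov[i, j] *
        (q_list[[i]][[j]] - p_list[[i]] %*% phi %*% p_list[[j]])
    }
  }
  phi_adj <- phi + 2 * (phi %*% kh %*% phi)
  list(phi = phi, phi_adj = phi_adj, p_list = p_list, w_cov = w_cov)
}

ensure_kr_cache <- function(fit) {
  if (!is.null(fit$kr)) return(fit)
  fit <- ensure_satt_cache(fit)
  fit$kr <- lapply(seq_along(fit$sigma2), function(gi) {
    kr_gene_cache(fit, gi)
  })
  fit
}

# KR-scaled F-test of L beta = 0 for one gene: returns c(stat, df2, p)
# where stat is the Phi_A-based Wald F (the scale is folded into p).
kr_f_test <- function(fit, gi, l_rows) {
  kc <- fit$kr[[gi]]
  r <- nrow(l_rows)
  beta <- fit$beta[gi, ]
  if (is.null(kc)) {
    # exact OLS F
    vc <- fit$sigma2[gi] * (l_rows %*% fit$cov_unscaled[, , gi] %*%
                              t(l_rows))
    lb <- drop(l_rows %*% beta)
    stat <- drop(crossprod(lb, solve(vc, lb))) / r
    return(c(stat, fit$df_resid,
             pf(stat, r, fit$df_resid, lower.tail = FALSE)))
  }
  if (r == 1L) {
    # single contrast: same route as kr_contrast, so t^2 == F exactly
    cv <- drop(l_rows)
    v <- quad_form(cv, kc$phi_adj)
    stat <- sum(beta * cv)^2 / v
    df <- satt_contrast_df(fit, gi, cv)
    return(c(stat, df, pf(stat, 1, df, lower.tail = FALSE)))
  }
  phi <- kc$phi
  lb <- drop(l_rows %*% beta)
  vc_adj <- l_rows %*% kc$phi_adj %*% t(l_rows)
  stat <- drop(crossprod(lb, solve(vc_adj, lb))) / r
  theta <- t(l_rows) %*% solve(l_rows %*% phi %*% t(l_rows)) %*% l_rows
  tp <- lapply(kc$p_list, function(pm) theta %*% phi %*% pm %*% phi)
  a1 <- 0; a2 <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      a1 <- a1 + kc$w_cov[i, j] *
        sum(diag(tp[[i]])) * sum(diag(tp[[j]]))
      a2 <- a2 + kc$w_cov[i, j] * sum(tp[[i]] * t(tp[[j]]))
    }
  }
  b <- (a1 + 6 * a2) / (2 * r)
  gg <- ((r + 1) * a1 - (r + 4) * a2) / ((r + 2) * a2)
  denom <- 3 * r + 2 * (1 - gg)
  c1 <- gg / denom
  c2 <- (r - gg) / denom
  c3 <- (r + 2 - gg) / denom
  estar <- 1 / (1 - a2 / r)
  vstar <- (2 / r) * (1 + c1 * b) / ((1 - c2 * b)^2 * (1 - c3 * b))
  rho <- vstar / (2 * estar^2)
  m_df <- 4 + (r + 2) / (r * rho - 1)
  if (!is.finite(m_df) || m_df <= 2) {
    m_df <- satt_f_ddf(fit, gi, l_rows)
    return(c(stat, m_df, pf(stat, r, m_df, lower.tail = FALSE)))
  }
  scale <- m_df / (estar * (m_df - 2))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  c(stat, m_df, pf(scale * stat, r, m_df, lower.tail = FALSE))
}

# t-test of one contrast with the KH-adjusted variance and Satterthwaite df
kr_contrast <- function(fit, gi, cv) {
  kc <- fit$kr[[gi]]
  est <- sum(fit$beta[gi, ] * cv)
  if (is.null(kc)) {
    v <- fit$sigma2[gi] * quad_form(cv, fit$cov_unscaled[, , gi])
    df <- fit$df_resid
  } else {
    v <- quad_form(cv, kc$phi_adj)
    df <- satt_contrast_df(fit, gi, cv)
  }
  if (v <= 0) return(c(est, 1))
  tt <- est / sqrt(v)
  c(est, 2 * pt(-abs(tt), df = df))
}
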