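# Per-observation influence diagnostics for the fitted mixed models:
# non-iterative case deletion in the marginal generalized-least-squares
# formulation, holding the estimated covariance structure fixed (the
# convention of SAS PROC MIXED's INFLUENCE option, which the screening rules
# come from). For observation i:
#   Cook's D      (b - b_(i))' X'V^-1X (b - b_(i)) / p
#   RLD           2 [ l_R(b) - l_R(b_(i)) ] = (b - b_(i))' X'V^-1X (b - b_(i)),
#                 the displacement of the full-data restricted log likelihood
#                 when the fixed effects move to their case-deleted estimates,
#                 covariance parameters held fixed. (Updating the residual
#                 scale as well makes the distance O(1) chi-square noise on
#                 clean data, incompatible with a 1.5 cutoff.)
#   studentized   externally studentized marginal residual, using the
#                 delete-case scale estimate s2_(i)
# Case deletion uses exact rank-one downdates of the GLS normal equations;
# the test suite cross-checks against brute-force refits.

# marginal covariance V = s2 (Z Lambda Lambda' Z' + I) of an lmer fit, dense
marginal_v <- function(fit) {
  s2 <- stats::sigma(fit)^2
  Z <- lme4::getME(fit, "Z")
  L <- lme4::getME(fit, "Lambda")
  ZL <- Z %*% L
  as.matrix(s2 * (Matrix::tcrossprod(ZL) + Matrix::Diagonal(nrow(Z))))
}

# case-deletion GLS quantities given X, y and the precision W = V^-1
gls_case_deletion <- function(X, y, W) {
  n <- nrow(X); p <- ncol(X)
  A <- crossprod(X, W %*% X)
  b_vec <- crossprod(X, W %*% y)
  beta <- solve(A, b_vec)
  Ainv <- solve(A)
  WX <- W %*% X          # n x p, row i = w_{i,.} X = u_i'
  Wy <- as.numeric(W %*% y)
  ywy <- sum(y * Wy)
  resid <- as.numeric(y - X %*% beta)
  rWr <- sum(resid * (W %*% resid))
  # marginal residual variance diag(V - X A^-1 X') in W^-1 units:
  V <- solve(W)
  m_ii <- diag(V) - rowSums((X %*% Ainv) * X)

  beta_i <- matrix(NA_real_, n, p)
  rss_i <- numeric(n)   # deleted-set weighted RSS, in W units
  dAd <- numeric(n)
  for (i in seq_len(n)) {
    x_i <- X[i, ]
    u_i <- WX[i, ]                    # X' W e_i
    w_ii <- W[i, i]
    s_i <- Wy[i]                      # w_{i,.} y
    c_i <- u_i - w_ii * x_i
    A_i <- A - tcrossprod(x_i, c_i) - tcrossprod(c_i, x_i) -
      w_ii * tcrossprod(x_i) - tcrossprod(c_i) / w_ii
    b_i <- b_vec - c_i * y[i] - x_i * s_i - c_i * (s_i - w_ii * y[i]) / w_ii
    bi <- solve(A_i, b_i)
    beta_i[i, ] <- bi
    yWy_i <- ywy - 2 * y[i] * s_i + w_ii * y[i]^2 -
      (s_i - w_ii * y[i])^2 / w_ii
    rss_i[i] <- yWy_i - 2 * sum(bi * b_i) + as.numeric(t(bi) %*% A_i %*% bi)
    d <- beta - bi
    dAd[i] <- as.numeric(t(d) %*% A %*% d)
  }
  list(A = A, beta = as.numeric(beta), beta_i = beta_i, rss_i = rss_i,
       dAd = dAd, rWr = rWr, m_ii = m_ii, resid = resid, n = n, p = p)
}

#' Influence diagnostics for a mixed-model fit
#'
#' @param fit A [fit_mixed_model()] result.
#' @return data.frame with one row per observation: `cooks_d`, `rld`,
#'   `studentized`, plus the observation's subject and task.
#' @export
influence_diagnostics <- function(fit) {
  m <- fit$fit
  X <- lme4::getME(m, "X")
  y <- lme4::getME(m, "y")
  V <- marginal_v(m)
  W <- chol2inv(chol(V))
  g <- gls_case_deletion(X, y, W)
  s2_hat <- stats::sigma(m)^2          # scale unit; W is in V-hat units
  n <- g$n; p <- g$p

  cooks_d <- g$dAd / p
  # delete-case scale relative to the full-data scale (V-hat units)
  scale_i <- g$rss_i / (n - 1 - p)
  rld <- g$dAd
  studentized <- g$resid / sqrt(scale_i * g$m_ii)

  data.frame(obs = seq_len(n),
             subject = as.character(fit$data$subject),
             task = as.character(fit$data$task),
             cooks_d = cooks_d, rld = rld, studentized = studentized)
}

#' Screen and remove influential observations
#'
#' Computes Cook's D, the restricted likelihood distance (RLD), and externally
#' studentized residuals per observation; flags observations with
#' `D > 1`, `RLD > 1.5`, or `|studentized| > 4`; removes them and refits once
#' (single pass). Warns loudly when more than 10% of rows are flagged, which
#' suggests model misspecification rather than isolated artifacts.
#'
#' @param fit A [fit_mixed_model()] result.
#' @param cooks_limit,rld_limit,stud_limit Flagging thresholds.
#' @return List: `report` (diagnostics with `flagged` and `reason`),
#'   `refit` (a new `fivs_fit` without the flagged rows, or `NULL` when
#'   nothing was flagged), `n_removed`.
#' @export
influence_screen <- function(fit, cooks_limit = 1, rld_limit = 1.5,
                             stud_limit = 4) {
  rep <- influence_diagnostics(fit)
  reasons <- character(nrow(rep))
  f1 <- rep$cooks_d > cooks_limit
  f2 <- rep$rld > rld_limit
  f3 <- abs(rep$studentized) > stud_limit
  flagged <- f1 | f2 | f3
  for (i in which(flagged)) {
    reasons[i] <- paste(c(if (f1[i]) "cooks_d", if (f2[i]) "rld",
                          if (f3[i]) "studentized"), collapse = "+")
  }
  rep$flagged <- flagged
  rep$reason <- ifelse(flagged, reasons, NA_character_)
  if (mean(flagged) > 0.10)
    warning(sprintf(
      "influence screen flagged %.0f%% of observations for %s: model misspecification likely",
      100 * mean(flagged), fit$outcome))
  refit <- NULL
  if (any(flagged)) {
    dat <- fit$data[!flagged, , drop = FALSE]
    refit <- tryCatch(fit_mixed_model(dat, fit$outcome, fit$covariates),
                      error = function(e) {
                        warning("influence refit failed (",
                                conditionMessage(e),
                                "); keeping the original fit")
                        NULL
                      })
  }
  list(report = rep, refit = refit, n_removed = sum(flagged))
}

#' Brute-force leave-one-out influence (reference implementation)
#'
#' Recomputes the case-deletion quantities by explicitly refitting the
#' generalized-least-squares problem without each observation, using the same
#' fixed marginal covariance as [influence_diagnostics()]. Quadratic in the
#' number of observations; intended for validation on small fits.
#'
#' @param fit A [fit_mixed_model()] result (keep `n_obs` small).
#' @return data.frame with `obs`, `cooks_d`, `rld`, `studentized`.
#' @export
influence_brute_force <- function(fit) {
  m <- fit$fit
  X <- lme4::getME(m, "X")
  y <- lme4::getME(m, "y")
  V <- marginal_v(m)
  W <- chol2inv(chol(V))
  n <- nrow(X); p <- ncol(X)
  A <- crossprod(X, W %*% X)
  beta <- solve(A, crossprod(X, W %*% y))
  resid <- as.numeric(y - X %*% beta)
  rWr <- as.numeric(t(resid) %*% W %*% resid)
  full_scale <- rWr / (n - p)
  m_ii <- diag(V) - rowSums((X %*% solve(A)) * X)

  out <- data.frame(obs = seq_len(n), cooks_d = NA_real_, rld = NA_real_,
                    studentized = NA_real_)
  for (i in seq_len(n)) {
    Vi <- V[-i, -i, drop = FALSE]
    Wi <- chol2inv(chol(Vi))
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    Ai <- crossprod(Xi, Wi %*% Xi)
    bi <- solve(Ai, crossprod(Xi, Wi %*% yi))
    ri <- as.numeric(yi - Xi %*% bi)
    rss <- as.numeric(t(ri) %*% Wi %*% ri)
    scale_i <- rss / (n - 1 - p)
    d <- as.numeric(beta - bi)
    dAd <- as.numeric(t(d) %*% A %*% d)
    out$cooks_d[i] <- dAd / p
    # likelihood displacement evaluated on the full data at the case-deleted
    # fixed effects (covariance held fixed)
    r_full <- as.numeric(y - X %*% bi)
    out$rld[i] <- as.numeric(t(r_full) %*% W %*% r_full) - rWr
    out$studentized[i] <- resid[i] / sqrt(scale_i * m_ii[i])
  }
  out
}
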