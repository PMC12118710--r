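# Independent oracles used across test files.

# Brute-force cosinor: minimise SSE over an acrophase grid, solving the
# conditional linear least squares (mesor, amplitude) in closed form at each
# candidate phase. Independent of the sin/cos linear parameterisation used
# by fit_cosinor().
grid_cosinor <- function(y, t, period = 24, phi_step = 1e-3) {
  phis <- seq(0, period - phi_step, by = phi_step)
  n <- length(y)
  best <- list(sse = Inf)
  # vectorised over the phase grid
  C <- cos(2 * pi * outer(phis, t, "-") / period)   # grid x n
  cm <- rowMeans(C)
  ym <- mean(y)
  cc <- C - cm
  denom <- rowSums(cc^2)
  num <- as.numeric(cc %*% (y - ym))
  A <- ifelse(denom > 0, num / denom, 0)
  M <- ym - A * cm
  sse <- vapply(seq_along(phis), function(i)
    sum((y - M[i] - A[i] * C[i, ])^2), numeric(1))
  i <- which.min(sse)
  a <- A[i]; phi <- phis[i]
  if (a < 0) { a <- -a; phi <- (phi + period / 2) %% period }
  list(mesor = M[i], amplitude = a, acrophase = phi, sse = sse[i])
}

# Separate per-group linear cosinor fits with delta-method standard errors
# for the three contrasts; the oracle for the joint nonlinear fit.
separate_fits_oracle <- function(y1, t1, y2, t2, period = 24) {
  one <- function(y, t) {
    w <- 2 * pi / period
    X <- cbind(1, sin(w * t), cos(w * t))
    fit <- lm.fit(X, y)
    b <- fit$coefficients
    df <- length(y) - 3
    s2 <- sum(fit$residuals^2) / df
    V <- s2 * chol2inv(chol(crossprod(X)))
    A <- sqrt(b[2]^2 + b[3]^2)
    phi <- ((period / (2 * pi)) * atan2(b[2], b[3])) %% period
    # gradients of A and phi wrt (bs, bc)
    gA <- c(0, b[2] / A, b[3] / A)
    gphi <- (period / (2 * pi)) * c(0, b[3], -b[2]) / A^2
    list(M = b[1], A = A, phi = phi,
         vM = V[1, 1], vA = drop(t(gA) %*% V %*% gA),
         vphi = drop(t(gphi) %*% V %*% gphi), df = df)
  }
  f1 <- one(y1, t1); f2 <- one(y2, t2)
  wrap <- function(d) { w <- ((d + period / 2) %% period) - period / 2
    if (w == -period / 2) period / 2 else w }
  list(dM = unname(f2$M - f1$M), dA = unname(f2$A - f1$A),
       dphi = unname(wrap(f2$phi - f1$phi)),
       se_dM = unname(sqrt(f1$vM + f2$vM)), se_dA = unname(sqrt(f1$vA + f2$vA)),
       se_dphi = unname(sqrt(f1$vphi + f2$vphi)), df = f1$df + f2$df)
}

# Exact hypergeometric upper tail by direct combinatorial enumeration.
hyper_tail_enum <- function(overlap, set_size, universe, n_hits) {
  ks <- overlap:min(set_size, n_hits)
  sum(choose(set_size, ks) * choose(universe - set_size, n_hits - ks)) /
    choose(universe, n_hits)
}

# standard around-the-clock design used in many tests
design_t <- function(n_rep = 3) rep(c(2, 6, 10, 14, 18, 22), each = n_rep)
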