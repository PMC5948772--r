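# Independent brute-force reference implementations used as oracles.
# They deliberately share no code with the package internals.

# Kennard-Stone, recomputing every distance from scratch at every step.
ks_brute <- function(X, n_cal) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(-1, 1, 2)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (d(i, j) > best[1] + 1e-15) best <- c(d(i, j), i, j)
  sel <- best[2:3]
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(c)
      min(vapply(sel, function(s) d(c, s), 0)), 0)
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# SPA chain, recomputing all projections from scratch each step via lm
# residuals (no incremental update).
spa_chain_brute <- function(Xcal, start, n_select) {
  sel <- start
  for (step in seq_len(n_select - 1)) {
    rest <- setdiff(seq_len(ncol(Xcal)), sel)
    S <- Xcal[, sel, drop = FALSE]
    norms <- vapply(rest, function(j) {
      r <- stats::lm.fit(S, Xcal[, j])$residuals
      sum(r^2)
    }, 0)
    sel <- c(sel, rest[which.max(norms)])
  }
  sel
}

# Plain-R NIPALS PLS1 returning c(intercept, beta); independent of the
# compiled path.
r_nipals_pls1 <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    if (sqrt(sum(w^2)) < 1e-12) break
    w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pl <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0) return(c(ym, rep(0, p)))
  W <- W[, 1:a_used, drop = FALSE]; P <- P[, 1:a_used, drop = FALSE]
  beta <- W %*% solve(crossprod(P, W), q[1:a_used])
  c(ym - sum(xm * beta), beta)
}

# Spectra with a handful of informative bands planted among pure-noise
# bands. Each planted band carries the (standardized) class signal at
# scale effect_sd plus an independent per-band latent component at scale
# latent_sd, so every informative band contributes predictive value of
# its own (they are neither redundant nor collinear), and both scales
# sit far above the noise floor.
planted_spectra <- function(n_per_class = 75, n_classes = 7, p = 100,
                            planted = c(10, 30, 50, 70, 90),
                            effect_sd = 0.5, latent_sd = 0.3,
                            noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  n <- n_per_class * n_classes
  cls <- rep(seq_len(n_classes), each = n_per_class)
  cvec <- (cls - mean(cls)) / stats::sd(cls)
  X <- matrix(rnorm(n * p, 0, noise_sd), n, p)
  for (k in seq_along(planted))
    X[, planted[k]] <- X[, planted[k]] + effect_sd * cvec +
      latent_sd * rnorm(n)
  list(X = X, y = as.numeric(cls), cls = cls, planted = sort(planted))
}

# small signature/scene helpers reused across test files
tiny_config <- function(...) {
  scene_config(samples_per_class = 2, beans_per_sample = 3,
               bean_height = 4, bean_width = 5, ...)
}
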