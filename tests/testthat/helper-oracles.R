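# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: brute-force enumeration for the rank
# tests, lm()/vegan for the transform fits, fine-grid quadrature for
# volumes.

# exact two-sided signed-rank p by enumerating all 2^n sign patterns,
# mirroring the exact two-sided convention (2 * tail, capped at 1)
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p <- if (v_obs > n * (n + 1) / 4) 2 * mean(v_all >= v_obs) else
    2 * mean(v_all <= v_obs)
  min(1, p)
}

# exact two-sided Mann-Whitney p by enumerating all group-A index sets
enum_rank_sum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2L, u_of)
  p <- if (u_obs > m * n / 2) 2 * mean(u_all >= u_obs) else
    2 * mean(u_all <= u_obs)
  min(1, p)
}

# random proper rotation (uniform axis, uniform angle)
random_rotation_oracle <- function(max_deg = 180) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# straight-tube vessel model along +z with given radii profiles
straight_tube <- function(n = 101, length_mm = 100, lumen = 10,
                          outer = lumen, stations = NULL) {
  pts <- cbind(0, 0, seq(0, length_mm, length.out = n))
  cl <- centerline(pts, stations = stations %||% integer())
  vessel_model(cl, rep_len(lumen, n), rep_len(outer, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# affine fit oracle: ordinary least squares via lm()
lm_affine_oracle <- function(X, Y) {
  fit <- lm(Y ~ X)
  list(A = t(coef(fit)[-1, ]), t = as.numeric(coef(fit)[1, ]))
}
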