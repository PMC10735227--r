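# Independent oracles and small fixture builders. Each oracle is a direct,
# unoptimised transcription of the defining rule, kept separate from the
# package's implementation paths.

# Greedy clumping by exhaustive rule evaluation: repeatedly take the
# lowest-p (then lexicographically smallest) remaining candidate and check
# it against every accepted variant.
oracle_clump <- function(ids, p, ld, thr) {
  remaining <- order(p, ids)
  accepted <- character(0)
  for (i in remaining) {
    ok <- TRUE
    for (a in accepted) {
      if (ld[ids[i], a] > thr) ok <- FALSE
    }
    if (ok) accepted <- c(accepted, ids[i])
  }
  accepted
}

# Step-up BH by direct evaluation of adj_(i) = min_{j>=i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# HC1 sandwich by the explicit matrix formula
# (X'X)^-1 X' diag(e^2) X (X'X)^-1 * n/(n-k), X including the intercept.
oracle_hc1 <- function(y, X) {
  X <- cbind(1, X)
  n <- nrow(X); k <- ncol(X)
  bread <- solve(crossprod(X))
  beta <- bread %*% crossprod(X, y)
  e <- as.vector(y - X %*% beta)
  meat <- t(X) %*% (X * e^2)
  vc <- bread %*% meat %*% bread * n / (n - k)
  list(beta = as.vector(beta), se = unname(sqrt(diag(vc))))
}

# IVW point estimate as weighted least squares through the origin of the
# outcome betas on the exposure betas, weights 1/se_out^2.
oracle_wls_origin <- function(bx, by, sy) {
  w <- sy^-2
  sum(w * by * bx) / sum(w * bx^2)
}

# Weighted-mode location by direct evaluation of the stated kernel
# density on the stated grid.
oracle_mode_grid <- function(ratios, weights, phi = 1, n_grid = 512L) {
  med <- median(ratios)
  h <- phi * 1.4826 * median(abs(ratios - med))
  if (h == 0) {
    wp <- weights / sum(weights)
    mu <- sum(wp * ratios)
    h <- phi * sqrt(sum(wp * (ratios - mu)^2))
  }
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(x) {
    sum(weights * dnorm((ratios - x) / h))
  }, numeric(1))
  grid[which.max(dens)]
}

# Construct a harmonized set directly (already-aligned instruments).
make_hs <- function(bx, sx, by, sy, eaf = 0.3) {
  n <- length(bx)
  structure(data.frame(id = sprintf("rs%03d", seq_len(n)),
                       effect_allele = "A", other_allele = "G",
                       beta_exp = bx, se_exp = rep_len(sx, n), eaf_exp = eaf,
                       beta_out = by, se_out = rep_len(sy, n), eaf_out = eaf,
                       stringsAsFactors = FALSE),
            exposure = "exposure", outcome = "outcome",
            class = c("harmonized_set", "data.frame"))
}

# Minimal summary-stats builder for clumping/harmonization tests.
make_stats <- function(id, beta, se, p, ea = "A", oa = "G", eaf = NA,
                       trait = "trait", units = "logOR", region = NA) {
  summary_stats(data.frame(id = id, effect_allele = rep_len(ea, length(id)),
                           other_allele = rep_len(oa, length(id)),
                           eaf = rep_len(eaf, length(id)),
                           beta = beta, se = se, p = p,
                           region = rep_len(region, length(id)),
                           stringsAsFactors = FALSE),
                trait = trait, units = units)
}
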