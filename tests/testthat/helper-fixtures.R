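# shared fixtures: tiny gradient tables, single-tensor signal synthesis,
# and brute-force statistical oracles kept independent of package internals

tiny_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 24L, 10L), ...)
}

# unit gradient set: 6 canonical + extras from a fixed table
test_gradients <- function(n = 12) {
  g <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
             c(1, -1, 0), c(1, 0, -1), c(0, 1, -1),
             c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1))
  g <- g[seq_len(n), , drop = FALSE]
  g / sqrt(rowSums(g^2))
}

# noiseless DWI whose every voxel carries the same 3x3 tensor D
single_tensor_dwi <- function(D, b = 1000, n_dirs = 12, s0 = 1000,
                              grid = c(3L, 3L, 3L)) {
  dirs <- test_gradients(n_dirs)
  bvals <- c(0, rep(b, n_dirs))
  bvecs <- cbind(c(0, 0, 0), t(dirs))
  att <- vapply(seq_len(n_dirs), function(i) {
    g <- dirs[i, ]
    exp(-b * drop(t(g) %*% D %*% g))
  }, numeric(1))
  sig <- array(rep(s0 * c(1, att), each = prod(grid)),
               dim = c(grid, n_dirs + 1))
  dwi_volume(sig, bvals, bvecs, voxel_size_mm = 2)
}

# brute-force partial correlation: explicit residual regressions via lm()
oracle_partial_cor <- function(df, x, y, covariates, method = "pearson") {
  xv <- df[[x]]; yv <- df[[y]]
  if (method == "spearman") { xv <- rank(xv); yv <- rank(yv) }
  d <- cbind(df[covariates], .x = xv, .y = yv)
  rx <- if (length(covariates)) {
    resid(lm(as.formula(paste(".x ~", paste(covariates, collapse = "+"))),
             data = d))
  } else xv - mean(xv)
  ry <- if (length(covariates)) {
    resid(lm(as.formula(paste(".y ~", paste(covariates, collapse = "+"))),
             data = d))
  } else yv - mean(yv)
  cor(rx, ry)
}

# exhaustive pairwise AUC: P(pos > neg) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# brute-force Youden scan over all observed thresholds (midpoints),
# oriented so low score = positive when direction == "<"
oracle_youden <- function(scores, labels, direction = ">") {
  s <- if (direction == ">") scores else -scores
  pos <- s[labels == 1]; neg <- s[labels == 0]
  u <- sort(unique(s))
  thr <- c(min(u) - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)
  best_j <- -Inf; best <- NULL
  for (t in thr) {
    se <- mean(pos > t); sp <- mean(neg <= t)
    j <- se + sp - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && !is.null(best) && se > best$se)) {
      best_j <- j; best <- list(thr = t, se = se, sp = sp)
    }
  }
  list(cutoff = if (direction == ">") best$thr else -best$thr,
       sensitivity = best$se, specificity = best$sp, j = best_j)
}

# direct maximum-likelihood logistic oracle via optim on the log-likelihood
oracle_logistic <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(beta) {
    p <- plogis(drop(X %*% beta))
    -drop(t(X) %*% (y - p))
  }
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}
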