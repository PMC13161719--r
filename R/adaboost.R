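# Discrete AdaBoost over depth-1 decision stumps.
#
# Weak learner: h(x) = polarity * sign(x_j > threshold), chosen each round
# to minimise the weighted 0/1 error over all features, thresholds (split
# points between consecutive distinct sorted values, plus the two extremes)
# and both polarities. Round weight alpha = 0.5 * log((1 - err) / err);
# sample weights are multiplied by exp(-alpha * y * h) and renormalised.
# The classifier score is the signed margin sum(alpha_m * h_m(x)).

fit_ada_stumps <- function(X, y01, n_rounds = 50) {
  n <- nrow(X)
  p <- ncol(X)
  yy <- ifelse(y01 == 1, 1, -1)
  w <- rep(1 / n, n)
  ord <- apply(X, 2, order)
  eps <- 1e-10
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  m_used <- 0L
  for (m in seq_len(n_rounds)) {
    best_err <- Inf
    best <- NULL
    for (j in seq_len(p)) {
      o <- ord[, j]
      xs <- X[o, j]
      # polarity +1 predicts -1 for the first i sorted samples and +1 after;
      # i = 0 predicts +1 everywhere. Weighted error then counts positives
      # among the first i plus negatives after i. Valid split points are
      # where the sorted feature value strictly increases.
      cpos <- c(0, cumsum(w[o] * (yy[o] == 1)))
      cneg <- c(0, cumsum(w[o] * (yy[o] == -1)))
      totneg <- cneg[n + 1]
      err_p <- cpos + (totneg - cneg)       # length n+1, index i+1
      err_m <- sum(w) - err_p
      valid <- c(TRUE, xs[-1] != xs[-n], TRUE)
      err_p[!valid] <- Inf
      err_m[!valid] <- Inf
      ip <- which.min(err_p)
      im <- which.min(err_m)
      if (err_p[ip] < best_err) {
        best_err <- err_p[ip]
        best <- list(j = j, i = ip - 1, polarity = 1)
      }
      if (err_m[im] < best_err) {
        best_err <- err_m[im]
        best <- list(j = j, i = im - 1, polarity = -1)
      }
    }
    o <- ord[, best$j]
    xs <- X[o, best$j]
    thr <- if (best$i == 0) xs[1] - 1
           else if (best$i == n) xs[n] + 1
           else (xs[best$i] + xs[best$i + 1]) / 2
    h <- best$polarity * ifelse(X[, best$j] > thr, 1, -1)
    err <- max(best_err / sum(w), eps)
    if (err >= 0.5 && m > 1) break
    alpha <- 0.5 * log((1 - err) / max(err, eps))
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    m_used <- m
    stumps[[m]] <- list(feature = best$j, threshold = thr,
                        polarity = best$polarity)
    alphas[m] <- alpha
    if (err <= eps) break
  }
  list(stumps = stumps[seq_len(m_used)], alphas = alphas[seq_len(m_used)],
       features = colnames(X))
}

predict_ada_stumps <- function(model, X) {
  s <- numeric(nrow(X))
  for (m in seq_along(model$stumps)) {
    st <- model$stumps[[m]]
    s <- s + model$alphas[m] * st$polarity *
      ifelse(X[, st$feature] > st$threshold, 1, -1)
  }
  s
}
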