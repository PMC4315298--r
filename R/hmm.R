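# Three-state Gaussian hidden Markov model: Baum-Welch EM with scaling,
# most-likely-path (Viterbi) decoding. Written for univariate emission
# tracks segmented by gaps (each segment is an independent chain sharing
# parameters).

hmm_init <- function(x, n_states = 3, anchor = NULL) {
  qs <- quantile(x, probs = seq(0, 1, length.out = n_states + 1))
  grp <- cut(x, breaks = unique(c(-Inf, qs[-c(1, n_states + 1)], Inf)),
             labels = FALSE)
  mu <- tapply(x, grp, mean)
  sig <- tapply(x, grp, sd)
  # pad if tercile split degenerates (heavy ties)
  mu <- as.numeric(mu)[seq_len(n_states)]
  sig <- as.numeric(sig)[seq_len(n_states)]
  mu[is.na(mu)] <- mean(x)
  sig[is.na(sig) | sig < 1e-3] <- max(sd(x), 1e-3)
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]
  if (!is.null(anchor)) mu[(n_states + 1) %/% 2] <- anchor
  A <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(A) <- 0.9
  list(pi = rep(1 / n_states, n_states), A = A, mu = mu, sigma = sig)
}

hmm_emissions <- function(x, mu, sigma) {
  B <- vapply(seq_along(mu),
              function(s) dnorm(x, mu[s], sigma[s]), numeric(length(x)))
  B <- matrix(B, nrow = length(x))
  B[B < 1e-300] <- 1e-300
  B
}

# scaled forward-backward for one segment; returns gamma, xi sums, loglik
hmm_fwd_bwd <- function(B, pi, A) {
  n <- nrow(B); k <- ncol(B)
  alpha <- matrix(0, n, k); beta <- matrix(0, n, k); cvec <- numeric(n)
  alpha[1, ] <- pi * B[1, ]
  cvec[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / cvec[1]
  if (n > 1) for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  if (n > 1) for (t in (n - 1):1) {
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, k, k)
  if (n > 1) for (t in 1:(n - 1)) {
    m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A
    xi <- xi + m / sum(m)
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)))
}

hmm_viterbi <- function(B, pi, A) {
  n <- nrow(B); k <- ncol(B)
  logA <- log(A); logB <- log(B)
  delta <- matrix(-Inf, n, k); psi <- matrix(0L, n, k)
  delta[1, ] <- log(pi) + logB[1, ]
  if (n > 1) for (t in 2:n) {
    for (s in 1:k) {
      v <- delta[t - 1, ] + logA[, s]
      psi[t, s] <- which.max(v)
      delta[t, s] <- v[psi[t, s]] + logB[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# x_segments: list of numeric vectors (independent chains). When
# `anchor` is non-NULL the middle state's emission mean is pinned to
# that value throughout EM (the "no bias" state is defined by a zero
# emission centre). With `symmetric = TRUE` (3 states only) the flanking
# states are additionally constrained to mirror emissions around the
# anchor (mu_lo = -mu_hi, shared sigma): up- and downstream bias are the
# same phenomenon reflected, and the constraint stops the flanking
# states from degenerating into variance classes on heavy-tailed,
# sign-symmetric tracks.
hmm_fit_gaussian <- function(x_segments, n_states = 3,
                             max_iter = 500, tol = 1e-6, anchor = NULL,
                             symmetric = FALSE) {
  x_all <- unlist(x_segments)
  mid <- (n_states + 1) %/% 2
  par <- hmm_init(x_all, n_states, anchor = anchor)
  if (symmetric && n_states == 3) {
    m0 <- max(abs(par$mu[c(1, 3)]))
    par$mu <- c(-m0, par$mu[2], m0)
    s0 <- mean(par$sigma[c(1, 3)])
    par$sigma[c(1, 3)] <- s0
  }
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    gsum <- matrix(0, length(x_all), n_states)
    xi_sum <- matrix(0, n_states, n_states)
    pi_sum <- numeric(n_states)
    ll <- 0
    pos <- 0
    gamma_all <- vector("list", length(x_segments))
    for (si in seq_along(x_segments)) {
      x <- x_segments[[si]]
      B <- hmm_emissions(x, par$mu, par$sigma)
      fb <- hmm_fwd_bwd(B, par$pi, par$A)
      gamma_all[[si]] <- fb$gamma
      gsum[pos + seq_along(x), ] <- fb$gamma
      xi_sum <- xi_sum + fb$xi
      pi_sum <- pi_sum + fb$gamma[1, ]
      ll <- ll + fb$loglik
      pos <- pos + length(x)
    }
    # M step
    par$pi <- pi_sum / sum(pi_sum)
    rs <- rowSums(xi_sum)
    keep <- rs > 0
    par$A[keep, ] <- xi_sum[keep, ] / rs[keep]
    w <- colSums(gsum)
    par$mu <- colSums(gsum * x_all) / w
    if (!is.null(anchor)) par$mu[mid] <- anchor
    if (symmetric && n_states == 3) {
      ctr <- anchor %||% 0
      m <- (sum(gsum[, 3] * (x_all - ctr)) -
              sum(gsum[, 1] * (x_all - ctr))) / (w[1] + w[3])
      m <- max(m, 1e-6)
      par$mu[1] <- ctr - m
      par$mu[3] <- ctr + m
    }
    par$sigma <- sqrt(colSums(gsum * (outer(x_all, par$mu, `-`))^2) / w)
    if (symmetric && n_states == 3) {
      s <- sqrt((sum(gsum[, 1] * (x_all - par$mu[1])^2) +
                   sum(gsum[, 3] * (x_all - par$mu[3])^2)) / (w[1] + w[3]))
      par$sigma[c(1, 3)] <- s
    }
    par$sigma <- pmax(par$sigma, 1e-4)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("HMM EM reached max_iter without convergence; ",
            "using best-so-far parameters", call. = FALSE)
  }
  paths <- lapply(x_segments, function(x) {
    B <- hmm_emissions(x, par$mu, par$sigma)
    hmm_viterbi(B, par$pi, par$A)
  })
  list(par = par, paths = paths, loglik = ll, converged = converged,
       n_iter = iter)
}
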