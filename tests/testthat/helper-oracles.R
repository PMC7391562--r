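# Independent oracles shared across test files.

# Generic convex-solver oracle for the maxent objective: box-constrained
# quasi-Newton on the split lambda = u - w (u, w >= 0), which makes the L1
# penalty a smooth linear term.
oracle_fit <- function(Fp, Fb, beta) {
  fbar <- colMeans(Fp)
  p <- length(fbar)
  obj <- function(th) {
    lam <- th[1:p] - th[(p + 1):(2 * p)]
    e <- Fb %*% lam
    mx <- max(e)
    -sum(lam * fbar) + mx + log(sum(exp(e - mx))) +
      sum(beta * (th[1:p] + th[(p + 1):(2 * p)]))
  }
  gr <- function(th) {
    lam <- th[1:p] - th[(p + 1):(2 * p)]
    e <- as.vector(Fb %*% lam)
    w <- exp(e - max(e)); w <- w / sum(w)
    g <- as.vector(crossprod(Fb, w)) - fbar
    c(g + beta, -g + beta)
  }
  fit <- stats::optim(rep(0, 2 * p), obj, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 2000, factr = 1e1))
  fit$par[1:p] - fit$par[(p + 1):(2 * p)]
}

raw_from_lambda <- function(lam, Fb) {
  e <- as.vector(Fb %*% lam)
  exp(e - (max(e) + log(sum(exp(e - max(e))))))
}
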