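## Observation likelihood families on the linear-predictor (log-link) scale.
## Each evaluation returns the per-observation log-likelihood, its first
## derivative g = d ll / d eta, and the (observed) negative second
## derivative w, which is the Newton weight.

ETA_CLAMP <- 30  # guards exp() overflow in degenerate line-search steps

lik_eval <- function(likelihood, y, eta, extra = numeric(0)) {
  eta_c <- pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)
  if (likelihood == "poisson") {
    lam <- exp(eta_c)
    list(ll = stats::dpois(y, lam, log = TRUE) + y * (eta - eta_c),
         g = y - lam,
         w = pmax(lam, 1e-12))
  } else if (likelihood == "gaussian") {
    prec <- exp(extra[["log_prec"]])
    list(ll = stats::dnorm(y, eta, sqrt(1 / prec), log = TRUE),
         g = prec * (y - eta),
         w = rep(prec, length(y)))
  } else if (likelihood == "negbinomial") {
    size <- exp(extra[["log_size"]])
    lam <- exp(eta_c)
    list(ll = stats::dnbinom(y, size = size, mu = lam, log = TRUE),
         g = y - (y + size) * lam / (size + lam),
         w = pmax((y + size) * size * lam / (size + lam)^2, 1e-12))
  } else stop("unknown likelihood: ", likelihood)
}

## number of likelihood-specific hyperparameters and their names
lik_extra_names <- function(likelihood) {
  switch(likelihood,
         poisson = character(0),
         gaussian = "log_prec",
         negbinomial = "log_size")
}
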