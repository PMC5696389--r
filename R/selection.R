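## DIC and CPO goodness-of-fit diagnostics and the candidate-model
## comparison table. Lower DIC and larger (less negative) summed log CPO
## indicate a better fit.
##
## Both are computed from seeded Monte-Carlo draws of the Gaussian
## approximation to the latent posterior at the hyperparameter mode; draws
## are processed in blocks so memory stays flat for large observation sets.

## draws (d x S) from the latent Gaussian approximation N(mode, Q_post^-1);
## z2 = squared norms of the generating z, i.e. (x-mode)' Q_post (x-mode),
## which gives the approximation's log-density up to a constant
latent_draws <- function(fit, n_draws, seed) {
  set.seed(seed)
  d <- length(fit$mode)
  z <- matrix(stats::rnorm(d * n_draws), d, n_draws)
  x <- Matrix::solve(fit$md$cache$chol,
                     Matrix::solve(fit$md$cache$chol, z, system = "Lt"),
                     system = "Pt")
  list(x = as.matrix(x) + fit$mode, z2 = colSums(z^2))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior mean)`; the expected
#' deviance `Dbar` is estimated from seeded draws of the Gaussian
#' approximation to the latent posterior.
#'
#' @param fit an `spde_fit`.
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed (fixed for reproducibility to six decimals).
#' @return list with `dic`, `dbar`, `dhat`, `p_d`.
#' @export
dic <- function(fit, n_draws = 1000, seed = 1) {
  md <- fit$md
  ## the Gaussian approximation must be positioned at this fit's mode
  ga <- gaussian_approx(md, fit$theta_mode, x0 = fit$mode)
  extra <- theta_extras(md, fit$theta_mode)
  draws <- latent_draws(fit, n_draws, seed)$x
  dev <- numeric(n_draws)
  block <- max(1L, floor(2e6 / length(md$y)))
  s <- 1L
  while (s <= n_draws) {
    e <- min(n_draws, s + block - 1L)
    eta <- as.matrix(md$A %*% draws[, s:e, drop = FALSE]) + md$offset
    for (j in seq_len(e - s + 1L)) {
      dev[s + j - 1L] <- -2 * sum(lik_eval(md$spec$likelihood, md$y,
                                           eta[, j], extra)$ll)
    }
    s <- e + 1L
  }
  dhat <- -2 * ga$ll
  dbar <- mean(dev)
  list(dic = 2 * dbar - dhat, dbar = dbar, dhat = dhat, p_d = dbar - dhat)
}

#' Conditional predictive ordinates
#'
#' Leave-one-out predictive density of each observation by the
#' harmonic-mean importance identity `CPO_i = 1 / E[1 / p(y_i | x)]` over
#' the full latent posterior: draws come from the Gaussian approximation
#' and are importance-reweighted to the exact (unnormalized) posterior, so
#' the estimate converges to the true CPO. Observations whose combined
#' importance weights have effective sample size below `ess_min` are
#' flagged as unreliable.
#'
#' @param fit an `spde_fit`.
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @param ess_min effective-sample-size flag threshold.
#' @return list with per-observation `cpo`, `cpo_sum` (sum of log CPO, the
#'   log pseudomarginal likelihood), `ess`, and `flagged` indices.
#' @export
cpo <- function(fit, n_draws = 1000, seed = 1, ess_min = 30) {
  md <- fit$md
  ga <- gaussian_approx(md, fit$theta_mode, x0 = fit$mode)
  extra <- theta_extras(md, fit$theta_mode)
  dr <- latent_draws(fit, n_draws, seed)
  n <- length(md$y)
  block <- max(1L, floor(2e6 / n))
  ## pass 1: total log-likelihood per draw -> posterior/approx log-weights
  ll_s <- numeric(n_draws)
  s <- 1L
  while (s <= n_draws) {
    e <- min(n_draws, s + block - 1L)
    eta <- as.matrix(md$A %*% dr$x[, s:e, drop = FALSE]) + md$offset
    for (j in seq_len(e - s + 1L)) {
      ll_s[s + j - 1L] <- sum(lik_eval(md$spec$likelihood, md$y,
                                       eta[, j], extra)$ll)
    }
    s <- e + 1L
  }
  quad_prior <- colSums(dr$x * as.matrix(ga$Q_prior %*% dr$x))
  lw <- ll_s - 0.5 * quad_prior + 0.5 * dr$z2
  lw <- lw - max(lw)
  w <- exp(lw)
  ## pass 2: per-observation harmonic accumulation with weights w
  sum_u <- sum_u2 <- numeric(n)
  s <- 1L
  while (s <= n_draws) {
    e <- min(n_draws, s + block - 1L)
    eta <- as.matrix(md$A %*% dr$x[, s:e, drop = FALSE]) + md$offset
    for (j in seq_len(e - s + 1L)) {
      lp <- lik_eval(md$spec$likelihood, md$y, eta[, j], extra)$ll
      u <- w[s + j - 1L] * exp(pmin(-lp, 700))
      sum_u <- sum_u + u
      sum_u2 <- sum_u2 + u^2
    }
    s <- e + 1L
  }
  cpo_i <- sum(w) / sum_u
  ess <- sum_u^2 / sum_u2
  flagged <- which(ess < ess_min | cpo_i <= 0)
  list(cpo = cpo_i, cpo_sum = sum(log(cpo_i)), ess = ess, flagged = flagged)
}

#' Compare candidate models by DIC and CPO
#'
#' Fits each candidate specification on identical data and returns a
#' comparison table sorted by ascending DIC (ties broken by larger summed
#' log CPO). Candidates that fail to fit are kept as flagged rows.
#'
#' @param specs named list of `model_spec` objects (>= 2).
#' @param records validated survey sets.
#' @param mesh a `trawl_mesh`.
#' @param control a [fit_control()] list.
#' @param n_draws,seed Monte-Carlo settings passed to [dic()] and [cpo()].
#' @return `data.frame` with columns `model`, `dic`, `cpo_sum`, `failed`,
#'   sorted best first; fitted objects in the `fits` attribute.
#' @export
compare_models <- function(specs, records, mesh, control = fit_control(),
                           n_draws = 1000, seed = 1) {
  if (length(specs) < 2) stop("need at least two candidate models")
  labels <- names(specs) %||% paste0("model", seq_along(specs))
  if (is.null(names(specs))) names(specs) <- labels
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    res <- tryCatch({
      f <- fit_spde(records, mesh, specs[[i]], control)
      fits[[i]] <<- f
      data.frame(model = labels[i],
                 dic = dic(f, n_draws, seed)$dic,
                 cpo_sum = cpo(f, n_draws, seed)$cpo_sum,
                 failed = FALSE)
    }, error = function(e) {
      data.frame(model = labels[i], dic = NA_real_, cpo_sum = NA_real_,
                 failed = TRUE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$failed, tab$dic, -tab$cpo_sum)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Candidate label in the conventional latent-field notation
#'
#' @param covariates covariate names.
#' @return e.g. `"xi(s,t) + temperature"`.
#' @export
candidate_label <- function(covariates) {
  if (length(covariates) == 0) return("xi(s,t)")
  pretty <- sub("^bottom_temp$", "temperature", covariates)
  paste(c("xi(s,t)", pretty), collapse = " + ")
}
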