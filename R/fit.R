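## INLA-style inference for the latent Gaussian spatiotemporal model:
## an inner Newton optimization gives the Gaussian (Laplace) approximation
## to the latent field at fixed hyperparameters; the Laplace-approximate
## marginal likelihood is maximized over the (unconstrained) hyperparameters
## and explored on a centered grid for posterior summaries.
##
## Latent vector layout: [field weights (n_nodes x T, period-major); fixed
## effects (intercept, covariates)]. Hyperparameters theta are
## (log kappa, log tau[, log((1+a)/(1-a))][, likelihood extras]).

#' Model specification
#'
#' @param likelihood observation family: `"poisson"` (the survey count
#'   model), `"negbinomial"` or `"gaussian"`.
#' @param temporal_mode `"ar1"` (persistence across periods),
#'   `"independent"` (one field per period, uncorrelated) or `"shared"`
#'   (a single field common to all periods).
#' @param covariates character vector of record columns entering as linear
#'   fixed effects (e.g. `"bottom_temp"`).
#' @param include_latent include the spatiotemporal random field.
#' @param zeros `"exclude"` fits the likelihood to positive sets only (the
#'   convention for the real surveys, where zero sets inform only the mesh);
#'   `"include"` keeps zero counts as Poisson observations, which is the
#'   generatively consistent choice for synthetic-recovery experiments.
#' @return a `model_spec` list.
#' @export
model_spec <- function(likelihood = c("poisson", "negbinomial", "gaussian"),
                       temporal_mode = c("ar1", "independent", "shared"),
                       covariates = character(0),
                       include_latent = TRUE,
                       zeros = c("exclude", "include")) {
  structure(list(likelihood = match.arg(likelihood),
                 temporal_mode = match.arg(temporal_mode),
                 covariates = covariates,
                 include_latent = include_latent,
                 zeros = match.arg(zeros)),
            class = "model_spec")
}

#' Fitting control parameters
#'
#' @param newton_tol inner Newton convergence: max absolute gradient.
#' @param newton_maxit maximum inner Newton iterations.
#' @param outer_reltol relative tolerance of the outer (hyperparameter)
#'   optimization.
#' @param outer_maxit maximum outer iterations.
#' @param n_grid grid points per hyperparameter dimension for posterior
#'   summaries.
#' @param z_range half-width of the grid in posterior standard deviations.
#' @param beta_prior_sd prior standard deviation of fixed effects.
#' @param theta_prior_sd prior sds of (log kappa, log tau, z(a), extras).
#' @return list of control values.
#' @export
fit_control <- function(newton_tol = 1e-8, newton_maxit = 100,
                        outer_reltol = 1e-6, outer_maxit = 500,
                        n_grid = 5, z_range = 2.5,
                        beta_prior_sd = 10,
                        theta_prior_sd = c(3, 3, 2, 2)) {
  list(newton_tol = newton_tol, newton_maxit = newton_maxit,
       outer_reltol = outer_reltol, outer_maxit = outer_maxit,
       n_grid = n_grid, z_range = z_range,
       beta_prior_sd = beta_prior_sd, theta_prior_sd = theta_prior_sd)
}

## theta vector -> interpretable parameters
theta_to_params <- function(theta, spec) {
  nm <- theta_names(spec)
  out <- list()
  if (spec$include_latent) {
    kappa <- exp(theta[1]); tau <- exp(theta[2])
    sp <- spde_params(kappa = kappa, tau = tau)
    out$rho <- sp$rho; out$sigma2 <- sp$sigma2
    out$kappa <- kappa; out$tau <- tau
    if (spec$temporal_mode == "ar1") {
      z <- theta[3]
      out$a <- (exp(z) - 1) / (exp(z) + 1)
    }
  }
  ex <- lik_extra_names(spec$likelihood)
  for (e in ex) out[[e]] <- theta[[match(e, nm)]]
  out
}

theta_names <- function(spec) {
  nm <- character(0)
  if (spec$include_latent) {
    nm <- c("log_kappa", "log_tau")
    if (spec$temporal_mode == "ar1") nm <- c(nm, "z_a")
  }
  c(nm, lik_extra_names(spec$likelihood))
}

## ---- model data ------------------------------------------------------------

#' Assemble model data for a spec on a mesh
#'
#' Builds the observation vector, joint design matrix (field projector plus
#' fixed effects), offset, prior structure and cached sparse patterns used
#' by the Newton iterations. Returned as an environment so factorizations
#' and warm starts persist across hyperparameter evaluations.
#'
#' @param records validated survey sets.
#' @param mesh a `trawl_mesh`.
#' @param spec a `model_spec`.
#' @param control a [fit_control()] list.
#' @return an environment of model data.
#' @export
build_model_data <- function(records, mesh, spec,
                             control = fit_control()) {
  md <- new.env(parent = emptyenv())
  md$spec <- spec; md$mesh <- mesh; md$control <- control
  if (spec$zeros == "exclude") records <- records[records$count > 0, ,
                                                  drop = FALSE]
  if (nrow(records) == 0) stop("no observations left after zero handling")
  md$records <- records
  md$y <- records$count
  md$offset <- log(records$effort)
  md$T <- max(records$period)
  n <- mesh$n_nodes
  md$n <- n
  md$field_dim <- if (!spec$include_latent) 0L else
    if (spec$temporal_mode == "shared") n else n * md$T

  X <- cbind(intercept = rep(1, nrow(records)))
  for (cv in spec$covariates) {
    if (is.null(records[[cv]])) stop("covariate column not found: ", cv)
    X <- cbind(X, records[[cv]])
    colnames(X)[ncol(X)] <- cv
  }
  md$p <- ncol(X)

  if (spec$include_latent) {
    Aloc <- projector(mesh, cbind(records$lon, records$lat))
    if (spec$temporal_mode == "shared") {
      Afield <- Aloc
    } else {
      ## shift each record's weights into its period block
      trip <- Matrix::mat2triplet(Aloc)
      Afield <- Matrix::sparseMatrix(
        i = trip$i,
        j = trip$j + (records$period[trip$i] - 1L) * n,
        x = trip$x, dims = c(nrow(records), md$field_dim))
    }
    md$A <- cbind(Afield, Matrix::Matrix(X, sparse = TRUE))
  } else {
    md$A <- Matrix::Matrix(X, sparse = TRUE)
  }
  md$A <- methods::as(methods::as(md$A, "generalMatrix"), "CsparseMatrix")
  md$d <- ncol(md$A)
  md$tA <- Matrix::t(md$A)

  ## FEM operators and reusable precision pieces
  if (spec$include_latent) {
    fem <- fem_matrices(mesh)
    md$C <- fem$C
    md$G <- fem$G
    Ci <- Matrix::Diagonal(n, 1 / Matrix::diag(fem$C))
    md$GCG <- Matrix::forceSymmetric(fem$G %*% Ci %*% fem$G)
    md$diam <- max(stats::dist(mesh$nodes[grDevices::chull(mesh$nodes), ]))
  }

  ## quadratic-form map: values of crossprod(A, W A) as a linear map of w
  M0 <- Matrix::forceSymmetric(Matrix::crossprod(md$A))
  md$M0 <- M0
  keyM0 <- (rep(seq_len(md$d), diff(M0@p)) - 1) * md$d + (M0@i + 1)
  tA <- md$tA
  counts <- diff(tA@p)
  slot <- obs <- val <- vector("list", 0)
  for (k in sort(unique(counts))) {
    cols <- which(counts == k)
    idx <- rep(tA@p[cols], each = k) + rep(seq_len(k), times = length(cols))
    dims <- matrix(tA@i[idx] + 1L, nrow = k)
    vals <- matrix(tA@x[idx], nrow = k)
    for (r in seq_len(k)) for (l in r:k) {
      rr <- pmin(dims[r, ], dims[l, ])
      cc <- pmax(dims[r, ], dims[l, ])
      slot[[length(slot) + 1L]] <- match((cc - 1) * md$d + rr, keyM0)
      obs[[length(obs) + 1L]] <- cols
      val[[length(val) + 1L]] <- vals[r, ] * vals[l, ]
    }
  }
  md$P <- Matrix::sparseMatrix(i = unlist(slot), j = unlist(obs),
                               x = unlist(val),
                               dims = c(length(M0@x), nrow(records)))

  ## prior centering for (log kappa, log tau): range at a fifth of the
  ## domain diameter, unit field variance
  if (spec$include_latent) {
    rho0 <- md$diam / 5
    k0 <- sqrt(8) / rho0
    md$theta_center <- c(log(k0), log(1 / sqrt(4 * pi * k0^2 * 1)))
  } else {
    md$theta_center <- numeric(0)
  }
  md$theta_dim <- length(theta_names(spec))
  md$cache <- new.env(parent = emptyenv())
  md
}

## Gaussian prior on theta (unconstrained scale), weakly informative.
log_prior_theta <- function(md, theta) {
  spec <- md$spec; ctl <- md$control
  lp <- 0; i <- 0
  if (spec$include_latent) {
    lp <- lp + stats::dnorm(theta[1], md$theta_center[1],
                            ctl$theta_prior_sd[1], log = TRUE) +
      stats::dnorm(theta[2], md$theta_center[2], ctl$theta_prior_sd[2],
                   log = TRUE)
    i <- 2
    if (spec$temporal_mode == "ar1") {
      i <- 3
      lp <- lp + stats::dnorm(theta[3], 0, ctl$theta_prior_sd[3], log = TRUE)
    }
  }
  while (i < length(theta)) {
    i <- i + 1
    lp <- lp + stats::dnorm(theta[i], 0, ctl$theta_prior_sd[4], log = TRUE)
  }
  lp
}

## Prior precision of the joint latent vector at theta, with log-determinant.
build_prior <- function(md, theta) {
  spec <- md$spec
  bprec <- 1 / md$control$beta_prior_sd^2
  if (!spec$include_latent) {
    Q <- Matrix::Diagonal(md$p, bprec)
    return(list(Q = Matrix::forceSymmetric(Q),
                logdet = md$p * log(bprec)))
  }
  kappa <- exp(theta[1]); tau <- exp(theta[2])
  Qs <- Matrix::forceSymmetric(
    tau^2 * (kappa^4 * md$C + 2 * kappa^2 * md$G + md$GCG))
  ld_s <- logdet_spd(Qs)
  if (spec$temporal_mode == "shared") {
    Qf <- Qs
    ld <- ld_s
  } else if (spec$temporal_mode == "independent") {
    Qf <- st_precision(Qs, Matrix::Diagonal(md$T))
    ld <- md$T * ld_s
  } else {
    z <- theta[3]
    a <- (exp(z) - 1) / (exp(z) + 1)
    Qt <- ar1_precision(a, md$T)
    Qf <- st_precision(Qs, Qt)
    ld <- md$T * ld_s + md$n * (-(md$T - 1) * log(1 - a^2))
  }
  Q <- Matrix::bdiag(Qf, Matrix::Diagonal(md$p, bprec))
  list(Q = Matrix::forceSymmetric(Q),
       logdet = ld + md$p * log(bprec))
}

## likelihood extras subvector of theta, named
theta_extras <- function(md, theta) {
  ex <- lik_extra_names(md$spec$likelihood)
  if (length(ex) == 0) return(numeric(0))
  nm <- theta_names(md$spec)
  stats::setNames(theta[match(ex, nm)], ex)
}

## ---- Gaussian (Laplace) approximation --------------------------------------

#' Gaussian approximation of the latent posterior at fixed hyperparameters
#'
#' Newton maximization of the joint log-posterior of `[field; beta]`; the
#' returned Gaussian has mean the mode and precision
#' `Q_post = Q_prior + A' W A` with `W` the negative log-likelihood Hessian
#' at the mode.
#'
#' @param md model data from [build_model_data()].
#' @param theta hyperparameter vector (unconstrained scale).
#' @param x0 optional warm start for the latent vector.
#' @return list with mode `x`, per-observation pieces, the posterior
#'   Cholesky factor and both log-determinants.
#' @export
gaussian_approx <- function(md, theta = numeric(0), x0 = NULL) {
  ctl <- md$control
  prior <- build_prior(md, theta)
  Qp <- prior$Q
  extra <- theta_extras(md, theta)
  x <- x0 %||% md$cache$x_last %||% numeric(md$d)
  eta <- as.vector(md$A %*% x) + md$offset
  le <- lik_eval(md$spec$likelihood, md$y, eta, extra)
  Qx <- Qp %*% x
  f <- sum(le$ll) - 0.5 * sum(x * as.vector(Qx))
  converged <- FALSE
  stagnant <- FALSE
  grad_norm <- Inf
  for (it in seq_len(ctl$newton_maxit)) {
    grad <- as.vector(md$tA %*% le$g) - as.vector(Qx)
    grad_norm <- max(abs(grad))
    Qlik <- md$M0
    Qlik@x <- as.vector(md$P %*% le$w)
    Qpost <- Matrix::forceSymmetric(Qp + Qlik)
    if (is.null(md$cache$chol)) {
      md$cache$chol <- Matrix::Cholesky(Qpost, LDL = FALSE, perm = TRUE)
    } else {
      md$cache$chol <- Matrix::update(md$cache$chol, Qpost)
    }
    if (grad_norm < ctl$newton_tol || stagnant) { converged <- TRUE; break }
    delta <- as.vector(Matrix::solve(md$cache$chol, grad))
    step <- 1
    repeat {
      xn <- x + step * delta
      etan <- as.vector(md$A %*% xn) + md$offset
      len <- lik_eval(md$spec$likelihood, md$y, etan, extra)
      Qxn <- Qp %*% xn
      fn <- sum(len$ll) - 0.5 * sum(xn * as.vector(Qxn))
      if (is.finite(fn) && fn >= f - 1e-10 * (1 + abs(f))) break
      step <- step / 2
      if (step < 1e-10)
        stop("Newton line search failed (last gradient norm ", grad_norm, ")")
    }
    ## stagnation: the objective is converged to round-off (large data sets
    ## cannot push the summed gradient below float accumulation error);
    ## one more pass refreshes the factorization at the accepted iterate
    stagnant <- abs(fn - f) <= 1e-9 * (1 + abs(f)) && grad_norm < 1e-4
    x <- xn; eta <- etan; le <- len; Qx <- Qxn; f <- fn
  }
  if (!converged)
    stop("Newton did not converge in ", ctl$newton_maxit,
         " iterations (last gradient norm ", grad_norm, ")")
  md$cache$x_last <- x
  logdet_post <- 2 * as.numeric(Matrix::determinant(md$cache$chol,
                                                    logarithm = TRUE,
                                                    sqrt = TRUE)$modulus)
  list(x = x, eta = eta, ll = sum(le$ll), w = le$w,
       quad = sum(x * as.vector(Qx)),
       chol = md$cache$chol,
       logdet_prior = prior$logdet, logdet_post = logdet_post,
       Q_prior = Qp, n_iter = it, grad_norm = grad_norm)
}

#' Laplace-approximate log marginal posterior of the hyperparameters
#'
#' `log p(theta | y)` up to a constant:
#' `ll(x_hat) - x_hat' Q_prior x_hat / 2 + logdet(Q_prior)/2 -
#'  logdet(Q_post)/2 + log prior(theta)`.
#'
#' @inheritParams gaussian_approx
#' @return scalar log posterior (unnormalized).
#' @export
log_marginal <- function(md, theta = numeric(0)) {
  ga <- gaussian_approx(md, theta)
  ga$ll - 0.5 * ga$quad + 0.5 * ga$logdet_prior - 0.5 * ga$logdet_post +
    log_prior_theta(md, theta)
}

## ---- hyperparameter optimization and posterior ------------------------------

#' Maximize the hyperparameter posterior
#'
#' Nelder-Mead over the unconstrained hyperparameters (each marginal
#' evaluation runs the warm-started inner Newton), followed by a
#' finite-difference Hessian at the mode.
#'
#' @param md model data.
#' @param init optional initial theta; defaults to a mesh-informed start
#'   (range a quarter of the domain diameter, field variance 0.5,
#'   persistence 0.5).
#' @return list with `theta_mode`, `curvature` (negative Hessian),
#'   `lm_mode`, and the evaluation count.
#' @export
optimize_hyper <- function(md, init = NULL) {
  nm <- theta_names(md$spec)
  k <- length(nm)
  if (k == 0)
    return(list(theta_mode = numeric(0), curvature = matrix(0, 0, 0),
                lm_mode = log_marginal(md, numeric(0)), n_eval = 1L))
  if (is.null(init)) {
    init <- numeric(k)
    if (md$spec$include_latent) {
      rho_i <- md$diam / 4
      k_i <- sqrt(8) / rho_i
      init[1] <- log(k_i)
      init[2] <- log(1 / sqrt(4 * pi * k_i^2 * 0.5))
      if (md$spec$temporal_mode == "ar1")
        init[3] <- log((1 + 0.5) / (1 - 0.5))
    }
  }
  negf <- function(th) -log_marginal(md, th)
  n_eval <- 0L
  wrapped <- function(th) { n_eval <<- n_eval + 1L; negf(th) }
  if (k == 1) {
    opt <- stats::optim(init, wrapped, method = "Brent",
                        lower = init - 12, upper = init + 12)
  } else {
    opt <- stats::optim(init, wrapped, method = "Nelder-Mead",
                        control = list(reltol = md$control$outer_reltol,
                                       maxit = md$control$outer_maxit))
    ## one restart from the incumbent polishes the simplex mode
    opt <- stats::optim(opt$par, wrapped, method = "Nelder-Mead",
                        control = list(reltol = md$control$outer_reltol,
                                       maxit = md$control$outer_maxit))
    if (opt$convergence != 0)
      warning("outer optimization did not fully converge (code ",
              opt$convergence, ")")
  }
  H <- stats::optimHess(opt$par, negf)
  H <- (H + t(H)) / 2
  list(theta_mode = stats::setNames(opt$par, nm), curvature = H,
       lm_mode = -opt$value, n_eval = n_eval)
}

## weighted quantile by linear interpolation of the weighted ECDF
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cdf <- cumsum(w) - w / 2
  stats::approx(cdf, x, probs, rule = 2, ties = "ordered")$y
}

#' Grid exploration of the hyperparameter posterior
#'
#' Evaluates the log marginal posterior on a regular grid in the principal
#' axes of the curvature (`n_grid` points per dimension spanning
#' `z_range` posterior sds), normalizes the weights, maps each grid atom to
#' the interpretable parameters (range `rho`, field variance `sigma2`,
#' persistence `a`, likelihood extras), and reports the weighted mean, sd
#' and 0.025/0.5/0.975 quantiles of the induced mixture.
#'
#' @param md model data (or `lm_fun` given directly).
#' @param theta_mode,curvature output of [optimize_hyper()].
#' @param n_grid,z_range grid resolution and half-width (defaults from the
#'   control list).
#' @param lm_fun optional log-posterior function overriding `md` (used for
#'   validation against closed forms).
#' @param transform optional function theta -> named list of reported
#'   parameters; defaults to the model's parameter transform.
#' @return list with `summary` (one row per parameter) and the weighted
#'   grid (`theta`, `weight`, `params`).
#' @export
hyper_posterior <- function(md = NULL, theta_mode, curvature,
                            n_grid = NULL, z_range = NULL,
                            lm_fun = NULL, transform = NULL) {
  if (is.null(lm_fun)) lm_fun <- function(th) log_marginal(md, th)
  if (is.null(transform))
    transform <- function(th) theta_to_params(th, md$spec)
  if (is.null(n_grid)) n_grid <- md$control$n_grid %||% 5
  if (is.null(z_range)) z_range <- md$control$z_range %||% 2.5
  k <- length(theta_mode)
  if (k == 0) return(list(summary = data.frame(), grid = NULL))
  Sigma <- tryCatch(solve(curvature), error = function(e) NULL)
  if (is.null(Sigma) || any(!is.finite(Sigma)) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    ## fall back to a diagonal scale if the curvature is not usable
    Sigma <- diag(pmax(1 / pmax(diag(curvature), 1e-8), 1e-4), k)
  }
  ee <- eigen(Sigma, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 1e-12)), k)
  zs <- seq(-z_range, z_range, length.out = n_grid)
  zgrid <- as.matrix(expand.grid(rep(list(zs), k)))
  thetas <- t(theta_mode + L %*% t(zgrid))
  lp <- apply(thetas, 1, lm_fun)
  wgt <- exp(lp - max(lp))
  wgt <- wgt / sum(wgt)
  if (max(wgt) > 0.999)
    warning("hyperparameter grid too narrow: one atom carries ",
            "essentially all posterior weight")
  plist <- lapply(seq_len(nrow(thetas)),
                  function(i) transform(thetas[i, ]))
  pnames <- names(plist[[1]])
  pnames <- setdiff(pnames, c("kappa", "tau"))
  rows <- lapply(pnames, function(pn) {
    v <- vapply(plist, function(p) p[[pn]], numeric(1))
    m <- sum(wgt * v)
    s <- sqrt(max(sum(wgt * (v - m)^2), 0))
    q <- wquantile(v, wgt, c(0.025, 0.5, 0.975))
    data.frame(parameter = pn, mean = m, sd = s,
               q0.025 = q[1], q0.5 = q[2], q0.975 = q[3])
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary,
       grid = list(theta = thetas, weight = wgt, lp = lp))
}

## ---- top-level fit -----------------------------------------------------------

#' Fit the spatiotemporal latent Gaussian model
#'
#' Full pipeline at fixed data: optimize the hyperparameters, summarize
#' their posterior on a grid, and return empirical-Bayes latent summaries
#' (posterior mean and sd of the field and fixed effects at the
#' hyperparameter mode).
#'
#' @param records validated survey sets.
#' @param mesh a `trawl_mesh`.
#' @param spec a `model_spec`.
#' @param control a [fit_control()] list.
#' @param init optional initial hyperparameter vector.
#' @return an object of class `spde_fit`.
#' @export
fit_spde <- function(records, mesh, spec = model_spec(),
                     control = fit_control(), init = NULL) {
  md <- build_model_data(records, mesh, spec, control)
  opt <- optimize_hyper(md, init = init)
  hp <- if (length(opt$theta_mode) > 0)
    hyper_posterior(md, opt$theta_mode, opt$curvature)
  else list(summary = data.frame(), grid = NULL)
  ga <- gaussian_approx(md, opt$theta_mode)
  ## marginal sds: dense inverse is fine at these latent dimensions
  Vdiag <- if (md$d <= 5000) {
    Qinv <- Matrix::solve(ga$chol, Matrix::Diagonal(md$d), system = "A")
    Matrix::diag(Qinv)
  } else rep(NA_real_, md$d)
  nT <- md$field_dim
  latent_mean <- latent_sd <- NULL
  if (md$spec$include_latent) {
    Tm <- if (spec$temporal_mode == "shared") 1L else md$T
    latent_mean <- matrix(ga$x[seq_len(nT)], md$n, Tm)
    latent_sd <- matrix(sqrt(pmax(Vdiag[seq_len(nT)], 0)), md$n, Tm)
  }
  beta <- data.frame(
    effect = c("intercept", spec$covariates),
    mean = ga$x[nT + seq_len(md$p)],
    sd = sqrt(pmax(Vdiag[nT + seq_len(md$p)], 0)))
  structure(list(spec = spec, mesh = mesh, md = md,
                 theta_mode = opt$theta_mode, curvature = opt$curvature,
                 hyper_summary = hp$summary, hyper_grid = hp$grid,
                 latent_mean = latent_mean, latent_sd = latent_sd,
                 beta = beta, mode = ga$x, eta_hat = ga$eta,
                 log_marginal = opt$lm_mode, n_eval = opt$n_eval,
                 n_obs = length(md$y)),
            class = "spde_fit")
}

#' @export
print.spde_fit <- function(x, ...) {
  cat("spde_fit:", x$spec$likelihood, "likelihood,",
      x$spec$temporal_mode, "temporal mode,", x$n_obs, "observations\n")
  if (nrow(x$hyper_summary) > 0) {
    cat("hyperparameter posterior:\n")
    print(x$hyper_summary, digits = 4)
  }
  cat("fixed effects:\n")
  print(x$beta, digits = 4)
  invisible(x)
}

#' Posterior latent-field raster by period
#'
#' Projects the posterior mean of the latent field (log-abundance scale)
#' onto a regular lon/lat grid clipped to the mesh; grid points outside the
#' mesh hull are masked (NA), not errors.
#'
#' @param fit an `spde_fit`.
#' @param grid_step grid spacing in degrees.
#' @return list with `raster` (long data.frame: lon, lat, period, value)
#'   and `stats` (per-period min/mean/max over unmasked cells).
#' @export
latent_summary <- function(fit, grid_step = 0.25) {
  mesh <- fit$mesh
  rng <- apply(mesh$nodes, 2, range)
  lon <- seq(rng[1, 1], rng[2, 1], by = grid_step)
  lat <- seq(rng[1, 2], rng[2, 2], by = grid_step)
  gr <- expand.grid(lon = lon, lat = lat)
  A <- projector(mesh, as.matrix(gr), allow_outside = TRUE)
  outside <- attr(A, "outside")
  Tm <- ncol(fit$latent_mean)
  out <- lapply(seq_len(Tm), function(t) {
    v <- as.vector(A %*% fit$latent_mean[, t])
    v[outside] <- NA
    data.frame(lon = gr$lon, lat = gr$lat, period = t, value = v)
  })
  raster <- do.call(rbind, out)
  stats <- do.call(rbind, lapply(seq_len(Tm), function(t) {
    v <- raster$value[raster$period == t]
    data.frame(period = t, min = min(v, na.rm = TRUE),
               mean = mean(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  }))
  list(raster = raster, stats = stats)
}
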