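# The Laplace machinery is validated against closed forms in the Gaussian
# limit (where the approximation is exact) and against generic numerical
# optimization for the Poisson likelihood.

gaussian_toy <- function(theta = c(log(2), log(0.3), log(2)), seed = 4) {
  set.seed(3)
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
               cbind(runif(8), runif(8)))
  mesh <- build_mesh(pts, max_edge = 0.5, cutoff = 0.05, extension = 0.1)
  recs <- square_records(15, seed = seed)
  recs$count <- recs$count + 1L
  spec <- model_spec("gaussian", "shared", "bottom_temp", zeros = "include")
  md <- build_model_data(recs, mesh, spec)
  list(md = md, theta = theta)
}

test_that("Gaussian likelihood: one Newton step reaches the exact posterior", {
  gt <- gaussian_toy()
  md <- gt$md; theta <- gt$theta
  ga <- gaussian_approx(md, theta)
  Qp <- as.matrix(trawlGMRF:::build_prior(md, theta)$Q)
  A <- as.matrix(md$A)
  prec <- exp(theta[3])
  Qpost <- Qp + prec * crossprod(A)
  mu <- solve(Qpost, prec * t(A) %*% (md$y - md$offset))
  expect_equal(as.numeric(ga$x), as.numeric(mu), tolerance = 1e-9)
  expect_lte(ga$n_iter, 3)
})

test_that("Gaussian likelihood: log marginal equals the closed-form MVN
           marginal to 6 decimals", {
  gt <- gaussian_toy()
  md <- gt$md; theta <- gt$theta
  lm_pkg <- log_marginal(md, theta)
  A <- as.matrix(md$A)
  Qp <- as.matrix(trawlGMRF:::build_prior(md, theta)$Q)
  n <- length(md$y)
  Sy <- A %*% solve(Qp, t(A)) + diag(n) / exp(theta[3])
  r <- md$y - md$offset
  lm_cf <- -0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(Sy)$modulus) -
    0.5 * as.numeric(t(r) %*% solve(Sy, r)) +
    trawlGMRF:::log_prior_theta(md, theta)
  expect_equal(lm_pkg, lm_cf, tolerance = 1e-9)
})

test_that("Poisson mode matches a generic optimizer on a 5-node toy", {
  mesh <- unit_square_mesh()
  recs <- square_records(15, seed = 4)
  spec <- model_spec("poisson", "shared", character(0), zeros = "include")
  md <- build_model_data(recs, mesh, spec)
  theta <- c(log(3), log(0.5))
  ga <- gaussian_approx(md, theta)
  Qp <- as.matrix(trawlGMRF:::build_prior(md, theta)$Q)
  A <- as.matrix(md$A)
  nl <- function(x) -(sum(dpois(md$y, exp(A %*% x + md$offset), log = TRUE)) -
                        0.5 * t(x) %*% Qp %*% x)
  o <- optim(rep(0, ncol(A)), nl, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(ga$x - o$par)), 1e-6)
})

test_that("single observation with a flat prior: mode is the Poisson MLE", {
  mesh <- unit_square_mesh()
  recs <- make_sets(count = 3, lon = 0.5, lat = 0.5)
  spec <- model_spec("poisson", covariates = character(0),
                     include_latent = FALSE, zeros = "include")
  md <- build_model_data(recs, mesh, spec, fit_control(beta_prior_sd = 1e4))
  ga <- gaussian_approx(md, numeric(0))
  expect_equal(as.numeric(ga$x), log(3), tolerance = 1e-6)
})

test_that("log marginal is deterministic, decreases with a duplicated
           observation, and is invariant to node re-ordering", {
  mesh <- unit_square_mesh(max_edge = 0.6)
  recs <- square_records(20, seed = 7)
  spec <- model_spec("poisson", "shared", character(0), zeros = "include")
  theta <- c(log(3), log(0.5))
  md1 <- build_model_data(recs, mesh, spec)
  lm1a <- log_marginal(md1, theta)
  lm1b <- log_marginal(build_model_data(recs, mesh, spec), theta)
  expect_identical(lm1a, lm1b)

  md2 <- build_model_data(rbind(recs, recs[1, ]), mesh, spec)
  expect_lt(log_marginal(md2, theta), lm1a)

  perm <- rev(seq_len(mesh$n_nodes))
  mesh_p <- mesh
  mesh_p$nodes <- mesh$nodes[perm, ]
  inv <- integer(mesh$n_nodes); inv[perm] <- seq_len(mesh$n_nodes)
  mesh_p$triangles <- matrix(inv[mesh$triangles], ncol = 3)
  lm_p <- log_marginal(build_model_data(recs, mesh_p, spec), theta)
  expect_equal(lm_p, lm1a, tolerance = 1e-8)
})

test_that("outer optimization: fixed point on restart, multistart agreement", {
  sc <- small_scenario(seed = 11, sets_per_period = 2000, beta_temp = 0,
                       occupancy = 0.2)
  spec <- model_spec("poisson", "independent", character(0),
                     zeros = "include")
  md <- build_model_data(sc$sets, sc$mesh, spec)
  opt <- optimize_hyper(md)
  opt2 <- optimize_hyper(md, init = opt$theta_mode)
  expect_lt(abs(opt2$lm_mode - opt$lm_mode), 1e-5)
  opt3 <- optimize_hyper(md, init = opt$theta_mode + c(1.5, -1.5))
  expect_equal(unname(opt3$theta_mode), unname(opt$theta_mode),
               tolerance = 0.05)
})

test_that("hyper posterior: Gaussian limit, ordered quantiles, and a 1-d
           conjugate quadrature oracle", {
  ## symmetric quadratic log-posterior: mean = mode, Gaussian quantiles
  lm_quad <- function(th) -0.5 * sum((th - c(1, -2))^2 / c(0.5, 2)^2)
  hp <- hyper_posterior(theta_mode = c(x = 1, y = -2),
                        curvature = diag(1 / c(0.5, 2)^2),
                        n_grid = 21, z_range = 4, lm_fun = lm_quad,
                        transform = function(th) list(x = th[1], y = th[2]))
  expect_equal(hp$summary$mean, c(1, -2), tolerance = 1e-6)
  expect_equal(hp$summary$sd, c(0.5, 2), tolerance = 0.01)
  expect_equal(hp$summary$q0.025, c(1, -2) - 1.96 * c(0.5, 2),
               tolerance = 0.02)
  expect_true(all(hp$summary$q0.025 <= hp$summary$q0.5 &
                    hp$summary$q0.5 <= hp$summary$q0.975))

  ## 1-d conjugate toy: Gaussian observations with known mean, unknown log
  ## precision; oracle quantiles by direct quadrature of the exact posterior
  set.seed(5)
  y <- rnorm(40, 0, sqrt(1 / 2.5))
  loglik <- function(lp) sum(dnorm(y, 0, sqrt(1 / exp(lp)), log = TRUE)) +
    dnorm(lp, 0, 2, log = TRUE)
  o <- optimize(function(lp) -loglik(lp), c(-4, 4))
  H <- -numDeriv_hess(loglik, o$minimum)
  hp1 <- hyper_posterior(theta_mode = c(lp = o$minimum),
                         curvature = matrix(H, 1, 1),
                         n_grid = 41, z_range = 5, lm_fun = loglik,
                         transform = function(th) list(prec = exp(th[1])))
  grid <- seq(o$minimum - 6, o$minimum + 6, length.out = 4001)
  w <- exp(sapply(grid, loglik) - loglik(o$minimum))
  w <- w / sum(w)
  cdf <- cumsum(w) - w / 2
  qs <- approx(cdf, exp(grid), c(0.025, 0.5, 0.975), rule = 2,
               ties = "ordered")$y
  expect_equal(hp1$summary$q0.025, qs[1], tolerance = 0.02 * qs[1])
  expect_equal(hp1$summary$q0.5, qs[2], tolerance = 0.02 * qs[2])
  expect_equal(hp1$summary$q0.975, qs[3], tolerance = 0.02 * qs[3])
})

test_that("latent summary rasters: node identity, constant field, masking", {
  sc <- small_scenario(seed = 13, sets_per_period = 400, beta_temp = 0,
                       occupancy = 0.15)
  spec <- model_spec("poisson", "ar1", character(0), zeros = "include")
  fit <- fit_spde(sc$sets, sc$mesh, spec,
                  fit_control(n_grid = 3, outer_maxit = 200))
  ## raster values at node locations equal the node values
  Anode <- projector(fit$mesh, fit$mesh$nodes)
  expect_equal(as.vector(Anode %*% fit$latent_mean[, 1]),
               fit$latent_mean[, 1], tolerance = 1e-9)
  ls <- latent_summary(fit, grid_step = 0.5)
  expect_equal(nrow(ls$stats), 3)
  expect_true(any(is.na(ls$raster$value)))   # masked outside hull
  ## constant field -> constant raster
  fit$latent_mean[, 1] <- 1
  ls2 <- latent_summary(fit, grid_step = 1)
  v <- ls2$raster$value[ls2$raster$period == 1]
  expect_equal(range(v, na.rm = TRUE), c(1, 1), tolerance = 1e-9)
})
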