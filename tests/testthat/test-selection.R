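# DIC against quadrature/closed forms, CPO against literal leave-one-out
# refits, and the comparison table semantics.

intercept_spec <- model_spec("poisson", covariates = character(0),
                             include_latent = FALSE, zeros = "include")
tight_ctl <- fit_control(beta_prior_sd = 1)

test_that("DIC matches direct numerical integration on a Poisson toy", {
  mesh <- unit_square_mesh()
  yy <- c(18, 22, 25, 19, 21)
  recs <- make_sets(count = yy, lon = 0.5, lat = 0.5)
  fit <- fit_spde(recs, mesh, intercept_spec, tight_ctl)
  d <- dic(fit, n_draws = 20000, seed = 42)
  b <- seq(-6, 6, length.out = 8001)
  post <- dnorm(b, 0, 1)
  for (y in yy) post <- post * dpois(y, exp(b))
  post <- post / sum(post)
  dbar <- sum(post * vapply(b, function(bb)
    -2 * sum(dpois(yy, exp(bb), log = TRUE)), numeric(1)))
  dhat <- -2 * sum(dpois(yy, exp(sum(post * b)), log = TRUE))
  dic_q <- 2 * dbar - dhat
  expect_equal(d$dic, dic_q, tolerance = 0.01 * abs(dic_q))
})

test_that("DIC matches the conjugate closed form for a Gaussian toy", {
  mesh <- unit_square_mesh()
  yv <- c(2, 4, 1, 3)
  recs <- make_sets(count = yv, lon = 0.5, lat = 0.5)
  spec <- model_spec("gaussian", covariates = character(0),
                     include_latent = FALSE, zeros = "include")
  md <- build_model_data(recs, mesh, spec, tight_ctl)
  th <- c(log_prec = log(4))
  ga <- gaussian_approx(md, th)
  fit <- fit_spde(recs, mesh, spec, tight_ctl, init = th)
  fit$theta_mode <- th       # evaluate DIC at a fixed observation precision
  fit$mode <- ga$x
  d <- dic(fit, n_draws = 50000, seed = 7)
  ## prior b ~ N(0,1), y_i ~ N(b, 1/prec): posterior b ~ N(m, 1/postprec)
  n <- 4; prec <- 4
  postprec <- 1 + n * prec
  m <- prec * sum(yv) / postprec
  dhat <- sum(-2 * dnorm(yv, m, sqrt(1 / prec), log = TRUE))
  dbar <- dhat + prec * n / postprec
  dic_cf <- 2 * dbar - dhat
  expect_equal(d$dic, dic_cf, tolerance = 0.01 * dic_cf)
})

test_that("DIC approximately doubles on a duplicated dataset and is
           reproducible to 6 decimals under a fixed seed", {
  mesh <- unit_square_mesh()
  recs <- make_sets(count = c(3, 5, 2, 4), lon = c(0.2, 0.4, 0.6, 0.8),
                    lat = 0.5)
  fit1 <- fit_spde(recs, mesh, intercept_spec, tight_ctl)
  fit2 <- fit_spde(rbind(recs, recs), mesh, intercept_spec, tight_ctl)
  d1 <- dic(fit1, n_draws = 10000, seed = 5)$dic
  d2 <- dic(fit2, n_draws = 10000, seed = 5)$dic
  expect_equal(d2 / d1, 2, tolerance = 0.1)
  expect_equal(dic(fit1, n_draws = 2000, seed = 9)$dic,
               dic(fit1, n_draws = 2000, seed = 9)$dic, tolerance = 1e-7)
  cp <- cpo(fit1, n_draws = 2000, seed = 9)$cpo_sum
  expect_equal(cp, cpo(fit1, n_draws = 2000, seed = 9)$cpo_sum,
               tolerance = 1e-7)
})

test_that("CPO matches literal leave-one-out refits on an n = 3 toy", {
  mesh <- unit_square_mesh()
  ys <- c(2, 3, 1)
  recs <- make_sets(count = ys, lon = 0.5, lat = 0.5)
  fit <- fit_spde(recs, mesh, intercept_spec, tight_ctl)
  cp <- cpo(fit, n_draws = 200000, seed = 42)
  ## literal LOO by quadrature: p(y_i | y_-i) under prior b ~ N(0,1)
  b <- seq(-6, 6, length.out = 8001)
  oracle <- vapply(1:3, function(i) {
    post <- dnorm(b, 0, 1)
    for (j in setdiff(1:3, i)) post <- post * dpois(ys[j], exp(b))
    post <- post / sum(post)
    sum(post * dpois(ys[i], exp(b)))
  }, numeric(1))
  expect_lt(max(abs(cp$cpo - oracle) / oracle), 0.02)
  expect_true(all(cp$cpo > 0 & cp$cpo <= 1))
  expect_length(cp$flagged, 0)
})

test_that("CPO matches the closed-form LOO density for independent
           Gaussian observations", {
  mesh <- unit_square_mesh()
  yv <- c(2, 4, 1)
  recs <- make_sets(count = yv, lon = 0.5, lat = 0.5)
  spec <- model_spec("gaussian", covariates = character(0),
                     include_latent = FALSE, zeros = "include")
  md <- build_model_data(recs, mesh, spec, tight_ctl)
  th <- c(log_prec = log(2))
  ga <- gaussian_approx(md, th)
  fit <- fit_spde(recs, mesh, spec, tight_ctl, init = th)
  fit$theta_mode <- th
  fit$mode <- ga$x
  cp <- cpo(fit, n_draws = 100000, seed = 11)
  ## closed form: b ~ N(0,1), y_i ~ N(b, 1/2) ->
  ## y_i | y_-i ~ N(m_-i, 1/2 + v_-i)
  prec <- 2
  oracle <- vapply(1:3, function(i) {
    pp <- 1 + 2 * prec
    m <- prec * sum(yv[-i]) / pp
    dnorm(yv[i], m, sqrt(1 / prec + 1 / pp))
  }, numeric(1))
  expect_equal(as.numeric(cp$cpo), oracle, tolerance = 0.02)
})

test_that("DIC ordering agrees with exact marginal likelihood on nested
           Gaussian toys", {
  mesh <- unit_square_mesh()
  set.seed(8)
  n <- 40
  x <- runif(n, 2, 7)
  y <- round(pmax(2 + 0.8 * x + rnorm(n, 0, 1), 0))
  recs <- make_sets(count = y, lon = 0.5, lat = 0.5, bottom_temp = x)
  sp_with <- model_spec("gaussian", covariates = "bottom_temp",
                        include_latent = FALSE, zeros = "include")
  sp_null <- model_spec("gaussian", covariates = character(0),
                        include_latent = FALSE, zeros = "include")
  f1 <- fit_spde(recs, mesh, sp_with, tight_ctl)
  f0 <- fit_spde(recs, mesh, sp_null, tight_ctl)
  expect_lt(dic(f1, 5000, 3)$dic, dic(f0, 5000, 3)$dic)
  expect_gt(f1$log_marginal, f0$log_marginal)
})

test_that("comparison table: identical specs tie, ranking is by DIC", {
  sc <- small_scenario(seed = 17, sets_per_period = 500, beta_temp = 0.5,
                       occupancy = 0.15)
  specs <- list(
    a = model_spec("poisson", "independent", "bottom_temp",
                   zeros = "include"),
    b = model_spec("poisson", "independent", "bottom_temp",
                   zeros = "include"))
  tab <- compare_models(specs, sc$sets, sc$mesh,
                        fit_control(n_grid = 3), n_draws = 300, seed = 2)
  expect_equal(tab$dic[1], tab$dic[2], tolerance = 1e-8)
  expect_equal(tab$cpo_sum[1], tab$cpo_sum[2], tolerance = 1e-8)
  expect_false(any(tab$failed))
  expect_true(all(diff(tab$dic) >= 0))
})

test_that("candidate labels use the latent-field notation", {
  expect_equal(candidate_label(character(0)), "xi(s,t)")
  expect_equal(candidate_label("bottom_temp"), "xi(s,t) + temperature")
  expect_equal(candidate_label(c("depth", "bottom_temp")),
               "xi(s,t) + depth + temperature")
})
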