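test_that("management-regime periods map regime boundary years correctly", {
  expect_equal(assign_period(1989), 1L)
  expect_equal(assign_period(1990), 2L)
  expect_equal(assign_period(2003), 2L)
  expect_equal(assign_period(2004), 3L)
  expect_equal(assign_period(c(1978, 2013)), c(1L, 3L))
  expect_error(assign_period(1977), "1978-2013")
  expect_error(assign_period(2014), "1978-2013")
})

test_that("reading validates rows and round-trips generated surveys", {
  path <- tempfile(fileext = ".csv")
  df <- make_sets(count = c(2, 0, 5), lon = c(-60, -61, -62))
  write_survey_sets(df, path)
  got <- read_survey_sets(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$count, c(2L, 0L, 5L))

  ## a missing column is a format error naming the column
  df2 <- df[, setdiff(names(df), "effort")]
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_survey_sets(path), "effort")

  ## a non-numeric count drops the row with a warning
  df3 <- df
  df3$count <- as.character(df3$count)
  df3$count[2] <- "NA"
  utils::write.table(df3, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_warning(got3 <- read_survey_sets(path), "rejected")
  expect_equal(nrow(got3), 2)

  ## 1,000 generated rows round-trip identically through write/read
  design <- survey_design()
  mesh <- design_mesh(design, n_points = 120, max_edge = 2.5, cutoff = 1.2,
                      seed = 3)
  truth <- synthetic_truth(sets_per_period = 313, n_estuary = 61, seed = 8)
  sets <- simulate_sets(mesh, simulate_field(mesh, truth), design, truth)
  expect_equal(nrow(sets), 313 * 3 + 61)
  write_survey_sets(sets, path)
  back <- read_survey_sets(path)
  expect_equal(nrow(back), nrow(sets))
  expect_equal(back$count, sets$count)
  expect_equal(back$lat, sets$lat)
  expect_equal(back$effort, sets$effort)
})

test_that("effort standardization: offset and multiplier modes", {
  r <- make_sets(count = 4, effort = 2)
  expect_equal(standardize_effort(make_sets(effort = 1), "offset"), 0)
  expect_equal(standardize_effort(r, "offset"), log(2))
  expect_equal(standardize_effort(r, "multiplier"), 2)
  r$effort <- -1
  expect_error(standardize_effort(r, "offset"), "positive")
})

test_that("a log-effort offset is equivalent to scaling the Poisson mean", {
  ## 1-node toy: the flat-prior mode with offset log(2) equals the GLM
  ## fit, and doubling effort halves the fitted per-unit rate
  mesh <- unit_square_mesh()
  ctl <- fit_control(beta_prior_sd = 1e4)
  spec <- model_spec("poisson", covariates = character(0),
                     include_latent = FALSE, zeros = "include")
  r2 <- make_sets(count = 4, lon = 0.5, lat = 0.5, effort = 2)
  md <- build_model_data(r2, mesh, spec, ctl)
  ga <- gaussian_approx(md, numeric(0))
  or <- stats::glm(count ~ 1, family = stats::poisson, data = r2,
                   offset = log(effort))
  expect_equal(as.numeric(ga$x), unname(coef(or)), tolerance = 1e-6)
  expect_equal(as.numeric(ga$x), log(4 / 2), tolerance = 1e-6)

  r1 <- r2; r1$effort <- 1
  md1 <- build_model_data(r1, mesh, spec, ctl)
  ga1 <- gaussian_approx(md1, numeric(0))
  ## same count at doubled effort -> fitted mean halves on the rate scale
  expect_equal(exp(as.numeric(ga$x)) * 2, exp(as.numeric(ga1$x)),
               tolerance = 1e-6)
})

test_that("polygon exclusion removes strict-interior points only", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  empty <- matrix(numeric(0), 0, 2)
  recs <- make_sets(count = 1, lon = c(0.5, 0, 2), lat = c(0.5, 0.5, 2))
  expect_equal(exclude_polygon(recs, empty)$n_removed, 0L)
  out <- exclude_polygon(recs, square)
  expect_equal(out$n_removed, 1L)           # centroid removed
  expect_true(0 %in% out$records$lon)       # boundary point kept
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(exclude_polygon(recs, bow), "self-intersecting")
})

test_that("the generator plants exactly 61 estuary records inside the ring", {
  design <- survey_design()
  mesh <- design_mesh(design, n_points = 120, max_edge = 2.5, cutoff = 1.2,
                      seed = 3)
  truth <- synthetic_truth(sets_per_period = 200, n_estuary = 61, seed = 5)
  sets <- simulate_sets(mesh, simulate_field(mesh, truth), design, truth)
  out <- exclude_polygon(sets, design$estuary_ring)
  expect_equal(out$n_removed, 61L)
  expect_equal(nrow(out$records), 600)
})

test_that("occupancy summary is internally consistent and scale invariant", {
  set.seed(21)
  recs <- make_sets(count = rpois(300, 0.2),
                    region = sample(c("NL", "NS", "USA"), 300, TRUE),
                    year = sample(1978:2013, 300, TRUE))
  occ <- occupancy_summary(recs)
  reg <- occ[occ$region != "Summary", ]
  tot <- occ[occ$region == "Summary", ]
  expect_equal(sum(reg$total_sets), tot$total_sets)
  expect_equal(sum(reg$sets_with_halibut), tot$sets_with_halibut)
  ## duplicating every record leaves the percentages unchanged
  occ2 <- occupancy_summary(rbind(recs, recs))
  expect_equal(occ2$percent, occ$percent)
  ## single zero-count record
  expect_equal(occupancy_summary(make_sets(count = 0))$percent, c(0, 0))
  ## empty input -> empty table
  expect_equal(nrow(occupancy_summary(recs[0, ])), 0)
})

test_that("percent rounding is half-up to two decimals", {
  expect_equal(round_half_up(16.405, 2), 16.41)
  expect_equal(round_half_up(6.005, 2), 6.01)
  expect_equal(round_half_up(2.034, 2), 2.03)
})

test_that("stratified mean reduces to the plain mean and matches a direct
           re-summation", {
  one <- data.frame(stratum = "h1", area = 500, region = "NS")
  recs <- make_sets(count = c(1, 2, 6), year = 2000)
  recs$stratum <- "h1"
  expect_equal(stratified_mean(recs, one)$mean, 3)

  two <- data.frame(stratum = c("h1", "h2"), area = c(300, 300),
                    region = "NS")
  recs2 <- make_sets(count = c(1, 3), year = 2000, stratum = c("h1", "h2"))
  expect_equal(stratified_mean(recs2, two)$mean, 2)

  ## random allocation over 5 strata vs brute-force weighted sum
  set.seed(9)
  st <- data.frame(stratum = paste0("h", 1:5), area = runif(5, 100, 1000),
                   region = "NS")
  rr <- make_sets(count = rpois(200, 2), year = 2000,
                  stratum = sample(st$stratum, 200, TRUE))
  got <- stratified_mean(rr, st)$mean
  m <- tapply(rr$count, rr$stratum, mean)
  ar <- st$area[match(names(m), st$stratum)]
  expect_equal(got, sum(ar * m) / sum(ar))

  ## positive-only restricts before averaging
  rp <- stratified_mean(rr, st, value = "positive_only")$mean
  mp <- tapply(rr$count[rr$count > 0], rr$stratum[rr$count > 0], mean)
  arp <- st$area[match(names(mp), st$stratum)]
  expect_equal(rp, sum(arp * mp) / sum(arp))

  expect_error(stratified_mean(make_sets(stratum = "zz"), st), "zz")
})

test_that("uniform areas with balanced allocation equal the global mean", {
  set.seed(14)
  st <- data.frame(stratum = paste0("h", 1:4), area = rep(250, 4),
                   region = "NS")
  counts <- rpois(400, 1.7)
  rr <- make_sets(count = counts, year = 2001,
                  stratum = rep(st$stratum, each = 100))
  expect_equal(stratified_mean(rr, st)$mean, mean(counts))
})
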