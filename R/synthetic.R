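## Synthetic stratified-random trawl surveys with the statistical structure
## the spatiotemporal model assumes: a Matern GMRF with AR(1) persistence
## across three periods, a smooth bottom-temperature covariate partially
## confounded with space, log-normal effort, Poisson counts, ~6% occupancy,
## and a planted block of estuary records exercising the exclusion step.

#' Generating parameters for synthetic surveys
#'
#' Defaults are the study conditions of the recovery experiments: range
#' 2.25 degrees, field variance 0.12, persistence 0.77 (the posterior means
#' of the fitted survey model), three periods of 25,000 sets targeting 6%
#' occupancy (~1,500 positive sets per period), and a weak positive
#' temperature effect.
#'
#' @param rho spatial range, degrees latitude.
#' @param sigma2 marginal variance of the latent field.
#' @param a AR(1) persistence in (-1, 1).
#' @param beta0 intercept (log scale); `NA` calibrates it to hit
#'   `occupancy_target`.
#' @param beta_temp linear effect of bottom temperature per degree C.
#' @param T_periods number of periods.
#' @param sets_per_period trawl sets per period.
#' @param occupancy_target fraction of sets with positive catch.
#' @param n_estuary records planted inside the estuary exclusion ring.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(rho = 2.25, sigma2 = 0.12, a = 0.77,
                            beta0 = NA_real_, beta_temp = 0.1,
                            T_periods = 3L, sets_per_period = 25000L,
                            occupancy_target = 0.06, n_estuary = 61L,
                            seed = 1L) {
  stopifnot(rho > 0, sigma2 > 0, abs(a) < 1, T_periods >= 1,
            sets_per_period > 0, occupancy_target > 0, occupancy_target < 1)
  structure(list(rho = rho, sigma2 = sigma2, a = a, beta0 = beta0,
                 beta_temp = beta_temp, T_periods = as.integer(T_periods),
                 sets_per_period = as.integer(sets_per_period),
                 occupancy_target = occupancy_target,
                 n_estuary = as.integer(n_estuary), seed = as.integer(seed)),
            class = "synthetic_truth")
}

## deterministic region labels over the synthetic shelf
region_of <- function(lon, lat) {
  out <- rep("NS", length(lon))
  out[lat > 47.5 & lon < -62] <- "NGSL"
  out[lat > 46.5 & lon >= -62] <- "NL"
  out[lat <= 47.5 & lat > 45 & lon < -64.5] <- "SGSL"
  out[lat <= 45 & lon < -66] <- "USA"
  out
}

#' Synthetic shelf survey design
#'
#' A shelf-like lon/lat polygon (~12 x 8 degrees) with a triangular estuary
#' notch cut out of its northern edge, a matching estuary exclusion ring, a
#' 4 x 3 block stratification with areas from a fine-grid clip to the
#' polygon, and the smooth temperature surface parameters.
#'
#' @param n_lon,n_lat stratification blocks along each axis.
#' @return a `survey_design` list with `boundary`, `estuary_ring`, `strata`
#'   (stratum, area km^2, region, block bounds) and temperature settings.
#' @export
survey_design <- function(n_lon = 4, n_lat = 3) {
  boundary <- rbind(c(-68, 42), c(-56, 42), c(-56, 50), c(-62, 50),
                    c(-64, 48.5), c(-66, 50), c(-68, 50))
  estuary_ring <- rbind(c(-66.3, 50.3), c(-61.7, 50.3), c(-64, 48.6))
  lon_b <- seq(-68, -56, length.out = n_lon + 1)
  lat_b <- seq(42, 50, length.out = n_lat + 1)
  ## clip block areas to the polygon on a fine deterministic grid
  gx <- seq(-68 + 0.025, -56 - 0.025, by = 0.05)
  gy <- seq(42 + 0.025, 50 - 0.025, by = 0.05)
  gr <- expand.grid(lon = gx, lat = gy)
  inside <- points_inside_ring(as.matrix(gr), boundary, strict = FALSE)
  km2_per_cell <- 0.05 * 111 * 0.05 * 111 * cos(46 * pi / 180)
  strata <- NULL
  k <- 0
  for (i in seq_len(n_lon)) for (j in seq_len(n_lat)) {
    k <- k + 1
    inb <- gr$lon >= lon_b[i] & gr$lon < lon_b[i + 1] &
      gr$lat >= lat_b[j] & gr$lat < lat_b[j + 1]
    area <- sum(inside & inb) * km2_per_cell
    if (area <= 0) next
    ctr_lon <- (lon_b[i] + lon_b[i + 1]) / 2
    ctr_lat <- (lat_b[j] + lat_b[j + 1]) / 2
    strata <- rbind(strata, data.frame(
      stratum = sprintf("S%02d", k), area = area,
      region = region_of(ctr_lon, ctr_lat),
      lon_min = lon_b[i], lon_max = lon_b[i + 1],
      lat_min = lat_b[j], lat_max = lat_b[j + 1],
      stringsAsFactors = FALSE))
  }
  ## small nominal stratum for the planted estuary records
  strata <- rbind(strata, data.frame(
    stratum = "EST", area = 1000, region = "NGSL",
    lon_min = -66.3, lon_max = -61.7, lat_min = 48.6, lat_max = 50.3))
  structure(list(boundary = boundary, estuary_ring = estuary_ring,
                 strata = strata,
                 temp = list(base = 4.5, lat_slope = -0.35, lon_amp = 0.5,
                             period_shift = c(0, 0.4, 0), noise_sd = 0.5,
                             range = c(2, 7))),
            class = "survey_design")
}

## smooth temperature surface + period shift (noise added at sampling time)
temp_surface <- function(design, lon, lat, period) {
  tp <- design$temp
  shift <- tp$period_shift[pmin(period, length(tp$period_shift))]
  tp$base + tp$lat_slope * (lat - 46) + tp$lon_amp * sin((lon + 62) / 3) +
    shift
}

#' Simulate the latent spatiotemporal field on a mesh
#'
#' One exact draw of the space-time GMRF with Matern SPDE spatial precision
#' and standardized AR(1) temporal precision, so interior slice marginal
#' variance is approximately `sigma2` and consecutive slices correlate at
#' `a`.
#'
#' @param mesh a `trawl_mesh` on the design domain.
#' @param truth a [synthetic_truth()].
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return n_nodes x T matrix of field values.
#' @export
simulate_field <- function(mesh, truth, seed = truth$seed) {
  fem <- fem_matrices(mesh)
  sp <- spde_params(rho = truth$rho, sigma2 = truth$sigma2)
  Qs <- spatial_precision(fem, sp$kappa, sp$tau)
  Q <- st_precision(Qs, ar1_precision(truth$a, truth$T_periods))
  x <- sample_gmrf(Q, 1, seed = seed)
  matrix(x, mesh$n_nodes, truth$T_periods)
}

## stratified-random locations: uniform within block intersected with the
## domain polygon, by rejection
sample_stratum_points <- function(design, stratum_row, n) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 20)
    cand <- cbind(stats::runif(m, stratum_row$lon_min, stratum_row$lon_max),
                  stats::runif(m, stratum_row$lat_min, stratum_row$lat_max))
    ok <- points_inside_ring(cand, design$boundary, strict = TRUE)
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

## largest-remainder apportionment of n sets proportional to areas
apportion <- function(areas, n) {
  raw <- n * areas / sum(areas)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate trawl-survey sets from a latent field
#'
#' Places stratified-random sets in each period (allocation proportional to
#' stratum area), evaluates the smooth temperature surface plus noise,
#' draws log-normal effort, forms the linear predictor
#' `eta = field + beta0 + beta_temp * temp + log(effort)` and Poisson
#' counts. When `truth$beta0` is `NA` the intercept is calibrated by root
#' finding so the expected positive-set fraction matches
#' `truth$occupancy_target`. True zero counts are retained in the output;
#' `truth$n_estuary` extra records are planted inside the estuary ring to
#' exercise the exclusion step.
#'
#' @param mesh the mesh the field was simulated on.
#' @param field n_nodes x T field matrix from [simulate_field()].
#' @param design a [survey_design()].
#' @param truth a [synthetic_truth()].
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return survey-set `data.frame`; the calibrated intercept is stored in
#'   the `beta0` attribute.
#' @export
simulate_sets <- function(mesh, field, design, truth, seed = truth$seed) {
  set.seed(seed)
  strata <- design$strata[design$strata$stratum != "EST", , drop = FALSE]
  alloc <- apportion(strata$area, truth$sets_per_period)
  period_years <- list(1978:1989, 1990:2003, 2004:2013)
  recs <- vector("list", 0)
  for (t in seq_len(truth$T_periods)) {
    for (h in seq_len(nrow(strata))) {
      n_h <- alloc[h]
      if (n_h == 0) next
      pts <- sample_stratum_points(design, strata[h, ], n_h)
      recs[[length(recs) + 1L]] <- data.frame(
        lon = pts[, 1], lat = pts[, 2], period = t,
        stratum = strata$stratum[h], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  df$year <- vapply(df$period, function(t)
    sample(period_years[[min(t, 3)]], 1), integer(1))
  tp <- design$temp
  df$bottom_temp <- pmin(pmax(
    temp_surface(design, df$lon, df$lat, df$period) +
      stats::rnorm(nrow(df), 0, tp$noise_sd), tp$range[1]), tp$range[2])
  df$effort <- exp(stats::rnorm(nrow(df), 0, 0.1))
  df$depth <- pmin(pmax(100 + 150 * (df$lat - 42) / 8 +
                          30 * sin(df$lon / 2) +
                          stats::rnorm(nrow(df), 0, 15), 20), 500)
  A <- projector(mesh, cbind(df$lon, df$lat))
  xi <- numeric(nrow(df))
  for (t in seq_len(truth$T_periods)) {
    sel <- df$period == t
    xi[sel] <- as.vector(A[sel, , drop = FALSE] %*% field[, t])
  }
  eta0 <- xi + truth$beta_temp * df$bottom_temp + log(df$effort)
  beta0 <- truth$beta0
  if (is.na(beta0)) {
    fr <- function(b0) mean(1 - exp(-exp(eta0 + b0))) - truth$occupancy_target
    if (fr(-12) > 0 || fr(4) < 0)
      stop("occupancy calibration failed to bracket the target")
    beta0 <- stats::uniroot(fr, c(-12, 4), tol = 1e-8)$root
  }
  df$count <- stats::rpois(nrow(df), exp(pmin(eta0 + beta0, ETA_CLAMP)))
  df$weight <- round(df$count * stats::runif(nrow(df), 1.5, 3), 2)
  df$survey_id <- paste0("SYN-", region_of(df$lon, df$lat))
  df$region <- region_of(df$lon, df$lat)

  ## planted estuary records (inside the exclusion ring, outside the domain)
  if (truth$n_estuary > 0) {
    ring <- design$estuary_ring
    shrink <- 0.9
    ctr <- colMeans(ring)
    inner <- sweep(sweep(ring, 2, ctr) * shrink, 2, ctr, "+")
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < truth$n_estuary) {
      m <- 4 * (truth$n_estuary - nrow(pts)) + 20
      cand <- cbind(stats::runif(m, min(inner[, 1]), max(inner[, 1])),
                    stats::runif(m, min(inner[, 2]), max(inner[, 2])))
      ok <- points_inside_ring(cand, inner, strict = TRUE)
      pts <- rbind(pts, cand[ok, , drop = FALSE])
    }
    pts <- pts[seq_len(truth$n_estuary), , drop = FALSE]
    est <- data.frame(
      lon = pts[, 1], lat = pts[, 2],
      period = sample(seq_len(truth$T_periods), truth$n_estuary,
                      replace = TRUE),
      stratum = "EST", stringsAsFactors = FALSE)
    est$year <- vapply(est$period, function(t)
      sample(period_years[[min(t, 3)]], 1), integer(1))
    est$bottom_temp <- pmin(pmax(stats::rnorm(truth$n_estuary, 4, 0.5),
                                 tp$range[1]), tp$range[2])
    est$effort <- exp(stats::rnorm(truth$n_estuary, 0, 0.1))
    est$depth <- pmin(pmax(stats::rnorm(truth$n_estuary, 80, 20), 20), 500)
    est$count <- stats::rpois(truth$n_estuary, 0.3)
    est$weight <- round(est$count * stats::runif(truth$n_estuary, 1.5, 3), 2)
    est$survey_id <- "SYN-EST"
    est$region <- "NGSL"
    df <- rbind(df, est)
  }
  cols <- c("survey_id", "region", "year", "period", "lat", "lon", "depth",
            "bottom_temp", "count", "weight", "effort", "stratum")
  df <- df[, cols]
  df$lat <- round(df$lat, 5); df$lon <- round(df$lon, 5)
  df$bottom_temp <- round(df$bottom_temp, 3)
  df$depth <- round(df$depth, 1)
  df$effort <- round(df$effort, 5)
  rownames(df) <- NULL
  attr(df, "beta0") <- beta0
  df
}

#' Default mesh for the synthetic design
#'
#' Builds the recovery-experiment mesh: a seeded uniform sample of domain
#' locations thinned and refined to roughly 300 nodes, the problem size
#' used throughout the simulation studies.
#'
#' @param design a [survey_design()].
#' @param n_points seed locations before thinning.
#' @param max_edge,cutoff,extension mesh parameters (see [build_mesh()]).
#' @param seed RNG seed for the location sample.
#' @return a `trawl_mesh`.
#' @export
design_mesh <- function(design, n_points = 500, max_edge = 1.1,
                        cutoff = 0.5, extension = 0.10, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n_points) {
    cand <- cbind(stats::runif(2 * n_points, -68, -56),
                  stats::runif(2 * n_points, 42, 50))
    ok <- points_inside_ring(cand, design$boundary, strict = TRUE)
    pts <- rbind(pts, cand[ok, , drop = FALSE])
  }
  build_mesh(pts[seq_len(n_points), , drop = FALSE],
             boundary = design$boundary, max_edge = max_edge,
             cutoff = cutoff, extension = extension)
}

#' Seeded parameter-recovery experiment
#'
#' For each replicate: simulate a field and survey sets at the generating
#' truth, drop the planted estuary records via the exclusion ring, fit the
#' final model (Poisson, AR(1), bottom temperature, zeros included for
#' generative consistency), and record the hyperparameter posterior
#' summaries. Reports per-replicate bias, 95%-interval coverage of the
#' truth, and whether each posterior mean falls within `band_sds` reference
#' standard deviations of the truth. Replicate failures are recorded, not
#' raised.
#'
#' @param truth a [synthetic_truth()].
#' @param design a [survey_design()].
#' @param n_replicates number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param mesh optional prebuilt mesh (defaults to [design_mesh()]).
#' @param control a [fit_control()] list.
#' @param band_sds named reference sds for the +/- 2 sd recovery bands
#'   (defaults: 0.44 for rho, 0.02 for sigma2, 0.06 for a — the posterior
#'   sds of the fitted survey model).
#' @return a `recovery_report` list with `truth`, `results` (one row per
#'   replicate) and `summary`.
#' @export
recovery_experiment <- function(truth = synthetic_truth(),
                                design = survey_design(),
                                n_replicates = 20, seed = 1,
                                mesh = NULL, control = fit_control(),
                                band_sds = c(rho = 0.44, sigma2 = 0.02,
                                             a = 0.06)) {
  if (is.null(mesh)) mesh <- design_mesh(design, seed = seed)
  spec <- model_spec("poisson", "ar1", "bottom_temp", zeros = "include")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- seed + r
    row <- tryCatch({
      field <- simulate_field(mesh, truth, seed = s)
      sets <- simulate_sets(mesh, field, design, truth, seed = s + 10000L)
      sets <- exclude_polygon(sets, design$estuary_ring)$records
      fit <- fit_spde(sets, mesh, spec, control)
      hs <- fit$hyper_summary
      out <- data.frame(replicate = r, seed = s, failed = FALSE)
      for (pn in c("rho", "sigma2", "a")) {
        i <- match(pn, hs$parameter)
        tv <- truth[[pn]]
        out[[paste0(pn, "_mean")]] <- hs$mean[i]
        out[[paste0(pn, "_sd")]] <- hs$sd[i]
        out[[paste0(pn, "_cover")]] <- hs$q0.025[i] <= tv &
          tv <= hs$q0.975[i]
        out[[paste0(pn, "_within")]] <- abs(hs$mean[i] - tv) <=
          2 * band_sds[[pn]]
      }
      out
    }, error = function(e) {
      data.frame(replicate = r, seed = s, failed = TRUE,
                 rho_mean = NA_real_, rho_sd = NA_real_, rho_cover = NA,
                 rho_within = NA, sigma2_mean = NA_real_,
                 sigma2_sd = NA_real_, sigma2_cover = NA,
                 sigma2_within = NA, a_mean = NA_real_, a_sd = NA_real_,
                 a_cover = NA, a_within = NA)
    })
    rows[[r]] <- row
  }
  results <- do.call(rbind, rows)
  ok <- !results$failed
  summary <- data.frame(
    parameter = c("rho", "sigma2", "a"),
    truth = c(truth$rho, truth$sigma2, truth$a),
    mean_of_means = c(mean(results$rho_mean[ok]),
                      mean(results$sigma2_mean[ok]),
                      mean(results$a_mean[ok])),
    coverage = c(mean(results$rho_cover[ok]),
                 mean(results$sigma2_cover[ok]),
                 mean(results$a_cover[ok])),
    within_band = c(mean(results$rho_within[ok]),
                    mean(results$sigma2_within[ok]),
                    mean(results$a_within[ok])))
  structure(list(truth = truth, results = results, summary = summary,
                 n_failed = sum(results$failed)),
            class = "recovery_report")
}

#' Write / read a recovery report (delimited text)
#'
#' The truth is serialized as commented key=value header lines above the
#' per-replicate table, so a report round-trips through write/read.
#'
#' @param report a `recovery_report`.
#' @param path output file.
#' @return the path, invisibly (`write_recovery_report`); a
#'   `recovery_report` (`read_recovery_report`).
#' @export
write_recovery_report <- function(report, path) {
  tr <- report$truth
  hdr <- vapply(names(unclass(tr)), function(k)
    sprintf("# truth.%s=%.10g", k, as.numeric(tr[[k]])), character(1))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(report$results, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_recovery_report
#' @export
read_recovery_report <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# truth\\.", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# truth\\.", "", hdr), "="))
  tr <- as.list(suppressWarnings(as.numeric(kv[, 2])))
  names(tr) <- kv[, 1]
  tr$beta0 <- if (is.null(tr$beta0) || is.na(tr$beta0)) NA_real_ else tr$beta0
  truth <- do.call(synthetic_truth, tr[names(tr) %in%
    names(formals(synthetic_truth))])
  results <- utils::read.csv(text = lines[!grepl("^#", lines)])
  ok <- !results$failed
  summary <- data.frame(
    parameter = c("rho", "sigma2", "a"),
    truth = c(truth$rho, truth$sigma2, truth$a),
    mean_of_means = c(mean(results$rho_mean[ok]),
                      mean(results$sigma2_mean[ok]),
                      mean(results$a_mean[ok])),
    coverage = c(mean(results$rho_cover[ok]),
                 mean(results$sigma2_cover[ok]),
                 mean(results$a_cover[ok])),
    within_band = c(mean(results$rho_within[ok]),
                    mean(results$sigma2_within[ok]),
                    mean(results$a_within[ok])))
  structure(list(truth = truth, results = results, summary = summary,
                 n_failed = sum(results$failed)),
            class = "recovery_report")
}
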