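# Programmatic fixtures shared across the suite. Everything is built in
# code under fixed seeds; no data files.

# one or more survey-set rows with sensible defaults
make_sets <- function(count = 1, lon = -60, lat = 45, effort = 1,
                      bottom_temp = 4, depth = 100, year = 1985,
                      period = NULL, region = "NS", stratum = "s1",
                      survey_id = "SYN") {
  n <- max(length(count), length(lon), length(lat), length(effort),
           length(bottom_temp), length(year), length(stratum))
  df <- data.frame(survey_id = survey_id, region = region,
                   year = rep_len(year, n),
                   lat = rep_len(lat, n), lon = rep_len(lon, n),
                   depth = rep_len(depth, n),
                   bottom_temp = rep_len(bottom_temp, n),
                   count = rep_len(count, n), weight = 0,
                   effort = rep_len(effort, n),
                   stratum = rep_len(stratum, n),
                   stringsAsFactors = FALSE)
  df$period <- if (is.null(period)) assign_period(df$year) else
    rep_len(period, n)
  df
}

# small mesh over the unit square with an interior node
unit_square_mesh <- function(max_edge = 2) {
  build_mesh(cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)),
             max_edge = max_edge, cutoff = 0.01, extension = 0)
}

# hand-constructed mesh: the unit square split along the main diagonal
two_triangle_mesh <- function() {
  structure(list(nodes = cbind(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1)),
                 triangles = rbind(c(1, 2, 3), c(1, 3, 4)),
                 boundary_flag = rep(TRUE, 4), n_nodes = 4,
                 boundary = NULL),
            class = "trawl_mesh")
}

# records scattered strictly inside the unit square
square_records <- function(n, seed = 4, counts = NULL) {
  set.seed(seed)
  locs <- cbind(runif(n, 0.05, 0.95), runif(n, 0.05, 0.95))
  df <- make_sets(count = if (is.null(counts)) rpois(n, 2) else counts,
                  lon = locs[, 1], lat = locs[, 2],
                  bottom_temp = runif(n, 2, 7))
  df
}

# central finite-difference second derivative of a scalar function
numDeriv_hess <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# a compact, quickly identifiable synthetic scenario for fit tests
small_scenario <- function(seed = 11, sets_per_period = 1200,
                           beta_temp = 0.35, occupancy = 0.12) {
  design <- survey_design()
  mesh <- design_mesh(design, n_points = 300, max_edge = 1.6,
                      cutoff = 0.8, seed = 5)
  truth <- synthetic_truth(sets_per_period = sets_per_period,
                           beta_temp = beta_temp,
                           occupancy_target = occupancy, n_estuary = 0)
  field <- simulate_field(mesh, truth, seed = seed)
  sets <- simulate_sets(mesh, field, design, truth, seed = seed + 1000)
  list(design = design, mesh = mesh, truth = truth, field = field,
       sets = sets)
}
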