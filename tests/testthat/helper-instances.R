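# Fixture builders. Everything is generated in code under explicit seeds.

# Random small instance for oracle-equivalence and property tests.
# Demands are kept modest so trip counts stay in the exhaustive range of
# the enumeration oracle, and the growth-time grid is coarse.
make_small_instance <- function(seed, I = NULL, J = NULL,
                                t_min = 0.25, t_max = 1, dt = 0.25,
                                pmax = 0.5) {
  set.seed(seed)
  if (is.null(I)) I <- sample(1:4, 1)
  if (is.null(J)) J <- sample(1:4, 1)
  clusters <- data.frame(
    id = sprintf("c%d", seq_len(I)),
    n_reefs = 1L,
    centroid_lat = runif(I, -25, -10),
    centroid_lon = runif(I, 143, 152),
    annual_demand = runif(I, 5e4, 2.5e5),
    intra_allowance_km = runif(I, 0, 30)
  )
  facilities <- data.frame(
    id = sprintf("f%d", seq_len(J)),
    lat = runif(J, -25, -10),
    lon = runif(J, 142, 146)
  )
  problem_instance(
    clusters, facilities, cost_params(),
    survival_spec("asymptotic", c = 25, t0 = 0, pmax = pmax),
    solver_config(t_min = t_min, t_max = t_max, dt = dt)
  )
}

# Shared case-study-scale synthetic instance (50 reefs, 7 ports), built
# once per test run.
field_instance <- local({
  cache <- NULL
  function(dt = 0.04) {
    if (is.null(cache)) {
      reefs <- generate_synthetic_reefs(synthetic_field_spec(n_reefs = 50,
                                                             seed = 7))
      cache <<- build_instance(reefs)
    }
    inst <- cache
    inst$config <- solver_config(t_min = 0.02, t_max = 1, dt = dt)
    inst
  }
})

# Place a point `km` kilometres due south of (lat, lon) on the 6371-km
# sphere, so haversine distances are exact by construction.
offset_south <- function(lat, lon, km) {
  c(lat = lat - km / 6371 * 180 / pi, lon = lon)
}

tmp_file <- function(ext = "") tempfile(fileext = ext)

tmp_dir <- function() {
  d <- tempfile("dir")
  dir.create(d)
  d
}
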