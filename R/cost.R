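#' Cost and logistics parameters
#'
#' Capital, operating and transport cost parameters plus vessel and floor
#' space constants. Defaults are the case-study values: a facility costs
#' $10M fixed plus $45,000 per m2 of floor area (both amortized at 5% p.a.
#' over 25 years), a coral unit in residence costs $2.56 per unit-year,
#' transport costs $100 per km travelled, a deployment vessel carries
#' 432,000 units per trip, and settlement tanks hold 24,000 units per
#' 8.05 m2 of floor (walkways included), giving `a = 8.05/24000` m2 per
#' unit.
#'
#' @param c_f_cap fixed capital cost per facility ($).
#' @param c_v_cap variable capital cost per m2 of facility floor ($/m2).
#' @param c_f_op operating cost per unit-year of residence ($/unit/yr).
#' @param c_d_op transport cost per km travelled ($/km).
#' @param interest periodic interest rate for amortization (fraction/yr).
#' @param horizon amortization period (years, >= 1).
#' @param s_c vessel capacity (units per trip).
#' @param a floor area per unit in residence (m2/unit).
#' @return an object of class `cost_params`.
#' @export
cost_params <- function(c_f_cap = 1e7, c_v_cap = 45000, c_f_op = 2.56,
                        c_d_op = 100, interest = 0.05, horizon = 25,
                        s_c = 432000, a = 8.05 / 24000) {
  vals <- c(c_f_cap = c_f_cap, c_v_cap = c_v_cap, c_f_op = c_f_op,
            c_d_op = c_d_op, horizon = horizon, s_c = s_c, a = a)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cost parameters except 'interest' must be finite and > 0",
         call. = FALSE)
  }
  if (!is.finite(interest) || interest < 0) {
    stop("'interest' must be >= 0", call. = FALSE)
  }
  structure(list(c_f_cap = c_f_cap, c_v_cap = c_v_cap, c_f_op = c_f_op,
                 c_d_op = c_d_op, interest = interest, horizon = horizon,
                 s_c = s_c, a = a),
            class = "cost_params")
}

#' Capital recovery factor
#'
#' Annuity rate converting a lump capital sum into the equivalent constant
#' annual payment over `horizon` years at periodic `interest`:
#' `i / (1 - (1+i)^-n)`, and the zero-interest limit `1/n`.
#'
#' @param interest periodic rate (fraction/yr), >= 0.
#' @param horizon amortization period (years), >= 1.
#' @return annual fraction of the capital sum.
#' @export
#' @examples
#' capital_recovery_factor(0.05, 25) # 0.0709525
capital_recovery_factor <- function(interest = 0.05, horizon = 25) {
  stopifnot(is.numeric(interest), is.numeric(horizon))
  if (horizon < 1) stop("'horizon' must be >= 1 year", call. = FALSE)
  if (interest < 0) stop("'interest' must be >= 0", call. = FALSE)
  if (interest == 0) 1 / horizon else interest / (1 - (1 + interest)^(-horizon))
}

# Annualized cost of producing one unit at residence time t:
# amortized variable capital for its Little's-law floor share plus
# operating cost for its residence. $/unit/yr of production throughput.
unit_production_cost <- function(params, t) {
  crf <- capital_recovery_factor(params$interest, params$horizon)
  t * (crf * params$c_v_cap * params$a + params$c_f_op)
}

#' Default candidate facility sites (Queensland ports)
#'
#' Approximate public coordinates of the seven coastal Queensland cities
#' used as candidate facility locations: Bundaberg, Gladstone, Rockhampton,
#' Mackay, Airlie Beach, Townsville and Cairns. Fully overridable — any
#' data.frame with columns `id`, `name`, `lat`, `lon` works wherever this
#' registry is accepted.
#'
#' @return a data.frame with columns `id`, `name`, `lat`, `lon`.
#' @export
default_ports <- function() {
  data.frame(
    id   = c("BDB", "GLT", "ROK", "MKY", "ABH", "TSV", "CNS"),
    name = c("Bundaberg", "Gladstone", "Rockhampton", "Mackay",
             "Airlie Beach", "Townsville", "Cairns"),
    lat  = c(-24.87, -23.84, -23.38, -21.14, -20.27, -19.26, -16.92),
    lon  = c(152.35, 151.25, 150.51, 149.19, 148.72, 146.82, 145.78)
  )
}

#' Return-trip cost matrix between clusters and candidate facilities
#'
#' `c[i, j] = c_d_op * (2 * haversine(facility j, centroid of cluster i) +
#' intra-cluster allowance of cluster i)`: the cost in $ of one return
#' vessel trip from facility `j` serving cluster `i`, including the
#' star-tour allowance for visiting each member reef.
#'
#' @param facilities data.frame of candidate sites (`id`, `lat`, `lon`).
#' @param clusters a [sweep_cluster()] result (or any data.frame with
#'   `centroid_lat`, `centroid_lon`, `intra_allowance_km`).
#' @param params a [cost_params()] (only `c_d_op` is used).
#' @return an `|I| x |J|` matrix in $/trip, rows named by cluster id,
#'   columns by facility id.
#' @export
trip_cost_matrix <- function(facilities, clusters, params = cost_params()) {
  stopifnot(is.data.frame(facilities),
            all(c("id", "lat", "lon") %in% names(facilities)),
            all(c("centroid_lat", "centroid_lon", "intra_allowance_km")
                %in% names(clusters)),
            inherits(params, "cost_params"))
  check_coords(facilities$lat, facilities$lon, where = "facilities")
  I <- nrow(clusters); J <- nrow(facilities)
  m <- matrix(0, I, J, dimnames = list(clusters$id, facilities$id))
  for (j in seq_len(J)) {
    d <- haversine_km(clusters$centroid_lat, clusters$centroid_lon,
                      facilities$lat[j], facilities$lon[j])
    m[, j] <- params$c_d_op * (2 * d + clusters$intra_allowance_km)
  }
  m
}

#' Annualized cost breakdown of a production plan
#'
#' Decomposes the annual cost of a solution at growth time `t` into:
#' \describe{
#'   \item{fixed_capital}{`CRF * c_f_cap * sum(Y)` — amortized opening cost
#'     of the open facilities.}
#'   \item{variable_capital}{`CRF * c_v_cap * a * t * sum(X)` — amortized
#'     build cost of the floor area implied by Little's law (in-process
#'     inventory `t * X` times area per unit).}
#'   \item{operating}{`c_f_op * t * sum(X)` — residence cost of the
#'     in-process inventory.}
#'   \item{transport}{`sum(c_trip * T)` — cost of all vessel trips.}
#' }
#' The four components sum to the inner-MIP objective value.
#'
#' @param solution a list with elements `X` (|I| x |J| production matrix),
#'   `Y` (binary facility indicator) and `T` (|I| x |J| integer trip
#'   matrix), e.g. a [solve_mip()] result.
#' @param t growth time in years.
#' @param instance a [problem_instance()] (supplies cost parameters and the
#'   trip-cost matrix).
#' @return a list with components `fixed_capital`, `variable_capital`,
#'   `operating`, `transport`, `total`, in $/yr.
#' @export
annual_cost_breakdown <- function(solution, t, instance) {
  stopifnot(is.list(solution), !is.null(solution$X), !is.null(solution$Y),
            !is.null(solution$T))
  p <- instance$cost_params
  crf <- capital_recovery_factor(p$interest, p$horizon)
  X_tot <- sum(solution$X)
  out <- list(
    fixed_capital    = crf * p$c_f_cap * sum(solution$Y),
    variable_capital = crf * p$c_v_cap * p$a * t * X_tot,
    operating        = p$c_f_op * t * X_tot,
    transport        = sum(instance$trip_costs * solution$T)
  )
  out$total <- out$fixed_capital + out$variable_capital +
    out$operating + out$transport
  out
}
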