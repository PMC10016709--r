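#' Parametric post-deployment survival curve
#'
#' Defines the proportion of cultivated units that survive one year after
#' deployment as a function of the time `t` (years) they were grown in a
#' facility. Four functional forms are supported; all are passed through a
#' common truncation that clamps raw values into `[0, pmax]`, followed by an
#' optional survival floor `pmin`.
#'
#' The forms are, with scaling factor `c` and horizontal shift `t0`:
#' \describe{
#'   \item{asymptotic}{`pmax - 1 / (c (t - t0) + 1/pmax)` — concave,
#'     increasing, x-intercept at `t0`, asymptote `pmax`. Base case.}
#'   \item{linear}{`c (t - t0)` — straight line with gradient `c`,
#'     x-intercept `t0`, capped at `pmax` by the truncation.}
#'   \item{logistic}{`pmax / (1 + exp(-c (t - t0)))` — sigmoid with
#'     inflection at `t0` where it equals `pmax/2`.}
#'   \item{pseudo_gamma}{`c (t - t0) exp(-c (t - t0))` — rises to a peak of
#'     `exp(-1)` at `t0 + 1/c` then decays, representing units that become
#'     reliant on facility conditions when held too long.}
#' }
#'
#' @param form one of `"asymptotic"`, `"linear"`, `"logistic"`,
#'   `"pseudo_gamma"`.
#' @param c scaling factor (gradient-like, form-specific units); must be > 0.
#' @param t0 horizontal shift (years).
#' @param pmax maximum proportional survival, in (0, 1].
#' @param pmin survival floor applied after truncation (default 0, a no-op).
#' @param pmin_allow allowable-minimum cutoff: growth times whose survival is
#'   at or below this value are excluded from optimization, avoiding the
#'   astronomically large production quantities implied by near-zero
#'   survival. Default `1e-4`.
#'
#' @return an object of class `survival_spec`.
#' @seealso [evaluate_survival()], [survival_grid()], [required_production()]
#' @export
#' @examples
#' sp <- survival_spec("asymptotic", c = 25, t0 = 0, pmax = 0.1)
#' evaluate_survival(sp, 0.10) # 0.02
survival_spec <- function(form = c("asymptotic", "linear", "logistic", "pseudo_gamma"),
                          c = 25, t0 = 0, pmax = 0.1, pmin = 0,
                          pmin_allow = 1e-4) {
  if (length(form) != 1L && !identical(form, eval(formals(survival_spec)$form))) {
    stop("'form' must be a single string", call. = FALSE)
  }
  form <- match.arg(form)
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(pmax), length(pmax) == 1L, is.finite(pmax),
            is.numeric(pmin), length(pmin) == 1L, is.finite(pmin),
            is.numeric(pmin_allow), length(pmin_allow) == 1L)
  if (c <= 0) stop("scaling factor 'c' must be > 0", call. = FALSE)
  if (!(pmax > 0 && pmax <= 1)) stop("'pmax' must lie in (0, 1]", call. = FALSE)
  if (!(pmin >= 0 && pmin < pmax)) stop("need 0 <= pmin < pmax", call. = FALSE)
  if (pmin_allow < 0) stop("'pmin_allow' must be >= 0", call. = FALSE)
  structure(list(form = form, c = c, t0 = t0, pmax = pmax, pmin = pmin,
                 pmin_allow = pmin_allow),
            class = "survival_spec")
}

#' @export
print.survival_spec <- function(x, ...) {
  cat(sprintf("Survival curve: %s  (c = %g, t0 = %g, pmax = %g, pmin = %g, pmin_allow = %g)\n",
              x$form, x$c, x$t0, x$pmax, x$pmin, x$pmin_allow))
  invisible(x)
}

#' Evaluate a survival curve at given growth times
#'
#' Applies the raw functional form of a [survival_spec()] and the common
#' truncation (raw values at or below 0 map to 0, values above `pmax` map to
#' `pmax`), then the `pmin` floor. Vectorized over `t`.
#'
#' @param spec a [survival_spec()].
#' @param t growth time(s) in years, finite and >= 0.
#' @return survival fraction(s) in `[0, pmax]` (or `[pmin, pmax]` if a floor
#'   is configured).
#' @export
#' @examples
#' sp <- survival_spec("asymptotic", c = 25, t0 = 0, pmax = 0.1)
#' evaluate_survival(sp, c(0, 0.02, 0.10, 10))
evaluate_survival <- function(spec, t) {
  stopifnot(inherits(spec, "survival_spec"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("growth time 't' must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("growth time 't' must be >= 0", call. = FALSE)
  z <- spec$c * (t - spec$t0)
  raw <- switch(spec$form,
    asymptotic   = spec$pmax - 1 / (z + 1 / spec$pmax),
    linear       = z,
    logistic     = spec$pmax / (1 + exp(-z)),
    pseudo_gamma = z * exp(-z)
  )
  # asymptotic form has a pole at z = -1/pmax; values left of the pole are
  # far below the x-intercept and truncate to zero like the rest
  if (spec$form == "asymptotic") raw[z <= -1 / spec$pmax] <- -Inf
  p <- ifelse(raw <= 0, 0, pmin(raw, spec$pmax))
  pmax(p, spec$pmin)
}

#' Growth-time grid with exclusion flags
#'
#' Enumerates the arithmetic grid `t_min, t_min + dt, ...` up to `t_max`
#' (the endpoint is included when it lands on the grid within a 1e-12
#' tolerance), evaluates survival at each point, and flags points whose
#' survival is at or below `pmin_allow` as excluded. Excluded points are
#' reported, not dropped, so callers can see which growth times the
#' optimizer will skip.
#'
#' @param spec a [survival_spec()].
#' @param t_min,t_max grid bounds in years, `t_min <= t_max`.
#' @param dt grid step in years, > 0.
#' @return a data.frame with columns `t`, `survival`, `included`.
#' @export
survival_grid <- function(spec, t_min = 0.02, t_max = 1.0, dt = 0.02) {
  stopifnot(inherits(spec, "survival_spec"))
  if (!(is.numeric(t_min) && is.numeric(t_max) && is.numeric(dt))) {
    stop("grid bounds must be numeric", call. = FALSE)
  }
  if (t_min > t_max) stop("need t_min <= t_max", call. = FALSE)
  if (dt <= 0) stop("grid step 'dt' must be > 0", call. = FALSE)
  k_max <- floor((t_max - t_min) / dt + 1e-12)
  t <- t_min + dt * seq.int(0L, k_max)
  if (length(t) == 0L) stop("empty growth-time grid", call. = FALSE)
  s <- evaluate_survival(spec, t)
  data.frame(t = t, survival = s, included = s > spec$pmin_allow)
}

#' Annual production required to meet a surviving-unit demand
#'
#' With proportional survival `P`, producing `X` units yields `P * X`
#' survivors, so meeting a demand `D` of surviving units requires
#' `X = D / P` produced units.
#'
#' @param total_demand surviving units required per year, >= 0.
#' @param survival survival fraction, must be > 0.
#' @return produced units per year.
#' @export
#' @examples
#' required_production(7.124e6, 0.02) # 356.2e6
required_production <- function(total_demand, survival) {
  stopifnot(is.numeric(total_demand), is.numeric(survival))
  if (any(total_demand < 0)) stop("'total_demand' must be >= 0", call. = FALSE)
  if (any(!is.finite(survival)) || any(survival <= 0)) {
    stop("production is undefined for survival <= 0; exclude such growth times",
         call. = FALSE)
  }
  total_demand / survival
}
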