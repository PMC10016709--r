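# Narrow mixed-integer linear programming interface.
#
# A model is a plain list: objective vector `obj`, integrality flags `integer`
# (logical per variable), variable bounds `lb`/`ub`, and linear constraints in
# sparse triplet form (`ai`, `aj`, `ax`) with row bounds `clb`/`cub`. Any MILP
# backend able to consume that structure can be plugged in; the default
# backend is the HiGHS solver, reached through scipy's `milp` interface in a
# python subprocess. Models are solved in batches so one subprocess serves a
# whole growth-time grid.

milp_model <- function(obj, integer, lb, ub, ai, aj, ax, clb, cub,
                       ncon = max(c(ai, 0L)), vars = NULL) {
  n <- length(obj)
  stopifnot(length(integer) == n, length(lb) == n, length(ub) == n,
            length(ai) == length(aj), length(aj) == length(ax),
            length(clb) == ncon, length(cub) == ncon)
  structure(list(obj = obj, integer = integer, lb = lb, ub = ub,
                 ai = ai, aj = aj, ax = ax, ncon = ncon,
                 clb = clb, cub = cub, vars = vars),
            class = "milp_model")
}

# Locate the python interpreter used by the HiGHS backend.
milp_python <- function() {
  py <- getOption("reefplan.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the MILP backend",
                        call. = FALSE)
  py
}

milp_bridge_script <- function() {
  path <- system.file("python", "milp_highs.py", package = "reefplan")
  if (!nzchar(path)) stop("bundled MILP bridge script not found", call. = FALSE)
  path
}

BIG_BOUND <- 1e30 # sentinel for +/- infinity across the JSON bridge

# Solve a list of milp_model objects in one backend invocation.
# Returns a list of lists: status ("optimal"/"infeasible"/"limit"),
# objective, x.
milp_solve_batch <- function(models, mip_gap = 0, time_limit = NULL) {
  stopifnot(is.list(models), all(vapply(models, inherits, logical(1), "milp_model")))
  if (length(models) == 0L) return(list())
  payload <- list(
    mip_gap = mip_gap,
    time_limit = if (is.null(time_limit)) -1 else time_limit,
    models = lapply(models, function(m) {
      list(n = length(m$obj), ncon = m$ncon,
           obj = as.numeric(m$obj),
           integer = as.integer(m$integer),
           lb = pmax(as.numeric(m$lb), -BIG_BOUND),
           ub = pmin(as.numeric(m$ub), BIG_BOUND),
           ai = as.integer(m$ai - 1L), # 0-based for python
           aj = as.integer(m$aj - 1L),
           ax = as.numeric(m$ax),
           clb = pmax(as.numeric(m$clb), -BIG_BOUND),
           cub = pmin(as.numeric(m$cub), BIG_BOUND))
    })
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  res <- suppressWarnings(
    system2(milp_python(), shQuote(c(milp_bridge_script(), fin, fout)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(res, "status")
  if (!file.exists(fout) || (!is.null(status) && status != 0L)) {
    stop("MILP backend failed:\n", paste(res, collapse = "\n"), call. = FALSE)
  }
  out <- jsonlite::read_json(fout, simplifyVector = TRUE)
  lapply(seq_len(length(models)), function(k) {
    r <- if (is.data.frame(out$solutions)) {
      as.list(out$solutions[k, ])
    } else out$solutions[[k]]
    x <- unlist(r$x)
    list(status = as.character(r$status),
         objective = as.numeric(r$objective),
         x = if (length(x)) as.numeric(x) else numeric(0))
  })
}
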