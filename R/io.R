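#' Read reef records from CSV
#'
#' Reads a comma-separated file (header row, UTF-8, "." decimal) of reef
#' records and validates every row. Column names are remappable through
#' `column_map` for files using different headers.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the canonical names
#'   `id`, `lat`, `lon`, `area_km2` to the file's column names.
#' @return a validated reef data.frame with canonical columns.
#' @export
read_reefs_csv <- function(path,
                           column_map = c(id = "id", lat = "lat", lon = "lon",
                                          area_km2 = "area_km2")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  need <- c("id", "lat", "lon", "area_km2")
  stopifnot(all(need %in% names(column_map)))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(id = as.character(raw[[column_map[["id"]]]]),
                    lat = suppressWarnings(as.numeric(raw[[column_map[["lat"]]]])),
                    lon = suppressWarnings(as.numeric(raw[[column_map[["lon"]]]])),
                    area_km2 = suppressWarnings(as.numeric(raw[[column_map[["area_km2"]]]])),
                    stringsAsFactors = FALSE)
  bad_num <- which(!is.finite(out$lat) | !is.finite(out$lon) |
                     !is.finite(out$area_km2))
  if (length(bad_num)) {
    stop("non-numeric field(s) at row(s) ",
         paste(utils::head(bad_num, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  bad_coord <- which(abs(out$lat) > 90 | abs(out$lon) > 180)
  if (length(bad_coord)) {
    stop("coordinates out of range at row(s) ",
         paste(utils::head(bad_coord, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  bad_area <- which(out$area_km2 <= 0)
  if (length(bad_area)) {
    stop("non-positive area at row(s) ",
         paste(utils::head(bad_area, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  out
}

#' Write reef records to CSV
#'
#' @param reefs reef data.frame (`id`, `lat`, `lon`, `area_km2`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reefs_csv <- function(reefs, path) {
  stopifnot(all(c("id", "lat", "lon", "area_km2") %in% names(reefs)))
  utils::write.csv(reefs[, c("id", "lat", "lon", "area_km2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write configuration files
#'
#' Plain YAML configuration covering the tool's parameter blocks:
#' `cost`, `survival`, `demand`, `solver` and optionally `seed` and
#' `ports`. Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return for `read_config`, a list with elements `cost` ([cost_params()]),
#'   `survival` ([survival_spec()]), `demand` ([demand_params()]),
#'   `solver` ([solver_config()]), `ports` (data.frame) and `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  list(
    cost = do.call(cost_params, as.list(y$cost %||% list())),
    survival = do.call(survival_spec, as.list(y$survival %||% list())),
    demand = do.call(demand_params, as.list(y$demand %||% list())),
    solver = do.call(solver_config, as.list(y$solver %||% list())),
    ports = if (is.null(y$ports)) default_ports() else
      do.call(rbind, lapply(y$ports, as.data.frame)),
    seed = y$seed %||% 1L
  )
}

#' @rdname read_config
#' @param config a list as returned by [read_config()] (classed components
#'   are serialized as plain key-value blocks).
#' @export
write_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  y <- list(cost = strip(config$cost), survival = strip(config$survival),
            demand = strip(config$demand), solver = strip(config$solver),
            seed = config$seed)
  if (!is.null(config$ports)) {
    y$ports <- lapply(seq_len(nrow(config$ports)),
                      function(i) as.list(config$ports[i, ]))
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a solve result to disk
#'
#' Emits three machine-readable views of a [two_stage_solve()] result:
#' a JSON summary (`<stem>.json`: growth time, objective, breakdown, open
#' facilities, per-grid-point trace), an assignment CSV
#' (`<stem>_assignment.csv`: one row per positive cluster-facility flow
#' with production and trips), and a GeoJSON file (`<stem>.geojson`,
#' RFC 7946 lon-lat Point features for cluster centroids and facilities,
#' demand and production as properties).
#'
#' @param result a `reefplan_solution`.
#' @param stem output path stem (directory must exist).
#' @return the three file paths, invisibly.
#' @export
write_solution <- function(result, stem) {
  stopifnot(inherits(result, "reefplan_solution"))
  inst <- result$instance
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, "_assignment.csv")
  geo_path <- paste0(stem, ".geojson")

  jsonlite::write_json(list(
    t_star = result$t_star,
    objective = result$objective,
    survival_at_t_star = result$solution$survival,
    production_total = result$production_total,
    open_facilities = as.character(result$open_facilities),
    breakdown = result$breakdown,
    trace = result$trace
  ), json_path, auto_unbox = TRUE, digits = NA, na = "null")

  pos <- which(result$solution$X > 0 | result$solution$T > 0, arr.ind = TRUE)
  assign_df <- data.frame(
    cluster = inst$clusters$id[pos[, 1]],
    facility = inst$facilities$id[pos[, 2]],
    production = result$solution$X[pos],
    trips = result$solution$T[pos],
    trip_cost = inst$trip_costs[pos]
  )
  assign_df <- assign_df[order(assign_df$cluster, assign_df$facility), ]
  utils::write.csv(assign_df, csv_path, row.names = FALSE, quote = FALSE)

  feat <- c(
    lapply(seq_len(nrow(inst$clusters)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(inst$clusters$centroid_lon[i],
                                           inst$clusters$centroid_lat[i])),
           properties = list(kind = "cluster", id = inst$clusters$id[i],
                             annual_demand = inst$clusters$annual_demand[i]))
    }),
    lapply(seq_len(nrow(inst$facilities)), function(j) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(inst$facilities$lon[j],
                                           inst$facilities$lat[j])),
           properties = list(kind = "facility", id = inst$facilities$id[j],
                             open = unbox_lgl(result$solution$Y[j] > 0.5),
                             production = sum(result$solution$X[, j])))
    })
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       geo_path, auto_unbox = TRUE, digits = NA)
  invisible(c(json = json_path, assignment = csv_path, geojson = geo_path))
}

unbox_lgl <- function(x) as.logical(x)
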