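#' @export
print.reefplan_solution <- function(x, ...) {
  cat("Two-stage facility plan\n")
  cat(sprintf("  optimal growth time t* : %.2f years\n", x$t_star))
  cat(sprintf("  annual cost z*         : $%.3f million\n", x$objective / 1e6))
  cat(sprintf("  open facilities        : %s\n",
              paste(x$open_facilities, collapse = ", ")))
  cat(sprintf("  annual production      : %.4g units (survival %.3g)\n",
              x$production_total, x$solution$survival))
  invisible(x)
}

#' @export
summary.reefplan_solution <- function(object, ...) {
  structure(list(result = object), class = "summary.reefplan_solution")
}

#' @export
print.summary.reefplan_solution <- function(x, ...) {
  r <- x$result
  print(r)
  bd <- r$breakdown
  cat("\nAnnualized cost breakdown ($ million, share of total):\n")
  for (nm in c("operating", "transport", "variable_capital", "fixed_capital")) {
    cat(sprintf("  %-17s %10.3f  (%4.1f%%)\n", nm, bd[[nm]] / 1e6,
                100 * bd[[nm]] / bd$total))
  }
  cat(sprintf("  %-17s %10.3f\n", "total", bd$total / 1e6))
  inc <- r$trace[r$trace$included, ]
  cat(sprintf("\nGrowth-time grid: %d points, %d included, %d solved\n",
              nrow(r$trace), nrow(inc), sum(!is.na(inc$objective))))
  open_j <- which(r$solution$Y > 0.5)
  if (length(open_j)) {
    prod_j <- colSums(r$solution$X)[open_j]
    cat("\nPer-facility annual production (units):\n")
    for (k in seq_along(open_j)) {
      cat(sprintf("  %-14s %.4g\n",
                  r$instance$facilities$id[open_j[k]], prod_j[k]))
    }
  }
  invisible(x)
}

#' Plot a two-stage solution
#'
#' `type = "trace"` draws the inner-MIP objective across the growth-time
#' grid with the incumbent marked; `type = "map"` draws cluster centroids
#' (scaled by demand) and candidate facilities, with open facilities filled
#' and assignments drawn as segments.
#'
#' @param x a `reefplan_solution`.
#' @param type `"trace"` or `"map"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.reefplan_solution <- function(x, type = c("trace", "map"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- x$trace[x$trace$included & !is.na(x$trace$objective), ]
    plot(tr$t, tr$objective / 1e6, type = "b", pch = 16,
         xlab = "growth time (years)", ylab = "annual cost ($ million)", ...)
    graphics::abline(v = x$t_star, lty = 2)
    graphics::points(x$t_star, x$objective / 1e6, col = 2, pch = 19, cex = 1.4)
  } else {
    cl <- x$instance$clusters
    fa <- x$instance$facilities
    plot(cl$centroid_lon, cl$centroid_lat, pch = 1,
         cex = 0.5 + 2 * sqrt(cl$annual_demand / max(cl$annual_demand, 1)),
         xlab = "longitude", ylab = "latitude",
         xlim = range(c(cl$centroid_lon, fa$lon)),
         ylim = range(c(cl$centroid_lat, fa$lat)), ...)
    assigned <- which(x$solution$X > 0, arr.ind = TRUE)
    graphics::segments(cl$centroid_lon[assigned[, 1]], cl$centroid_lat[assigned[, 1]],
                       fa$lon[assigned[, 2]], fa$lat[assigned[, 2]], col = "grey60")
    open <- x$solution$Y > 0.5
    graphics::points(fa$lon, fa$lat, pch = ifelse(open, 17, 2),
                     col = ifelse(open, 2, 1), cex = 1.3)
    graphics::text(fa$lon, fa$lat, fa$id, pos = 4, cex = 0.7)
  }
  invisible(x)
}
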