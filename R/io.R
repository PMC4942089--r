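#' Load a scenario configuration from a YAML file
#'
#' The file holds overrides of the named scenario's defaults (the scenario
#' name itself under `scenario:`). Unknown keys are rejected so typos never
#' pass silently; invariant violations name the offending key.
#'
#' @param path Path to a YAML (or empty) file.
#' @return An `ms_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  scen <- ov$scenario %||% "two_cell"
  ov$scenario <- NULL
  if (!is.null(ov$cells)) {
    ov$cells <- lapply(ov$cells, function(cs) do.call(cell_spec, cs))
  }
  build_scenario(scen, ov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a simulation result
#'
#' Persists the sampled series as CSV files and the scalar outcome plus
#' configuration as JSON in a directory, so that a result round-trips
#' losslessly and remains diffable.
#'
#' @param result An `ms_result`.
#' @param path Directory to write (created if missing).
#' @export
save_result <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$samples, file.path(path, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pair_dist, file.path(path, "pair_dist.csv"),
                   row.names = FALSE)
  meta <- list(success = result$success, mating_time = result$mating_time,
               partner = result$partner, seed = result$seed,
               scenario = result$scenario, events = as.list(result$events),
               version = matesim_version())
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg <- result$config
  cfg$cells <- lapply(cfg$cells, unclass)
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (fc in result$final_curves) {
    utils::write.csv(
      data.frame(x = fc$points[, 1], y = fc$points[, 2], u2 = fc$u2),
      file.path(path, paste0("curve_", fc$id, ".csv")), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  cur_ver <- matesim_version()
  if (!identical(meta$version, cur_ver))
    warning("result written by matesim ", meta$version, ", loading with ", cur_ver)
  samples <- utils::read.csv(file.path(path, "samples.csv"))
  pair_dist <- utils::read.csv(file.path(path, "pair_dist.csv"))
  curves <- list()
  for (f in list.files(path, pattern = "^curve_.*\\.csv$", full.names = TRUE)) {
    id <- sub("^curve_(.*)\\.csv$", "\\1", basename(f))
    d <- utils::read.csv(f)
    curves[[id]] <- list(id = id, points = cbind(d$x, d$y), u2 = d$u2)
  }
  structure(list(success = meta$success, mating_time = meta$mating_time,
                 partner = meta$partner, seed = meta$seed,
                 scenario = meta$scenario, samples = samples,
                 pair_dist = pair_dist, final_curves = curves,
                 events = unlist(meta$events)),
            class = "ms_result")
}

#' Manifest for reproducing a run
#'
#' A config digest plus seed suffices to reproduce a run bit-identically
#' (the simulator consumes randomness from the single seeded stream only).
#'
#' @param config An `ms_config`.
#' @param seed Seed used.
#' @export
run_manifest <- function(config, seed) {
  cfg <- config
  cfg$cells <- lapply(cfg$cells, unclass)
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(js, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(config_md5 = hash, seed = seed,
       version = matesim_version())
}

matesim_version <- function() {
  tryCatch(as.character(utils::packageVersion("matesim")),
           error = function(e) "dev")
}

#' Render a snapshot of a simulation result
#'
#' `what = "u2_polarization"` draws every membrane coloured by its final u2
#' with a dot at the polarisome (the standard polarisation plot);
#' `what = "cross_section"` exports the concentration profile along a line
#' between two points as a data frame (and CSV if `csv` given), for
#' quantitative gradient comparisons.
#'
#' @param result An `ms_result`.
#' @param what "u2_polarization" or "cross_section".
#' @param field For cross sections: matrix of field values on the grid.
#' @param grid The [ms_grid()] matching `field`.
#' @param from,to Endpoints of the cross-section line (um).
#' @param csv Optional CSV output path for the cross section.
#' @param file Optional PNG path for the polarisation plot.
#' @export
render_snapshot <- function(result, what = c("u2_polarization", "cross_section"),
                            field = NULL, grid = NULL, from = NULL, to = NULL,
                            csv = NULL, file = NULL) {
  what <- match.arg(what)
  if (what == "cross_section") {
    stopifnot(!is.null(field), !is.null(grid), !is.null(from), !is.null(to))
    n <- ceiling(sqrt(sum((to - from)^2)) / grid$h) + 1L
    tt <- seq(0, 1, length.out = n)
    pts <- cbind(from[1] + tt * (to[1] - from[1]),
                 from[2] + tt * (to[2] - from[2]))
    vals <- bilinear_at(grid, field, pts)
    out <- data.frame(s = tt * sqrt(sum((to - from)^2)),
                      x = pts[, 1], y = pts[, 2], concentration = vals)
    if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
    return(invisible(out))
  }
  if (!is.null(file)) grDevices::png(file, width = 900, height = 600)
  cfg <- result$config
  plot(NA, xlim = cfg$grid_bounds[1:2], ylim = cfg$grid_bounds[3:4],
       asp = 1, xlab = "x (um)", ylab = "y (um)",
       main = sprintf("%s seed %s: %s", result$scenario, result$seed,
                      if (result$success) "mated" else "no mating"))
  pal <- grDevices::hcl.colors(64, "viridis")
  for (fc in result$final_curves) {
    u2 <- fc$u2
    cl <- pal[pmin(63L, floor(63 * u2 / max(u2, 1e-12))) + 1L]
    graphics::points(fc$points[, 1], fc$points[, 2], col = cl, pch = 16, cex = 0.4)
    if (!is.null(fc$pol) && isTRUE(fc$pol$found))
      graphics::points(fc$pol$position[1], fc$pol$position[2],
                       pch = 21, bg = "black", cex = 1.2)
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(result)
}
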