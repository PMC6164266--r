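# Delimited-text readers and writers.  All tables are comma-delimited
# UTF-8 with a header row; missing values are empty fields.

#' Read a monitor panel
#'
#' Expects columns \code{site_id, lon, lat, day, pm25} (or planar
#' \code{x_km, y_km} instead of lon/lat, in which case no projection is
#' applied).
#'
#' @param path CSV file.
#' @param ref_lat Reference latitude for the equirectangular projection
#'   (default: mean monitor latitude).
#' @return Data frame with planar kilometre coordinates.
#' @export
read_monitors <- function(path, ref_lat = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "day", "pm25")
  if (!all(need %in% names(d))) {
    stop("read_monitors: need columns ", paste(need, collapse = ", "))
  }
  project_table(d, ref_lat, "read_monitors")
}

#' Read a grid panel
#'
#' Expects columns \code{cell_id, lon, lat, day, aod} (or \code{x_km,
#' y_km}) plus covariate columns; empty AOD fields become \code{NA}.
#'
#' @inheritParams read_monitors
#' @export
read_grid <- function(path, ref_lat = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "day", "aod")
  if (!all(need %in% names(d))) {
    stop("read_grid: need columns ", paste(need, collapse = ", "))
  }
  project_table(d, ref_lat, "read_grid")
}

project_table <- function(d, ref_lat, who) {
  if (all(c("x_km", "y_km") %in% names(d))) return(d)
  if (!all(c("lon", "lat") %in% names(d))) {
    stop(who, ": need either x_km/y_km or lon/lat columns")
  }
  if (is.null(ref_lat)) ref_lat <- mean(d$lat)
  xy <- project_lonlat(d$lon, d$lat, ref_lat)
  d$x_km <- xy[, "x_km"]
  d$y_km <- xy[, "y_km"]
  d
}

#' Read a region definition file
#'
#' Either a polygon table (\code{region_id, vertex_order, x_km, y_km} or
#' lon/lat) or a site-label table (\code{site_id, region_id}).
#'
#' @param path CSV file.
#' @param buffer_km Buffer width for the resulting \code{\link{region_set}}.
#' @param ref_lat Projection reference latitude for lon/lat polygons.
#' @export
read_regions <- function(path, buffer_km = 100, ref_lat = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("vertex_order" %in% names(d)) {
    d <- project_table(d, ref_lat, "read_regions")
    region_set(polygons = d, buffer_km = buffer_km)
  } else if (all(c("site_id", "region_id") %in% names(d))) {
    region_set(labels = stats::setNames(d$region_id, d$site_id),
               buffer_km = buffer_km)
  } else {
    stop("read_regions: unrecognised region file layout")
  }
}

#' Write a prediction cube or aggregate table to CSV
#'
#' @param x A \code{prediction_cube} or the data frame returned by
#'   \code{\link{aggregate_time}}.
#' @param path Output CSV path.
#' @export
write_predictions <- function(x, path) {
  tab <- if (inherits(x, "prediction_cube")) x$table else x
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cross-validation report (pooled + per-fold + assignments)
#'
#' @param report A \code{cv_report}.
#' @param dir Output directory; writes \code{cv_<scheme>_metrics.csv} and
#'   \code{cv_<scheme>_predictions.csv}.
#' @export
write_cv_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  metrics <- rbind(cbind(fold = 0, report$pooled), report$per_fold)
  utils::write.csv(metrics,
                   file.path(dir, paste0("cv_", report$scheme,
                                         "_metrics.csv")),
                   row.names = FALSE, na = "")
  utils::write.csv(report$predictions,
                   file.path(dir, paste0("cv_", report$scheme,
                                         "_predictions.csv")),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' Minimal schema: \code{paths} (monitors, grid, regions, output_dir),
#' \code{covariates} (names, optional log_set, interaction flag),
#' \code{cell_km}, \code{blocks} (list of \code{first}/\code{last} day),
#' \code{chain} (n_iter, n_burn, thin), \code{seed}, \code{cv}
#' (k, schemes).  Missing entries fall back to defaults.
#'
#' @param path YAML file.
#' @return Named list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$cell_km)) cfg$cell_km <- 12
  structure(cfg, class = "run_config")
}

config_cov_spec <- function(cfg) {
  cv <- cfg$covariates
  if (is.null(cv$names)) stop("config: covariates$names is required")
  covariate_spec(
    names = unlist(cv$names),
    log_set = if (is.null(cv$log_set)) {
      intersect(c("fire", "emission", "road"), unlist(cv$names))
    } else unlist(cv$log_set),
    interaction_aod_temp = isTRUE(cv$interaction_aod_temp))
}

config_chain <- function(cfg, seed_offset = 0L) {
  ch <- cfg$chain
  chain_control(
    n_iter = if (is.null(ch$n_iter)) 5000 else ch$n_iter,
    n_burn = if (is.null(ch$n_burn)) 2500 else ch$n_burn,
    thin = if (is.null(ch$thin)) 5 else ch$thin,
    seed = cfg$seed + seed_offset,
    verbose = isTRUE(cfg$verbose))
}

config_blocks <- function(cfg, days) {
  if (is.null(cfg$blocks)) return(list(all = days))
  out <- lapply(cfg$blocks, function(b) seq(b$first, b$last))
  names(out) <- vapply(seq_along(out), function(i) {
    if (!is.null(cfg$blocks[[i]]$name)) cfg$blocks[[i]]$name
    else paste0("block", i)
  }, character(1))
  out
}

log_line <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Pipeline commands (simulate / fit / predict / cv)
#'
#' Thin orchestration over the package functions, driven by a YAML run
#' configuration; these are what the command-line wrapper calls.
#' \code{cmd_simulate} writes synthetic monitor/grid/region files plus a
#' truth manifest; \code{cmd_fit} fits one model per region and temporal
#' block and saves each chain with a key-value manifest; \code{cmd_predict}
#' predicts all regional surfaces, blends them, and writes daily and
#' period-aggregate tables; \code{cmd_cv} runs the configured
#' cross-validation schemes and writes their reports.
#'
#' @param config_path Path to a YAML run configuration.
#' @return Invisibly, the paths written.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config_path) {
  cfg <- read_run_config(config_path)
  out <- cfg$paths$output_dir
  if (is.null(out)) stop("config: paths$output_dir is required")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  sc_args <- cfg$simulate
  sc_args$seed <- cfg$seed
  sc <- do.call(sim_config, sc_args[names(sc_args) %in%
                                      names(formals(sim_config))])
  sim <- simulate_dataset(sc)
  paths <- file.path(out, c("monitors.csv", "grid.csv", "regions.csv",
                            "truth.csv"))
  utils::write.csv(sim$monitors, paths[1], row.names = FALSE, na = "")
  utils::write.csv(sim$grid, paths[2], row.names = FALSE, na = "")
  utils::write.csv(sim$regions$polygons, paths[3], row.names = FALSE)
  truth <- data.frame(
    parameter = c("mu0", "mu_aod", sc$covariates, "c1", "c2", "c3",
                  "sigma2", "tau0", "tau1", "phi_km"),
    value = c(sc$gamma, sc$c_coef, sc$sigma2, sc$tau0, sc$tau1, sc$phi_km))
  utils::write.csv(truth, paths[4], row.names = FALSE)
  log_line("cmd_simulate: wrote ", length(paths), " files to ", out)
  invisible(paths)
}

#' @rdname pipeline-commands
#' @export
cmd_fit <- function(config_path) {
  cfg <- read_run_config(config_path)
  out <- cfg$paths$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  monitors <- read_monitors(cfg$paths$monitors)
  grid <- read_grid(cfg$paths$grid)
  regions <- read_regions(cfg$paths$regions,
                          buffer_km = if (is.null(cfg$buffer_km)) 100
                                      else cfg$buffer_km)
  spec <- config_cov_spec(cfg)
  blocks <- config_blocks(cfg, sort(unique(monitors$day)))
  sites <- unique(monitors[c("site_id", "x_km", "y_km")])
  memb <- assign_regions(sites, regions)
  written <- character(0)
  i <- 0L
  for (r in regions$region_ids) {
    in_r <- vapply(memb$buffered, function(b) r %in% b, logical(1))
    keep_sites <- memb$site_id[in_r]
    for (b in names(blocks)) {
      i <- i + 1L
      mon_rb <- monitors[monitors$site_id %in% keep_sites &
                           monitors$day %in% blocks[[b]], , drop = FALSE]
      log_line("cmd_fit: region ", r, " block ", b, " (",
               nrow(mon_rb), " monitor records)")
      fit <- tryCatch(
        downscale(mon_rb, grid[grid$day %in% blocks[[b]], , drop = FALSE],
                  spec, cell_km = cfg$cell_km,
                  control = config_chain(cfg, i), days = blocks[[b]]),
        error = function(e) {
          stop("cmd_fit failed for region ", r, " block ", b, ": ",
               conditionMessage(e))
        })
      base <- file.path(out, paste0("chain_", r, "_", b))
      saveRDS(fit, paste0(base, ".rds"))
      ctl <- fit$samples$control
      writeLines(c(paste0("region=", r), paste0("block=", b),
                   paste0("seed=", ctl$seed),
                   paste0("n_iter=", ctl$n_iter),
                   paste0("n_burn=", ctl$n_burn),
                   paste0("thin=", ctl$thin),
                   paste0("n_states=", length(fit$samples$states)),
                   paste0("acceptance_gibbs=1")),
                 paste0(base, "_manifest.txt"))
      written <- c(written, paste0(base, ".rds"))
    }
  }
  invisible(written)
}

#' @rdname pipeline-commands
#' @export
cmd_predict <- function(config_path) {
  cfg <- read_run_config(config_path)
  out <- cfg$paths$output_dir
  grid <- read_grid(cfg$paths$grid)
  regions <- read_regions(cfg$paths$regions,
                          buffer_km = if (is.null(cfg$buffer_km)) 100
                                      else cfg$buffer_km)
  blocks <- config_blocks(cfg, sort(unique(grid$day)))
  cells <- unique(grid[c("cell_id", "x_km", "y_km")])
  names(cells)[1] <- "site_id"      # assign_regions works on generic points
  cell_memb <- assign_regions(cells, regions)
  written <- character(0)
  daily_all <- list()
  for (b in names(blocks)) {
    cubes <- list()
    for (r in regions$region_ids) {
      path <- file.path(out, paste0("chain_", r, "_", b, ".rds"))
      if (!file.exists(path)) stop("cmd_predict: missing chain ", path)
      fit <- readRDS(path)
      core <- cell_memb$site_id[cell_memb$core == r |
                                  vapply(cell_memb$buffered,
                                         function(x) r %in% x, logical(1))]
      g <- grid[grid$cell_id %in% core & grid$day %in% blocks[[b]], ,
                drop = FALSE]
      if (!is.null(cfg$prediction_seed)) {
        set.seed(cfg$prediction_seed + match(r, regions$region_ids))
      }
      cubes[[r]] <- predict_cells(fit, g)
    }
    blended <- blend_regions(cubes)
    p <- file.path(out, paste0("predictions_daily_", b, ".csv"))
    write_predictions(blended, p)
    written <- c(written, p)
    agg <- aggregate_time(blended, label = b)
    p2 <- file.path(out, paste0("predictions_", b, "_mean.csv"))
    write_predictions(agg, p2)
    written <- c(written, p2)
    daily_all[[b]] <- blended
  }
  log_line("cmd_predict: wrote ", length(written), " tables")
  invisible(written)
}

#' @rdname pipeline-commands
#' @export
cmd_cv <- function(config_path) {
  cfg <- read_run_config(config_path)
  out <- cfg$paths$output_dir
  monitors <- read_monitors(cfg$paths$monitors)
  grid <- read_grid(cfg$paths$grid)
  spec <- config_cov_spec(cfg)
  k <- if (is.null(cfg$cv$k)) 10 else cfg$cv$k
  schemes <- if (is.null(cfg$cv$schemes)) c("random", "spatial")
             else unlist(cfg$cv$schemes)
  for (s in schemes) {
    log_line("cmd_cv: scheme ", s)
    rep <- run_cv(monitors, grid, spec, cell_km = cfg$cell_km, k = k,
                  scheme = s, control = config_chain(cfg),
                  seed = cfg$seed)
    write_cv_report(rep, out)
  }
  invisible(out)
}
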