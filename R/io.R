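# File formats: receiver-database CSV exports in (reading), grids,
# reports and metrics out (writing). All timestamps are UTC; distances
# are horizontal ranges in metres; depths are positive down.

.parse_utc <- function(x) {
  formats <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
               "%m/%d/%Y %H:%M:%S", "%m/%d/%Y %H:%M", "%d/%m/%Y %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  left <- rep(TRUE, length(x))
  for (f in formats) {
    if (!any(left)) break
    p <- as.POSIXct(x[left], tz = "UTC", format = f)
    ok <- !is.na(p)
    out[which(left)[ok]] <- p[ok]
    left[left] <- !ok
  }
  out
}

#' Read a receiver-database detection CSV export
#'
#' Reads the CSV dialect exported by the VUE receiver database: one row
#' per detection with a UTC timestamp, a receiver identifier and a
#' transmitter identifier. Column naming is tolerant to the common
#' variants (`"Date and Time (UTC)"` vs `"Date/Time"`, etc.); extra
#' sensor columns are ignored. Rows whose timestamp cannot be parsed are
#' dropped with a warning giving the count.
#'
#' @param path Path to the CSV file.
#' @return Detection-log data frame with columns `timestamp` (POSIXct,
#'   UTC), `receiver`, `transmitter`, sorted by time.
#' @export
read_vue_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  nm <- names(raw)
  find <- function(patterns, label) {
    for (p in patterns) {
      hit <- grep(p, nm, ignore.case = TRUE)
      if (length(hit)) return(nm[hit[1]])
    }
    stop("mandatory column missing from ", path, ": ", label)
  }
  ts_col <- find(c("^date and time", "^date.?time", "^timestamp",
                   "^date"), "timestamp (e.g. 'Date and Time (UTC)')")
  rec_col <- find("^receiver", "Receiver")
  tx_col <- find("^transmitter", "Transmitter")
  ts <- .parse_utc(as.character(raw[[ts_col]]))
  bad <- is.na(ts)
  if (any(bad))
    warning(sum(bad), " row(s) with unparseable timestamps dropped")
  out <- data.frame(timestamp = ts[!bad],
                    receiver = as.character(raw[[rec_col]])[!bad],
                    transmitter = as.character(raw[[tx_col]])[!bad])
  if (any(!nzchar(out$receiver)) || any(!nzchar(out$transmitter)))
    stop("empty receiver or transmitter ids in ", path)
  out[order(out$timestamp), , drop = FALSE]
}

#' Write a detection log as a VUE-dialect CSV
#'
#' @param log Detection-log data frame (`timestamp`, `receiver`,
#'   `transmitter`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vue_csv <- function(log, path) {
  out <- data.frame(
    `Date and Time (UTC)` = format(log$timestamp, "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"),
    Receiver = log$receiver,
    Transmitter = log$transmitter,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a tag-distance table
#'
#' @param path CSV with columns `tag_id`, `distance_m`.
#' @return Data frame with those columns.
#' @export
read_tag_distances_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tag_id", "distance_m") %in% names(d)))
    stop("tag-distance CSV needs columns tag_id, distance_m")
  if (any(d$distance_m < 0)) stop("distances must be >= 0")
  d
}

#' Read a daily meta-log CSV
#'
#' @param path CSV with columns `date`, `detections`, `syncs`, `pings`,
#'   `checksum_rejects`.
#' @return Data frame with `date` parsed as `Date`.
#' @export
read_meta_log_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "detections", "syncs", "pings", "checksum_rejects")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("meta-log CSV missing column(s): ", paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  d
}

#' Write a CPDI grid as CSV
#'
#' Columns `range_m`, `tag_depth_m`, `cpdi` (bit-exact 0/1), `n_cat2`;
#' deterministic row order (depth then range).
#'
#' @param grid A `cpdi_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpdi_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "cpdi_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' Read a CPDI grid CSV back as a data frame
#'
#' @param path Path written by [write_cpdi_grid_csv()].
#' @return Data frame with columns `range_m`, `tag_depth_m`, `cpdi`,
#'   `n_cat2`.
#' @export
read_cpdi_grid_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("range_m", "tag_depth_m", "cpdi", "n_cat2")
  if (!all(need %in% names(d)))
    stop("not a CPDI grid CSV: ", path)
  d[, need]
}

# Provenance block attached to every JSON report.
.provenance <- function(config = NULL, seed = NULL) {
  p <- list(package = "cpditools",
            version = as.character(utils::packageVersion("cpditools")))
  if (!is.null(config)) p$config <- config
  if (!is.null(seed)) p$seed <- seed
  p
}

#' Write a CPDI extent report as JSON
#'
#' One extent per tag depth of the grid, plus a full configuration echo.
#'
#' @param grid A `cpdi_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpdi_report_json <- function(grid, path) {
  stopifnot(inherits(grid, "cpdi_grid"))
  report <- list(
    extent_m = as.list(stats::setNames(
      vapply(grid$depth_axis, function(z) cpdi_extent(grid, z),
             numeric(1)),
      paste0("tag_depth_", grid$depth_axis))),
    provenance = .provenance(config = list(
      water_depth_m = grid$env$water_depth,
      sound_speed_m_s = grid$env$sound_speed,
      blanking_interval_s = grid$spec$blanking_interval,
      amdr_m = grid$spec$amdr,
      receiver_depth_m = grid$receiver_depth,
      resolution_m = grid$enumeration$resolution,
      enumeration = grid$enumeration)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a ranging-analysis report as JSON
#'
#' @param est A [ranging_estimate()].
#' @param path Output path.
#' @param config Optional configuration list echoed into the report.
#' @return `path`, invisibly.
#' @export
write_ranging_report_json <- function(est, path, config = NULL) {
  stopifnot(inherits(est, "ranging_estimate"))
  report <- list(amdr = est$amdr, cpdi_extent = est$cpdi_extent,
                 candidate_count = est$candidate_count,
                 provenance = .provenance(config = config))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a run configuration file
#'
#' A single YAML (or JSON) file collecting the environment, receiver
#' spec, geometry, grid, enumeration and analysis options; every block is
#' validated through the same constructors the API uses, so a bad value
#' fails before any run starts.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return Named list with validated `env` ([acoustic_env()]) and `spec`
#'   ([receiver_spec()]) plus the remaining raw sections.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  }
  if (is.null(cfg$environment) || is.null(cfg$receiver))
    stop("config must contain 'environment' and 'receiver' blocks")
  env <- acoustic_env(cfg$environment$water_depth,
                      cfg$environment$sound_speed %||% 1530)
  spec <- receiver_spec(cfg$receiver$amdr,
                        cfg$receiver$blanking_interval %||% 0.260,
                        cfg$receiver$pings_per_train %||% 8L)
  c(list(env = env, spec = spec),
    cfg[setdiff(names(cfg), c("environment", "receiver"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
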