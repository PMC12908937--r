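#' Construct a force trace
#'
#' A force trace is one pull of a (mock) finger across a surface: a
#' tangential-force time series plus the rig metadata needed downstream
#' (surface identity, applied mass, driving velocity, sampling rate, and
#' set/pull indices within the acquisition protocol).
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param force Numeric vector of tangential force in newtons, same length
#'   as `time`, all finite.
#' @param surface_id Character scalar naming the surface coating.
#' @param applied_mass Mass added on top of the finger, grams.
#' @param velocity Stage driving velocity, mm/s.
#' @param deadweight Deadweight of the finger itself, grams (default 6).
#' @param displacement Total stage displacement, mm (default 4).
#' @param sampling_rate Acquisition rate in Hz (default 550).
#' @param set_index,pull_index Integer indices of the slide set and of the
#'   pull within its set. Pull 1 of each set is conventionally discarded
#'   before analysis because of contact aging during setup.
#'
#' @return An object of class `force_trace`: a list with elements `time`,
#'   `force` and `meta`.
#' @export
force_trace <- function(time, force, surface_id, applied_mass, velocity,
                        deadweight = 6, displacement = 4,
                        sampling_rate = 550, set_index = 1L,
                        pull_index = 1L) {
  meta <- list(surface_id = as.character(surface_id)[1],
               applied_mass = as.numeric(applied_mass)[1],
               deadweight = as.numeric(deadweight)[1],
               velocity = as.numeric(velocity)[1],
               displacement = as.numeric(displacement)[1],
               sampling_rate = as.numeric(sampling_rate)[1],
               set_index = as.integer(set_index)[1],
               pull_index = as.integer(pull_index)[1])
  x <- structure(list(time = as.numeric(time), force = as.numeric(force),
                      meta = meta),
                 class = "force_trace")
  validate_force_trace(x)
}

validate_force_trace <- function(x) {
  if (length(x$time) != length(x$force))
    abort("time and force must have equal length", "frinstab_validation_error")
  if (length(x$time) < 2L)
    abort("force trace needs at least 2 samples", "frinstab_validation_error")
  if (anyNA(x$time) || any(!is.finite(x$time)))
    abort("time contains non-finite values", "frinstab_validation_error")
  if (any(diff(x$time) <= 0))
    abort("time must be strictly increasing", "frinstab_validation_error")
  if (anyNA(x$force) || any(!is.finite(x$force)))
    abort("force contains non-finite values", "frinstab_validation_error")
  if (!is_scalar_number(x$meta$sampling_rate) || x$meta$sampling_rate <= 0)
    abort("sampling_rate must be a positive number", "frinstab_validation_error")
  x
}

#' @export
print.force_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<force_trace> %s  M=%g g  v=%g mm/s  set %d pull %d\n",
              m$surface_id, m$applied_mass, m$velocity,
              m$set_index, m$pull_index))
  cat(sprintf("  %d samples @ %g Hz, duration %.3f s, force range [%.3f, %.3f] N\n",
              length(x$force), m$sampling_rate,
              diff(range(x$time)), min(x$force), max(x$force)))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, ...) {
  graphics::plot(x$time, x$force, type = "l", xlab = "time (s)",
                 ylab = "tangential force (N)",
                 main = sprintf("%s  M=%g g  v=%g mm/s", x$meta$surface_id,
                                x$meta$applied_mass, x$meta$velocity), ...)
  invisible(x)
}

#' Condition grid of applied masses and driving velocities
#'
#' The mechanical protocol measures every combination of applied mass and
#' driving velocity. The default grid is 4 masses (0, 25, 75, 100 g) by
#' 4 velocities (5, 10, 25, 45 mm/s) with 9 retained pulls per condition,
#' i.e. 16 conditions and 144 pulls per surface.
#'
#' @param masses Strictly increasing vector of applied masses, grams.
#' @param velocities Strictly increasing vector of velocities, mm/s.
#' @param n_reps Retained pulls per condition.
#' @return An object of class `condition_grid`.
#' @export
condition_grid <- function(masses = c(0, 25, 75, 100),
                           velocities = c(5, 10, 25, 45), n_reps = 9L) {
  masses <- as.numeric(masses); velocities <- as.numeric(velocities)
  if (anyDuplicated(masses) || any(diff(masses) <= 0))
    abort("masses must be strictly increasing with no duplicates",
          "frinstab_validation_error")
  if (anyDuplicated(velocities) || any(diff(velocities) <= 0))
    abort("velocities must be strictly increasing with no duplicates",
          "frinstab_validation_error")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) abort("n_reps must be >= 1", "frinstab_validation_error")
  structure(list(masses = masses, velocities = velocities, n_reps = n_reps),
            class = "condition_grid")
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf("<condition_grid> %d masses x %d velocities, %d pulls/condition (%d total)\n",
              length(x$masses), length(x$velocities), x$n_reps,
              length(x$masses) * length(x$velocities) * x$n_reps))
  cat("  masses (g):     ", paste(x$masses, collapse = ", "), "\n")
  cat("  velocities (mm/s):", paste(x$velocities, collapse = ", "), "\n")
  invisible(x)
}

#' Construct an AFM height map
#'
#' @param heights Numeric matrix of heights in meters (rows are fast-scan
#'   lines).
#' @param pixel_size Pixel size in meters.
#' @param scan_size Physical scan size in meters (default 10 micrometres,
#'   the usual tapping-mode field of view here).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size, scan_size = 10e-6) {
  heights <- as.matrix(heights)
  if (!is.numeric(heights) || anyNA(heights) || any(!is.finite(heights)))
    abort("heights must be a finite numeric matrix", "frinstab_validation_error")
  if (!is_scalar_number(pixel_size) || pixel_size <= 0)
    abort("pixel_size must be a positive number", "frinstab_validation_error")
  structure(list(heights = heights, pixel_size = pixel_size,
                 scan_size = scan_size),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d pixels, pixel %.3g m, rms %.3g m\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              stats::sd(as.vector(x$heights))))
  invisible(x)
}

#' @export
plot.height_map <- function(x, ...) {
  graphics::image(x$heights, useRaster = TRUE, axes = FALSE,
                  main = "height map", ...)
  invisible(x)
}

#' Construct/validate a behavioural trial table
#'
#' One row per 3-AFC trial: the subject, the surface pair, where the odd
#' sample was placed (1-3), which position the subject chose, whether the
#' choice was correct, and the response time. `correct` is recomputed from
#' the positions; a stored flag inconsistent with the positions is an
#' error.
#'
#' @param df Data frame with columns `subject_id`, `pair_label`,
#'   `odd_position`, `chosen_position`, `correct`, `response_time`.
#' @return The validated data frame with class `behavioral_table` prepended.
#' @export
behavioral_table <- function(df) {
  need <- c("subject_id", "pair_label", "odd_position", "chosen_position",
            "correct", "response_time")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          "frinstab_format_error")
  if (nrow(df) == 0L)
    abort("behavioural table is empty", "frinstab_validation_error")
  if (!all(df$odd_position %in% 1:3) || !all(df$chosen_position %in% 1:3))
    abort("positions must be in 1..3", "frinstab_validation_error")
  recomputed <- df$chosen_position == df$odd_position
  if (any(as.logical(df$correct) != recomputed))
    abort("stored `correct` flag inconsistent with odd/chosen positions",
          "frinstab_validation_error")
  if (any(!is.finite(df$response_time)) || any(df$response_time <= 0))
    abort("response_time must be positive and finite",
          "frinstab_validation_error")
  df$correct <- recomputed
  class(df) <- unique(c("behavioral_table", class(df)))
  df
}

## ---- force trace files ---------------------------------------------------

TRACE_META_FIELDS <- c("surface_id", "applied_mass", "deadweight", "velocity",
                       "displacement", "sampling_rate", "set_index",
                       "pull_index")

#' Write a force trace to a delimited text file
#'
#' Format: `# key: value` header lines carrying all metadata, a `time<TAB>force`
#' column header, then two tab-separated numeric columns at full double
#' precision (so a read after write reproduces the trace exactly).
#'
#' @param trace A `force_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_force_trace(trace)
  m <- trace$meta
  hdr <- vapply(TRACE_META_FIELDS, function(f) {
    v <- m[[f]]
    sprintf("# %s: %s", f, if (is.character(v)) v else fmt_num(as.numeric(v)))
  }, character(1))
  body <- paste(fmt_num(trace$time), fmt_num(trace$force), sep = "\t")
  writeLines(c(hdr, "time\tforce", body), path)
  invisible(path)
}

#' Read a force trace written by [write_trace()]
#'
#' @param path File path.
#' @return A validated `force_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    abort(paste("no such file:", path), "frinstab_format_error")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) abort("empty trace file", "frinstab_format_error")
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(z) trimws(z[2]), character(1))
  vals <- vapply(kv, function(z) trimws(z[3]), character(1))
  names(vals) <- keys
  missing_meta <- setdiff(TRACE_META_FIELDS, keys)
  if (length(missing_meta))
    abort(paste("missing metadata field(s):",
                paste(missing_meta, collapse = ", ")),
          "frinstab_format_error")
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("^time", body[1])) body <- body[-1]
  if (!length(body)) abort("trace file has no data rows", "frinstab_format_error")
  parts <- strsplit(body, "[\t ]+")
  bad_ncol <- which(lengths(parts) != 2L)
  if (length(bad_ncol))
    abort(sprintf("row %d: expected 2 columns", bad_ncol[1]),
          "frinstab_parse_error")
  num <- suppressWarnings(vapply(parts, function(p) as.numeric(p), numeric(2)))
  bad <- which(colSums(is.na(num)) > 0)
  if (length(bad))
    abort(sprintf("row %d: non-numeric cell", bad[1]), "frinstab_parse_error")
  numeric_meta <- setdiff(TRACE_META_FIELDS, "surface_id")
  mv <- suppressWarnings(as.numeric(vals[numeric_meta]))
  if (anyNA(mv))
    abort(sprintf("non-numeric metadata value for '%s'",
                  numeric_meta[which(is.na(mv))[1]]),
          "frinstab_parse_error")
  names(mv) <- numeric_meta
  force_trace(time = num[1, ], force = num[2, ],
              surface_id = vals[["surface_id"]],
              applied_mass = mv[["applied_mass"]],
              deadweight = mv[["deadweight"]],
              velocity = mv[["velocity"]],
              displacement = mv[["displacement"]],
              sampling_rate = mv[["sampling_rate"]],
              set_index = mv[["set_index"]],
              pull_index = mv[["pull_index"]])
}

#' Canonical on-disk location of a trace within a fixture tree
#'
#' `traces/<surface>/<mass>_<velocity>/<set>_<pull>.tsv` under `root`.
#'
#' @param root Root directory.
#' @param meta A force-trace `meta` list.
#' @return File path (directories not created).
#' @export
trace_path <- function(root, meta) {
  file.path(root, "traces", meta$surface_id,
            sprintf("%g_%g", meta$applied_mass, meta$velocity),
            sprintf("%d_%d.tsv", meta$set_index, meta$pull_index))
}

#' Write a list of traces into the canonical tree; read a tree back
#'
#' @param traces List of `force_trace` objects.
#' @param root Root directory (created if needed).
#' @return `write_traces`: the paths written. `read_traces`: a list of
#'   `force_trace` objects.
#' @export
write_traces <- function(traces, root) {
  paths <- vapply(traces, function(tr) {
    p <- trace_path(root, tr$meta)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_trace(tr, p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_traces
#' @export
read_traces <- function(root) {
  files <- list.files(file.path(root, "traces"), pattern = "\\.tsv$",
                      recursive = TRUE, full.names = TRUE)
  if (!length(files))
    abort(paste("no trace files under", root), "frinstab_format_error")
  lapply(sort(files), read_trace)
}

#' Check that a trace set covers the condition grid completely
#'
#' A surface's trace set is complete iff every (mass, velocity) node holds
#' exactly `n_reps` pulls.
#'
#' @param traces List of `force_trace` objects for one surface.
#' @param grid A `condition_grid`.
#' @return List with `complete` (logical), `counts` (mass x velocity matrix
#'   of pull counts) and `problems` (character vector describing deviating
#'   nodes).
#' @export
check_completeness <- function(traces, grid) {
  counts <- matrix(0L, length(grid$masses), length(grid$velocities),
                   dimnames = list(grid$masses, grid$velocities))
  for (tr in traces) {
    i <- match(tr$meta$applied_mass, grid$masses)
    j <- match(tr$meta$velocity, grid$velocities)
    if (is.na(i) || is.na(j))
      abort(sprintf("trace at (%g g, %g mm/s) is off the grid",
                    tr$meta$applied_mass, tr$meta$velocity),
            "frinstab_validation_error")
    counts[i, j] <- counts[i, j] + 1L
  }
  bad <- which(counts != grid$n_reps, arr.ind = TRUE)
  problems <- if (nrow(bad)) {
    sprintf("(%s g, %s mm/s): %d pulls, expected %d",
            rownames(counts)[bad[, 1]], colnames(counts)[bad[, 2]],
            counts[bad], grid$n_reps)
  } else character(0)
  list(complete = nrow(bad) == 0L, counts = counts, problems = problems)
}

## ---- height map files ----------------------------------------------------

#' Write/read a height map as plain text
#'
#' One JSON header line (`pixel_size`, `scan_size`, in meters), then the
#' height matrix row by row, whitespace-delimited, at full precision.
#'
#' @param hm A `height_map`.
#' @param path File path.
#' @return `write_heightmap`: `path` invisibly; `read_heightmap`: a
#'   `height_map`.
#' @export
write_heightmap <- function(hm, path) {
  hdr <- jsonlite::toJSON(list(pixel_size = hm$pixel_size,
                               scan_size = hm$scan_size),
                          auto_unbox = TRUE, digits = NA)
  rows <- apply(hm$heights, 1L, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(as.character(hdr), rows), path)
  invisible(path)
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(path) {
  if (!file.exists(path))
    abort(paste("no such file:", path), "frinstab_format_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    abort("height map file needs a header and at least one row",
          "frinstab_format_error")
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]),
                  error = function(e) abort("bad height-map header",
                                            "frinstab_parse_error"))
  if (is.null(hdr$pixel_size))
    abort("height-map header lacks pixel_size", "frinstab_format_error")
  rows <- strsplit(trimws(lines[-1]), "[ \t]+")
  n <- unique(lengths(rows))
  if (length(n) != 1L)
    abort("height map rows have unequal lengths (not rectangular)",
          "frinstab_parse_error")
  h <- suppressWarnings(do.call(rbind, lapply(rows, as.numeric)))
  if (anyNA(h)) {
    bad <- which(rowSums(is.na(h)) > 0)[1]
    abort(sprintf("row %d: non-numeric cell", bad), "frinstab_parse_error")
  }
  height_map(h, pixel_size = hdr$pixel_size,
             scan_size = if (is.null(hdr$scan_size)) NULL else hdr$scan_size)
}

## ---- behavioural tables --------------------------------------------------

#' Write/read a behavioural trial table as CSV
#'
#' Six named columns (`subject_id`, `pair_label`, `odd_position`,
#' `chosen_position`, `correct`, `response_time`). The reader recomputes
#' `correct` from the positions and rejects inconsistent rows; an empty
#' file is an explicit error.
#'
#' @param table A `behavioral_table` (or plain data frame with the columns).
#' @param path File path.
#' @return `write_behavior`: `path` invisibly; `read_behavior`: a
#'   `behavioral_table`.
#' @export
write_behavior <- function(table, path) {
  table <- behavioral_table(as.data.frame(table))
  utils::write.csv(as.data.frame(table)[, c("subject_id", "pair_label",
                                            "odd_position", "chosen_position",
                                            "correct", "response_time")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  if (!file.exists(path))
    abort(paste("no such file:", path), "frinstab_format_error")
  if (file.size(path) == 0L)
    abort("behavioural file is empty", "frinstab_validation_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(paste("cannot parse CSV:",
                                                 conditionMessage(e)),
                                           "frinstab_parse_error"))
  if (nrow(df) == 0L)
    abort("behavioural file has no rows", "frinstab_validation_error")
  behavioral_table(df)
}
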