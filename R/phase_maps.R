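#' Tally instability labels over the condition grid
#'
#' Builds a per-surface phase-count grid: for every (mass, velocity) node
#' the number of retained pulls classified as steady sliding, slow
#' frictional wave or stiction spike (primary label only), plus per-label
#' totals over the whole grid. With the default grid the totals sum to
#' 16 x 9 = 144.
#'
#' @param classified Data frame from [classify_traces()] for one surface;
#'   flagged first pulls are ignored.
#' @param grid A `condition_grid`.
#' @return An object of class `phase_count_grid`.
#' @export
count_phases <- function(classified, grid) {
  df <- classified[!classified$flagged, , drop = FALSE]
  if (anyDuplicated(df[, c("surface_id", "applied_mass", "velocity",
                           "set_index", "pull_index")]))
    abort("duplicate pull identifiers in classified set",
          "frinstab_validation_error")
  labels <- c("SS", "SFW", "Sp")
  if (!all(df$label %in% labels))
    abort("unknown instability label in classified set",
          "frinstab_validation_error")
  counts <- array(0L, c(length(grid$masses), length(grid$velocities), 3L),
                  dimnames = list(grid$masses, grid$velocities, labels))
  for (r in seq_len(nrow(df))) {
    i <- match(df$applied_mass[r], grid$masses)
    j <- match(df$velocity[r], grid$velocities)
    if (is.na(i) || is.na(j))
      abort(sprintf("pull at (%g g, %g mm/s) is off the grid",
                    df$applied_mass[r], df$velocity[r]),
            "frinstab_validation_error")
    l <- match(df$label[r], labels)
    counts[i, j, l] <- counts[i, j, l] + 1L
  }
  node_totals <- apply(counts, c(1, 2), sum)
  if (any(node_totals != grid$n_reps))
    abort("condition grid incomplete: some nodes lack pulls",
          "frinstab_completeness_error")
  totals <- apply(counts, 3, sum)
  structure(list(surface_id = df$surface_id[1], grid = grid,
                 counts = counts, totals = totals),
            class = "phase_count_grid")
}

#' @export
print.phase_count_grid <- function(x, ...) {
  cat(sprintf("<phase_count_grid> %s: SS %d, SFW %d, Sp %d of %d pulls\n",
              x$surface_id, x$totals["SS"], x$totals["SFW"], x$totals["Sp"],
              sum(x$totals)))
  invisible(x)
}

#' Interpolate a phase-count grid into a smooth frequency map
#'
#' Bilinear interpolation of the per-node occurrence frequency
#' (count / n_reps) for each label, on linear mass and velocity axes; the
#' raster reproduces the node frequencies exactly at the node coordinates
#' and stays within [0, 1] everywhere.
#'
#' @param pcg A `phase_count_grid` (at least 2 x 2).
#' @param resolution Number of raster points per axis.
#' @return List with `mass`, `velocity` (axis vectors) and `maps`, a named
#'   list of `resolution x resolution` matrices (SS, SFW, Sp).
#' @export
interpolate_map <- function(pcg, resolution = 101L) {
  grid <- pcg$grid
  nm <- length(grid$masses); nv <- length(grid$velocities)
  if (nm < 2L || nv < 2L)
    abort("need at least a 2 x 2 grid to interpolate",
          "frinstab_validation_error")
  if (resolution < max(nm, nv))
    abort("resolution must be at least the grid size",
          "frinstab_validation_error")
  mx <- seq(min(grid$masses), max(grid$masses), length.out = resolution)
  vy <- seq(min(grid$velocities), max(grid$velocities),
            length.out = resolution)
  maps <- lapply(c(SS = "SS", SFW = "SFW", Sp = "Sp"), function(lab) {
    z <- pcg$counts[, , lab] / grid$n_reps
    # tensor-product linear interpolation: along mass, then velocity
    half <- apply(z, 2, function(col)
      stats::approx(grid$masses, col, xout = mx)$y)
    t(apply(half, 1, function(row)
      stats::approx(grid$velocities, row, xout = vy)$y))
  })
  list(mass = mx, velocity = vy, maps = maps)
}

#' @export
plot.phase_count_grid <- function(x, resolution = 101L, ...) {
  ip <- interpolate_map(x, resolution)
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pal <- list(SS = grDevices::hcl.colors(64, "Oranges", rev = TRUE),
              SFW = grDevices::hcl.colors(64, "Blues", rev = TRUE),
              Sp = grDevices::hcl.colors(64, "Greens", rev = TRUE))
  for (lab in names(ip$maps)) {
    graphics::image(ip$mass, ip$velocity, ip$maps[[lab]], zlim = c(0, 1),
                    col = pal[[lab]], xlab = "applied mass (g)",
                    ylab = "velocity (mm/s)",
                    main = paste(x$surface_id, lab))
    graphics::points(expand.grid(x$grid$masses, x$grid$velocities),
                     pch = 4, col = "grey40")
  }
  invisible(x)
}

#' Differential instability score for a pair of surfaces
#'
#' For each instability the absolute difference in total occurrence
#' between the two surfaces, as a count out of the maximum number of
#' pulls (144 on the default grid) and as a percentage reported to three
#' significant figures. The absolute value makes the score symmetric in
#' the two surfaces, matching a discrimination task that does not
#' distinguish sample order.
#'
#' @param a,b `phase_count_grid` objects on identical grids.
#' @param label Optional pair label (default "A vs B" from surface ids).
#' @return An object of class `pair_difference` with `delta_count` and
#'   `delta_percent` per label.
#' @export
pair_difference <- function(a, b, label = NULL) {
  ga <- a$grid; gb <- b$grid
  if (!isTRUE(all.equal(ga$masses, gb$masses)) ||
      !isTRUE(all.equal(ga$velocities, gb$velocities)) ||
      ga$n_reps != gb$n_reps)
    abort("phase-count grids do not match", "frinstab_validation_error")
  max_pulls <- length(ga$masses) * length(ga$velocities) * ga$n_reps
  delta_count <- abs(a$totals - b$totals)
  delta_percent <- signif(100 * delta_count / max_pulls, 3)
  if (is.null(label)) label <- paste(a$surface_id, "vs", b$surface_id)
  structure(list(label = label, surfaces = c(a$surface_id, b$surface_id),
                 delta_count = delta_count, delta_percent = delta_percent,
                 max_pulls = max_pulls),
            class = "pair_difference")
}

#' @export
print.pair_difference <- function(x, ...) {
  cat(sprintf("<pair_difference> %s (max %d pulls)\n", x$label, x$max_pulls))
  for (lab in names(x$delta_count))
    cat(sprintf("  |d%s| = %d (%g%%)\n", lab, x$delta_count[[lab]],
                x$delta_percent[[lab]]))
  invisible(x)
}
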