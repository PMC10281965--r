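#' Guide shape templates
#'
#' The three guide shapes traced by participants: an Archimedean spiral
#' traced outward from the center, and square / triangular waves traced left
#' to right. Templates are polylines in screen points (y downward); the
#' prescribed start point is the first polyline vertex (spiral: the center;
#' waves: the leftmost point). True on-screen dimensions of the study
#' guides are not published, so all geometry is a documented default; the
#' tracing duration is controlled by the simulator, not by template size.
#'
#' @param turns Number of spiral turns (>= 1).
#' @param spacing Radial growth per turn, points.
#' @param points_per_turn Polyline resolution per turn (>= 8).
#'
#' @return A `shape_template`: list with `shape`, `points` (data.frame
#'   `x,y`), `start_index` (1-based, always 1), `arc_length` (points).
#' @export
#' @examples
#' sp <- make_spiral(turns = 3, spacing = 40)
#' nrow(sp$points)      # turns * points_per_turn + 1
#' sp$arc_length
make_spiral <- function(turns = 3, spacing = 40, points_per_turn = 64) {
  if (turns < 1 || spacing <= 0 || points_per_turn < 8)
    stop_validation("spiral parameters must be positive (turns >= 1, points_per_turn >= 8)")
  theta <- seq(0, 2 * pi * turns, length.out = turns * points_per_turn + 1)
  r <- spacing * theta / (2 * pi)
  new_template("spiral", data.frame(x = r * cos(theta), y = -r * sin(theta)))
}

#' @rdname make_spiral
#' @param cycles Number of wave cycles (>= 1).
#' @param amplitude Half peak-to-peak excursion, points (wave spans
#'   `±amplitude` about its midline).
#' @param wavelength Horizontal extent of one cycle, points.
#' @export
#' @examples
#' make_square_wave(1, 50, 100)$arc_length  # 100 + 4*50
make_square_wave <- function(cycles = 3, amplitude = 60, wavelength = 160) {
  check_wave_args(cycles, amplitude, wavelength)
  a <- amplitude
  pts <- list(data.frame(x = 0, y = 0))
  for (k in seq_len(cycles)) {
    x0 <- (k - 1) * wavelength
    # up a, right half-wavelength, down 2a, right half-wavelength, up a
    pts[[k + 1]] <- data.frame(
      x = x0 + c(0, wavelength / 2, wavelength / 2, wavelength, wavelength),
      y = c(-a, -a, a, a, 0))
  }
  new_template("square", do.call(rbind, pts))
}

#' @rdname make_spiral
#' @export
#' @examples
#' make_triangular_wave(1, 50, 100)$arc_length  # 2*sqrt(50^2 + 100^2)
make_triangular_wave <- function(cycles = 3, amplitude = 60,
                                 wavelength = 160) {
  check_wave_args(cycles, amplitude, wavelength)
  # zigzag of right-descending / right-ascending strokes (y down on screen),
  # peak-to-peak 2*amplitude
  x <- seq(0, cycles * wavelength, by = wavelength / 2)
  y <- rep(c(0, -2 * amplitude), length.out = length(x))
  new_template("triangular", data.frame(x = x, y = y))
}

check_wave_args <- function(cycles, amplitude, wavelength) {
  if (cycles < 1 || amplitude <= 0 || wavelength <= 0)
    stop_validation("wave parameters must be positive (cycles >= 1)")
}

new_template <- function(shape, points) {
  seg <- sqrt(diff(points$x)^2 + diff(points$y)^2)
  if (any(seg == 0)) stop_validation("consecutive template points coincide")
  structure(list(shape = shape, points = points, start_index = 1L,
                 arc_length = sum(seg)),
            class = "shape_template")
}

#' @export
print.shape_template <- function(x, ...) {
  cat(sprintf("<shape_template> %s: %d points, arc length %.1f pt\n",
              x$shape, nrow(x$points), x$arc_length))
  invisible(x)
}

#' Default templates for the three guide shapes
#'
#' @return Named list of `shape_template`s (`spiral`, `square`,
#'   `triangular`) at the package default geometry.
#' @export
default_templates <- function() {
  list(spiral = make_spiral(), square = make_square_wave(),
       triangular = make_triangular_wave())
}

#' Export a template polyline as CSV (`x,y`) for plotting/debugging
#'
#' @param template A `shape_template`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  utils::write.csv(template$points, path, row.names = FALSE)
  invisible(path)
}
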