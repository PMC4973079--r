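#' Electrode grid geometry
#'
#' Describes the high-density electrode grid: number of rows and columns and
#' the inter-electrode distance (pitch). Channels are numbered row-major:
#' channel 1 is (row 1, col 1), channel `n_cols` is (row 1, col `n_cols`),
#' and so on. Row 1 is the most proximal row and column 1 the reference
#' corner; this ordering is a package convention that makes channel subsets
#' reproducible.
#'
#' @param n_rows,n_cols grid dimensions (default the 8 x 24 = 192-channel
#'   grid used throughout).
#' @param pitch_mm inter-electrode distance in millimetres (default 10).
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry()
#' n_channels(g)
#' channel_positions(g)
#' @export
grid_geometry <- function(n_rows = 8, n_cols = 24, pitch_mm = 10) {
  stopifnot(
    length(n_rows) == 1, n_rows >= 1, n_rows == as.integer(n_rows),
    length(n_cols) == 1, n_cols >= 1, n_cols == as.integer(n_cols),
    length(pitch_mm) == 1, pitch_mm > 0
  )
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch_mm = as.numeric(pitch_mm)),
    class = "grid_geometry"
  )
}

#' @rdname grid_geometry
#' @param geometry a `grid_geometry`.
#' @export
n_channels <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  geometry$n_rows * geometry$n_cols
}

#' @rdname grid_geometry
#' @return `channel_positions()` returns a tibble with one row per channel
#'   (`channel`, `row`, `col`); the channel index map is a bijection onto the
#'   grid.
#' @export
channel_positions <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  tibble::tibble(
    channel = seq_len(n_channels(geometry)),
    row = rep(seq_len(geometry$n_rows), each = geometry$n_cols),
    col = rep(seq_len(geometry$n_cols), times = geometry$n_rows)
  )
}

#' @rdname grid_geometry
#' @param channel integer channel indices.
#' @return `channel_distance_mm()` returns the physical distance in mm
#'   between two channels on the grid.
#' @param channel2 second channel index vector.
#' @export
channel_distance_mm <- function(geometry, channel, channel2) {
  pos <- channel_positions(geometry)
  p1 <- pos[channel, ]
  p2 <- pos[channel2, ]
  geometry$pitch_mm * sqrt((p1$row - p2$row)^2 + (p1$col - p2$col)^2)
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d channels, %.1f mm pitch\n",
              x$n_rows, x$n_cols, x$pitch_mm))
  invisible(x)
}

# centered uniform pick of m indices out of 1..n with equal step floor(n/m)
pick_centered <- function(n, m) {
  stopifnot(m >= 1, m <= n)
  step <- n %/% m
  span <- step * (m - 1) + 1
  offset <- (n - span) %/% 2 + 1
  offset + step * (0:(m - 1))
}

subset_layouts <- function() {
  # n_channels -> rows x cols kept from the 8 x 24 grid
  list(
    `192` = c(8, 24), `96` = c(8, 12), `48` = c(8, 6), `24` = c(4, 6),
    `16` = c(4, 4), `12` = c(3, 4), `10` = c(2, 5), `8` = c(2, 4),
    `6` = c(2, 3), `4` = c(2, 2)
  )
}

#' Allowed electrode-subset sizes
#'
#' The channel-reduction analysis uses the full grid (192 channels) and nine
#' reduced regular sub-grids.
#'
#' @return integer vector of supported subset sizes.
#' @export
allowed_subset_sizes <- function() {
  as.integer(names(subset_layouts()))
}

#' Select a regular electrode sub-grid
#'
#' Reduced channel sets are regular sub-grids of the full 8 x 24 grid, with
#' uniform row/column steps and centered placement. The row x column layout
#' for each supported size is: 192 = 8x24, 96 = 8x12, 48 = 8x6, 24 = 4x6,
#' 16 = 4x4, 12 = 3x4, 10 = 2x5, 8 = 2x4, 6 = 2x3, 4 = 2x2.
#'
#' @param geometry a [grid_geometry()] (must be the 8 x 24 grid for reduced
#'   sizes; 192 returns the identity selection on any grid of that size).
#' @param n_channels requested subset size, one of
#'   [allowed_subset_sizes()].
#' @return An object of class `subset_spec`: a list with `n_channels`,
#'   `rows`, `cols` (kept grid rows/columns) and `channels` (row-major
#'   channel indices into the full grid). Selection depends only on the
#'   geometry, never on data values, and is idempotent.
#' @examples
#' select_regular_subset(grid_geometry(), 24)
#' @export
select_regular_subset <- function(geometry, n_channels) {
  stopifnot(inherits(geometry, "grid_geometry"), length(n_channels) == 1)
  layouts <- subset_layouts()
  key <- as.character(as.integer(n_channels))
  if (!key %in% names(layouts)) {
    stop("unsupported subset size ", n_channels, "; allowed sizes are ",
         paste(allowed_subset_sizes(), collapse = ", "), call. = FALSE)
  }
  dims <- layouts[[key]]
  if (dims[1] > geometry$n_rows || dims[2] > geometry$n_cols) {
    stop("subset layout ", dims[1], "x", dims[2],
         " does not fit the ", geometry$n_rows, "x", geometry$n_cols, " grid",
         call. = FALSE)
  }
  rows <- pick_centered(geometry$n_rows, dims[1])
  cols <- pick_centered(geometry$n_cols, dims[2])
  channels <- as.integer(outer(
    (rows - 1) * geometry$n_cols, cols, `+`
  ))
  structure(
    list(n_channels = as.integer(n_channels), rows = rows, cols = cols,
         channels = sort(channels)),
    class = "subset_spec"
  )
}

#' @export
print.subset_spec <- function(x, ...) {
  cat(sprintf("<subset_spec> %d channels (%d rows x %d cols)\n",
              x$n_channels, length(x$rows), length(x$cols)))
  invisible(x)
}
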