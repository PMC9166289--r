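#' @importFrom rlang .data abort warn
#' @importFrom stats cor sd quantile rnorm runif rpois pf setNames approx
#' @importFrom tibble tibble as_tibble
NULL

# Axis-aligned rectangle, half-open in both axes: [x0, x1) x [y0, y1).
rect <- function(x0, x1, y0, y1) {
  stopifnot(x1 > x0, y1 > y0)
  c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

in_rect <- function(x, y, r) {
  x >= r[["x0"]] & x < r[["x1"]] & y >= r[["y0"]] & y < r[["y1"]]
}

rect_center <- function(r) c((r[["x0"]] + r[["x1"]]) / 2, (r[["y0"]] + r[["y1"]]) / 2)

rects_overlap <- function(a, b) {
  a[["x0"]] < b[["x1"]] && b[["x0"]] < a[["x1"]] &&
    a[["y0"]] < b[["y1"]] && b[["y0"]] < a[["y1"]]
}

# Shortest distance from a point to a rectangle (0 inside).
rect_distance <- function(x, y, r) {
  dx <- pmax(r[["x0"]] - x, 0, x - r[["x1"]])
  dy <- pmax(r[["y0"]] - y, 0, y - r[["y1"]])
  sqrt(dx^2 + dy^2)
}

#' Spatial bin specification
#'
#' Defines a regular `nx` by `ny` grid of half-open bins over a rectangular
#' arena. Bin 1 is the bottom-left bin; the linear index runs row-major along
#' x first (`index = ix + (iy - 1) * nx`).
#'
#' @param nx,ny Number of bins along x and y.
#' @param extent Numeric length-2, arena width and height.
#' @return A `bin_spec` list with fields `nx`, `ny`, `extent`.
#' @export
bin_spec <- function(nx = 20, ny = nx, extent = c(1, 1)) {
  stopifnot(nx >= 1, ny >= 1, length(extent) == 2, all(extent > 0))
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 extent = as.numeric(extent)),
            class = "bin_spec")
}

n_bins <- function(spec) spec$nx * spec$ny

# Linear bin index of points; positions on the top/right edge fall in the
# last bin (closed at the arena boundary).
bin_index <- function(x, y, spec) {
  ix <- pmin(pmax(floor(x / spec$extent[1] * spec$nx), 0), spec$nx - 1)
  iy <- pmin(pmax(floor(y / spec$extent[2] * spec$ny), 0), spec$ny - 1)
  as.integer(ix + iy * spec$nx + 1)
}

bin_centers <- function(spec) {
  ix <- rep(seq_len(spec$nx), times = spec$ny)
  iy <- rep(seq_len(spec$ny), each = spec$nx)
  tibble(
    bin = seq_len(n_bins(spec)), ix = ix, iy = iy,
    x = (ix - 0.5) / spec$nx * spec$extent[1],
    y = (iy - 0.5) / spec$ny * spec$extent[2]
  )
}

same_bins <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny && isTRUE(all.equal(a$extent, b$extent))
}

# Gridded map container: values is a vector of length nx*ny with NA for
# unvisited bins (never silently 0).
new_map <- function(values, spec, kind, counts = NULL, extra = list()) {
  structure(c(list(values = values, counts = counts, spec = spec, kind = kind),
              extra),
            class = c(paste0("rl_", kind, "_map"), "rl_map"))
}

#' @export
print.rl_map <- function(x, ...) {
  cat(sprintf("<rl_map: %s, %d x %d bins, %d/%d visited>\n", x$kind,
              x$spec$nx, x$spec$ny, sum(!is.na(x$values)), n_bins(x$spec)))
  invisible(x)
}

#' Turn a gridded map into a tibble of bin centers and values
#'
#' @param x An `rl_map` (state-value, policy, diverse-density or tuning map).
#' @param ... Unused.
#' @return A tibble with bin index, bin center coordinates and map value(s).
#' @export
tidy.rl_map <- function(x, ...) {
  out <- bin_centers(x$spec)
  out$value <- x$values
  if (!is.null(x$counts)) out$n <- x$counts
  out
}

map_matrix <- function(m) {
  matrix(m$values, nrow = m$spec$ny, ncol = m$spec$nx, byrow = TRUE)
}

# Seeded RNG stream that does not disturb the caller's global RNG.
# `holder` is an environment with a `state` field.
rng_stream <- function(seed) {
  holder <- new.env(parent = emptyenv())
  old <- get_rng()
  set.seed(seed)
  holder$state <- get_rng()
  set_rng(old)
  holder
}

get_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  else NULL
}

set_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

with_stream <- function(holder, expr) {
  old <- get_rng()
  set_rng(holder$state)
  on.exit({ holder$state <- get_rng(); set_rng(old) })
  expr
}

# Pearson correlation over jointly finite entries; NA when degenerate.
cor_finite <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# Permutation p-value with the +1 correction (upper tail).
perm_p <- function(observed, nulls) {
  (1 + sum(nulls >= observed, na.rm = TRUE)) / (1 + sum(is.finite(nulls)))
}
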