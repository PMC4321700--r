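# Analytic track constructors used as fixtures throughout the suite.

make_traj <- function(x, y, id = "a", t = seq_along(x) - 1,
                      ventral_is_left = NA) {
  tibble::tibble(animal_id = id, t_s = t, x_mm = x, y_mm = y,
                 ventral_is_left = ventral_is_left, excluded = FALSE)
}

# Circle of given radius sampled at a fixed arc step; total_arc_mm of
# true arc length, counter-clockwise unless ccw = FALSE.
circle_track <- function(radius, total_arc_mm, arc_step_mm = 0.1,
                         ccw = TRUE, id = "circle", ventral_is_left = NA,
                         x0 = 0, y0 = 0) {
  th <- seq(0, total_arc_mm / radius, by = arc_step_mm / radius)
  if (!ccw) th <- -th
  make_traj(x0 + radius * cos(th), y0 + radius * sin(th), id = id,
            ventral_is_left = ventral_is_left)
}

straight_track <- function(length_mm, step_mm = 0.15, id = "straight",
                           ventral_is_left = NA) {
  x <- seq(0, length_mm, by = step_mm)
  make_traj(x, rep(0, length(x)), id = id, ventral_is_left = ventral_is_left)
}

# 20 mm straight run followed by one full circle of the given diameter,
# sharing the junction point: the classifier's mixed-track construction.
straight_plus_loop_track <- function(straight_mm = 20, loop_diameter = 6,
                                     step = 0.1, id = "mixed") {
  xs <- seq(0, straight_mm, by = step)
  r <- loop_diameter / 2
  th <- seq(0, 2 * pi, by = step / r)
  if (th[length(th)] < 2 * pi) th <- c(th, 2 * pi)
  # circle tangent to the +x heading at the junction, turning left
  x <- c(xs, straight_mm + r * sin(th[-1]))
  y <- c(rep(0, length(xs)), r - r * cos(th[-1]))
  make_traj(x, y, id = id)
}

rotate_traj <- function(tr, angle_deg, dx = 0, dy = 0) {
  a <- angle_deg * pi / 180
  x <- tr$x_mm * cos(a) - tr$y_mm * sin(a) + dx
  y <- tr$x_mm * sin(a) + tr$y_mm * cos(a) + dy
  tr$x_mm <- x
  tr$y_mm <- y
  tr
}

mirror_traj <- function(tr) {
  tr$y_mm <- -tr$y_mm
  if ("ventral_is_left" %in% names(tr) && !all(is.na(tr$ventral_is_left))) {
    tr$ventral_is_left <- !tr$ventral_is_left
  }
  tr
}

# Independent brute-force curving oracle: plain loop over retained
# points, no shared code with compute_curving's vectorised pipeline.
oracle_curving <- function(x, y) {
  n <- length(x)
  vals <- numeric(0)
  wts <- numeric(0)
  for (i in 2:(n - 1)) {
    h1 <- atan2(y[i] - y[i - 1], x[i] - x[i - 1]) * 180 / pi
    h2 <- atan2(y[i + 1] - y[i], x[i + 1] - x[i]) * 180 / pi
    d <- h2 - h1
    while (d <= -180) d <- d + 360
    while (d > 180) d <- d - 360
    l1 <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
    l2 <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    w <- (l1 + l2) / 2
    vals <- c(vals, d / w)
    wts <- c(wts, w)
  }
  list(curving = vals, weights = wts)
}
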