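# The EdgeLine value type: one straight line in image coordinates in
# normal (rho-theta) form, x*cos(theta) + y*sin(theta) = rho, with theta in
# [0, 180) degrees. x = column, y = row, origin top-left, 0-based.
# bottom_x caches the intersection with the bottom pixel row y = height - 1,
# the reference point for the lateral-error metric.

#' Construct an edge line in rho-theta form
#'
#' @param rho signed normal distance from the origin, pixels.
#' @param theta_deg normal angle from the +x axis, degrees; any value is
#'   accepted and canonicalized into [0, 180) (flipping the sign of rho as
#'   needed).
#' @param height image height in pixels, used to cache `bottom_x`.
#' @return an object of class `edge_line`: list with `rho`, `theta_deg`,
#'   `bottom_x`, `height`.
#' @export
edge_line <- function(rho, theta_deg, height) {
  th <- theta_deg %% 180
  k <- round((theta_deg - th) / 180)
  if (k %% 2 != 0) rho <- -rho
  ct <- cos(th * pi / 180); st <- sin(th * pi / 180)
  bottom_x <- if (abs(ct) < 1e-9) NA_real_ else (rho - (height - 1) * st) / ct
  structure(list(rho = rho, theta_deg = th, bottom_x = bottom_x,
                 height = height),
            class = "edge_line")
}

#' Edge line from bottom intersection and vertical-axis angle
#'
#' The field convention for a guidance line: where it meets the bottom image
#' row and how far it leans from the image vertical (positive = the top of
#' the line leans right).
#'
#' @param bottom_x x of the intersection with row y = height - 1.
#' @param angle_deg signed angle from the vertical axis, degrees, |angle| < 90.
#' @param height image height in pixels.
#' @return an `edge_line`.
#' @export
edge_line_from_vertical <- function(bottom_x, angle_deg, height) {
  a <- angle_deg * pi / 180
  rho <- bottom_x * cos(a) + (height - 1) * sin(a)
  edge_line(rho, angle_deg, height)
}

#' Signed angle of an edge line from the image vertical axis
#'
#' @param line an `edge_line`.
#' @return degrees in (-90, 90]; positive when the top leans right.
#' @export
vertical_angle <- function(line) {
  th <- line$theta_deg
  if (th > 90) th - 180 else th
}

#' @export
print.edge_line <- function(x, ...) {
  cat(sprintf(
    "edge line: rho = %.2f px, theta = %.2f deg (%.2f deg from vertical), bottom_x = %.2f\n",
    x$rho, x$theta_deg, vertical_angle(x), x$bottom_x))
  invisible(x)
}

# x of the line at row y (continuous coordinates)
line_x_at <- function(line, y) {
  ct <- cos(line$theta_deg * pi / 180)
  st <- sin(line$theta_deg * pi / 180)
  (line$rho - y * st) / ct
}
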