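#' Reference position and velocity of the target movement
#'
#' The target traverses the circle once at constant peripheral speed,
#' starting at `start_angle` (12 o'clock by default) and moving
#' counter-clockwise, then rests at the start point for the remainder of
#' the trial with zero velocity.
#'
#' @param target a [target_spec()].
#' @param t numeric vector of elapsed times in seconds (>= 0).
#' @return `target_position()`: a tibble with columns `t`, `x`, `y` (m);
#'   `target_velocity()`: a tibble with columns `t`, `vx`, `vy` (m/s).
#' @examples
#' tg <- target_spec()
#' target_velocity(tg, 0.5)
#' @export
target_position <- function(target, t) {
  stopifnot(inherits(target, "target_spec"), all(t >= -1e-12))
  r <- target$radius
  v <- target$peripheral_speed
  t_full <- 2 * pi * r / v
  arc <- v * pmin(t, t_full)
  phi <- target$start_angle + arc / r
  tibble::tibble(
    t = t,
    x = target$center[1] + r * cos(phi),
    y = target$center[2] + r * sin(phi)
  )
}

#' @rdname target_position
#' @export
target_velocity <- function(target, t) {
  stopifnot(inherits(target, "target_spec"), all(t >= -1e-12))
  r <- target$radius
  v <- target$peripheral_speed
  t_full <- 2 * pi * r / v
  moving <- t < t_full
  phi <- target$start_angle + v * pmin(t, t_full) / r
  tibble::tibble(
    t = t,
    vx = ifelse(moving, -v * sin(phi), 0),
    vy = ifelse(moving, v * cos(phi), 0)
  )
}
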