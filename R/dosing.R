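# Concentration-vs-time profiles and the hard switching gates.

#' Drug concentration at a given time
#'
#' 0 before the therapy start; from `t_start` on, the plateau `C0` for a
#' constant drug or `C0 * exp(-decay_rate * t)` for a decaying one. The
#' decay clock is absolute simulation time by default (so a drug started
#' at day 50 with decay 1e-3 enters at `C0 * exp(-0.05)`), or time since
#' `t_start` when the schedule sets `decay_from_start = TRUE`.
#'
#' @param t time in days (>= 0); vectorised.
#' @param sched a [drug_schedule()].
#' @return Concentration in mg.m^-2, non-increasing on `[t_start, Inf)`.
#' @examples
#' sc <- drug_schedule(C0 = 0.2, t_start = 50, decay_rate = 1e-3)
#' concentration(c(10, 50, 500), sc)
#' @export
concentration <- function(t, sched) {
  check_num(t, "t", 0, len = length(t))
  clock <- if (sched$decay_from_start) pmax(t - sched$t_start, 0) else t
  ifelse(t < sched$t_start, 0, sched$C0 * exp(-sched$decay_rate * clock))
}

#' Hard on/off switch
#'
#' 1 once `t` has reached the on-time, 0 before; the boundary `t = t_on`
#' is on (closed on the left).
#'
#' @param t time in days (>= 0); vectorised.
#' @param t_on switch-on time in days (>= 0).
#' @return 0 or 1.
#' @export
gate <- function(t, t_on) {
  check_num(t, "t", 0, len = length(t))
  check_num(t_on, "t_on", 0)
  as.numeric(t >= t_on)
}
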