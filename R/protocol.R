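#' Mode parameter sets for the opioid-exposure states
#'
#' Each addiction mode is a small parameter vector: drive amplitudes
#' `k_exc`, `k_inh` of the noisy external input, synaptic weight scales
#' `s_exc` (>= 0) and `s_inh` (<= 0), the astrocytic transporter-activity
#' factor `delta` (0.5 = high clearance, 0.8 = normal, 1 = transporters
#' inactive), and `glio_release_scale`, a `[0, 1]` multiplier on the
#' gliotransmitter current gain used by the release-toggling protocols.
#'
#' Canonical modes:
#' * `normal`: (5, 2, 0.5, -1, 0.8) — baseline cortical regime.
#' * `acute`: (7.5, 1, 0.5, -1, 0.8) — disinhibition: excitatory drive
#'   +50%, inhibitory drive -50%, weights unchanged.
#' * `chronic`: (6.25, 1.5, 0.625, -0.75, 0.8) — drives relax 25% toward
#'   normal while excitatory weights strengthen 25% and inhibitory
#'   weights weaken 25%.
#' * `withdrawal`: (3.75, 2.5, 0.56, -0.875, 0.8) — excitatory drive
#'   -25%, inhibitory drive +25%, weights halfway back to normal.
#'
#' @param mode_name one of `"normal"`, `"acute"`, `"chronic"`,
#'   `"withdrawal"`.
#' @return a `mode_parameters` object.
#' @export
mode_parameters <- function(mode_name) {
  tab <- list(
    normal     = c(k_exc = 5,    k_inh = 2,   s_exc = 0.5,   s_inh = -1),
    acute      = c(k_exc = 7.5,  k_inh = 1,   s_exc = 0.5,   s_inh = -1),
    chronic    = c(k_exc = 6.25, k_inh = 1.5, s_exc = 0.625, s_inh = -0.75),
    withdrawal = c(k_exc = 3.75, k_inh = 2.5, s_exc = 0.56,  s_inh = -0.875)
  )
  if (!mode_name %in% names(tab))
    stop("unknown mode '", mode_name, "'; valid modes: ",
         paste(names(tab), collapse = ", "))
  p <- as.list(tab[[mode_name]])
  new_mode(p$k_exc, p$k_inh, p$s_exc, p$s_inh, delta = 0.8,
           glio_release_scale = 1, label = mode_name)
}

#' Construct an arbitrary mode parameter set
#'
#' @param k_exc,k_inh drive amplitudes.
#' @param s_exc,s_inh weight scales (`s_inh` nonpositive).
#' @param delta transporter-activity factor.
#' @param glio_release_scale multiplier on the gliotransmitter gain.
#' @param label optional mode label.
#' @return a `mode_parameters` object.
#' @export
new_mode <- function(k_exc, k_inh, s_exc, s_inh, delta = 0.8,
                     glio_release_scale = 1, label = "custom") {
  structure(list(k_exc = k_exc, k_inh = k_inh, s_exc = s_exc,
                 s_inh = s_inh, delta = delta,
                 glio_release_scale = glio_release_scale, label = label),
            class = "mode_parameters")
}

#' Override fields of a mode parameter set
#'
#' @param mode a `mode_parameters` object.
#' @param ... named scalar overrides (e.g. `k_exc = 3.8`).
#' @param label new label (defaults to the old label).
#' @return modified `mode_parameters`.
#' @export
mode_override <- function(mode, ..., label = mode$label) {
  ov <- list(...)
  bad <- setdiff(names(ov), c("k_exc", "k_inh", "s_exc", "s_inh",
                              "delta", "glio_release_scale"))
  if (length(bad))
    stop("unknown mode parameter(s): ", paste(bad, collapse = ", "))
  m <- modifyList(unclass(mode), ov)
  m$label <- label
  structure(m, class = "mode_parameters")
}

#' Build a protocol schedule from contiguous segments
#'
#' A schedule maps simulation time (ms) to mode parameters as a
#' piecewise-constant, half-open segmentation `[t_start, t_end)` covering
#' `[0, total_duration_ms)`.
#'
#' @param segments list of segments, each a list with `t_start_ms`,
#'   `t_end_ms`, `params` (a `mode_parameters`), and `label`.
#' @return a `schedule` object.
#' @export
make_schedule <- function(segments) {
  stopifnot(length(segments) >= 1L)
  starts <- vapply(segments, function(s) s$t_start_ms, numeric(1))
  ends <- vapply(segments, function(s) s$t_end_ms, numeric(1))
  if (starts[1] != 0) stop("schedule must start at t = 0")
  if (any(ends <= starts)) stop("segments must have positive duration")
  if (length(segments) > 1L &&
      any(abs(starts[-1] - ends[-length(ends)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  structure(list(segments = segments,
                 total_duration_ms = ends[length(ends)]),
            class = "schedule")
}

seg <- function(t0_s, t1_s, params, label = params$label) {
  list(t_start_ms = t0_s * 1000, t_end_ms = t1_s * 1000,
       params = params, label = label)
}

#' Single-mode schedule
#'
#' @param params a `mode_parameters`.
#' @param duration_ms total duration.
#' @return a `schedule` holding `params` throughout.
#' @export
constant_schedule <- function(params, duration_ms) {
  make_schedule(list(list(t_start_ms = 0, t_end_ms = duration_ms,
                          params = params, label = params$label)))
}

#' The four-mode addiction timeline
#'
#' 8-s schedule: normal `[0, 2)` s, acute `[2, 3)` s, chronic `[3, 6)` s,
#' withdrawal `[6, 8)` s. Chronic parameters are held piecewise-constant
#' at their printed values (see the methods vignette for the optional
#' ramp reading).
#'
#' @return a `schedule`.
#' @export
figure2_schedule <- function() {
  make_schedule(list(
    seg(0, 2, mode_parameters("normal")),
    seg(2, 3, mode_parameters("acute")),
    seg(3, 6, mode_parameters("chronic")),
    seg(6, 8, mode_parameters("withdrawal"))
  ))
}

#' Gliotransmitter on/off timeline for one mode
#'
#' 2-s schedule holding `mode_name`'s parameters with gliotransmitter
#' release disabled on `[0, 1)` s and enabled on `[1, 2)` s. The
#' astrocyte's internal dynamics run throughout; only the feedback
#' current is gated.
#'
#' @param mode_name canonical mode name.
#' @return a `schedule`.
#' @export
figure3_schedule <- function(mode_name) {
  m <- mode_parameters(mode_name)
  make_schedule(list(
    seg(0, 1, mode_override(m, glio_release_scale = 0,
                            label = paste0(mode_name, ":glio_off"))),
    seg(1, 2, mode_override(m, glio_release_scale = 1,
                            label = paste0(mode_name, ":glio_on")))
  ))
}

#' Chronic-mode intervention timeline
#'
#' 6-s schedule: chronic `[0, 1)` s, then chronic with one override per
#' second — excitatory drive reduced to `k_exc = 3.8` (24% below normal),
#' interneuron drive doubled to `k_inh = 4`, excitatory weights weakened
#' to `s_exc = 0.47` (6% below normal), inhibitory weights amplified to
#' `s_inh = -1.4` (40% above normal), and transporter activity enhanced
#' (`delta = 0.5`, 37.5% above normal).
#'
#' @return a `schedule`.
#' @export
figure4_schedule <- function() {
  ch <- mode_parameters("chronic")
  make_schedule(list(
    seg(0, 1, ch),
    seg(1, 2, mode_override(ch, k_exc = 3.8, label = "chronic:k_exc=3.8")),
    seg(2, 3, mode_override(ch, k_inh = 4, label = "chronic:k_inh=4")),
    seg(3, 4, mode_override(ch, s_exc = 0.47, label = "chronic:s_exc=0.47")),
    seg(4, 5, mode_override(ch, s_inh = -1.4, label = "chronic:s_inh=-1.4")),
    seg(5, 6, mode_override(ch, delta = 0.5, label = "chronic:delta=0.5"))
  ))
}

#' Withdrawal, transporter-inactivation and reduced-release timeline
#'
#' 3-s schedule: withdrawal with normal transporter activity
#' (`delta = 0.8`) on `[0, 1)` s; transporters inactive (`delta = 1`) on
#' `[1, 2)` s; transporters still inactive with gliotransmitter release
#' reduced on `[2, 3)` s. The release reduction has no canonical
#' magnitude; the default multiplier is 0.25 and is configurable.
#'
#' @param reduced_release_scale `glio_release_scale` for the final
#'   segment (default 0.25).
#' @return a `schedule`.
#' @export
figure5_schedule <- function(reduced_release_scale = 0.25) {
  w <- mode_parameters("withdrawal")
  make_schedule(list(
    seg(0, 1, w),
    seg(1, 2, mode_override(w, delta = 1, label = "withdrawal:delta=1")),
    seg(2, 3, mode_override(w, delta = 1,
                            glio_release_scale = reduced_release_scale,
                            label = "withdrawal:delta=1:glio_reduced"))
  ))
}

#' Look up the mode parameters active at a time point
#'
#' Segments are half-open `[t_start, t_end)`: a segment boundary belongs
#' to the later segment.
#'
#' @param schedule a `schedule`.
#' @param t_ms time in ms, `0 <= t_ms < total_duration_ms`.
#' @return the `mode_parameters` of the containing segment.
#' @export
parameters_at <- function(schedule, t_ms) {
  stopifnot(inherits(schedule, "schedule"))
  if (t_ms < 0 || t_ms >= schedule$total_duration_ms)
    stop(sprintf("t_ms = %g outside schedule [0, %g)", t_ms,
                 schedule$total_duration_ms))
  for (s in schedule$segments)
    if (t_ms >= s$t_start_ms && t_ms < s$t_end_ms) return(s$params)
  stop("internal error: no segment contains t_ms")  # unreachable
}

#' Resolve a named canonical schedule
#'
#' Accepts `"figure2"`, `"figure3:<mode>"`, `"figure4"`, `"figure5"`.
#'
#' @param name schedule name.
#' @return a `schedule`.
#' @export
named_schedule <- function(name) {
  if (name == "figure2") return(figure2_schedule())
  if (name == "figure4") return(figure4_schedule())
  if (name == "figure5") return(figure5_schedule())
  if (grepl("^figure3:", name))
    return(figure3_schedule(sub("^figure3:", "", name)))
  stop("unknown schedule '", name,
       "'; use figure2, figure3:<mode>, figure4 or figure5")
}

#' Serialize a schedule to a list of plain segments
#'
#' The representation round-trips exactly through JSON or YAML: each
#' segment becomes a flat record of times, label and the six mode
#' parameters.
#'
#' @param schedule a `schedule`.
#' @return list of plain segment lists.
#' @export
schedule_to_list <- function(schedule) {
  lapply(schedule$segments, function(s) {
    p <- s$params
    list(t_start_ms = s$t_start_ms, t_end_ms = s$t_end_ms,
         label = s$label, k_exc = p$k_exc, k_inh = p$k_inh,
         s_exc = p$s_exc, s_inh = p$s_inh, delta = p$delta,
         glio_release_scale = p$glio_release_scale)
  })
}

#' Rebuild a schedule from its serialized list form
#'
#' @param x list as produced by [schedule_to_list()] (or parsed from a
#'   JSON/YAML config).
#' @return a `schedule`.
#' @export
schedule_from_list <- function(x) {
  make_schedule(lapply(x, function(s) {
    list(t_start_ms = s$t_start_ms, t_end_ms = s$t_end_ms,
         params = new_mode(s$k_exc, s$k_inh, s$s_exc, s$s_inh,
                           delta = s$delta,
                           glio_release_scale = s$glio_release_scale,
                           label = s$label),
         label = s$label)
  }))
}

#' Write a schedule to a JSON or YAML file
#'
#' @param schedule a `schedule`.
#' @param path output path; format chosen by extension (`.json`, `.yaml`
#'   or `.yml`).
#' @export
write_schedule <- function(schedule, path) {
  x <- schedule_to_list(schedule)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a schedule from a JSON or YAML file
#'
#' @param path file path.
#' @return a `schedule`.
#' @export
read_schedule <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  schedule_from_list(x)
}
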