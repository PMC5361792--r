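# Configuration files (YAML), tabular trajectories (CSV), and plotting.

CONFIG_SCHEMA <- list(
  growth = c("r_N", "r_T", "r_R", "r_M", "K_N", "K_T", "K_R", "K_M",
             "kappa", "T_star"),
  transitions = c("tau", "tau1", "tau2", "tau_MR",
                  "t_tau1_on", "t_tau2_on", "t_conv_on"),
  drug1 = c("C0", "decay_rate", "t_start", "M", "a_N", "a_T", "a_TM",
            "decay_from_start"),
  drug2 = c("C0", "decay_rate", "t_start", "M", "a_TR", "decay_from_start"),
  initial_state = c("N", "T", "T_R", "T_M"),
  thresholds = c("detection", "extinction_eps")
)
CONFIG_TOP <- c("name", "preset", "model", names(CONFIG_SCHEMA),
                "horizon")
# keys that may be omitted even without a preset
CONFIG_OPTIONAL <- c("name", "preset", "drug1.decay_from_start",
                     "drug2.decay_from_start", "drug2.M")

config_from_spec <- function(spec) {
  p <- spec$params
  list(
    name = spec$name,
    model = spec$model,
    growth = p[CONFIG_SCHEMA$growth],
    transitions = list(tau = p$tau, tau1 = p$tau1, tau2 = p$tau2,
                       tau_MR = p$tau_MR,
                       t_tau1_on = spec$gates$t_tau1_on,
                       t_tau2_on = spec$gates$t_tau2_on,
                       t_conv_on = spec$gates$t_conv_on),
    drug1 = list(C0 = spec$drug1$C0, decay_rate = spec$drug1$decay_rate,
                 t_start = spec$drug1$t_start, M = spec$drug1$M,
                 a_N = spec$drug1$kill_N, a_T = spec$drug1$kill_T,
                 a_TM = spec$drug1$kill_TM,
                 decay_from_start = spec$drug1$decay_from_start),
    drug2 = list(C0 = spec$drug2$C0, decay_rate = spec$drug2$decay_rate,
                 t_start = spec$drug2$t_start, M = spec$drug2$M,
                 a_TR = spec$drug2$kill_TR,
                 decay_from_start = spec$drug2$decay_from_start),
    initial_state = list(N = spec$initial_state$N, T = spec$initial_state$T,
                         T_R = spec$initial_state$T_R,
                         T_M = spec$initial_state$T_M),
    horizon = spec$horizon,
    thresholds = list(detection = spec$detection_threshold,
                      extinction_eps = spec$extinction_eps)
  )
}

spec_from_config <- function(cfg) {
  g <- cfg$growth
  tr <- cfg$transitions
  d1 <- cfg$drug1
  d2 <- cfg$drug2
  if (is.null(d1$decay_from_start)) d1$decay_from_start <- FALSE
  if (is.null(d2$decay_from_start)) d2$decay_from_start <- FALSE
  if (is.null(d2$M)) d2$M <- d1$M # single pharmacokinetic coefficient
  scenario_spec(
    name = if (is.null(cfg$name)) "config" else cfg$name,
    model = cfg$model,
    params = model_params(r_N = g$r_N, r_T = g$r_T, r_R = g$r_R, r_M = g$r_M,
                          K_N = g$K_N, K_T = g$K_T, K_R = g$K_R, K_M = g$K_M,
                          kappa = g$kappa, T_star = g$T_star,
                          tau = tr$tau, tau1 = tr$tau1, tau2 = tr$tau2,
                          tau_MR = tr$tau_MR),
    drug1 = drug_schedule(C0 = d1$C0, t_start = d1$t_start,
                          decay_rate = d1$decay_rate, M = d1$M,
                          kill_N = d1$a_N, kill_T = d1$a_T,
                          kill_TM = d1$a_TM,
                          decay_from_start = d1$decay_from_start),
    drug2 = drug_schedule(C0 = d2$C0, t_start = d2$t_start,
                          decay_rate = d2$decay_rate, M = d2$M,
                          kill_TR = d2$a_TR,
                          decay_from_start = d2$decay_from_start),
    gates = gate_times(t_tau2_on = tr$t_tau2_on, t_conv_on = tr$t_conv_on,
                       t_tau1_on = tr$t_tau1_on),
    initial_state = population_state(N = cfg$initial_state$N,
                                     T = cfg$initial_state$T,
                                     T_R = cfg$initial_state$T_R,
                                     T_M = cfg$initial_state$T_M),
    horizon = cfg$horizon,
    detection_threshold = cfg$thresholds$detection,
    extinction_eps = cfg$thresholds$extinction_eps
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(override[[k]]) && is.list(base[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else {
      override[[k]]
    }
  }
  base
}

#' Read a scenario configuration file
#'
#' The file is a YAML document mirroring [scenario_spec()] field for
#' field (blocks `growth`, `transitions`, `drug1`, `drug2`,
#' `initial_state`, plus `model`, `horizon`, `thresholds`). Unknown keys
#' are rejected. If a `preset` key naming one of the four preset
#' scenarios is present, every other key is optional and overrides that
#' preset; otherwise the document must be complete.
#'
#' @param path path to the YAML file.
#' @return A validated [scenario_spec()].
#' @seealso [write_scenario_config()] for the inverse.
#' @export
load_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed configuration document", call. = FALSE)
  unknown <- setdiff(names(cfg), CONFIG_TOP)
  if (length(unknown)) {
    stop("unknown configuration key: ", unknown[1], call. = FALSE)
  }
  for (blk in names(CONFIG_SCHEMA)) {
    bad <- setdiff(names(cfg[[blk]]), CONFIG_SCHEMA[[blk]])
    if (length(bad)) {
      stop(sprintf("unknown configuration key: %s.%s", blk, bad[1]),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$preset)) {
    base <- config_from_spec(scenario_preset(cfg$preset))
    if (is.null(cfg$name)) cfg$name <- cfg$preset
    cfg$preset <- NULL
    cfg <- merge_config(base, cfg)
  } else {
    for (key in setdiff(c("model", "horizon"), names(cfg))) {
      stop("missing configuration key: ", key, call. = FALSE)
    }
    for (blk in names(CONFIG_SCHEMA)) {
      missing <- setdiff(paste(blk, CONFIG_SCHEMA[[blk]], sep = "."),
                         c(paste(blk, names(cfg[[blk]]), sep = "."),
                           CONFIG_OPTIONAL))
      if (length(missing)) {
        stop("missing configuration key: ", missing[1], call. = FALSE)
      }
    }
  }
  spec_from_config(cfg)
}

#' Write a scenario configuration file
#'
#' Serialises a [scenario_spec()] to the YAML layout read by
#' [load_scenario_config()]; the round trip is lossless.
#'
#' @param spec a [scenario_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  yaml::write_yaml(config_from_spec(spec), path, precision = 15L)
  invisible(path)
}

#' Write a trajectory as a CSV table
#'
#' Comma-separated, header `time,N,T,T_R,T_M`, one row per grid point,
#' times in days and counts in cells at full floating precision (the
#' written file re-reads to identical values).
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  cols <- c("time", POPULATIONS)
  txt <- vapply(cols, function(cn) sprintf("%.17g", traj[[cn]]),
                character(nrow(traj)))
  txt <- matrix(txt, nrow = nrow(traj),
                dimnames = list(NULL, cols)) # vapply drops dims for n = 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  write.table(txt, con, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV table
#'
#' @param path a file written by [write_trajectory()] (or any CSV with
#'   columns `time,N,T,T_R,T_M`).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  if (!all(c("time", POPULATIONS) %in% names(df))) {
    stop("trajectory file must have columns time,N,T,T_R,T_M",
         call. = FALSE)
  }
  trajectory(df$time, df[POPULATIONS], meta = list(source = path))
}

#' Plot the cell-population dynamics of a scenario
#'
#' One panel with the four populations over time — normal cells in
#' black, wild tumor cells in orange, mutated tumor cells in blue and
#' drug-resistant tumor cells in red — and the detection threshold as a
#' dashed horizontal reference line.
#'
#' @param result a `scenario_result` from [run_scenario()], or a
#'   [trajectory()].
#' @param path optional output file (e.g. `.pdf` or `.png`); when `NULL`
#'   the plot object is only returned.
#' @param threshold detection threshold drawn as the reference line;
#'   defaults to the scenario's when `result` is a `scenario_result`.
#' @return The ggplot object, invisibly.
#' @export
plot_scenario <- function(result, path = NULL, threshold = NULL) {
  if (inherits(result, "scenario_result")) {
    traj <- result$trajectory
    if (is.null(threshold)) threshold <- result$spec$detection_threshold
    title <- sprintf("Scenario \"%s\"", result$spec$name)
  } else if (inherits(result, "trajectory")) {
    traj <- result
    if (is.null(threshold)) threshold <- 2e5
    title <- "Cell population dynamics"
  } else {
    stop("`result` must be a scenario_result or a trajectory", call. = FALSE)
  }
  if (nrow(traj) < 2L) stop("trajectory has too few points to plot",
                            call. = FALSE)
  labels <- c(N = "normal", T = "wild tumor", T_M = "mutated tumor",
              T_R = "resistant tumor")
  colors <- c("normal" = "black", "wild tumor" = "orange",
              "mutated tumor" = "blue", "resistant tumor" = "red")
  long <- do.call(rbind, lapply(names(labels), function(p) {
    data.frame(time = traj$time, cells = traj[[p]],
               population = labels[[p]])
  }))
  long$population <- factor(long$population, levels = unname(labels))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cells,
                                          color = .data$population)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_color_manual(values = colors, name = NULL) +
    ggplot2::labs(x = "time (days)", y = "cells", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4.5)
  }
  invisible(p)
}
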