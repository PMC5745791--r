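#' Race track of action and rest pads
#'
#' @param pads ordered character vector of pad classes (three action pad
#'   types plus "REST").
#' @param pad_length pad length in distance units (default 11.25; with unit
#'   base speed one pad takes 11.25 s without commands).
#' @return An object of class `race_track`.
#' @export
race_track <- function(pads, pad_length = 11.25) {
  pads <- as.character(pads)
  if (!length(pads)) stop("a track needs at least one pad")
  if (pad_length <= 0) stop("`pad_length` must be positive")
  structure(list(pads = pads, pad_length = pad_length,
                 n_pads = length(pads)),
            class = "race_track")
}

#' @export
print.race_track <- function(x, ...) {
  tab <- table(x$pads)
  cat(sprintf("<race_track> %d pads x %g units (%s)\n", x$n_pads,
              x$pad_length, paste(sprintf("%s=%d", names(tab), tab),
                                  collapse = ", ")))
  invisible(x)
}

#' Generate a pseudorandom track with exact per-class pad counts
#'
#' @param trials_per_class pads per class (5 for training, 4 in competition
#'   settings).
#' @param classes pad classes (default HAND, FEET, SUB, REST).
#' @param pad_length pad length in distance units.
#' @param seed shuffle seed; identical seeds give identical pad orders.
#' @return A [race_track()] with `trials_per_class * length(classes)` pads.
#' @export
generate_track <- function(trials_per_class = 5,
                           classes = c("HAND", "FEET", "SUB", "REST"),
                           pad_length = 11.25, seed = 1) {
  if (trials_per_class < 1) stop("`trials_per_class` must be >= 1")
  pads <- with_seed(seed, sample(rep(classes, times = trials_per_class)))
  tr <- race_track(pads, pad_length)
  tr$trials_per_class <- trials_per_class
  tr
}

#' Avatar dynamics configuration
#'
#' On action pads the avatar moves at `base_speed * boost_factor` while the
#' correct command is active, at `base_speed * slow_factor` for a wrong
#' command, and at `base_speed` with no command.  On rest pads there is no
#' correct command and any action command slows the avatar.  A command's
#' effect lasts one decision tick.
#'
#' @param base_speed distance units per second without commands.
#' @param boost_factor speed multiplier for correct commands (> 1).
#' @param slow_factor multiplier for wrong commands (in (0, 1)).
#' @param tick decision tick length in seconds (default 1/16).
#' @return An object of class `race_config`.
#' @export
race_config <- function(base_speed = 1, boost_factor = 2, slow_factor = 0.5,
                        tick = 1 / 16) {
  if (!(boost_factor > 1 && slow_factor > 0 && slow_factor < 1))
    stop("need boost_factor > 1 > slow_factor > 0")
  if (base_speed <= 0 || tick <= 0) stop("speeds and tick must be positive")
  structure(list(base_speed = base_speed, boost_factor = boost_factor,
                 slow_factor = slow_factor, tick = tick),
            class = "race_config")
}

speed_factor <- function(cmd, pad_class, cfg) {
  if (is.na(cmd) || cmd == "none" || cmd == "REST") return(1)
  if (pad_class == "REST") return(cfg$slow_factor)
  if (cmd == pad_class) return(cfg$boost_factor)
  cfg$slow_factor
}

cmd_outcome <- function(cmd, pad_class) {
  if (is.na(cmd) || cmd == "none" || cmd == "REST") return("none")
  if (pad_class == "REST") return("wrong")
  if (cmd == pad_class) return("correct")
  "wrong"
}

#' Run a simulated race
#'
#' Advances the avatar tick by tick; the command active in a tick is either
#' taken from a `command_stream` (the latest command no older than one tick)
#' or, for closed-loop policies, obtained by calling
#' `commands(tick_time, current_pad_class)`.  Pad crossings within a tick are
#' integrated exactly, and the race ends the instant the last pad is
#' traversed.
#'
#' @param track a [race_track()].
#' @param cfg a [race_config()].
#' @param commands a `command_stream` data frame (`time`, `command`) as
#'   produced by [decide()], or a function `(time, pad_class) -> command`.
#' @return An object of class `race_result`: `runtime` (s), `counts`
#'   (correct / wrong / none ticks), `pad_log` (per-pad traversal times and
#'   command counts), `track`.
#' @export
run_race <- function(track, cfg, commands) {
  stopifnot(inherits(track, "race_track"), inherits(cfg, "race_config"))
  use_fun <- is.function(commands)
  if (!use_fun) {
    stopifnot(is.data.frame(commands))
    if (is.unsorted(commands$time)) stop("commands must be time-ordered")
    cmd_t <- commands$time
    cmd_v <- commands$command
  }
  L <- track$pad_length
  total <- track$n_pads * L
  tick <- cfg$tick
  t <- 0; pos <- 0
  counts <- c(correct = 0L, wrong = 0L, none = 0L)
  pad_enter <- numeric(track$n_pads)
  pad_counts <- matrix(0L, track$n_pads, 3,
                       dimnames = list(NULL, c("correct", "wrong", "none")))
  pad_enter[1] <- 0
  t_max <- 10 * total / (cfg$base_speed * cfg$slow_factor)
  last_pad <- 1L
  while (pos < total && t < t_max) {
    pad <- min(track$n_pads, floor(pos / L) + 1L)
    pad_class <- track$pads[pad]
    cmd <- if (use_fun) {
      commands(t, pad_class)
    } else {
      i <- findInterval(t + 1e-9, cmd_t)
      if (i >= 1 && cmd_t[i] > t - tick + 1e-9) cmd_v[i] else "none"
    }
    oc <- cmd_outcome(cmd, pad_class)
    counts[oc] <- counts[oc] + 1L
    pad_counts[pad, oc] <- pad_counts[pad, oc] + 1L
    tick_end <- t + tick
    while (t < tick_end - 1e-12 && pos < total) {
      pad <- min(track$n_pads, floor(pos / L) + 1L)
      if (pad != last_pad) { pad_enter[pad] <- t; last_pad <- pad }
      v <- cfg$base_speed * speed_factor(cmd, track$pads[pad], cfg)
      d_bound <- (pad * L - pos) / v
      dt <- min(tick_end - t, d_bound)
      pos <- pos + v * dt
      t <- t + dt
    }
  }
  pad_exit <- c(pad_enter[-1], t)
  pad_log <- data.frame(pad = seq_len(track$n_pads), class = track$pads,
                        enter = pad_enter, traversal = pad_exit - pad_enter,
                        pad_counts)
  structure(list(runtime = t, counts = counts, pad_log = pad_log,
                 track = track, finished = pos >= total),
            class = "race_result")
}

#' @export
print.race_result <- function(x, ...) {
  cat(sprintf("<race_result> runtime %.1f s over %d pads (ticks: %d correct, %d wrong, %d none)\n",
              x$runtime, x$track$n_pads, x$counts["correct"],
              x$counts["wrong"], x$counts["none"]))
  invisible(x)
}

#' Command policy with a fixed per-tick correctness probability
#'
#' With probability `p` the policy issues the correct command for the current
#' pad (no command on rest pads); otherwise it issues a uniformly random
#' wrong action command.  Useful for calibration curves of runtime versus
#' command accuracy.
#'
#' @param p per-tick correctness probability.
#' @param classes action classes (REST excluded automatically).
#' @return A function `(time, pad_class) -> command` for [run_race()].
#' @export
accuracy_policy <- function(p, classes = c("HAND", "FEET", "SUB", "REST")) {
  actions <- setdiff(classes, "REST")
  function(time, pad_class) {
    if (stats::runif(1) < p) {
      if (pad_class == "REST") "none" else pad_class
    } else {
      sample(setdiff(actions, pad_class), 1)
    }
  }
}

#' Median runtime of the race under uniformly random input
#'
#' Simulates `n_runs` races whose command at every decision tick is drawn
#' uniformly from the class set (rest predictions send no command); the
#' median runtime is the significance baseline a working BCI has to beat.
#'
#' @param track_spec a fixed [race_track()], or a pads-per-class count from
#'   which a fresh track is shuffled for every run.
#' @param cfg a [race_config()].
#' @param n_runs number of simulated races (>= 100).
#' @param classes command classes drawn from.
#' @param seed RNG seed.
#' @return List: `median` runtime (s), `runtimes` (per run).
#' @export
random_baseline <- function(track_spec, cfg, n_runs = 1000,
                            classes = c("HAND", "FEET", "SUB", "REST"),
                            seed = 1) {
  if (n_runs < 100) stop("`n_runs` must be at least 100")
  fixed <- inherits(track_spec, "race_track")
  runtimes <- with_seed(seed, {
    vapply(seq_len(n_runs), function(i) {
      track <- if (fixed) track_spec else
        race_track(sample(rep(classes, times = track_spec)))
      policy <- function(time, pad_class) sample(classes, 1)
      run_race(track, cfg, policy)$runtime
    }, numeric(1))
  })
  list(median = stats::median(runtimes), runtimes = runtimes)
}

#' Training-paradigm trigger events for a track
#'
#' One task-onset trigger per pad at pad entry (coded with the pad class) and
#' a break marker at half-pad, matching a training protocol of task
#' performance on the first half of each pad and relaxation on the second
#' half under no-command dynamics.
#'
#' @param track a [race_track()].
#' @param cfg a [race_config()]; pad traversal time `pad_length/base_speed`
#'   must be at least 10 s (5 s task + 5 s break).
#' @return data frame `time`, `code` with strictly increasing times.
#' @export
paradigm_triggers <- function(track, cfg) {
  stopifnot(inherits(track, "race_track"), inherits(cfg, "race_config"))
  pad_t <- track$pad_length / cfg$base_speed
  if (pad_t < 10)
    stop("pad traversal time ", round(pad_t, 2),
         " s is too short for the 5 s task + 5 s break paradigm")
  onset <- (seq_len(track$n_pads) - 1) * pad_t
  ev <- rbind(data.frame(time = onset, code = track$pads),
              data.frame(time = onset + pad_t / 2, code = "break"))
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  ev
}
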