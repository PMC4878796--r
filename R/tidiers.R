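# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation trace
#'
#' @param x A `petri_trace` from [simulate_net()].
#' @param ... Unused.
#' @return A tibble with columns `step` (0..steps), `place`, `tokens`.
#' @method tidy petri_trace
#' @export
tidy.petri_trace <- function(x, ...) {
  tibble::tibble(
    step = rep(0:x$steps, times = length(x$places)),
    place = rep(x$places, each = x$steps + 1L),
    tokens = as.integer(x$markings)
  )
}

#' Tidy the per-step firing counts of a trace
#'
#' @inheritParams tidy.petri_trace
#' @return A tibble with columns `step` (1..steps), `transition`, `count`.
#' @export
firings_of <- function(x, ...) {
  stopifnot(inherits(x, "petri_trace"))
  tibble::tibble(
    step = rep(seq_len(x$steps), times = length(x$transitions)),
    transition = rep(x$transitions, each = x$steps),
    count = as.integer(x$firings)
  )
}

#' One-row summary of a trace
#'
#' @inheritParams tidy.petri_trace
#' @return A tibble with `steps`, `n_places`, `n_transitions`, `seed`,
#'   `total_tokens_final`.
#' @method glance petri_trace
#' @export
glance.petri_trace <- function(x, ...) {
  tibble::tibble(
    steps = x$steps,
    n_places = length(x$places),
    n_transitions = length(x$transitions),
    seed = x$seed,
    total_tokens_final = sum(x$markings[x$steps + 1L, ])
  )
}

#' @method tidy ensemble_summary
#' @export
tidy.ensemble_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("step", "mean", "sd")])
}

#' @method glance ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...) {
  tibble::tibble(
    steps = max(x$step),
    replicates = attr(x, "replicates"),
    base_seed = attr(x, "base_seed"),
    final_mean = x$mean[which.max(x$step)],
    final_sd = x$sd[which.max(x$step)]
  )
}

#' @method tidy wnt_sweep
#' @export
tidy.wnt_sweep <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)))
}

#' Endpoint summary of a sweep
#'
#' One row per swept parameter value with the ensemble mean and standard
#' deviation at the final step.
#'
#' @param x A `wnt_sweep`.
#' @param ... Unused.
#' @return A tibble with the sweep parameter column(s), `final_mean` and
#'   `final_sd`.
#' @method glance wnt_sweep
#' @export
glance.wnt_sweep <- function(x, ...) {
  param <- attr(x, "param")
  last <- max(x$step)
  d <- tibble::as_tibble(as.data.frame(unclass(x)))
  d <- d[d$step == last, , drop = FALSE]
  out <- d[, param, drop = FALSE]
  out$final_mean <- d$mean
  out$final_sd <- d$sd
  out
}

#' Plot an ensemble summary as mean with SD ribbon
#'
#' @param object An `ensemble_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ensemble_summary
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$step, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation step", y = "observable (tokens)")
}

#' Plot a sweep, one curve per parameter value
#'
#' @param object A `wnt_sweep`.
#' @param ... Unused.
#' @return A ggplot object; feedback sweeps are facetted by WNT level.
#' @method autoplot wnt_sweep
#' @export
autoplot.wnt_sweep <- function(object, ...) {
  param <- attr(object, "param")
  d <- tidy(object)
  if (length(param) == 2L) {
    p <- ggplot2::ggplot(
      d, ggplot2::aes(x = .data$step, y = .data$mean,
                      colour = factor(.data$feedback))
    ) +
      ggplot2::facet_wrap(ggplot2::vars(.data$wnt), labeller = "label_both") +
      ggplot2::labs(colour = "feedback")
  } else {
    p <- ggplot2::ggplot(
      d, ggplot2::aes(x = .data$step, y = .data$mean,
                      colour = factor(.data[[param]]))
    ) +
      ggplot2::labs(colour = param)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "simulation step",
                  y = "total β-catenin (tokens, ensemble mean)")
}

#' Plot the token time course of selected places in one trace
#'
#' @param trace A `petri_trace`.
#' @param places Character vector of places to show (default: all with any
#'   tokens during the run).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, places = NULL) {
  stopifnot(inherits(trace, "petri_trace"))
  d <- tidy(trace)
  if (is.null(places)) {
    keep <- vapply(split(d$tokens, d$place), function(v) any(v > 0), logical(1))
    places <- names(keep)[keep]
  }
  d <- d[d$place %in% places, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$tokens,
                                  colour = .data$place)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "simulation step", y = "tokens")
}

#' @importFrom rlang .data :=
NULL
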