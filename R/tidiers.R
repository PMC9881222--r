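#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a test result
#'
#' One row per comparison for post-hoc procedures, one row for two-sample
#' and omnibus tests.
#'
#' @param x An `fp_stat`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fp_stat
#' @export
tidy.fp_stat <- function(x, ...) {
  if (!is.null(x$comparisons)) {
    out <- mutate(x$comparisons, test = x$test, method = x$method)
    return(dplyr::relocate(out, "test"))
  }
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n = paste(x$n, collapse = "/"), method = x$method,
         stars = p_stars(x$p_value))
}

#' @rdname tidy.fp_stat
#' @method glance fp_stat
#' @export
glance.fp_stat <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         method = x$method,
         n_comparisons = if (is.null(x$comparisons)) 0L else nrow(x$comparisons))
}

#' Tidy a session summary
#'
#' @param x An `fp_session`.
#' @param ... Unused.
#' @return One-row tibble with validity, event count and metrics.
#' @method tidy fp_session
#' @export
tidy.fp_session <- function(x, ...) {
  dplyr::bind_cols(
    tibble(session_id = x$session_id, condition = x$condition,
           n_events = x$n_events, valid = x$valid, reason = x$reason),
    x$metrics %||% tibble(.rows = 1)
  )
}

#' @rdname tidy.fp_session
#' @method glance fp_session
#' @export
glance.fp_session <- function(x, ...) {
  tibble(n_events = x$n_events, valid = x$valid)
}

#' Long-format view of an event-aligned ensemble
#'
#' @param x An `fp_ensemble`.
#' @param ... Unused.
#' @return The ensemble's long tibble (`event_id`, `onset`, `time`,
#'   `value`, carried event columns).
#' @method as_tibble fp_ensemble
#' @export
as_tibble.fp_ensemble <- function(x, ...) ensemble_long(x)

#' Plot an event-aligned ensemble
#'
#' Individual snippets as thin lines plus the event mean.
#'
#' @param object An `fp_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fp_ensemble
#' @export
autoplot.fp_ensemble <- function(object, ...) {
  long <- ensemble_long(object)
  mean_df <- tibble(time = object$time,
                    value = colMeans(object$snippets))
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$time, .data$value,
                               group = .data$event_id)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, ggplot2::aes(group = NULL),
                       linewidth = 0.8, colour = "#d95f02") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event (s)", y = "normalized signal")
}

#' Plot a group-average trace with its SEM ribbon
#'
#' @param object An `fp_group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fp_group
#' @export
autoplot.fp_group <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event (s)",
                  y = "normalized signal (mean ± SEM)")
}

#' Plot a hypnogram
#'
#' @param object An `fp_hypnogram` or `sim_hypnogram`.
#' @param ... Unused.
#' @return A ggplot object (step plot of state over time).
#' @method autoplot fp_hypnogram
#' @export
autoplot.fp_hypnogram <- function(object, ...) {
  df <- mutate(object$seconds,
               level = match(.data$state, c("rem", "nrem", "wake")))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$level)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = c("REM", "NREM", "Wake")) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @rdname autoplot.fp_hypnogram
#' @method autoplot sim_hypnogram
#' @export
autoplot.sim_hypnogram <- autoplot.fp_hypnogram

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
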