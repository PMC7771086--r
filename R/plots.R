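# ggplot2 visualisations of entropy profiles and per-position
# observable summaries.

#' Plot a cleavage-entropy profile
#'
#' @param object a `subsites_entropy`.
#' @param ... unused.
#' @return a ggplot: H(j) per substrate position.
#' @export
autoplot.subsites_entropy <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$H)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "substrate position", y = "H(j) (base-20)",
                  title = "Per-position cleavage entropy") +
    ggplot2::theme_minimal()
}

#' Plot per-position observable averages
#'
#' One panel per observable, positions P4 to P4' on the x axis.
#'
#' @param object a `subsites_observables`.
#' @param normalized plot min-max normalised averages instead of raw
#'   averages.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.subsites_observables <- function(object, normalized = FALSE, ...) {
  dat <- object$position
  y <- if (normalized) "normalized" else "mean"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position,
                                    y = .data[[y]], group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "substrate position",
                  y = if (normalized) "normalised average" else "average",
                  title = "Per-position structural observables") +
    ggplot2::theme_minimal()
}

#' Overlay observable and entropy profiles
#'
#' Plots one observable's min-max normalised per-position profile next
#' to the (also normalised) entropy profile, the comparison behind the
#' per-position rank correlations.
#'
#' @param observables a `subsites_observables`.
#' @param entropy a `subsites_entropy`.
#' @param observable which observable to overlay.
#' @return a ggplot.
#' @export
plot_observable_vs_entropy <- function(observables, entropy,
                                       observable = "rel_asa") {
  prof <- position_profile(observables, observable)
  h <- tidy(entropy)
  hrange <- range(h$H)
  h$normalized <- if (diff(hrange) > 0) {
    (h$H - hrange[1]) / diff(hrange)
  } else rep(0.5, nrow(h))
  dat <- bind_rows(
    tibble(position = prof$position, value = prof$normalized,
           series = observable),
    tibble(position = h$position, value = h$normalized,
           series = "entropy H(j)")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$value,
                                    colour = .data$series, group = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "substrate position", y = "min-max normalised value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
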