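#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_errorbar labs theme_minimal scale_fill_brewer
#' @export
ggplot2::autoplot

#' Tidy a fitted DMS model
#'
#' One row per variant with the posterior summary of its functional score,
#' in the usual estimate/std.error/conf.low/conf.high layout, plus the local
#' false sign rate.
#'
#' @param x A `dms_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dms_fit
#' @export
tidy.dms_fit <- function(x, ...) {
  x$scores |>
    dplyr::transmute(
      term = .data$variant_id,
      position = .data$position,
      mclass = .data$mclass,
      estimate = .data$beta_mean,
      std.error = .data$beta_sd,
      conf.low = .data$beta_q05,
      conf.high = .data$beta_q95,
      lfsr = .data$lfsr
    )
}

#' One-row summary of a fitted DMS model
#'
#' @param x A `dms_fit`.
#' @param ... Unused.
#' @return A tibble with the model id, dimensions, worst split-R-hat,
#'   smallest effective sample size, and the variance shares.
#' @method glance dms_fit
#' @export
glance.dms_fit <- function(x, ...) {
  dec <- variance_decomposition(x)
  d <- x$diagnostics
  tibble(
    model = x$model,
    n_variants = nrow(x$scores),
    n_positions = nrow(x$positions),
    chains = x$chains,
    draws = x$iter * x$chains,
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_ess = min(d$ess, na.rm = TRUE),
    share_position = dec$share_position,
    share_aa = dec$share_aa,
    share_unexplained = dec$share_unexplained
  )
}

#' Position-landscape plot of a fitted model
#'
#' The package's signature diagnostic view: one point per residue position,
#' position effect on x, activation score on y (model 3), point size by
#' residual variance. A downward-parabola cloud indicates interacting
#' position and substitution effects; a horizontal band at 0.5 indicates
#' uninformative substitution signal.
#'
#' @param object A `dms_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dms_fit
#' @export
autoplot.dms_fit <- function(object, ...) {
  ps <- object$positions |> filter(.data$type == "residue")
  if (object$model == 3) {
    ggplot(ps, aes(x = .data$phi_mean, y = .data$rho_mean,
                   size = .data$sigma2_mean)) +
      geom_point(alpha = 0.7) +
      labs(x = "position effect (phi)", y = "activation score (rho)",
           size = "residual\nvariance") +
      theme_minimal()
  } else {
    ggplot(ps, aes(x = .data$phi_mean, y = .data$sigma2_mean)) +
      geom_point(alpha = 0.7) +
      labs(x = "position effect (phi)", y = "residual variance (sigma^2)") +
      theme_minimal()
  }
}

#' Stacked-bar view of a variance decomposition
#'
#' @param object A `dms_decomposition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dms_decomposition
#' @export
autoplot.dms_decomposition <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::starts_with("share_"),
                        names_to = "component", values_to = "share") |>
    mutate(component = sub("^share_", "", .data$component))
  ggplot(long, aes(x = factor(.data$model), y = .data$share,
                   fill = .data$component)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "model", y = "share of score variance", fill = NULL) +
    theme_minimal()
}
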