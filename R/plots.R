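#' Trace plot of the variance-component chains
#'
#' One panel per variance (diagonal of G and R), the usual first look at
#' mixing of a variance-component Gibbs chain.
#'
#' @param object An `mtm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mtm_fit <- function(object, ...) {
  traits <- object$traits
  keep <- c(tri_names(traits, "G")[tri_diag_pos(length(traits))],
            tri_names(traits, "R")[tri_diag_pos(length(traits))])
  long <- tidyr::pivot_longer(object$chain[c("iter", keep)],
                              -"iter", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "sampled value",
                  title = "Variance-component traces") +
    ggplot2::theme_minimal()
}

#' Posterior densities of the structural coefficients
#'
#' @param object An `rm_chain` from [transform_chain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rm_chain <- function(object, ...) {
  lam_cols <- grep("^lambda_", names(object), value = TRUE)
  if (length(lam_cols) == 0) stop("no structural coefficients in this chain")
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[lam_cols],
                              dplyr::everything(),
                              names_to = "coefficient")
  long$coefficient <- sub("^lambda_", "", sub("_to_", " → ",
                                              long$coefficient))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~coefficient, scales = "free") +
    ggplot2::labs(x = expression(lambda), y = "posterior density",
                  title = "Structural coefficients") +
    ggplot2::theme_minimal()
}

#' Point-range plot of a posterior summary
#'
#' Means with +/- 2 posterior-SD intervals for a chosen component of a
#' [summarize_chain()] table.
#'
#' @param summary A summary tibble.
#' @param component One of the values in `summary$component`.
#' @return A ggplot object.
#' @export
plot_summary <- function(summary, component = "heritability") {
  sub <- summary[summary$component == component, ]
  if (nrow(sub) == 0) stop("component not present in summary")
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$parameter, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                          ymax = .data$mean + 2 * .data$sd)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior mean ± 2 SD",
                  title = component) +
    ggplot2::theme_minimal()
}
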