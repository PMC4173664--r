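#' Tidy an LDC validation report
#'
#' @param x an `ldc_validation`.
#' @param ... unused.
#' @return long tibble: `truth`, `predicted`, `mean_percent`, `sd_percent`.
#' @export
tidy.ldc_validation <- function(x, ...) {
  m <- as.data.frame(as.table(x$mean))
  s <- as.data.frame(as.table(x$sd))
  tibble::tibble(
    predicted = as.character(m$predicted),
    truth = as.character(m$truth),
    mean_percent = m$Freq,
    sd_percent = s$Freq
  )
}

#' One-row summary of an LDC validation report
#'
#' @param x an `ldc_validation`.
#' @param ... unused.
#' @export
glance.ldc_validation <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter,
    accuracy_mean = mean(x$accuracies),
    accuracy_sd = sd(x$accuracies),
    diagonal_mean = mean(diag(x$mean)),
    pcs_retained = median(x$k_retained),
    n_classes = length(x$classes)
  )
}

#' Confusion-matrix heatmap for an LDC validation report
#'
#' @param object an `ldc_validation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ldc_validation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                   fill = .data$mean_percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f±%.1f", .data$mean_percent, .data$sd_percent)
    ), color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "%") +
    ggplot2::labs(x = "True class", y = "Predicted class",
                  title = "Mean confusion matrix over validation splits")
}

#' Tidy an EDR decomposition
#'
#' @param x an `edr_decomposition`.
#' @param ... unused.
#' @return the SCR event tibble.
#' @export
tidy.edr_decomposition <- function(x, ...) x$scr_events

#' One-row summary of an EDR decomposition
#'
#' @param x an `edr_decomposition`.
#' @param ... unused.
#' @export
glance.edr_decomposition <- function(x, ...) {
  tibble::tibble(
    n_scr = nrow(x$scr_events),
    mean_tonic = mean(x$signal$tonic),
    driver_area = sum(x$signal$driver) / x$fs,
    negativity_clipped_frac = x$residual$negativity_clipped_frac,
    tau1 = x$params$tau1,
    tau2 = x$params$tau2
  )
}

#' Plot an EDR decomposition
#'
#' Conductance, tonic component and phasic driver in aligned panels, with
#' detected SCR onsets marked.
#'
#' @param object an `edr_decomposition`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.edr_decomposition <- function(object, ...) {
  sig <- object$signal
  long <- dplyr::bind_rows(
    tibble::tibble(time = sig$time, value = sig$edr, component = "conductance (uS)"),
    tibble::tibble(time = sig$time, value = sig$tonic, component = "tonic (uS)"),
    tibble::tibble(time = sig$time, value = sig$driver, component = "phasic driver (uS/s)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL)
  if (nrow(object$scr_events)) {
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(time = object$scr_events$onset_time,
                            component = "phasic driver (uS/s)"),
      ggplot2::aes(xintercept = .data$time),
      linetype = "dotted", color = "red", alpha = 0.6
    )
  }
  p
}

#' Trial-by-trial conditioned-response curves
#'
#' Group means (+/- SEM) of the normalized first-interval amplitude sum per
#' trial, faceted by session, one line per CS type.
#'
#' @param trials a trial table from [build_trial_table()].
#' @return a ggplot.
#' @export
plot_conditioning_curves <- function(trials) {
  tw <- edr_block_stats(trials)$trialwise
  ggplot2::ggplot(tw, ggplot2::aes(x = .data$trial, y = .data$mean,
                                   color = .data$cs_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = "Trial", y = "Normalized amplitude sum",
                  color = "CS type")
}
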