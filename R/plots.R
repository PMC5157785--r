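#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a posterior-median dose-toxicity surface
#'
#' Tile map of the posterior-median DLT probability over the dose grid,
#' annotated with the values; combinations within the MTD window
#' `Gamma +/- epsilon` are outlined.
#'
#' @param object A `tox_summary`.
#' @param epsilon Half-width of the highlighted MTD window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tox_summary <- function(object, epsilon = 0.025, ...) {
  df <- tidy(object)
  df$near_target <- df$distance <= epsilon
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$a_idx),
                                   y = factor(.data$b_idx))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$median), colour = "grey40") +
    ggplot2::geom_tile(data = df[df$near_target, ], fill = NA,
                       colour = "black", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$median)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "dose level of drug A", y = "dose level of drug B",
                  fill = "P(DLT)",
                  title = "Posterior median DLT probability") +
    ggplot2::theme_minimal()
}

#' Plot a true scenario surface
#'
#' @param object A `scenario`.
#' @param Gamma Target toxicity level used to outline near-target
#'   combinations.
#' @param epsilon Half-width of the highlighted window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario <- function(object, Gamma = 0.25, epsilon = 0.025, ...) {
  J <- nrow(object$true_pi); K <- ncol(object$true_pi)
  df <- tibble::tibble(
    a_idx = rep(seq_len(J), K), b_idx = rep(seq_len(K), each = J),
    p = as.vector(object$true_pi)
  )
  df$near_target <- abs(df$p - Gamma) <= epsilon
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$a_idx),
                                   y = factor(.data$b_idx))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$p), colour = "grey40") +
    ggplot2::geom_tile(data = df[df$near_target, ], fill = NA,
                       colour = "black", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "dose level of drug A", y = "dose level of drug B",
                  fill = "P(DLT)", title = object$name) +
    ggplot2::theme_minimal()
}

#' Plot operating characteristics
#'
#' Side-by-side bars of the experimentation and MTD-recommendation
#' percentages by true-DLT-probability bin.
#'
#' @param object A `tox_oc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tox_oc <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$experimentation, what = "patients treated"),
    dplyr::mutate(object$mtd_distribution, what = "MTD recommendations")
  )
  df$bin <- factor(df$bin, levels = object$experimentation$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$pct,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "true DLT probability", y = "percent", fill = NULL,
                  title = paste0("Operating characteristics: ",
                                 object$scenario)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a single trial trajectory
#'
#' Dose path over cohorts, with DLT outcomes marked.
#'
#' @param object A `trial_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_result <- function(object, ...) {
  df <- object$patients
  df$outcome_lab <- factor(df$outcome, levels = 0:2,
                           labels = c("no DLT", "DLT before t_B",
                                      "DLT after t_B"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$a_idx, colour = "drug A")) +
    ggplot2::geom_step(ggplot2::aes(y = .data$b_idx, colour = "drug B")) +
    ggplot2::geom_point(data = df[df$outcome != 0L, ],
                        ggplot2::aes(y = .data$a_idx,
                                     shape = .data$outcome_lab), size = 2) +
    ggplot2::labs(x = "patient", y = "dose level", colour = NULL,
                  shape = NULL, title = "Trial dose path") +
    ggplot2::theme_minimal()
}
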