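#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' sample score traces, convergence curves, decoy landscapes and the
#' scattering degeneracy experiment.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name msxtal-autoplot
NULL

#' @rdname msxtal-autoplot
#' @method autoplot msx_sample
#' @export
autoplot.msx_sample <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td[!td$polished, ],
                  ggplot2::aes(x = .data$step, y = .data$score,
                               group = .data$trajectory,
                               colour = factor(.data$w_xray))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(data = td[td$polished, ], shape = 4, size = 2) +
    ggplot2::labs(x = "dynamics step", y = "score S",
                  colour = "w_xray") +
    ggplot2::theme_minimal()
}

#' @rdname msxtal-autoplot
#' @method autoplot convergence_curve
#' @export
autoplot.convergence_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "trajectories in subsample",
                  y = paste("best", attr(object, "criterion"))) +
    ggplot2::theme_minimal()
}

#' @rdname msxtal-autoplot
#' @method autoplot decoy_landscape
#' @export
autoplot.decoy_landscape <- function(object, ...) {
  ggplot2::ggplot(object[!object$native, ],
                  ggplot2::aes(x = .data$accuracy, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_point(data = object[object$native, ], colour = "red",
                        shape = 4, size = 4, stroke = 2) +
    ggplot2::labs(x = "accuracy (RMSD* to native, Å)",
                  y = "joint negative log-likelihood") +
    ggplot2::theme_minimal()
}

#' @rdname msxtal-autoplot
#' @method autoplot degeneracy_result
#' @export
autoplot.degeneracy_result <- function(object, ...) {
  labs <- c("1: per-cell random", "2: two blocks", "3: partial occupancy",
            "4: labels swapped", "5: per-atom random")
  df <- object
  df$configuration <- factor(labs[df$config], levels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$error,
                                   colour = .data$configuration)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "unit cells per axis",
                  y = "mean normalized amplitude error") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
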