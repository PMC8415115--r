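#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: obstacle fields (with the node-level conduction mask respecting
#' diagonal cracks), RVI maps, saliency maps, per-density re-entry
#' probability curves and classifier training history.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot.
#' @name fibroblock-autoplot
NULL

#' @rdname fibroblock-autoplot
#' @export
autoplot.fibrosis_pattern <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(object$n_rows),
                           col = seq_len(object$n_cols))
  df$obstacle <- as.vector(object$occupancy[cbind(df$row, df$col)]) == 1L
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$obstacle)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "grey15"),
                               name = "obstacle") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "element column", y = "element row",
                  title = sprintf("fibrosis pattern (rho = %s)", format(object$rho)))
}

#' @rdname fibroblock-autoplot
#' @export
autoplot.rvi_map <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$rvi <- as.vector(m[cbind(df$row, df$col)])
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$rvi)),
                  ggplot2::aes(.data$col, .data$row, fill = .data$rvi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  midpoint = 0, name = "RVI (ms)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "node column", y = "node row",
                  title = "re-entry vulnerability index")
}

#' @rdname fibroblock-autoplot
#' @export
autoplot.saliency_map <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$weight <- as.vector(m[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "|d score / d element|") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "element column", y = "element row",
                  title = "gradient saliency")
}

#' @rdname fibroblock-autoplot
#' @export
autoplot.protocol_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_rho,
                            c("p_reentry_realisation", "p_reentry_simulation"),
                            names_to = "granularity", values_to = "probability")
  df$granularity <- sub("p_reentry_", "per ", df$granularity)
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, .data$probability,
                                   colour = .data$granularity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "obstruction density rho", y = "re-entry probability",
                  title = "re-entry probability vs fibrosis density")
}

#' @rdname fibroblock-autoplot
#' @export
autoplot.fibro_mlp <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "classifier training history",
                  y = "binary cross-entropy")
}

#' @rdname fibroblock-autoplot
#' @export
autoplot.ap_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$u)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "potential u (dimensionless)",
                  title = "single-cell action potential")
}
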