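#' Consensus summary of a fitted chain
#'
#' Computes the posterior similarity matrix from the recorded draws and picks
#' the PEAR-optimal draw as the single consensus partition.
#'
#' @param fit a `tip_fit` from [run_tip()] or [run_epa()].
#' @return object of class `tip_consensus`: list with `assignment`,
#'   `pear_value`, `argmax_index`, `pear_trace`, `Bbar`, `K`, `subject_ids`.
#' @export
tip_consensus <- function(fit) {
  stopifnot(inherits(fit, "tip_fit"))
  Bbar <- posterior_similarity(fit$draws)
  sel <- select_consensus(fit$draws, Bbar)
  structure(c(sel, list(Bbar = Bbar, K = max(sel$assignment),
                        subject_ids = fit$subject_ids)),
            class = "tip_consensus")
}

#' @export
print.tip_fit <- function(x, ...) {
  cat("<tip_fit> prior =", x$prior, "| n =", ncol(x$draws),
      "| draws =", nrow(x$draws), "(burn-in", x$config$burn_in, ")\n")
  cat("K trace (recorded draws): ",
      paste(range(utils::tail(x$K_trace, nrow(x$draws))), collapse = "-"), "\n")
  invisible(x)
}

#' @export
print.tip_consensus <- function(x, ...) {
  cat("<tip_consensus> K =", x$K, "| PEAR =", format(x$pear_value, digits = 4),
      "| draw", x$argmax_index, "\n")
  invisible(x)
}

#' Tidy a fitted chain into per-subject consensus assignments
#'
#' @param x a `tip_fit`.
#' @param ... unused.
#' @return tibble with `subject_id` and consensus `cluster`.
#' @export
tidy.tip_fit <- function(x, ...) {
  cons <- tip_consensus(x)
  tibble::tibble(subject_id = x$subject_ids,
                 cluster = cons$assignment)
}

#' @rdname tidy.tip_fit
#' @export
tidy.tip_consensus <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_ids, cluster = x$assignment)
}

#' One-row summary of a fitted chain
#'
#' @param x a `tip_fit`.
#' @param ... unused.
#' @return tibble with the prior, consensus cluster count, PEAR value, and
#'   sampler settings.
#' @export
glance.tip_fit <- function(x, ...) {
  cons <- tip_consensus(x)
  tibble::tibble(prior = x$prior, n = ncol(x$draws), K = cons$K,
                 pear = cons$pear_value, samples = nrow(x$draws),
                 burn_in = x$config$burn_in,
                 seed = x$config$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trace plot of the cluster count along the chain
#'
#' @param object a `tip_fit`.
#' @param ... unused.
#' @return a ggplot object; the burn-in boundary is marked.
#' @export
autoplot.tip_fit <- function(object, ...) {
  df <- tibble::tibble(t = seq_along(object$K_trace), K = object$K_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$K)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$config$burn_in,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "iteration", y = "number of clusters K") +
    ggplot2::theme_minimal()
}

#' Heatmap of a posterior similarity matrix
#'
#' @param Bbar posterior similarity matrix, or a `tip_consensus`.
#' @param order optional subject order (e.g. by consensus cluster) for a
#'   block-diagonal display.
#' @return a ggplot object.
#' @export
plot_psm <- function(Bbar, order = NULL) {
  if (inherits(Bbar, "tip_consensus")) {
    if (is.null(order)) order <- base::order(Bbar$assignment)
    Bbar <- Bbar$Bbar
  }
  n <- nrow(Bbar)
  if (is.null(order)) order <- seq_len(n)
  M <- Bbar[order, order]
  df <- tibble::tibble(i = rep(seq_len(n), times = n),
                       j = rep(seq_len(n), each = n),
                       p = as.vector(M))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "P(co-cluster)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
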