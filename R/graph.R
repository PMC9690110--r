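#' One-cluster co-clustering graph (maximum-weight spanning tree)
#'
#' Sparsifies the posterior similarity matrix to the fewest edges that keep
#' the subjects in a single connected component while retaining the largest
#' total co-clustering probability: a maximum-weight spanning tree over the
#' positive entries of `Bbar`. When zero entries disconnect the support, a
#' maximum-weight spanning forest is returned with a warning and
#' `components > 1`.
#'
#' Kruskal's algorithm with a deterministic tie-break: edges sorted by weight
#' descending, then by (i, j) lexicographically.
#'
#' @param Bbar posterior similarity matrix.
#' @return object of class `cocluster_graph`: a tibble of edges `(i, j,
#'   weight)` with attributes `n_vertices` and `components`.
#' @export
one_cluster_graph <- function(Bbar) {
  n <- nrow(Bbar)
  stopifnot(ncol(Bbar) == n, n >= 2)
  idx <- which(upper.tri(Bbar), arr.ind = TRUE)
  w <- Bbar[upper.tri(Bbar)]
  keep <- w > 0
  idx <- idx[keep, , drop = FALSE]
  w <- w[keep]
  ord <- order(-w, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]

  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (e in seq_along(w)) {
    ra <- find(idx[e, 1]); rb <- find(idx[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      ei <- c(ei, idx[e, 1]); ej <- c(ej, idx[e, 2]); ew <- c(ew, w[e])
      if (length(ew) == n - 1) break
    }
  }
  comps <- length(unique(vapply(seq_len(n), find, integer(1))))
  if (comps > 1)
    warning("co-clustering graph support is disconnected; returning a ",
            "spanning forest with ", comps, " components")
  out <- tibble::tibble(i = as.integer(unname(ei)), j = as.integer(unname(ej)),
                        weight = unname(ew))
  structure(out, n_vertices = n, components = comps,
            class = c("cocluster_graph", class(out)))
}

#' Plot a one-cluster co-clustering graph
#'
#' Force-directed (Fruchterman-Reingold) layout via igraph when available,
#' otherwise a deterministic circular layout; vertices can be coloured by a
#' label vector.
#'
#' @param object a `cocluster_graph` from [one_cluster_graph()].
#' @param labels optional vertex labels (e.g. consensus clusters) for colour.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cocluster_graph <- function(object, labels = NULL, seed = 1, ...) {
  n <- attr(object, "n_vertices")
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = object$i, to = object$j, weight = object$weight),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    set.seed(seed)
    xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
    xy <- xy[match(seq_len(n), as.integer(igraph::V(g)$name)), , drop = FALSE]
  } else {
    th <- 2 * pi * (seq_len(n) - 1) / n
    xy <- cbind(cos(th), sin(th))
  }
  verts <- tibble::tibble(x = xy[, 1], y = xy[, 2],
                          label = if (is.null(labels)) "1" else factor(labels))
  edges <- tibble::tibble(x = xy[object$i, 1], y = xy[object$i, 2],
                          xend = xy[object$j, 1], yend = xy[object$j, 2],
                          weight = object$weight)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey60", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 1)) +
    ggplot2::geom_point(data = verts,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label), size = 2) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_void()
}
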