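#' Among-group covariance-matrix distance matrix
#'
#' Distance between two groups' covariance structures defined as one minus
#' the matrix correlation of their covariance matrices (off-diagonal
#' lower-triangle elements only), giving a symmetric matrix with zero
#' diagonal and entries in \[0, 2\].
#'
#' @param covs A named list of covariance matrices, or a [group_matrices()]
#'   tibble (`type = "covariance"`).
#' @return A square distance matrix with group labels.
#' @examples
#' tab <- simulate_traits(sim_config(seed = 1))
#' gm <- group_matrices(tab, type = "covariance")
#' D <- group_distance_matrix(gm)
#' @export
group_distance_matrix <- function(covs) {
  if (is.data.frame(covs)) covs <- stats::setNames(covs$matrix, covs$label)
  stopifnot(is.list(covs), length(covs) >= 2)
  k <- length(covs)
  D <- matrix(0, k, k, dimnames = list(names(covs), names(covs)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- 1 - matrix_correlation(covs[[i]], covs[[j]])
    }
  }
  D
}

#' Principal coordinate analysis of a group distance matrix
#'
#' Classical (metric) multidimensional scaling: coordinates whose Euclidean
#' distances best reproduce the input distances, obtained by
#' eigendecomposition of the double-centred squared-distance matrix (via
#' [stats::cmdscale()]). Axes with negative eigenvalues are reported but
#' dropped from the coordinates.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param n_axes Maximum number of axes to retain.
#' @return A `pcoa_result` object: `coordinates` (tibble: group + axis
#'   scores), `eigenvalues`, `proportion` (share of the positive-eigenvalue
#'   sum per retained axis).
#' @examples
#' D <- matrix(1, 3, 3) - diag(3)
#' dimnames(D) <- list(letters[1:3], letters[1:3])
#' pcoa(D)$coordinates
#' @export
pcoa <- function(D, n_axes = 2) {
  stopifnot(is.matrix(D), isSymmetric(unname(D)), all(diag(D) == 0))
  k_max <- min(n_axes, nrow(D) - 1)
  fit <- stats::cmdscale(stats::as.dist(D), k = k_max, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  if (length(pos) == 0) stop("no positive eigenvalues; distances degenerate",
                             call. = FALSE)
  keep <- seq_len(min(k_max, length(pos)))
  coords <- fit$points[, keep, drop = FALSE]
  coords <- sweep(coords, 2, colMeans(coords))
  colnames(coords) <- paste0("axis", keep)
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(group = rownames(D)),
        tibble::as_tibble(coords)
      ),
      eigenvalues = eig,
      proportion = pos[keep] / sum(pos)
    ),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("Principal coordinate analysis:",
      sprintf("%d groups, axis proportions %s\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$proportion), collapse = ", ")))
  print(x$coordinates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_result <- function(object, ...) {
  co <- object$coordinates
  ggplot2::ggplot(co, ggplot2::aes(.data$axis1,
                                   if ("axis2" %in% names(co)) .data$axis2 else 0,
                                   label = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(
      x = sprintf("PCo 1 (%.1f%%)", 100 * object$proportion[1]),
      y = if (length(object$proportion) > 1)
        sprintf("PCo 2 (%.1f%%)", 100 * object$proportion[2]) else "",
      title = "Principal coordinates of among-group covariance distances"
    ) +
    ggplot2::theme_minimal()
}
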