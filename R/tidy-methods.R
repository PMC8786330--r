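#' Tidy a binning result
#'
#' One row per scaffold with its bin assignment; unassigned scaffolds
#' appear with `bin = NA`.
#'
#' @param x A `mag_binning`.
#' @param ... Unused.
#' @return Tibble `scaffold`, `bin`.
#' @export
tidy.mag_binning <- function(x, ...) {
  dplyr::bind_rows(
    x$membership,
    tibble::tibble(scaffold = x$unassigned, bin = NA_character_)
  )
}

#' One-row summary of a binning result
#'
#' @param x A `mag_binning`.
#' @param ... Unused.
#' @return Tibble: `n_bins`, `n_scaffolds`, `n_unassigned`, `n_iter`.
#' @export
glance.mag_binning <- function(x, ...) {
  tibble::tibble(
    n_bins = length(unique(x$membership$bin)),
    n_scaffolds = nrow(x$membership) + length(x$unassigned),
    n_unassigned = length(x$unassigned),
    n_iter = x$n_iter
  )
}

#' Tidy a feature-correlation result
#'
#' @param x A `mag_correlations`.
#' @param ... Unused.
#' @return Plain tibble of pairwise correlations.
#' @export
tidy.mag_correlations <- function(x, ...) {
  out <- x
  attr(out, "matrix") <- NULL
  class(out) <- setdiff(class(out), "mag_correlations")
  out
}

#' Plot a cumulative GC skew profile
#'
#' Cumulative skew along the genome with the inferred ori and ter marked.
#'
#' @param object A `skew_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.skew_profile <- function(object, ...) {
  df <- tibble::tibble(
    pos = (seq_along(object$cumulative) - 0.5) * object$window,
    cumulative = object$cumulative
  )
  marks <- tibble::tibble(
    pos = c(object$ori_pos, object$ter_pos),
    label = c("ori", "ter")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$pos,
                                     colour = .data$label),
                        linetype = "dashed") +
    ggplot2::labs(x = "genome position (bp)", y = "cumulative GC skew",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pairwise feature correlations
#'
#' Heatmap of the Spearman rho matrix.
#'
#' @param object A `mag_correlations`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mag_correlations <- function(object, ...) {
  m <- attr(object, "matrix")
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "rho"))
  names(df)[1:2] <- c("var1", "var2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the abundance-tier distribution
#'
#' Per-bin relative abundance on a log scale, coloured by tier, with the
#' 1% and 0.1% tier boundaries drawn.
#'
#' @param abundance Tibble from [abundance_profile()] (columns `bin`,
#'   `abundance`, `tier`).
#' @return A ggplot.
#' @export
plot_abundance_tiers <- function(abundance) {
  df <- dplyr::arrange(abundance, dplyr::desc(.data$abundance))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$abundance,
                                   colour = .data$tier)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.01, 0.001), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "relative abundance",
                  colour = "tier") +
    ggplot2::theme_minimal()
}
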