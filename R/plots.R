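slice_tibble <- function(arr, slices, value_name = "value") {
  dims <- dim(arr)
  rows <- lapply(slices, function(k) {
    v <- arr[, , k]
    g <- expand.grid(i = seq_len(dims[1]) - 1L, j = seq_len(dims[2]) - 1L)
    tibble(i = g$i, j = g$j, k = k - 1L, !!value_name := as.vector(v))
  })
  dplyr::bind_rows(rows)
}

default_slices <- function(nz, n = 4) {
  unique(round(seq(1, nz, length.out = n + 2))[-c(1, n + 2)])
}

#' Axial montage of the contrast t-map
#'
#' @param object An `scn_fit`.
#' @param slices 1-based axial (k) slice indices; defaults to 4 evenly
#'   spaced interior slices.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scn_fit
#' @export
autoplot.scn_fit <- function(object, slices = NULL, ...) {
  arr <- fit_image(object, "t")
  if (is.null(slices)) slices <- default_slices(dim(arr)[3])
  df <- slice_tibble(arr, slices, "t")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "grey95", high = "firebrick", na.value = "white"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0("Covariance contrast t-map (seed: ", object$design$seed_name, ")"),
      x = "i (voxels)", y = "j (voxels)"
    ) +
    ggplot2::theme_minimal()
}

#' Axial montage of a lesion probability map
#'
#' @param object A `lesion_prob_map`.
#' @param slices 1-based axial slice indices (default: interior spread).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lesion_prob_map
#' @export
autoplot.lesion_prob_map <- function(object, slices = NULL, ...) {
  if (is.null(slices)) slices <- default_slices(dim(object$prob)[3])
  df <- slice_tibble(object$prob, slices, "probability")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0("Lesion probability map (", object$n_patients, " patients)"),
      x = "i (voxels)", y = "j (voxels)"
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of subfield volume group differences
#'
#' @param object A `subfield_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object showing each subfield's group-difference t by
#'   hemisphere, FDR-significant results filled.
#' @method autoplot subfield_comparison
#' @export
autoplot.subfield_comparison <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    subfield = factor(.data$subfield, levels = rev(thalamic_subfields()))
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$t, y = .data$subfield,
      colour = .data$hemisphere, alpha = .data$significant
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1)) +
    ggplot2::labs(
      title = "Adjusted group difference (CS - NC) in subfield volume",
      x = "t statistic", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a brain-behaviour correlation screen
#'
#' @param object An `scn_corr_screen` tibble.
#' @param ... Unused.
#' @return A ggplot tile map of partial rho with uncorrected hits dotted
#'   and FDR-surviving hits starred.
#' @method autoplot scn_corr_screen
#' @export
autoplot.scn_corr_screen <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    mark = dplyr::case_when(
      .data$fdr_significant ~ "*",
      .data$uncorrected_significant ~ ".",
      TRUE ~ ""
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$seed, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark), size = 5) +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick", limits = c(-1, 1)
    ) +
    ggplot2::labs(
      title = paste0(
        "Spearman partial correlations (group ", attr(object, "group") %||% "?", ")"
      ),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
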