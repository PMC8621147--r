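# ggplot2 visualizations of segmentations, epitope maps and identity
# matrices.

DOMAIN_FILL <- c(S = "grey70", I = "#8dd3c7", II = "#fb8072",
                 III = "#80b1d3", IV = "#fdb462", V = "#b3de69")

#' Plot a domain segmentation as a linear protein diagram
#'
#' @param object A [segment_domains()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.domain_segmentation <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$start))
  ggplot(df) +
    geom_rect(aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                  ymin = 0, ymax = 1, fill = .data$domain)) +
    geom_text(aes(x = (.data$start + .data$end) / 2, y = 0.5,
                  label = .data$domain)) +
    scale_fill_manual(values = DOMAIN_FILL, guide = "none") +
    labs(x = "protein position (aa)", y = NULL) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid = element_blank())
}

#' Plot an epitope positional map
#'
#' Each hit is drawn as a horizontal segment at its protein position, one
#' lane per epitope (the layout used to show epitope clustering along the
#' protein).
#'
#' @param object An [epitope_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epitope_summary <- function(object, ...) {
  if (!nrow(object$map)) {
    return(ggplot() + labs(title = "no epitope hits") + theme_minimal())
  }
  ggplot(object$map) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     y = .data$epitope, yend = .data$epitope,
                     colour = .data$epitope),
                 linewidth = 4, show.legend = FALSE) +
    labs(x = "protein position (aa)", y = NULL,
         subtitle = sprintf("clustering fraction %.2f",
                            object$clustering_fraction)) +
    theme_minimal()
}

#' Plot an identity matrix as a heatmap
#'
#' Upper triangle nucleotide identity, lower triangle amino-acid identity.
#'
#' @param object An [identity_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.identity_matrix <- function(object, ...) {
  m <- object$combined
  df <- tibble(
    label_a = rep(rownames(m), times = ncol(m)),
    label_b = rep(colnames(m), each = nrow(m)),
    identity = as.vector(m)
  ) |>
    mutate(label_a = factor(.data$label_a, levels = rev(rownames(m))),
           label_b = factor(.data$label_b, levels = colnames(m)))
  ggplot(df, aes(x = .data$label_b, y = .data$label_a,
                 fill = .data$identity)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f", .data$identity)), size = 3) +
    scale_fill_gradient(low = "#f7fbff", high = "#2171b5",
                        limits = c(0, 100)) +
    labs(x = NULL, y = NULL, fill = "% identity",
         subtitle = "upper triangle NT, lower triangle AA") +
    theme_minimal()
}
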