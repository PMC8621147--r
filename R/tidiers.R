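# broom-style tidiers for the package's result objects.

#' Tidy an identity matrix into long form
#'
#' @param x An [identity_matrix()].
#' @param ... Unused.
#' @return Tibble with `label_a`, `label_b`, `metric` ("nt"/"aa") and
#'   `identity`, one row per unordered pair and metric.
#' @export
tidy.identity_matrix <- function(x, ...) {
  long <- function(m, metric) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    tibble(label_a = rownames(m)[idx[, 1]],
           label_b = colnames(m)[idx[, 2]],
           metric = metric,
           identity = m[idx])
  }
  bind_rows(long(x$nt, "nt"), long(x$aa, "aa"))
}

#' One-row summary of an identity matrix
#'
#' @param x An [identity_matrix()].
#' @param ... Unused.
#' @return Tibble with sequence count and min/mean/max identity per metric.
#' @export
glance.identity_matrix <- function(x, ...) {
  td <- tidy(x)
  td |>
    group_by(.data$metric) |>
    summarise(min = min(.data$identity), mean = mean(.data$identity),
              max = max(.data$identity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("min", "mean", "max")) |>
    mutate(n_sequences = length(x$labels), .before = 1)
}

#' Tidy an epitope summary
#'
#' @param x An [epitope_summary()].
#' @param ... Unused.
#' @return The per-epitope count tibble.
#' @export
tidy.epitope_summary <- function(x, ...) x$counts

#' One-row summary of an epitope scan
#'
#' @param x An [epitope_summary()].
#' @param ... Unused.
#' @return Tibble with total hits, distinct epitopes, clustering fraction and
#'   B-cell 7-mer count.
#' @export
glance.epitope_summary <- function(x, ...) {
  tibble(total_hits = x$total_hits,
         n_epitopes = nrow(x$counts),
         clustering_fraction = x$clustering_fraction,
         no_hits = x$no_hits,
         bcell_7mer_count = x$bcell_7mer_count)
}

#' Tidy a cysteine profile
#'
#' @param x A [cysteine_profile()].
#' @param ... Unused.
#' @return Tibble of cysteine positions and their domains.
#' @export
tidy.cysteine_profile <- function(x, ...) {
  per <- x$per_domain
  doms <- character(0)
  for (k in seq_len(nrow(per))) doms <- c(doms, rep(per$domain[k], per$n[k]))
  tibble(position = x$positions,
         domain = if (length(doms) == length(x$positions)) doms else NA_character_)
}

#' One-row summary of a physicochemical profile
#'
#' @param x A [physchem()].
#' @param ... Unused.
#' @return Tibble with length, MW, pI and the headline composition
#'   percentages.
#' @export
glance.physchem <- function(x, ...) {
  tibble(length_aa = x$length, mw_da = x$mw, pi = x$pi,
         glutamine_pct = x$glutamine_pct, proline_pct = x$proline_pct,
         essential_aa_pct = x$essential_pct)
}

#' Tidy a physicochemical profile
#'
#' @param x A [physchem()].
#' @param ... Unused.
#' @return The per-residue composition tibble.
#' @export
tidy.physchem <- function(x, ...) x$composition
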