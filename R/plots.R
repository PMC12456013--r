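#' Plot site category proportions
#'
#' @param annotated A [classify_tss()] / [classify_tep()] tibble.
#' @return A ggplot.
#' @export
plot_categories <- function(annotated) {
  lv <- c("P", "S", "C", "I", "A", "N")
  df <- annotated |>
    dplyr::count(category = factor(.data$category, levels = lv)) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "site category", y = "fraction of sites") +
    ggplot2::theme_minimal()
}

#' Plot a UTR length histogram (10-nt bins)
#'
#' @param utr_summary A [utr_stats()] result.
#' @param side `"five"` or `"three"`.
#' @return A ggplot.
#' @export
plot_utr_histogram <- function(utr_summary, side = c("five", "three")) {
  side <- match.arg(side)
  h <- utr_summary[[side]]$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + 5, y = .data$count)) +
    ggplot2::geom_col(width = 9, fill = "grey40") +
    ggplot2::labs(x = sprintf("%s'-UTR length (nt)",
                              if (side == "five") "5" else "3"),
                  y = "primary sites") +
    ggplot2::theme_minimal()
}

#' Plot base composition around site positions
#'
#' @param comp A [composition()] tibble.
#' @return A ggplot (stacked base fractions per offset).
#' @export
plot_composition <- function(comp) {
  df <- tidyr::pivot_longer(as_tibble(comp), cols = c("A", "C", "G", "T"),
                            names_to = "base", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$offset),
                                   y = .data$fraction, fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#33a02c", C = "#1f78b4",
                                          G = "#ff7f00", T = "#e31a1c")) +
    ggplot2::labs(x = "position relative to site (+1)", y = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot sigma-factor motif proportions
#'
#' @param assignment An [assign_sigma()] result.
#' @return A ggplot.
#' @export
plot_sigma_proportions <- function(assignment) {
  df <- assignment$proportions
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$sigma_name,
                                                      -.data$n_hits),
                                   y = .data$proportion)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "proportion of motifs") +
    ggplot2::theme_minimal()
}

#' Tidy a PWM into a long tibble
#'
#' @param x A `txa_pwm`.
#' @param ... Unused.
#' @return Tibble `position`, `base`, `prob`, `information_bits`.
#' @export
tidy.txa_pwm <- function(x, ...) {
  ic <- information_content(x)
  dplyr::bind_rows(lapply(seq_len(x$width), function(j) {
    tibble(position = j, base = BASES, prob = x$probs[, j],
           information_bits = ic[j])
  }))
}

#' One-row PWM summary
#'
#' @param x A `txa_pwm`.
#' @param ... Unused.
#' @return Tibble `width`, `consensus`, `total_ic_bits`.
#' @export
glance.txa_pwm <- function(x, ...) {
  tibble(width = x$width, consensus = pwm_consensus(x),
         total_ic_bits = sum(information_content(x)))
}

#' Tidy a sigma model into per-block PWM rows
#'
#' @param x A `txa_sigma_model`.
#' @param ... Unused.
#' @return Long tibble with a `block` column (`up` / `down`).
#' @export
tidy.txa_sigma_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$pwm_up), block = "up"),
    dplyr::mutate(tidy(x$pwm_down), block = "down"))
}
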