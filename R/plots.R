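# ggplot2 views of training reports and property profiles.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-epoch training losses
#'
#' @param object A `distill_fit`.
#' @param ... Unused.
#' @return A ggplot: one line per loss term across epochs.
#' @method autoplot distill_fit
#' @export
autoplot.distill_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean loss", colour = "term",
                  title = "Co-training loss trajectory") +
    ggplot2::theme_minimal()
}

#' Plot property distributions of one or more molecule sets
#'
#' Kernel-density curves of QED, SAS and LogP, optionally comparing sets
#' (e.g. generated vs training).
#'
#' @param ... Named character vectors of SMILES (names label the sets).
#' @return A ggplot faceted by property.
#' @export
plot_property_profile <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0L, !is.null(names(sets)), all(nzchar(names(sets))))
  df <- purrr::map_dfr(names(sets), function(nm) {
    prof <- property_profile(sets[[nm]])
    tidyr::pivot_longer(
      dplyr::mutate(prof, set = nm),
      c("qed", "sas", "logp"),
      names_to = "property", values_to = "value"
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
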