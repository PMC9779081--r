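#' Plot passive/active/total retention
#'
#' Retention panels per compartment: dashed line for passive (noninternalized)
#' content, solid colored line for active (macrophage-internalized) content,
#' gray line for their sum. Requires ggplot2.
#'
#' @param traj A `pk_trajectory`.
#' @param compartments Which compartments to show.
#' @return A ggplot object.
#' @export
plot_retention <- function(traj, compartments = c("tumor", "peripheral")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_retention requires the ggplot2 package", call. = FALSE)
  dec <- retention_decomposition(traj)
  dec <- dec[dec$compartment %in% compartments, ]
  long <- rbind(
    data.frame(dec[c("time_h", "compartment")], series = "passive",
               value = dec$passive),
    data.frame(dec[c("time_h", "compartment")], series = "active",
               value = dec$active),
    data.frame(dec[c("time_h", "compartment")], series = "total",
               value = dec$total)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = time_h, y = value,
                                     color = series, linetype = series)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::scale_color_manual(values = c(passive = "#4477aa",
                                           active = "#cc3311",
                                           total = "grey40")) +
    ggplot2::scale_linetype_manual(values = c(passive = "dashed",
                                              active = "solid",
                                              total = "solid")) +
    ggplot2::labs(x = "time (h)", y = "amount (%ID)",
                  color = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
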