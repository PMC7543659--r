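#' Plot an FSC curve
#'
#' FSC against inverse resolution, with the conventional 0.143 and 0.5
#' thresholds marked.
#'
#' @param stats A `shellstats` tibble (or a list of them, named by curve).
#' @return A ggplot object.
#' @export
plot_fsc <- function(stats) {
  curves <- if (inherits(stats, "shellstats")) list(map = stats) else stats
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    s <- curves[[nm]]
    data.frame(inv_d = 1 / s$d_min, fsc = s$fsc, curve = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inv_d, y = .data$fsc,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.143, 0.5), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression("1/d (" * ring(A)^-1 * ")"), y = "FSC") +
    ggplot2::theme_minimal()
}

#' Plot a radial SD profile
#'
#' Local map variation (shell SD) against distance from the box centre — flat
#' profiles indicate errors that are global in real space.
#'
#' @param profile A `radialprofile` tibble (or a named list of them).
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(profile) {
  curves <- if (inherits(profile, "radialprofile")) list(map = profile)
    else profile
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    p <- curves[[nm]]
    data.frame(r = (p$r_min + p$r_max) / 2, sd = p$sd, curve = nm)
  }))
  ggplot2::ggplot(df[!is.na(df$sd), ],
                  ggplot2::aes(x = .data$r, y = .data$sd,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("radius (" * ring(A) * ")"),
                  y = "shell SD of map values") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot shellstats
#' @export
autoplot.shellstats <- function(object, ...) plot_fsc(object)

#' @method autoplot radialprofile
#' @export
autoplot.radialprofile <- function(object, ...) plot_radial_profile(object)
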