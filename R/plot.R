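#' Taste colour palette
#'
#' One fixed colour per taste, plus grey for unassigned vertices.
#'
#' @return Named character vector of colours.
#' @export
taste_palette <- function() {
  c(sweet = "#E41A1C", bitter = "#377EB8", sour = "#4DAF4A",
    salt = "#984EA3", umami = "#FF7F00", co2 = "#00CED1",
    unassigned = "#BDBDBD")
}

#' Plot a prevalence (winner) map on the patch grid
#'
#' Renders the strip as a grid image: each masked vertex is coloured by
#' its winning taste, with colour intensity proportional to the
#' saturation (the winner's margin over the runner-up), the way
#' best-stimulus maps are conventionally displayed. Unassigned vertices
#' are grey; off-mask vertices are blank.
#'
#' @param x A `prevalence_map`.
#' @param patch The `cortical_patch` the map lives on.
#' @param sat_range Saturation (%) mapped onto the intensity ramp;
#'   values at or above `sat_range[2]` get full intensity.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.prevalence_map <- function(x, patch, sat_range = c(0, 100), ...) {
  pal <- taste_palette()
  n <- length(x$winner)
  cols <- rep(NA_character_, n)
  for (v in which(x$mask & !is.na(x$winner))) {
    base <- pal[[x$winner[v]]]
    if (x$winner[v] == "unassigned") {
      cols[v] <- base
    } else {
      f <- (min(max(x$saturation[v], sat_range[1]), sat_range[2]) -
              sat_range[1]) / diff(sat_range)
      rgb <- grDevices::col2rgb(base) / 255
      w <- 0.25 + 0.75 * f   # never fully washed out
      cols[v] <- grDevices::rgb(1 - w * (1 - rgb[1]), 1 - w * (1 - rgb[2]),
                                1 - w * (1 - rgb[3]))
    }
  }
  graphics::plot(NA, xlim = range(patch$vertices[, 1]),
                 ylim = range(patch$vertices[, 2]),
                 xlab = "posterior → anterior (mm)", ylab = "lateral (mm)",
                 asp = 1, ...)
  dx <- diff(range(patch$vertices[, 1])) / (patch$nu - 1) / 2
  dy <- diff(range(patch$vertices[, 2])) / (patch$nv - 1) / 2
  keep <- !is.na(cols)
  graphics::rect(patch$vertices[keep, 1] - dx, patch$vertices[keep, 2] - dy,
                 patch$vertices[keep, 1] + dx, patch$vertices[keep, 2] + dy,
                 col = cols[keep], border = NA)
  invisible(x)
}
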