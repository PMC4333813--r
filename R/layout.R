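#' Default flat 10-5 channel layout
#'
#' Flat top-view scalp coordinates (nose up, dimensionless) for the 20
#' channels of a standard 10-20 recording montage. Coordinates are scaled so
#' that `x` and `y` lie within \[-0.5, 0.5\]; the anterior-posterior (`y`)
#' axis is compressed as in flat 2-D layout files, so that prefrontal
#' channels map to a medial-position feature of about 0.9 and occipital
#' channels to about 0.15 (see [med_feature()]).
#'
#' @return A data frame with columns `name`, `x`, `y`.
#' @export
#' @examples
#' lay <- default_layout()
#' lay[lay$name == "Cz", ]
default_layout <- function() {
  lay <- data.frame(
    name = c("Fp1", "Fp2",
             "F7", "F3", "Fz", "F4", "F8",
             "T3", "C3", "Cz", "C4", "T4",
             "T5", "P3", "Pz", "P4", "T6",
             "O1", "Oz", "O2"),
    x = c(-0.12, 0.12,
          -0.33, -0.18, 0, 0.18, 0.33,
          -0.40, -0.20, 0, 0.20, 0.40,
          -0.33, -0.18, 0, 0.18, 0.33,
          -0.12, 0, 0.12),
    y = c(0.40, 0.40,
          0.26, 0.21, 0.20, 0.21, 0.26,
          0, 0, 0, 0, 0,
          -0.26, -0.21, -0.20, -0.21, -0.26,
          -0.35, -0.35, -0.35),
    stringsAsFactors = FALSE
  )
  validate_layout(lay)
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout), all(c("name", "x", "y") %in% names(layout)))
  layout$name <- as.character(layout$name)
  if (anyDuplicated(layout$name))
    stop("duplicate channel names in layout: ",
         paste(unique(layout$name[duplicated(layout$name)]), collapse = ", "))
  if (any(!is.finite(layout$x)) || any(!is.finite(layout$y)))
    stop("layout coordinates must be finite")
  if (any(abs(layout$x) > 0.5 + 1e-9) || any(abs(layout$y) > 0.5 + 1e-9))
    stop("layout coordinates must lie within [-0.5, 0.5]")
  layout
}

#' Read a channel layout file
#'
#' Reads whitespace-delimited rows of the form `name x y` (no header).
#'
#' @param path Path to the layout file.
#' @return A data frame with columns `name`, `x`, `y`.
#' @export
read_layout <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "x", "y"),
                           stringsAsFactors = FALSE)
  validate_layout(tab)
}

#' Write a channel layout file
#'
#' @param layout Layout data frame (`name`, `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  layout <- validate_layout(layout)
  utils::write.table(layout, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

layout_xy <- function(layout, channel) {
  i <- match(channel, layout$name)
  if (anyNA(i)) stop("channel not in layout: ",
                     paste(channel[is.na(i)], collapse = ", "))
  cbind(x = layout$x[i], y = layout$y[i])
}
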