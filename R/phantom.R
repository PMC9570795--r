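# Three-layer breast geometry with contrast-agent loading.
# z runs from the entrance surface (z = 0) through fat (d1), the
# contrast-loaded internal layer (d2) and fat again (d3) to the exit
# surface at z = d1 + d2 + d3.

#' Construct a layered breast phantom
#'
#' @param d1,d2,d3 Layer thicknesses, cm: upper fat, internal
#'   (fibrous/tumor) layer, lower fat.
#' @param internal_tissue `"fibrous"` or `"tumor"`.
#' @param dCA Nominal contrast-agent concentration, g/cm^3.
#' @param pdCA Packing density of the agent in the internal layer, (0, 1].
#' @param x_dimension,y_dimension Lateral extent, cm; the beam enters
#'   uniformly over the full face.
#' @return An object of class `kf_phantom`; `z_dimension = d1 + d2 + d3`.
#' @export
phantom <- function(d1, d2, d3, internal_tissue = c("fibrous", "tumor"),
                    dCA = 0.300, pdCA, x_dimension = 10, y_dimension = 10) {
  internal_tissue <- match.arg(internal_tissue)
  stopifnot(d1 >= 0, d3 >= 0, x_dimension > 0, y_dimension > 0)
  if (!is.numeric(d2) || d2 <= 0) stop("internal layer thickness d2 must be positive")
  if (!is.numeric(dCA) || dCA <= 0) stop("dCA must be positive")
  if (!is.numeric(pdCA) || pdCA <= 0 || pdCA > 1) stop("pdCA must be in (0, 1]")
  structure(
    list(d1 = d1, d2 = d2, d3 = d3, internal_tissue = internal_tissue,
         dCA = dCA, pdCA = pdCA,
         x_dimension = x_dimension, y_dimension = y_dimension,
         z_dimension = d1 + d2 + d3),
    class = "kf_phantom"
  )
}

#' @export
print.kf_phantom <- function(x, ...) {
  cat(sprintf(
    "<kf_phantom> fat %.3g cm | %s %.3g mm (iodine %.0f mg/mL x pd %.2f) | fat %.3g cm; face %.3g x %.3g cm\n",
    x$d1, x$internal_tissue, x$d2 * 10, x$dCA * 1000, x$pdCA, x$d3,
    x$x_dimension, x$y_dimension))
  invisible(x)
}

#' Study-configuration phantom
#'
#' Symmetric fat layers around a contrast-loaded internal layer with the
#' study's standard loading: 300 mg/mL nominal iodine concentration and a
#' packing density of 0.14 (fibrous, normal tissue) or 0.56 (tumor), i.e.
#' effective concentrations of 42 and 168 mg/mL.
#'
#' @param tissue `"fibrous"` or `"tumor"`.
#' @param d2_mm Internal-layer thickness, mm, in \[0.2, 2.5\].
#' @param total_fat_cm Total fat thickness, cm: 4 (average breast) or
#'   8 (large/dense breast); split equally above and below.
#' @param x_dimension,y_dimension Lateral extent, cm.
#' @return A `kf_phantom`.
#' @export
make_study_phantom <- function(tissue = c("fibrous", "tumor"), d2_mm,
                               total_fat_cm, x_dimension = 10,
                               y_dimension = 10) {
  tissue <- match.arg(tissue)
  if (!is.numeric(d2_mm) || length(d2_mm) != 1L || d2_mm < 0.2 || d2_mm > 2.5) {
    stop("d2_mm must be in [0.2, 2.5] mm")
  }
  if (!total_fat_cm %in% c(4, 8)) {
    stop("total_fat_cm must be 4 or 8 cm")
  }
  phantom(
    d1 = total_fat_cm / 2, d2 = d2_mm / 10, d3 = total_fat_cm / 2,
    internal_tissue = tissue, dCA = 0.300,
    pdCA = if (tissue == "tumor") 0.56 else 0.14,
    x_dimension = x_dimension, y_dimension = y_dimension
  )
}
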