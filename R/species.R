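#' Species-specific simulation profiles
#'
#' A species profile bundles the geometric parameters that differ between the
#' human-like and macaque-like simulation scenarios: patch extent,
#' stimulation-grid spacing (10 mm human-like, 5 mm macaque-like), cortical
#' fold amplitude and wavelength, the folding layout, and the baseline
#' coil-to-surface standoff. Prefrontal cortical extent is substantially
#' larger in humans than macaques (up to ~1.9-fold in gray matter), which the
#' default extents reflect.
#'
#' @param name `"human"` or `"macaque"` for the built-in defaults.
#' @param extent Numeric length-2, patch extent in mm (x = medial-lateral,
#'   y = posterior-anterior).
#' @param spacing Stimulation-grid spacing in mm.
#' @param fold_amplitude Peak fold height in mm.
#' @param fold_wavelength Crown-to-crown distance (multi-gyral) or
#'   sulcus-to-sulcus width of the dominant gyrus (single gyrus), mm.
#' @param fold_layout `"multi-gyral"` (periodic folds, human-like) or
#'   `"single-dominant-gyrus"` (one prominent crown flanked by two sulci,
#'   macaque-like prefrontal cortex).
#' @param standoff Coil-to-surface baseline distance in mm (scalp, skull and
#'   CSF thickness collapsed into one offset).
#' @return An object of class `species_profile`.
#' @examples
#' species_profile("human")
#' species_profile("macaque")
#' @export
species_profile <- function(name = c("human", "macaque"),
                            extent = NULL, spacing = NULL,
                            fold_amplitude = NULL, fold_wavelength = NULL,
                            fold_layout = NULL, standoff = NULL) {
  name <- match.arg(name)
  defaults <- if (name == "human") {
    list(extent = c(120, 120), spacing = 10, fold_amplitude = 10,
         fold_wavelength = 30, fold_layout = "multi-gyral", standoff = 15)
  } else {
    list(extent = c(64, 64), spacing = 5, fold_amplitude = 5,
         fold_wavelength = 24, fold_layout = "single-dominant-gyrus",
         standoff = 6)
  }
  p <- list(
    name = name,
    extent = extent %||% defaults$extent,
    spacing = spacing %||% defaults$spacing,
    fold_amplitude = fold_amplitude %||% defaults$fold_amplitude,
    fold_wavelength = fold_wavelength %||% defaults$fold_wavelength,
    fold_layout = fold_layout %||% defaults$fold_layout,
    standoff = standoff %||% defaults$standoff
  )
  validate_species_profile(p)
  structure(p, class = "species_profile")
}

validate_species_profile <- function(p) {
  if (length(p$extent) != 2 || any(!is.finite(p$extent)) || any(p$extent <= 0))
    stop_input("'extent' must be two positive lengths (mm)")
  for (f in c("spacing", "fold_wavelength", "standoff")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop_input("'", f, "' must be a single positive number")
  }
  if (!is.numeric(p$fold_amplitude) || p$fold_amplitude < 0)
    stop_input("'fold_amplitude' must be a non-negative number")
  if (!p$fold_layout %in% c("multi-gyral", "single-dominant-gyrus"))
    stop_input("unknown fold_layout: ", p$fold_layout)
  invisible(p)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("Species profile '%s'\n", x$name))
  cat(sprintf("  extent: %g x %g mm, grid spacing %g mm\n",
              x$extent[1], x$extent[2], x$spacing))
  cat(sprintf("  folds: %s, amplitude %g mm, wavelength %g mm\n",
              x$fold_layout, x$fold_amplitude, x$fold_wavelength))
  cat(sprintf("  coil standoff: %g mm\n", x$standoff))
  invisible(x)
}
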