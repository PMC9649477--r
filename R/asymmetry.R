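#' Asymmetry index of two lateralised measurements
#'
#' Computes the absolute asymmetry index
#' \deqn{AI = |side_1 - side_2| / (side_1 + side_2)}
#' between two non-negative measurements of the same quantity taken on the
#' two sides (of stimulation, or of the brain).  The index lies in
#' \eqn{[0, 1]}: 0 means perfect symmetry, 1 means one side contributes the
#' whole signal.  It is symmetric in its arguments and invariant to a common
#' positive rescaling of both sides.
#'
#' @param side1,side2 Non-negative scalar measurements (same units).
#' @return The asymmetry index, a number in \eqn{[0, 1]}.
#' @examples
#' asymmetry_index(100, 20)   # 0.6667
#' asymmetry_index(5, 5)      # 0: no asymmetry
#' asymmetry_index(3, 0)      # 1: maximal asymmetry
#' @export
asymmetry_index <- function(side1, side2) {
  stopifnot(length(side1) == 1L, length(side2) == 1L)
  if (!is.finite(side1) || !is.finite(side2) || side1 < 0 || side2 < 0)
    stop("asymmetry_index(): both sides must be finite and non-negative",
         call. = FALSE)
  s <- side1 + side2
  if (s <= 0)
    stop("asymmetry_index(): side1 + side2 must be positive (undefined asymmetry)",
         call. = FALSE)
  abs(side1 - side2) / s
}

#' Asymmetry index of the R2 recovery cycle at one interstimulus interval
#'
#' The two "sides" entering the asymmetry index are the R2 recovery ratios
#' (percent, conditioned over unconditioned R2 amplitude) obtained by
#' stimulating the clinically more affected side (MAS) and the less affected
#' side (LAS) at the same interstimulus interval (ISI).
#'
#' @param curve_mas,curve_las [r2_recovery_curve] objects for MAS- and
#'   LAS-side stimulation of the same patient.
#' @param isi Interstimulus interval in ms; must be present in both curves.
#' @return Asymmetry index in \eqn{[0, 1]}.
#' @seealso [asymmetry_index()], [build_recovery_cycle()]
#' @export
r2brrc_ai <- function(curve_mas, curve_las, isi) {
  stopifnot(inherits(curve_mas, "r2_recovery_curve"),
            inherits(curve_las, "r2_recovery_curve"))
  key <- as.character(isi)
  for (cv in list(curve_mas, curve_las))
    if (!key %in% names(cv$ratios))
      stop(sprintf("r2brrc_ai(): ISI %s ms absent from the %s-stimulation curve",
                   key, cv$stim_side), call. = FALSE)
  asymmetry_index(curve_mas$ratios[[key]], curve_las$ratios[[key]])
}

#' Hemispheric grey-matter metrics for one patient
#'
#' Container for the per-hemisphere cortical metrics consumed by [mri_ai()].
#' Values are taken from an upstream surface reconstruction; this package
#' does not compute them.  When `total_gm_volume` is supplied it is checked
#' against `left_volume + right_volume`.
#'
#' @param left_volume,right_volume Hemispheric grey-matter volumes (mm^3).
#' @param left_thickness,right_thickness Optional mean cortical thickness
#'   per hemisphere (mm).
#' @param total_gm_volume Optional total grey-matter volume (mm^3).
#' @param tol Relative tolerance for the total-volume consistency check.
#' @return An object of class `hemisphere_metrics`.
#' @export
hemisphere_metrics <- function(left_volume, right_volume,
                               left_thickness = NULL, right_thickness = NULL,
                               total_gm_volume = NULL, tol = 1e-6) {
  if (!is.finite(left_volume) || !is.finite(right_volume) ||
      left_volume <= 0 || right_volume <= 0)
    stop("hemisphere_metrics(): hemispheric volumes must be positive", call. = FALSE)
  if (!is.null(total_gm_volume)) {
    if (abs(left_volume + right_volume - total_gm_volume) >
        tol * abs(total_gm_volume))
      stop("hemisphere_metrics(): left + right volume inconsistent with total",
           call. = FALSE)
  }
  structure(list(left_volume = left_volume, right_volume = right_volume,
                 left_thickness = left_thickness,
                 right_thickness = right_thickness,
                 total_gm_volume = total_gm_volume),
            class = "hemisphere_metrics")
}

#' Map a clinical body side to its contralateral hemisphere
#'
#' Motor signs lateralise contralaterally: the hemisphere driving the more
#' affected body side (MAS) is the opposite one.  The mapping is an
#' involution (applying it twice returns the input).
#'
#' @param side `"left"` or `"right"` (a body side or a hemisphere).
#' @return The opposite side.
#' @export
contralateral <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") "right" else "left"
}

#' Asymmetry index of hemispheric MRI metrics
#'
#' Side 1 is the metric of the hemisphere contralateral to the clinically
#' more affected side (MAS), side 2 the metric of the hemisphere
#' contralateral to the less affected side; the absolute asymmetry index of
#' the two is returned, so the result does not depend on which body side is
#' the MAS.  The default metric is hemispheric grey-matter volume; mean
#' cortical thickness can be selected where both thickness fields are
#' present.
#'
#' @param metrics A [hemisphere_metrics] object.
#' @param mas_side Clinically more affected body side, `"left"` or `"right"`.
#' @param metric `"volume"` (default) or `"thickness"`.
#' @return Asymmetry index in \eqn{[0, 1]}.
#' @export
mri_ai <- function(metrics, mas_side, metric = c("volume", "thickness")) {
  stopifnot(inherits(metrics, "hemisphere_metrics"))
  metric <- match.arg(metric)
  mas_side <- match.arg(mas_side, c("left", "right"))
  vals <- if (metric == "volume") {
    c(left = metrics$left_volume, right = metrics$right_volume)
  } else {
    if (is.null(metrics$left_thickness) || is.null(metrics$right_thickness))
      stop("mri_ai(): thickness requested but not present for both hemispheres",
           call. = FALSE)
    c(left = metrics$left_thickness, right = metrics$right_thickness)
  }
  h1 <- contralateral(mas_side)  # hemisphere driving the MAS
  h2 <- contralateral(h1)        # hemisphere driving the LAS
  asymmetry_index(vals[[h1]], vals[[h2]])
}
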