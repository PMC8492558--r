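# Analysis configuration: eDISH thresholds / axis modes and P_ALT constants.

#' P_ALT mass-balance constants
#'
#' P_ALT estimates the percentage of hepatocytes lost from the magnitude of a
#' serum ALT elevation via a released-enzyme mass balance: the treatment-
#' emergent ALT excess (U/L) times the enzyme's distribution volume gives the
#' units of ALT released, expressed as a percentage of the total hepatocyte
#' ALT pool. Both constants are calibration-dependent and deliberately live in
#' configuration, not code.
#'
#' @param distribution_volume_l Apparent distribution volume of circulating
#'   ALT in litres; default 3 L (adult plasma volume).
#' @param total_hepatocyte_alt_u Total ALT content of the intact liver in
#'   enzyme units; default 30000 U, chosen so that a peak ALT around
#'   10000 U/L — the range seen with massive hepatic necrosis — corresponds to
#'   near-total hepatocyte loss.
#' @return A `p_alt_constants` list.
#' @export
p_alt_constants <- function(distribution_volume_l = 3,
                            total_hepatocyte_alt_u = 30000) {
  if (!is.numeric(distribution_volume_l) || distribution_volume_l <= 0 ||
      !is.numeric(total_hepatocyte_alt_u) || total_hepatocyte_alt_u <= 0) {
    abort("p_alt constants must be positive numbers",
          class = "edishr_config_error")
  }
  structure(list(distribution_volume_l = distribution_volume_l,
                 total_hepatocyte_alt_u = total_hepatocyte_alt_u),
            class = "p_alt_constants")
}

#' eDISH analysis configuration
#'
#' Holds every threshold and display setting the derivation, classification
#' and reporting steps consult.
#'
#' @param alt_fold_threshold Peak ALT fold-ULN cut separating marked
#'   transaminase elevation from normal; default 3 (Hy's Law convention).
#' @param tb_fold_threshold Peak total-bilirubin fold-ULN cut; default 2.
#' @param nr_threshold X-axis cut used when `x_axis_mode = "nr"` (the nR
#'   modified Hy's Law approach); default 5.
#' @param x_axis_mode What the eDISH x axis (and quadrant x value) measures:
#'   `"fold_uln"` (peak ALT fold-ULN, classic eDISH), `"fold_baseline"`
#'   (display only; quadrants stay on fold-ULN), or `"nr"` (peak nR ratio).
#' @param peak_window_days Maximum separation (days) between the ALT peak and
#'   the TB peak for the two to be considered temporally concordant;
#'   default 30.
#' @param point_size_measure Point-size encoding in the eDISH figure:
#'   `"none"`, `"alp_fold"` (peak ALP fold-ULN) or `"r_ratio"`.
#' @param pattern_basis Ratio used for the injury-pattern call: `"r"`
#'   (ALT-based R ratio) or `"nr"` (max(ALT, AST)-based nR ratio).
#' @param ratio_basis Whether the subject-level R/nR ratio is taken at the
#'   visit of the peak transaminase fold (`"visit"`, same-day folds — the
#'   standard clinical definition) or formed from peak folds possibly from
#'   different days (`"peak"`).
#' @param hepatocellular_cut,cholestatic_cut Injury-pattern breakpoints on the
#'   ratio scale; ratio `>=` hepatocellular_cut is hepatocellular, ratio `<=`
#'   cholestatic_cut is cholestatic, in between is mixed (CIOMS convention:
#'   5 and 2).
#' @param log_axes Draw the eDISH figure on log10 axes (fold values span
#'   orders of magnitude); default `TRUE`.
#' @param group_by Optional subject-attribute column used for grouped counts
#'   and the report's filter control.
#' @param p_alt [p_alt_constants()] block.
#' @return An `edish_config` list.
#' @examples
#' cfg <- edish_config(alt_fold_threshold = 5) # oncology-style relaxed cut
#' @export
edish_config <- function(alt_fold_threshold = 3, tb_fold_threshold = 2,
                         nr_threshold = 5,
                         x_axis_mode = c("fold_uln", "fold_baseline", "nr"),
                         peak_window_days = 30,
                         point_size_measure = c("none", "alp_fold", "r_ratio"),
                         pattern_basis = c("r", "nr"),
                         ratio_basis = c("visit", "peak"),
                         hepatocellular_cut = 5, cholestatic_cut = 2,
                         log_axes = TRUE, group_by = NULL,
                         p_alt = p_alt_constants()) {
  x_axis_mode <- match.arg(x_axis_mode)
  point_size_measure <- match.arg(point_size_measure)
  pattern_basis <- match.arg(pattern_basis)
  ratio_basis <- match.arg(ratio_basis)
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      abort(paste0("edish_config: '", nm, "' must be a positive number"),
            class = "edishr_config_error")
    }
  }
  check_pos(alt_fold_threshold, "alt_fold_threshold")
  check_pos(tb_fold_threshold, "tb_fold_threshold")
  check_pos(nr_threshold, "nr_threshold")
  check_pos(hepatocellular_cut, "hepatocellular_cut")
  check_pos(cholestatic_cut, "cholestatic_cut")
  if (!is.numeric(peak_window_days) || peak_window_days < 0) {
    abort("edish_config: 'peak_window_days' must be >= 0",
          class = "edishr_config_error")
  }
  if (cholestatic_cut >= hepatocellular_cut) {
    abort("edish_config: cholestatic_cut must be below hepatocellular_cut",
          class = "edishr_config_error")
  }
  if (!inherits(p_alt, "p_alt_constants")) p_alt <- do.call(p_alt_constants, p_alt)
  structure(
    list(alt_fold_threshold = alt_fold_threshold,
         tb_fold_threshold = tb_fold_threshold,
         nr_threshold = nr_threshold, x_axis_mode = x_axis_mode,
         peak_window_days = peak_window_days,
         point_size_measure = point_size_measure,
         pattern_basis = pattern_basis, ratio_basis = ratio_basis,
         hepatocellular_cut = hepatocellular_cut,
         cholestatic_cut = cholestatic_cut, log_axes = log_axes,
         group_by = group_by, p_alt = p_alt),
    class = "edish_config"
  )
}

#' @export
print.edish_config <- function(x, ...) {
  cat("<edish_config> ALT >= ", x$alt_fold_threshold, "xULN, TB >= ",
      x$tb_fold_threshold, "xULN (x axis: ", x$x_axis_mode,
      ", peak window: ", x$peak_window_days, " d)\n", sep = "")
  invisible(x)
}
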