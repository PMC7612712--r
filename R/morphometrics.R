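#' Photolabel deformation measurement
#'
#' Quantifies regional tissue deformation from a photolabelled cell stripe
#' measured at two timepoints: the fold change of the label's
#' length-to-height ratio, `(length_t1/height_t1) / (length_t0/height_t0)`,
#' together with the label's normalised start AP position (0 = posterior
#' end of the PSM, 1 = posterior boundary of the nascent somite).
#' Convergence-extension of the underlying tissue drives the fold change
#' above 1; a passively carried label stays near 1.
#'
#' @param length_t0,height_t0,length_t1,height_t1 Label AP extent and DV
#'   extent (micrometres) at the start and end timepoints; all > 0.
#' @param ap_position_norm Normalised initial AP position in [0, 1].
#' @return A one-row data.frame of class `photolabel_measurement`.
#' @export
photolabel_deformation <- function(length_t0, height_t0, length_t1, height_t1,
                                   ap_position_norm = NA_real_) {
  vals <- c(length_t0, height_t0, length_t1, height_t1)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("label lengths and heights must be positive")
  out <- data.frame(
    ap_position_norm = ap_position_norm,
    length_t0 = length_t0, height_t0 = height_t0,
    length_t1 = length_t1, height_t1 = height_t1,
    ratio_fold_change = (length_t1 / height_t1) / (length_t0 / height_t0)
  )
  class(out) <- c("photolabel_measurement", class(out))
  out
}

#' Compare two groups of cell volumes
#'
#' Welch two-sample two-sided t-test between cell-volume groups (e.g. the
#' same region at two somite stages, or posterior vs anterior PSM within a
#' stage).
#'
#' @param group_a,group_b Numeric volume vectors (each n >= 2).
#' @return List with elements `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_cell_volumes <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(t = 0, p = 1, df = NA_real_,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}
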