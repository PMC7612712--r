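#' Construct a stage-trendline model
#'
#' A trendline relates a morphometric response (length, cell number, volume,
#' density, ...) to the somite stage `x`.  Two families are supported:
#' linear (`y = a*x + b`) and exponential (`y = b*exp(a*x)`).
#'
#' @param form `"linear"` or `"exponential"`.
#' @param a,b Coefficients (slope / rate and intercept / prefactor).
#' @param r2 Coefficient of determination on the original response scale.
#' @param aic Akaike information criterion of the fit (Gaussian likelihood).
#' @param n Number of points the model was fitted to.
#' @param x_meaning Description of the covariate; somite stage throughout.
#' @return An object of class `psm_trendline`.
#' @export
new_trendline <- function(form, a, b, r2 = NA_real_, aic = NA_real_,
                          n = NA_integer_, x_meaning = "somite stage") {
  form <- match.arg(form, c("linear", "exponential"))
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!is.na(r2) && r2 > 1 + 1e-12)
    stop("r2 must not exceed 1")
  structure(
    list(form = form, a = a, b = b, r2 = r2, aic = aic,
         n = as.integer(n), x_meaning = x_meaning),
    class = "psm_trendline"
  )
}

#' @export
print.psm_trendline <- function(x, ...) {
  eqn <- if (x$form == "linear")
    sprintf("y = %.4g*x + %.4g", x$a, x$b)
  else
    sprintf("y = %.4g*exp(%.4g*x)", x$b, x$a)
  cat(sprintf("<psm_trendline %s> %s  (R2 = %.3g, AIC = %.4g, n = %d)\n",
              x$form, eqn, x$r2, x$aic, x$n))
  invisible(x)
}

#' Fit a stage trendline with AIC model selection
#'
#' Fits a linear model by least squares and, where all responses are
#' positive, an exponential model `y = b*exp(a*x)` by nonlinear least
#' squares initialised from the log-linear regression.  Both fits are
#' scored with a Gaussian AIC on the original response scale,
#' `AIC = n*log(RSS/n) + 2k` with `k = 3` (two coefficients plus the
#' variance), and the lower-AIC model is returned.  Ties are broken in
#' favour of the linear model.
#'
#' @param x Somite stages (numeric, length >= 3, not all equal).
#' @param y Responses.
#' @return A [new_trendline()] object for the selected family.
#' @export
fit_trendline <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (isTRUE(all.equal(min(x), max(x)))) stop("degenerate x: all stages equal")
  n <- length(x)
  tss <- sum((y - mean(y))^2)
  k <- 3  # two coefficients + error variance

  fit_lin <- stats::lm(y ~ x)
  rss_lin <- sum(stats::residuals(fit_lin)^2)
  aic_lin <- n * log(rss_lin / n) + 2 * k
  lin <- new_trendline("linear",
                       a = unname(stats::coef(fit_lin)[2L]),
                       b = unname(stats::coef(fit_lin)[1L]),
                       r2 = if (tss > 0) 1 - rss_lin / tss else 1,
                       aic = aic_lin, n = n)

  if (any(y <= 0)) return(lin)

  # exponential candidate, initialised from log-linear regression
  ll <- stats::lm(log(y) ~ x)
  a0 <- unname(stats::coef(ll)[2L])
  b0 <- exp(unname(stats::coef(ll)[1L]))
  exp_co <- tryCatch(suppressWarnings({
    nl <- stats::nls(y ~ b * exp(a * x), start = list(a = a0, b = b0),
                     control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
    stats::coef(nl)
  }), error = function(e) c(a = a0, b = b0))
  rss_exp <- sum((y - exp_co[["b"]] * exp(exp_co[["a"]] * x))^2)
  aic_exp <- n * log(rss_exp / n) + 2 * k
  if (aic_exp < aic_lin) {
    new_trendline("exponential", a = exp_co[["a"]], b = exp_co[["b"]],
                  r2 = if (tss > 0) 1 - rss_exp / tss else 1,
                  aic = aic_exp, n = n)
  } else {
    lin
  }
}

#' Evaluate a trendline at given somite stages
#'
#' @param model A [new_trendline()] object.
#' @param stage Numeric vector of stages.
#' @return Predicted response values.
#' @export
evaluate_trendline <- function(model, stage) {
  stopifnot(inherits(model, "psm_trendline"), is.numeric(stage))
  if (model$form == "linear") model$a * stage + model$b
  else model$b * exp(model$a * stage)
}

#' Cumulative paraxial-mesoderm reconstruction
#'
#' Reconstructs whole-paraxial-mesoderm values from PSM and nascent-somite
#' stage trendlines of the same quantity: for each stage `s`,
#' `PM(s) = psm(s) + sum(somite(u), u = stage_start..s)`, i.e. the current
#' PSM plus the current nascent somite and all somites formed since the
#' start stage.  This isolates PSM-driven change by excluding growth or
#' compaction within somites after their formation.
#'
#' @param psm_model,somite_model Trendlines of the same quantity for the PSM
#'   and the nascent somite.
#' @param stage_start,stage_end Integer stage range (inclusive).
#' @return A data.frame with columns `stage`, `psm`, `somite`, `cumulative`.
#' @export
cumulative_paraxial <- function(psm_model, somite_model, stage_start, stage_end) {
  stopifnot(stage_start <= stage_end)
  stages <- seq(stage_start, stage_end)
  psm <- evaluate_trendline(psm_model, stages)
  som <- evaluate_trendline(somite_model, stages)
  data.frame(stage = stages, psm = psm, somite = som,
             cumulative = psm + cumsum(som))
}

#' Cell density from count and volume
#'
#' @param cell_count Number of cells.
#' @param volume Tissue volume in cubic micrometres (> 0).
#' @return Density in cells per cubic micrometre.
#' @export
cell_density <- function(cell_count, volume) {
  stopifnot(is.numeric(cell_count), is.numeric(volume))
  if (any(volume <= 0)) stop("volume must be positive")
  cell_count / volume
}

#' Reference stage-trendline set for the zebrafish PSM
#'
#' The trendline coefficients reported for the zebrafish paraxial mesoderm
#' over somite stages 16 to the end of somitogenesis, used to parameterise
#' the synthetic-embryo simulator and the worked-example analyses.  `x` is
#' the somite stage in every equation.  Units: lengths/heights/widths in
#' micrometres, volumes in cubic micrometres, density in cells per cubic
#' micrometre.
#'
#' The published PSM *length* trendline (-14.1x + 155) is retained for
#' completeness but is internally inconsistent (negative beyond stage 11)
#' and is not used anywhere downstream; the simulator derives tissue length
#' from the volume and cross-section trendlines instead.
#'
#' @return Named list of [new_trendline()] objects.
#' @export
psm_reference_trendlines <- function() {
  list(
    psm_length       = new_trendline("linear", -14.1, 155, r2 = 0.97),
    psm_cells        = new_trendline("linear", -139, 4620, r2 = 0.95),
    psm_volume       = new_trendline("exponential", -0.159, 16.7e6, r2 = 0.98),
    somite_length    = new_trendline("linear", -1.58, 75, r2 = 0.72),
    somite_cells     = new_trendline("linear", -15.1, 525, r2 = 0.83),
    somite_volume    = new_trendline("exponential", -0.151, 1.63e6, r2 = 0.94),
    height_posterior = new_trendline("linear", -3.88, 172, r2 = 0.84),
    width_posterior  = new_trendline("linear", -2.20, 91.6, r2 = 0.77),
    height_anterior  = new_trendline("linear", -1.62, 98.7, r2 = 0.58),
    width_anterior   = new_trendline("linear", -2.45, 93.1, r2 = 0.91),
    somite_height    = new_trendline("linear", -2.85, 127, r2 = 0.89),
    somite_width     = new_trendline("linear", -2.12, 82.4, r2 = 0.79),
    density          = new_trendline("linear", 0.000121, 0.000187, r2 = 0.85),
    photolabel_ratio = new_trendline("linear", -2.17, 2.87, r2 = 0.78)
  )
}

#' Reference convergence displacement fields
#'
#' Linear displacement-versus-start-position fields for posterior-PSM cells
#' over a 120-minute window, relative to the tailbud-tip reference frame:
#' displacement along the axis as a function of start position along the
#' same axis (micrometres).  Negative slopes encode convergence toward the
#' midline; the DV field is the stronger of the two.
#'
#' @return Named list with elements `DV` and `ML`, each holding `slope`,
#'   `intercept`, `r2`, `n` and `window_min`.
#' @export
psm_reference_fields <- function() {
  list(
    DV = list(slope = -0.10, intercept = -0.67, r2 = 0.20, n = 1161L,
              window_min = 120),
    ML = list(slope = -0.08, intercept = 0.45, r2 = 0.08, n = 1161L,
              window_min = 120)
  )
}
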