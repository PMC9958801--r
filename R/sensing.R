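# log-scale interpolation of a transfer curve at an arbitrary gate bias
.interp_log_current <- function(curve, vlg_eval) {
  v <- curve$Vlg; i <- curve$Ids
  ord <- order(v); v <- v[ord]; i <- i[ord]
  if (vlg_eval < v[1] || vlg_eval > v[length(v)]) {
    abort(sprintf("Vlg = %g V lies outside the swept range [%g, %g] V",
                  vlg_eval, v[1], v[length(v)]))
  }
  if (any(i <= 0)) {
    abort("non-positive currents in the sweep; cannot interpolate on a log scale")
  }
  10^stats::approx(v, log10(i), xout = vlg_eval, ties = "ordered")$y
}

#' Threshold voltage of a transfer characteristic
#'
#' Two standard extraction methods:
#' \describe{
#'   \item{`constant_current`}{smallest gate voltage at which
#'     `Ids >= Ith * W/L` (default `Ith = 1e-7` A, scaled by the aspect
#'     ratio), interpolating linearly in `log10(Ids)` between grid points —
#'     exact for an ideal exponential subthreshold characteristic.}
#'   \item{`max_gm`}{linear extrapolation of `Ids` to zero from the point of
#'     maximum transconductance `gm = dIds/dVlg` (central differences).}
#' }
#'
#' @param curve A `biofet_iv` transfer sweep (or any tibble with `Vlg` and
#'   `Ids` columns).
#' @param method `"constant_current"` or `"max_gm"`.
#' @param Ith Threshold current density for the constant-current criterion,
#'   A (multiplied by `W/L`).
#' @param i_target Absolute threshold current, A; overrides `Ith * W/L`
#'   (required if the curve does not carry a `W/L` attribute).
#' @return Threshold voltage, V.
#' @export
threshold_voltage <- function(curve, method = c("constant_current", "max_gm"),
                              Ith = 1e-7, i_target = NULL) {
  method <- match.arg(method)
  .assert(all(c("Vlg", "Ids") %in% names(curve)),
          "`curve` must have `Vlg` and `Ids` columns")
  ord <- order(curve$Vlg)
  v <- curve$Vlg[ord]; i <- curve$Ids[ord]
  .assert(length(v) >= 3, "`curve` needs at least 3 bias points")

  if (method == "constant_current") {
    if (is.null(i_target)) {
      wl <- attr(curve, "WL")
      .assert(!is.null(wl),
              "`curve` has no W/L attribute; supply `i_target` explicitly")
      i_target <- Ith * wl
    }
    hit <- which(i >= i_target)
    if (length(hit) == 0 || hit[1] == 1) {
      abort(sprintf("constant-current criterion (%.3g A) not crossed within the sweep", i_target))
    }
    k <- hit[1]
    # log-linear interpolation between the bracketing grid points
    v[k - 1] + (v[k] - v[k - 1]) *
      (log10(i_target) - log10(i[k - 1])) / (log10(i[k]) - log10(i[k - 1]))
  } else {
    gm <- c(NA, diff(i, lag = 2) / diff(v, lag = 2), NA)
    k <- which.max(gm)
    if (!is.finite(gm[k]) || gm[k] <= 0) {
      abort("no positive-transconductance point found in the sweep")
    }
    v[k] - i[k] / gm[k]
  }
}

#' Threshold-voltage shift between two transfer curves
#'
#' `dVth = Vth(analyte) - Vth(reference)`, both extracted with the same
#' method. Negatively charged membranes shift the n-type turn-on to higher
#' gate voltages (`dVth > 0`); positively charged membranes to lower ones.
#'
#' @param curve_ref,curve_analyte `biofet_iv` transfer sweeps on comparable
#'   bias grids.
#' @param method,Ith,i_target Passed to [threshold_voltage()].
#' @return Threshold shift, V.
#' @export
threshold_shift <- function(curve_ref, curve_analyte,
                            method = c("constant_current", "max_gm"),
                            Ith = 1e-7, i_target = NULL) {
  method <- match.arg(method)
  threshold_voltage(curve_analyte, method, Ith, i_target) -
    threshold_voltage(curve_ref, method, Ith, i_target)
}

#' Relative current sensitivity between two sweeps
#'
#' `S = |I_after - I_before| / min(I_before, I_after)` evaluated at a common
#' gate bias: the relative change of the current caused by analyte binding,
#' normalised by the lower of the two currents. Symmetric under swapping the
#' two curves.
#'
#' @param curve_before,curve_after Transfer sweeps with `Vlg`, `Ids` columns.
#' @param vlg_eval Gate bias at which to compare the currents, V (must lie
#'   inside both sweeps; both currents must be positive).
#' @return Dimensionless sensitivity (>= 0).
#' @export
current_sensitivity <- function(curve_before, curve_after, vlg_eval) {
  i_b <- .interp_log_current(curve_before, vlg_eval)
  i_a <- .interp_log_current(curve_after, vlg_eval)
  abs(i_a - i_b) / min(i_b, i_a)
}

#' Classify the transistor operating region
#'
#' `subthreshold` if `Vlg < Vth - margin`; otherwise `saturation` when
#' `Vds > Vlg - Vth` and `linear` when the drain bias is below the overdrive.
#'
#' @param Vlg,Vds Bias point, V (vectorised).
#' @param Vth Threshold voltage, V.
#' @param margin Guard band below threshold, V (default 0).
#' @return Character vector in `c("subthreshold", "linear", "saturation")`.
#' @examples
#' classify_region(c(-0.5, 0.5, 2), Vds = c(1, 1, 0.05), Vth = 0)
#' @export
classify_region <- function(Vlg, Vds, Vth, margin = 0) {
  n <- max(length(Vlg), length(Vds))
  Vlg <- rep_len(Vlg, n); Vds <- rep_len(Vds, n)
  ifelse(Vlg < Vth - margin, "subthreshold",
         ifelse(Vds > Vlg - Vth, "saturation", "linear"))
}

#' Sensing report: threshold shift and per-region current sensitivity
#'
#' Simulates the reference (before binding) and analyte (after binding)
#' transfer characteristics, extracts both threshold voltages and the shift,
#' and evaluates the relative current sensitivity in three operating
#' regions of the reference device:
#' subthreshold (`Vlg = Vth_ref - sub_offset`, main `vds`),
#' saturation (`Vlg = Vth_ref + on_offset`, main `vds`), and
#' linear (`Vlg = Vth_ref + on_offset`, small `vds_linear`).
#'
#' @param config_ref,config_analyte [biofet_config()] objects for the two
#'   solution states (typically identical except for the membrane).
#' @param vlg Optional common gate grid, V; default: automatic grid of the
#'   reference device extended 0.3 V on both sides.
#' @param vds Main drain bias, V (default 1).
#' @param vb Back-gate bias, V.
#' @param method,Ith Threshold extraction (see [threshold_voltage()]).
#' @param sub_offset Subthreshold evaluation depth below the reference
#'   threshold, V (default 0.2).
#' @param on_offset Overdrive used for the on-state regions, V (default 0.5).
#' @param vds_linear Drain bias of the linear-region evaluation, V
#'   (default 0.05).
#' @return An object of class `biofet_sensing`: list with `Vth_ref`,
#'   `Vth_analyte`, `dVth` (V), a per-region tibble `report` (columns
#'   `region`, `Vlg_eval`, `Vds`, `I_before`, `I_after`, `S`), the threshold
#'   `method`, and the underlying `curves`.
#' @export
sensing_report <- function(config_ref, config_analyte, vlg = NULL, vds = 1,
                           vb = 0, method = c("constant_current", "max_gm"),
                           Ith = 1e-7, sub_offset = 0.2, on_offset = 0.5,
                           vds_linear = 0.05) {
  method <- match.arg(method)
  ref_main <- transfer_sweep(config_ref, vlg = vlg, vds = vds, vb = vb)
  if (is.null(vlg)) {
    r <- range(ref_main$Vlg)
    vlg <- seq(r[1] - 0.3, r[2] + 0.3,
               length.out = length(ref_main$Vlg) + 2L)
    ref_main <- transfer_sweep(config_ref, vlg = vlg, vds = vds, vb = vb,
                               interface = attr(ref_main, "interface"))
  }
  ana_main <- transfer_sweep(config_analyte, vlg = vlg, vds = vds, vb = vb)
  ref_lin <- transfer_sweep(config_ref, vlg = vlg, vds = vds_linear, vb = vb,
                            interface = attr(ref_main, "interface"))
  ana_lin <- transfer_sweep(config_analyte, vlg = vlg, vds = vds_linear,
                            vb = vb, interface = attr(ana_main, "interface"))

  vth_ref <- threshold_voltage(ref_main, method, Ith)
  vth_ana <- threshold_voltage(ana_main, method, Ith)

  eval_pts <- tibble(
    region = c("subthreshold", "saturation", "linear"),
    Vlg_eval = c(vth_ref - sub_offset, vth_ref + on_offset, vth_ref + on_offset),
    Vds = c(vds, vds, vds_linear)
  )
  before <- list(ref_main, ref_main, ref_lin)
  after <- list(ana_main, ana_main, ana_lin)
  report <- dplyr::mutate(
    eval_pts,
    I_before = purrr::map2_dbl(before, Vlg_eval, .interp_log_current),
    I_after = purrr::map2_dbl(after, Vlg_eval, .interp_log_current),
    S = abs(I_after - I_before) / pmin(I_before, I_after)
  )

  structure(
    list(Vth_ref = vth_ref, Vth_analyte = vth_ana, dVth = vth_ana - vth_ref,
         method = method, report = report,
         curves = list(ref_main = ref_main, analyte_main = ana_main,
                       ref_linear = ref_lin, analyte_linear = ana_lin)),
    class = "biofet_sensing"
  )
}

#' @export
print.biofet_sensing <- function(x, ...) {
  cat("<biofet_sensing>\n")
  cat(sprintf("  Vth (ref) = %.4g V, Vth (analyte) = %.4g V, dVth = %+.4g V  [%s]\n",
              x$Vth_ref, x$Vth_analyte, x$dVth, x$method))
  print(x$report)
  invisible(x)
}

#' Per-region sensitivities of a sensing report
#'
#' @param x A `biofet_sensing` object.
#' @param ... Unused.
#' @return The per-region tibble (`region`, `Vlg_eval`, `Vds`, `I_before`,
#'   `I_after`, `S`).
#' @method tidy biofet_sensing
#' @export
tidy.biofet_sensing <- function(x, ...) x$report

#' One-row summary of a sensing report
#'
#' @param x A `biofet_sensing` object.
#' @param ... Unused.
#' @return A one-row tibble with thresholds, shift and the three regional
#'   sensitivities.
#' @method glance biofet_sensing
#' @export
glance.biofet_sensing <- function(x, ...) {
  s <- stats::setNames(x$report$S, x$report$region)
  tibble(Vth_ref = x$Vth_ref, Vth_analyte = x$Vth_analyte, dVth = x$dVth,
         S_subthreshold = s[["subthreshold"]],
         S_saturation = s[["saturation"]], S_linear = s[["linear"]],
         method = x$method)
}

#' Serialize a sensing report to JSON
#'
#' Writes thresholds (V), threshold shift (V) and the per-region
#' sensitivities (dimensionless) as a small JSON document.
#'
#' @param x A `biofet_sensing` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensing_report <- function(x, path) {
  .assert(inherits(x, "biofet_sensing"), "`x` must be a biofet_sensing")
  out <- list(
    method = x$method,
    Vth_ref_V = x$Vth_ref, Vth_analyte_V = x$Vth_analyte, dVth_V = x$dVth,
    regions = lapply(seq_len(nrow(x$report)), function(i) {
      r <- x$report[i, ]
      list(region = r$region, Vlg_eval_V = r$Vlg_eval, Vds_V = r$Vds,
           I_before_A = r$I_before, I_after_A = r$I_after, S = r$S)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
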