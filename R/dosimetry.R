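# Hounsfield-unit statistics of immobilization structures and the
# measured-versus-calculated dose comparison arithmetic. Configurations:
# ALL (everything modeled), NC (no coils), NO (no overlay), NOC (neither).

DOSE_CONFIGS <- c("ALL", "NC", "NO", "NOC")

#' Hounsfield-unit statistics for a contoured structure
#'
#' @param ct a CT [volume_image].
#' @param structure non-empty [mask_roi] congruent with `ct`.
#' @param label structure name for the report.
#' @return A `hu_structure_stats` list: `label`, `mean_hu`, `sd_hu`,
#'   `max_hu`, `count`. Printed in the "mean +/- SD (max)" convention.
#' @export
hu_roi_stats <- function(ct, structure, label = structure$label) {
  stopifnot(inherits(ct, "volume_image"))
  if (ct$modality != "CT") stop("hu_roi_stats: volume must be CT")
  check_roi(structure, ct)
  s <- roi_stats(ct, structure)
  structure(list(label = label, mean_hu = s$mean, sd_hu = s$sd,
                 max_hu = s$max, count = s$count),
            class = "hu_structure_stats")
}

#' @export
print.hu_structure_stats <- function(x, ...) {
  cat(sprintf("%s: %.0f +/- %.1f (%.0f)\n", x$label, x$mean_hu, x$sd_hu,
              x$max_hu))
  invisible(x)
}

#' Percent dose difference (measured vs. calculated)
#'
#' `100 x (measured - calculated) / calculated`, the convention of the
#' end-to-end point-dose comparison (calculated dose as reference).
#'
#' @param measured,calculated doses in a common (arbitrary) unit;
#'   `calculated > 0`.
#' @param digits decimals for report parity (default 2; `NA` = unrounded).
#' @return Percent difference.
#' @export
percent_dose_difference <- function(measured, calculated, digits = 2) {
  if (!all(calculated > 0))
    stop("percent_dose_difference: calculated dose must be positive")
  v <- 100 * (measured - calculated) / calculated
  if (is.na(digits)) v else round(v, digits)
}

#' Modeled attenuation of the full treatment setup
#'
#' `100 x (dose_NOC - dose_ALL) / dose_ALL`: the planning-system-calculated
#' attenuation of the overlay plus coils, from the doses calculated with
#' everything modeled (ALL) and with neither overlay nor coils (NOC).
#'
#' @param dose_all,dose_noc calculated doses (> 0).
#' @param digits decimals (default 2; `NA` = unrounded).
#' @return Percent attenuation.
#' @export
tps_attenuation <- function(dose_all, dose_noc, digits = 2) {
  if (!all(dose_all > 0)) stop("tps_attenuation: dose_all must be positive")
  if (!all(dose_noc > 0)) stop("tps_attenuation: dose_noc must be positive")
  v <- 100 * (dose_noc - dose_all) / dose_all
  if (is.na(digits)) v else round(v, digits)
}

#' Dose comparison record
#'
#' @param gantry_angle_deg gantry angle.
#' @param measured measured dose (> 0).
#' @param calculated named list/vector of calculated doses keyed by
#'   configuration (`ALL`, `NC`, `NO`, `NOC`); at least one.
#' @return A `dose_comparison_record`.
#' @export
dose_comparison_record <- function(gantry_angle_deg, measured, calculated) {
  calculated <- as.list(calculated)
  if (length(calculated) == 0 ||
      !all(names(calculated) %in% DOSE_CONFIGS))
    stop("dose_comparison_record: calculated doses must be keyed by ",
         paste(DOSE_CONFIGS, collapse = "/"))
  if (!(measured > 0) || !all(unlist(calculated) > 0))
    stop("dose_comparison_record: doses must be positive")
  structure(list(gantry_angle_deg = gantry_angle_deg, measured = measured,
                 calculated = calculated),
            class = "dose_comparison_record")
}

#' Measured-versus-calculated attenuation report
#'
#' For each record: the percent dose difference of the measurement against
#' every available calculated configuration, the planning-system attenuation
#' column `(NOC - ALL)/ALL` when both are present, and a flag for rows whose
#' measured-vs-ALL difference exceeds `tolerance` (the commissioning action
#' level).
#'
#' @param records list of [dose_comparison_record()], or a data frame with
#'   columns `gantry_angle`, `measured`, and `dose_ALL`/`dose_NC`/
#'   `dose_NO`/`dose_NOC`.
#' @param tolerance flag threshold in percent (default 2).
#' @param tps_column require and compute the TPS attenuation column
#'   (default `TRUE` when every record carries ALL and NOC).
#' @return Data frame: `gantry_angle`, `measured`, `pctdiff_<config>`
#'   columns, `tps_attenuation_pct` (if computed), `flagged`.
#' @export
attenuation_report <- function(records, tolerance = 2, tps_column = NULL) {
  if (is.data.frame(records)) records <- records_from_df(records)
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, logical(1),
                       "dose_comparison_record")))
  have_tps <- all(vapply(records, function(r)
    all(c("ALL", "NOC") %in% names(r$calculated)), logical(1)))
  if (is.null(tps_column)) tps_column <- have_tps
  if (tps_column && !have_tps)
    stop("attenuation_report: TPS column requires ALL and NOC doses")
  configs <- DOSE_CONFIGS[DOSE_CONFIGS %in%
                            unique(unlist(lapply(records, function(r)
                              names(r$calculated))))]
  rows <- lapply(records, function(r) {
    row <- list(gantry_angle = r$gantry_angle_deg, measured = r$measured)
    for (cf in configs)
      row[[paste0("pctdiff_", cf)]] <-
        if (cf %in% names(r$calculated))
          percent_dose_difference(r$measured, r$calculated[[cf]])
        else NA_real_
    if (tps_column)
      row$tps_attenuation_pct <- tps_attenuation(r$calculated$ALL,
                                                 r$calculated$NOC)
    row$flagged <- if ("ALL" %in% names(r$calculated))
      abs(percent_dose_difference(r$measured, r$calculated$ALL)) > tolerance
    else NA
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

records_from_df <- function(df) {
  stopifnot(all(c("gantry_angle", "measured") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    calc <- list()
    for (cf in DOSE_CONFIGS) {
      col <- paste0("dose_", cf)
      if (col %in% names(df) && !is.na(df[[col]][i]))
        calc[[cf]] <- df[[col]][i]
    }
    dose_comparison_record(df$gantry_angle[i], df$measured[i], calc)
  })
}
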