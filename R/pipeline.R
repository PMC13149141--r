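#' Run the full analysis on one record
#'
#' Preprocesses a multimodal record, runs the coupling engine and extracts
#' HRV, respiratory and hemodynamic features into a single feature row.
#' Stage failures do not abort the run: the affected columns are set to
#' `NA` and a reason code is recorded.
#'
#' @param record a [crv_record()].
#' @param seed seed forwarded to the EEMD ensemble (default 1).
#' @param apply_notch see [preprocess_record()].
#' @param ... further arguments passed to [coupling_profile()].
#' @return one-row `data.frame` with subject metadata, HRV metrics
#'   (`MeanRR`, `SDNN`, `LF`, `HF`, `logLF`, `logHF`, `LF_HF`, `SampEn`),
#'   respiratory metrics (`AED`, `AID`, `BR`, `BR_CV`, `EDC_CV`, `IDC_CV`,
#'   `BR_in_HF`), hemodynamic means (`SBP`, `DBP`, `MAP`, `CO`, `PPV`,
#'   `SpO2`), the five pairwise coupling strengths (`rho_*`), complexities
#'   (`C_*`) and the totals. Attributes: `reasons` (named failure codes)
#'   and `provenance` (seed + parameter echo).
#' @export
run_record <- function(record, seed = 1L, apply_notch = TRUE, ...) {
  stopifnot(inherits(record, "crv_record"))
  cols <- c("MeanRR", "SDNN", "LF", "HF", "logLF", "logHF", "LF_HF",
            "SampEn", "AED", "AID", "BR", "BR_CV", "EDC_CV", "IDC_CV",
            "BR_in_HF", "SBP", "DBP", "MAP", "CO", "PPV", "SpO2",
            "rho_RSP_RRI", "rho_RSP_SBP", "rho_RSP_DBP", "rho_SBP_RRI",
            "rho_DBP_RRI", "C_RSP_RRI", "C_RSP_SBP", "C_RSP_DBP",
            "C_SBP_RRI", "C_DBP_RRI", "rho_total", "C_total")
  row <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(cols)),
                                               cols)))
  row <- cbind(data.frame(subject_id = record$subject_id,
                          group_label = record$group_label,
                          stringsAsFactors = FALSE), row)
  reasons <- character(0)
  note <- function(stage, e) reasons[[stage]] <<- conditionMessage(e)

  prep <- tryCatch(
    withCallingHandlers(
      preprocess_record(record, apply_notch = apply_notch),
      warning = function(w) {
        reasons[["preprocess_warning"]] <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) { note("preprocess", e); NULL })
  if (!is.null(prep)) {
    ht <- tryCatch(hrv_time(prep$rri_beats),
                   error = function(e) { note("hrv_time", e); NULL })
    if (!is.null(ht)) row[names(ht)] <- as.list(ht)
    hfq <- tryCatch(hrv_freq(prep$rri_beats),
                    error = function(e) { note("hrv_freq", e); NULL })
    if (!is.null(hfq)) row[names(hfq)] <- as.list(hfq)
    se <- tryCatch(sampen(prep$rri_beats$values),
                   error = function(e) { note("sampen", e); NULL })
    if (!is.null(se)) row$SampEn <- se
    br <- tryCatch(resp_features(segment_breaths(prep$rsp)),
                   error = function(e) { note("respiration", e); NULL })
    if (!is.null(br)) {
      row[names(br)] <- as.list(br)
      row$BR_in_HF <- as.numeric(br_in_hf_band(br[["BR"]]))
    }
    cp <- tryCatch(coupling_profile(prep$rsp, prep$rri, prep$sbp, prep$dbp,
                                    seed = seed, ...),
                   error = function(e) { note("coupling", e); NULL })
    if (!is.null(cp)) {
      pn <- gsub("-", "_", names(cp$strength))
      row[paste0("rho_", pn)] <- as.list(unname(cp$strength))
      row[paste0("C_", pn)] <- as.list(unname(cp$complexity))
      row$rho_total <- cp$rho_total
      row$C_total <- cp$C_total
    }
  }
  # scalar channels are consumed directly; per-beat pressures when available
  hemo <- tryCatch({
    chans <- record$scalars
    if (!is.null(prep))
      chans <- c(list(SBP = prep$sbp_beats$values,
                      DBP = prep$dbp_beats$values), chans)
    hemo_summary(chans)
  }, error = function(e) { note("hemodynamics", e); NULL })
  if (!is.null(hemo))
    for (i in seq_len(nrow(hemo)))
      if (hemo$channel[i] %in% cols) row[[hemo$channel[i]]] <- hemo$mean[i]
  attr(row, "reasons") <- reasons
  attr(row, "provenance") <- list(seed = seed,
                                  package_version =
                                    as.character(utils::packageVersion("crvcoupling")))
  row
}

#' Run the analysis over a cohort of records
#'
#' @param records list of [crv_record()] objects (e.g.
#'   `simulate_cohort(...)$records`).
#' @param seed EEMD seed used for every record.
#' @param ... passed to [run_record()].
#' @return a `crv_features` data.frame: one row per subject (see
#'   [run_record()]); per-record failure reasons in attribute `reasons`.
#' @export
run_cohort <- function(records, seed = 1L, ...) {
  rows <- lapply(records, run_record, seed = seed, ...)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$subject_id))
    stop("duplicate subject_id in cohort", call. = FALSE)
  attr(out, "reasons") <- lapply(rows, attr, "reasons")
  class(out) <- c("crv_features", "data.frame")
  out
}

#' @export
print.crv_features <- function(x, ...) {
  cat("<crv_features>", nrow(x), "subjects,", ncol(x) - 2, "metrics\n")
  if (!all(is.na(x$group_label)))
    print(table(group = x$group_label))
  nr <- attr(x, "reasons")
  nfail <- sum(vapply(nr %||% list(), length, 0L) > 0)
  if (nfail) cat(" ", nfail, "record(s) with stage failures\n")
  NextMethod()
  invisible(x)
}

#' Group means of a feature table
#'
#' @param x a `crv_features` table.
#' @param vars columns to summarise (default: all numeric metrics).
#' @return data.frame of group means (one row per group).
#' @export
group_means <- function(x, vars = NULL) {
  stopifnot(inherits(x, "crv_features"))
  if (is.null(vars))
    vars <- names(x)[vapply(x, is.numeric, TRUE)]
  agg <- stats::aggregate(x[vars], by = list(group = x$group_label),
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$group), , drop = FALSE]
}

#' Boxplots of a feature across groups
#'
#' @param x a `crv_features` table.
#' @param variable column name to plot.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, `x`.
#' @export
plot_feature <- function(x, variable, ...) {
  stopifnot(variable %in% names(x))
  graphics::boxplot(x[[variable]] ~ x$group_label, xlab = "group",
                    ylab = variable, ...)
  invisible(x)
}
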