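#' Within-subject normal-vision reference band
#'
#' Builds the band used by the equal/above/below (EAB) analysis: half the
#' interquartile range of the whole sample's normal-vision (NV) values,
#' added and subtracted around the subject's own NV value. Quartiles use
#' linear interpolation of order statistics (type 7), the common default;
#' the estimator is configurable because the choice matters for small
#' samples.
#'
#' @param subject_nv The subject's own NV value.
#' @param sample_nv NV values of all participants (including the subject).
#' @param qtype Quantile estimator type passed to [stats::quantile()].
#' @return An object of class `eab_band`: `center`, `half_width`, `lower`,
#'   `upper`.
#' @export
nv_band <- function(subject_nv, sample_nv, qtype = 7) {
  stopifnot(is.finite(subject_nv))
  if (anyNA(sample_nv)) {
    warning("dropping ", sum(is.na(sample_nv)), " missing reference value(s)")
    sample_nv <- sample_nv[!is.na(sample_nv)]
  }
  if (length(sample_nv) < 2L)
    stop("need at least 2 finite reference values to form a band")
  q <- stats::quantile(sample_nv, c(0.25, 0.75), type = qtype, names = FALSE)
  hw <- (q[2] - q[1]) / 2
  structure(list(center = subject_nv, half_width = hw,
                 lower = subject_nv - hw, upper = subject_nv + hw),
            class = "eab_band")
}

#' Classify a value against an EAB band
#'
#' @param value The impaired-condition value to classify.
#' @param band An [nv_band()].
#' @return `"equal"` when `lower <= value <= upper` (closed interval),
#'   `"above"` or `"below"` otherwise; `NA` for a missing value.
#' @export
eab_classify <- function(value, band) {
  stopifnot(inherits(band, "eab_band"))
  ifelse(!is.finite(value), NA_character_,
         ifelse(value > band$upper, "above",
                ifelse(value < band$lower, "below", "equal")))
}

#' Blind-side versus seeing-side EAB classification
#'
#' The modified form of the EAB analysis for per-hemifield measures: the
#' band is half the IQR of all participants' seeing-side values, centred on
#' this subject's own seeing-side value, and the subject's blind-side value
#' is classified against it (`"above"` = the blind side outnumbers the
#' seeing side beyond the band).
#'
#' @param blind_value Subject's blind-side value.
#' @param seeing_value Subject's seeing-side value (band centre).
#' @param sample_seeing Seeing-side values of all participants.
#' @param qtype Quantile estimator type.
#' @return A list: `classification`, `value`, `band`.
#' @export
classify_blind_seeing <- function(blind_value, seeing_value, sample_seeing,
                                  qtype = 7) {
  band <- nv_band(seeing_value, sample_seeing, qtype = qtype)
  list(classification = eab_classify(blind_value, band),
       value = blind_value, band = band)
}

#' EAB classification table for one metric over a study
#'
#' Classifies every impaired-condition scenario value against the subject's
#' own NV value in the same intersection type, with the band width taken
#' from the NV sample of that intersection type across participants.
#'
#' @param records `data.frame` of [scenario_metrics()] rows covering all
#'   conditions.
#' @param metric Name of the metric column to classify.
#' @param conditions Impaired conditions to classify (default LHH and RHH).
#' @param qtype Quantile estimator type.
#' @return A list: `classifications` (one row per classified scenario),
#'   `counts` (equal/above/below per condition and pooled, with percentages),
#'   `n_missing` (scenarios skipped for lack of a value or NV baseline).
#' @export
eab_table <- function(records, metric, conditions = c("LHH", "RHH"),
                      qtype = 7) {
  stopifnot(metric %in% names(records))
  rows <- list(); n_missing <- 0L
  for (itype in unique(records$intersection)) {
    nv <- records[records$condition == "NV" & records$intersection == itype, ]
    nv_sample <- nv[[metric]][is.finite(nv[[metric]])]
    for (cond in conditions) {
      sub <- records[records$condition == cond & records$intersection == itype, ]
      for (i in seq_len(nrow(sub))) {
        subj <- sub$subject[i]
        v <- sub[[metric]][i]
        base <- nv[[metric]][nv$subject == subj]
        if (length(base) != 1L || !is.finite(base) || !is.finite(v) ||
            length(nv_sample) < 2L) {
          n_missing <- n_missing + 1L
          next
        }
        band <- nv_band(base, nv_sample, qtype = qtype)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, condition = cond, intersection = itype,
          value = v, nv_value = base, lower = band$lower, upper = band$upper,
          classification = eab_classify(v, band), stringsAsFactors = FALSE)
      }
    }
  }
  cls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), condition = character(0),
               intersection = character(0), value = numeric(0),
               nv_value = numeric(0), lower = numeric(0), upper = numeric(0),
               classification = character(0))
  lv <- c("below", "equal", "above")
  count_block <- function(sub, label) {
    k <- table(factor(sub$classification, levels = lv))
    data.frame(condition = label, classification = lv, k = as.integer(k),
               K = nrow(sub), pct = percentage(as.integer(k), max(1L, nrow(sub))),
               stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, c(
    lapply(conditions, function(cond)
      count_block(cls[cls$condition == cond, , drop = FALSE], cond)),
    list(count_block(cls, "pooled"))))
  list(classifications = cls, counts = counts, n_missing = n_missing)
}

#' Lane-position buffer table from an EAB classification
#'
#' Translates equal/above/below classifications of mean lane position into
#' blind-side / seeing-side buffer counts: with a left-sided loss (LHH,
#' blind side left) a rightward shift relative to the NV band (`above`)
#' buffers the blind side, while with a right-sided loss (RHH) the blind
#' side is buffered by a leftward shift (`below`).
#'
#' @param records Scenario metrics covering NV, LHH and RHH.
#' @param metric Lane-position column, default `"lane_mean_cm"`.
#' @param qtype Quantile estimator type.
#' @return `data.frame` with per-condition and pooled blind/seeing buffer
#'   counts and percentages.
#' @export
buffer_table <- function(records, metric = "lane_mean_cm", qtype = 7) {
  et <- eab_table(records, metric, qtype = qtype)
  cls <- et$classifications
  blind_dir <- c(LHH = "above", RHH = "below")
  seeing_dir <- c(LHH = "below", RHH = "above")
  per <- do.call(rbind, lapply(c("LHH", "RHH"), function(cond) {
    sub <- cls[cls$condition == cond, , drop = FALSE]
    data.frame(condition = cond,
               buffer_blind = sum(sub$classification == blind_dir[cond]),
               buffer_seeing = sum(sub$classification == seeing_dir[cond]),
               K = nrow(sub), stringsAsFactors = FALSE)
  }))
  pooled <- data.frame(condition = "pooled",
                       buffer_blind = sum(per$buffer_blind),
                       buffer_seeing = sum(per$buffer_seeing),
                       K = sum(per$K), stringsAsFactors = FALSE)
  out <- rbind(per, pooled)
  out$pct_blind <- percentage(out$buffer_blind, pmax(1L, out$K))
  out$pct_seeing <- percentage(out$buffer_seeing, pmax(1L, out$K))
  out
}
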