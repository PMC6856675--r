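#' Construct or read a daily systolic blood-pressure series
#'
#' The series holds one systolic reading per day of life.  The CSV schema is
#' `day,systolic_mmHg`.  Days must be strictly increasing and pressures
#' must lie in the physiologically plausible band (20, 300) mmHg.
#'
#' @param day integer days of life, strictly increasing.
#' @param systolic_mmHg systolic blood pressure (mmHg).
#' @return A data frame of class `"bp_series"` with columns `day` and
#'   `systolic_mmHg` (plus `smoothed_mmHg` after [running_mean()]).
#' @export
bp_series <- function(day, systolic_mmHg) {
  if (length(day) != length(systolic_mmHg))
    stop("day and systolic_mmHg must have equal length")
  if (length(day) < 1L) stop("empty series")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(!is.finite(systolic_mmHg)) ||
      any(systolic_mmHg <= 20 | systolic_mmHg >= 300))
    stop("systolic values must be finite and in (20, 300) mmHg")
  structure(data.frame(day = as.integer(day),
                       systolic_mmHg = as.numeric(systolic_mmHg)),
            class = c("bp_series", "data.frame"))
}

#' @rdname bp_series
#' @param path CSV file with columns `day,systolic_mmHg`.
#' @export
read_bp_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("day", "systolic_mmHg") %in% names(df)))
    stop("expected columns day,systolic_mmHg in ", path)
  bp_series(df$day, df$systolic_mmHg)
}

#' Centered running mean with shrinking edges
#'
#' Smooths the systolic series with a centered moving average of odd width
#' `window` days.  At the edges the window shrinks to the available samples
#' (no padding, no dropped days), so the output has the same length as the
#' input and the first/last days keep a value.  `window = 1` is the
#' identity.
#'
#' @param series a `"bp_series"`, or a plain numeric vector.
#' @param window odd positive integer, at most the series length.
#' @return For a `"bp_series"`: the series with a `smoothed_mmHg` column.
#'   For a numeric vector: the smoothed vector.
#' @export
#' @examples
#' running_mean(c(1, 2, 3, 4, 5), window = 3)  # 1.5 2 3 4 4.5
running_mean <- function(series, window = 5) {
  x <- if (inherits(series, "bp_series")) series$systolic_mmHg
       else as.numeric(series)
  n <- length(x)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop("window must be an odd positive integer")
  if (window > n) stop("window must not exceed the series length")
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  if (inherits(series, "bp_series")) {
    series$smoothed_mmHg <- sm
    series
  } else sm
}

#' Flag hypertensive days against a healthy reference
#'
#' Flags the days whose smoothed systolic pressure strictly exceeds the
#' healthy reference value, and summarizes the excursion: peak value, peak
#' day and the percent rise from the first observation to the peak.
#' If the series has not been smoothed yet, [running_mean()] is applied
#' with the given window first.
#'
#' @param series a `"bp_series"`.
#' @param reference healthy systolic reference (mmHg), > 0.
#' @param window smoothing window used if the series is not yet smoothed.
#' @return A list: `series` (with `smoothed_mmHg` and logical `flagged`
#'   columns), `n_flagged`, `peak_mmHg`, `peak_day`, `pct_rise` (percent
#'   rise of the raw series from day one to its peak), `reference`.
#' @export
hypertension_flags <- function(series, reference = 100, window = 5) {
  if (!inherits(series, "bp_series")) stop("not a bp_series")
  if (!is.numeric(reference) || reference <= 0)
    stop("reference must be > 0")
  if (is.null(series$smoothed_mmHg))
    series <- running_mean(series, window = window)
  series$flagged <- series$smoothed_mmHg > reference
  raw <- series$systolic_mmHg
  i_peak <- which.max(raw)
  list(series = series,
       n_flagged = sum(series$flagged),
       peak_mmHg = raw[i_peak],
       peak_day = series$day[i_peak],
       pct_rise = percent_change(raw[i_peak], raw[1]),
       reference = reference)
}

# canonical ascending-aortic measurement sites
.aorta_sites <- c("outflow tract", "sinuses of valsalva",
                  "sinotubular junction", "tubular ascending aorta")

.norm_site <- function(x) {
  x <- tolower(trimws(gsub("\\s+", " ", x)))
  bad <- setdiff(unique(x), .aorta_sites)
  if (length(bad))
    stop("unknown aortic site(s): ", paste(bad, collapse = ", "),
         "; expected: ", paste(.aorta_sites, collapse = ", "))
  x
}

#' Construct or read a per-exam aortic diameter table
#'
#' One row per (exam age, site) with the diameter in cm.  The four sites
#' are the standard ascending-aortic measurement locations: outflow tract,
#' sinuses of Valsalva, sinotubular junction and tubular ascending aorta.
#' Site strings are matched case-insensitively after whitespace
#' normalization.  CSV schema: `age_days,site,diameter_cm`.
#'
#' @param age_days exam age (days of life).
#' @param site measurement site label.
#' @param diameter_cm diameter (cm), > 0.
#' @return A data frame of class `"diameter_table"`.
#' @export
diameter_table <- function(age_days, site, diameter_cm) {
  site <- .norm_site(site)
  if (any(!is.finite(diameter_cm)) || any(diameter_cm <= 0))
    stop("diameters must be finite and positive")
  structure(data.frame(age_days = as.integer(age_days), site = site,
                       diameter_cm = as.numeric(diameter_cm)),
            class = c("diameter_table", "data.frame"))
}

#' @rdname diameter_table
#' @param path CSV file with columns `age_days,site,diameter_cm`.
#' @export
read_diameters <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age_days", "site", "diameter_cm") %in% names(df)))
    stop("expected columns age_days,site,diameter_cm in ", path)
  diameter_table(df$age_days, df$site, df$diameter_cm)
}

#' Per-site percent change of aortic diameters between two exams
#'
#' Compares each of the four sites between a baseline exam and a later
#' exam; negative values are reductions.  Both exams must contain all four
#' sites; a missing site is reported by name.
#'
#' @param table a `"diameter_table"`.
#' @param baseline_day,compare_day exam ages (days) present in the table.
#' @return A data frame: `site`, `baseline_cm`, `compare_cm`, `pct_change`,
#'   ordered by the canonical site order.
#' @export
diameter_changes <- function(table, baseline_day, compare_day) {
  if (!inherits(table, "diameter_table")) stop("not a diameter_table")
  pick <- function(day) {
    sub <- table[table$age_days == day, ]
    miss <- setdiff(.aorta_sites, sub$site)
    if (length(miss))
      stop("exam at day ", day, " is missing site(s): ",
           paste(miss, collapse = ", "))
    stats::setNames(sub$diameter_cm[match(.aorta_sites, sub$site)],
                    .aorta_sites)
  }
  b <- pick(baseline_day)
  cmp <- pick(compare_day)
  data.frame(site = .aorta_sites,
             baseline_cm = as.numeric(b),
             compare_cm = as.numeric(cmp),
             pct_change = percent_change(as.numeric(cmp), as.numeric(b)),
             row.names = NULL)
}
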