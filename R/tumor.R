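#' Caliper tumor volume (ellipsoid approximation)
#'
#' The standard subcutaneous-tumor ellipsoid formula
#' \deqn{V = \pi \cdot L \cdot W^2 / 6} with \eqn{L} the longer and
#' \eqn{W} the shorter caliper axis (in mm, giving mm^3). Because the
#' width enters squared, axis order matters: if a width exceeds its
#' length the two are swapped with a warning (L = max, W = min).
#'
#' @param length_mm longer caliper axis, mm (vectorised).
#' @param width_mm shorter caliper axis, mm.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 5)       # pi * 10 * 25 / 6
#' tumor_volume(7, 7)        # sphere: pi * 7^3 / 6
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0))
    stop("caliper dimensions must be positive and finite")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had width > length; axes swapped")
    l <- pmax(length_mm, width_mm)
    w <- pmin(length_mm, width_mm)
  } else {
    l <- length_mm; w <- width_mm
  }
  pi * l * w^2 / 6
}

#' Normalise tumor records and derive caliper volume
#'
#' Validates a measurement table (columns \code{subject}, \code{day}, and
#' either \code{radiance} or \code{length_mm} + \code{width_mm}), checks
#' that days are strictly increasing within subject, and adds
#' \code{volume_mm3} for caliper data. The burden column used downstream is
#' recorded in the \code{"value_col"} attribute.
#'
#' @param df data.frame of measurements.
#' @return The validated data.frame with a \code{"value_col"} attribute.
#' @export
as_tumor_records <- function(df) {
  if (!all(c("subject", "day") %in% names(df)))
    stop("tumor records need `subject` and `day` columns")
  for (s in split(df$day, df$subject))
    if (any(diff(sort(s)) == 0))
      stop("days must be unique within subject")
  if (all(c("length_mm", "width_mm") %in% names(df))) {
    df$volume_mm3 <- tumor_volume(df$length_mm, df$width_mm)
    attr(df, "value_col") <- "volume_mm3"
  } else if ("radiance" %in% names(df)) {
    if (any(df$radiance <= 0)) stop("radiance must be positive")
    attr(df, "value_col") <- "radiance"
  } else {
    stop("need either radiance or length_mm + width_mm columns")
  }
  df
}

#' Relative tumor burden, baseline set to 1
#'
#' Divides each subject's burden series by its value at
#' \code{baseline_day}, the presentation convention of growth/regression
#' curves ("day X is set as 1"). The baseline time point maps to exactly 1;
#' subjects without a measurement at the baseline day are excluded with a
#' warning. The result is invariant to rescaling any subject's whole
#' series.
#'
#' @param df tumor records (passed through \code{\link{as_tumor_records}}).
#' @param baseline_day the day whose value becomes 1.
#' @param value_col burden column; default: the auto-detected one.
#' @return data.frame with an added \code{relative} column.
#' @export
relative_series <- function(df, baseline_day, value_col = NULL) {
  df <- as_tumor_records(df)
  if (is.null(value_col)) value_col <- attr(df, "value_col")
  parts <- lapply(split(df, df$subject), function(d) {
    i <- which(d$day == baseline_day)
    if (length(i) != 1) return(NULL)
    d$relative <- d[[value_col]] / d[[value_col]][i]
    d
  })
  dropped <- names(parts)[vapply(parts, is.null, TRUE)]
  if (length(dropped))
    warning("subject(s) without a day-", baseline_day, " baseline excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  if (is.null(out)) stop("no subject has a baseline measurement")
  rownames(out) <- NULL
  out
}

#' Percent change in tumor burden between two days
#'
#' Per subject, \code{100 * (value_to - value_from) / value_from}; a
#' negative value is regression (e.g. a fall from 100 to 1 is -99, the
#' arithmetic shape of a "99\% reduction").
#'
#' @param df tumor records.
#' @param from_day,to_day the two measurement days (both must be present
#'   for a subject to be reported).
#' @param value_col burden column; default: auto-detected.
#' @return data.frame with \code{subject} and \code{percent_change}.
#' @export
percent_change <- function(df, from_day, to_day, value_col = NULL) {
  df <- as_tumor_records(df)
  if (is.null(value_col)) value_col <- attr(df, "value_col")
  parts <- lapply(split(df, df$subject), function(d) {
    i <- which(d$day == from_day); j <- which(d$day == to_day)
    if (length(i) != 1 || length(j) != 1) return(NULL)
    v0 <- d[[value_col]][i]
    if (v0 == 0) stop("zero burden at from_day for subject ", d$subject[1])
    data.frame(subject = d$subject[1],
               percent_change = 100 * (d[[value_col]][j] - v0) / v0)
  })
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  if (is.null(out)) stop("no subject has both days")
  rownames(out) <- NULL
  out
}

#' Group summary of tumor burden (mean and SD)
#'
#' Mean and standard deviation of the chosen burden column per (group,
#' day), the conventional presentation of cohort growth curves.
#'
#' @param df tumor records with a \code{group} column.
#' @param value_col burden column; default: auto-detected (or
#'   \code{"relative"} if present).
#' @return data.frame with \code{group}, \code{day}, \code{n},
#'   \code{mean}, \code{sd}.
#' @export
tumor_summary <- function(df, value_col = NULL) {
  df0 <- as_tumor_records(df)
  if (is.null(value_col))
    value_col <- if ("relative" %in% names(df0)) "relative"
                 else attr(df0, "value_col")
  if (!"group" %in% names(df0)) df0$group <- "all"
  agg <- function(f) stats::aggregate(df0[[value_col]],
                                      list(group = df0$group, day = df0$day), f)
  out <- agg(mean)
  names(out)[3] <- "mean"
  out$sd <- agg(stats::sd)$x
  out$n <- agg(length)$x
  out[order(out$group, out$day), c("group", "day", "n", "mean", "sd")]
}
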