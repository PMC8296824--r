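#' Cross-jurisdiction pesticide action-level statistics
#'
#' One summary row per pesticide across all jurisdictions: record and
#' jurisdiction counts, min/median/max action level (ppm), fold-range, and
#' the ratio of the median to the reference tolerance when one is known.
#'
#' Conventions: exact duplicate records (same jurisdiction, pesticide,
#' product type and level) are collapsed before any statistic; the median
#' of an even count is the mean of the middle two values.  The fold-range
#' divides the maximum by the \emph{effective} minimum: the smallest
#' positive action level, with zero-tolerance records contributing their
#' LOQ when one is given and excluded from the denominator otherwise
#' (\code{min_level} still reports 0).  The fold-range is \code{NA} when
#' no positive denominator exists.
#'
#' @param records action-level records from [read_action_level_table()].
#' @param tolerances optional reference-tolerance table from
#'   [read_reference_tolerances()].
#' @param product_filter optional product-type string; default pools all
#'   product types.
#' @return data.frame with one row per pesticide: \code{pesticide},
#'   \code{class}, \code{n_records}, \code{n_jurisdictions},
#'   \code{min_level}, \code{median_level}, \code{max_level},
#'   \code{fold_range}, \code{reference_tolerance},
#'   \code{median_to_reference_ratio}; sorted by pesticide.
#' @export
pesticide_stats <- function(records, tolerances = NULL,
                            product_filter = NULL) {
  if (!is.null(product_filter)) {
    records <- records[records$product_type == tolower(product_filter), ,
                       drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no action-level records remain after filtering", call. = FALSE)
  }
  records <- collapse_duplicates(records)
  pests <- sort(unique(records$pesticide))
  rows <- lapply(pests, function(p) {
    r <- records[records$pesticide == p, , drop = FALSE]
    lev <- r$action_level
    eff <- effective_levels(r)
    fold <- if (length(eff)) max(lev) / min(eff) else NA_real_
    data.frame(pesticide = p, class = r$class[1L],
               n_records = nrow(r),
               n_jurisdictions = length(unique(r$jurisdiction)),
               min_level = min(lev),
               median_level = stats::median(lev),
               max_level = max(lev),
               fold_range = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(tolerances) && nrow(tolerances)) {
    idx <- match(out$pesticide, tolerances$pesticide)
    out$reference_tolerance <- tolerances$lowest_tolerance[idx]
  } else {
    out$reference_tolerance <- NA_real_
  }
  out$median_to_reference_ratio <- out$median_level / out$reference_tolerance
  rownames(out) <- NULL
  out
}

collapse_duplicates <- function(records) {
  key <- paste(records$jurisdiction, records$pesticide,
               records$product_type, records$action_level, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

## Positive levels usable as ratio denominators: substitute the LOQ for
## zero-tolerance records when available, drop them otherwise.
effective_levels <- function(r) {
  lev <- ifelse(r$zero_tolerance & !is.na(r$loq), r$loq, r$action_level)
  lev[lev > 0]
}

#' Regulation breadth per pesticide
#'
#' How many jurisdictions regulate each pesticide (a jurisdiction counts
#' once per pesticide regardless of product types), plus histogram counts
#' of that breadth per pesticide class with integer bins \code{1..J}
#' (J = total jurisdictions in the data).
#'
#' @param records action-level records.
#' @return list with \code{breadth} (data.frame \code{pesticide},
#'   \code{class}, \code{n_jurisdictions}) and \code{histogram}
#'   (data.frame \code{class}, \code{n_jurisdictions},
#'   \code{n_pesticides} for every bin 1..J).
#' @export
regulation_breadth <- function(records) {
  if (nrow(records) == 0L) {
    return(list(breadth = data.frame(pesticide = character(),
                                     class = character(),
                                     n_jurisdictions = integer(),
                                     stringsAsFactors = FALSE),
                histogram = data.frame(class = character(),
                                       n_jurisdictions = integer(),
                                       n_pesticides = integer(),
                                       stringsAsFactors = FALSE)))
  }
  pests <- sort(unique(records$pesticide))
  breadth <- data.frame(
    pesticide = pests,
    class = records$class[match(pests, records$pesticide)],
    n_jurisdictions = vapply(pests, function(p)
      length(unique(records$jurisdiction[records$pesticide == p])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  J <- length(unique(records$jurisdiction))
  classes <- sort(unique(breadth$class))
  histogram <- do.call(rbind, lapply(classes, function(cl) {
    b <- breadth$n_jurisdictions[breadth$class == cl]
    data.frame(class = cl, n_jurisdictions = seq_len(J),
               n_pesticides = vapply(seq_len(J), function(k) sum(b == k), 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(histogram) <- NULL
  list(breadth = breadth, histogram = histogram)
}

#' Top pesticides by action-level variation
#'
#' The k pesticides with the largest fold-range (max over effective min),
#' descending, ties broken lexicographically by pesticide name.  Rows with
#' an undefined fold-range are excluded with a message.
#'
#' @param stats output of [pesticide_stats()].
#' @param k positive integer.
#' @return the top-k rows of `stats`.
#' @export
top_variation <- function(stats, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  undef <- is.na(stats$fold_range)
  if (any(undef)) {
    message("excluding ", sum(undef),
            " pesticide(s) with undefined fold-range: ",
            paste(stats$pesticide[undef], collapse = ", "))
  }
  s <- stats[!undef, , drop = FALSE]
  s <- s[order(-s$fold_range, s$pesticide), , drop = FALSE]
  out <- utils::head(s, k)
  rownames(out) <- NULL
  out
}

#' Barbell comparison of tolerances and median action levels
#'
#' One row per pesticide that has a reference tolerance, pairing the
#' lowest reference tolerance with the median action level; a table of the
#' highest residue values reported in the open literature may be joined as
#' an optional third value.  All values stay in ppm; plotting on a log
#' scale is left to the consumer.
#'
#' @param stats output of [pesticide_stats()] (computed with a tolerance
#'   table).
#' @param reported optional data.frame with columns \code{pesticide},
#'   \code{reported_ppm}.
#' @return data.frame \code{pesticide}, \code{lowest_tolerance},
#'   \code{median_level}, \code{reported_ppm}.
#' @export
barbell_table <- function(stats, reported = NULL) {
  s <- stats[!is.na(stats$reference_tolerance), , drop = FALSE]
  out <- data.frame(pesticide = s$pesticide,
                    lowest_tolerance = s$reference_tolerance,
                    median_level = s$median_level,
                    stringsAsFactors = FALSE)
  out$reported_ppm <- if (!is.null(reported)) {
    reported$reported_ppm[match(out$pesticide,
                                tolower(trimws(reported$pesticide)))]
  } else NA_real_
  rownames(out) <- NULL
  out
}

#' Mean fold-difference of median action levels over reference tolerances
#'
#' For each pesticide in the subset, the ratio of its median action level
#' to its lowest reference tolerance; summarized by the arithmetic or
#' geometric mean (the averaging method is recorded in the output since
#' published aggregates rarely state it).
#'
#' @param stats output of [pesticide_stats()] with tolerances joined.
#' @param subset character vector of pesticide names; default all
#'   pesticides with a tolerance and a defined median.
#' @param method \code{"arithmetic"} (default) or \code{"geometric"}.
#' @return list with \code{mean_ratio}, \code{method}, \code{n} and the
#'   per-pesticide \code{ratios}.
#' @export
mean_fold_above_reference <- function(stats, subset = NULL,
                                      method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (is.null(subset)) {
    subset <- stats$pesticide[!is.na(stats$reference_tolerance)]
  }
  subset <- tolower(trimws(subset))
  idx <- match(subset, stats$pesticide)
  missing_pest <- subset[is.na(idx)]
  if (length(missing_pest)) {
    stop("pesticide(s) absent from the statistics table: ",
         paste(missing_pest, collapse = ", "), call. = FALSE)
  }
  tol <- stats$reference_tolerance[idx]
  no_tol <- subset[is.na(tol)]
  if (length(no_tol)) {
    stop("pesticide(s) without a reference tolerance: ",
         paste(no_tol, collapse = ", "), call. = FALSE)
  }
  ratios <- stats$median_level[idx] / tol
  m <- switch(method, arithmetic = mean(ratios),
              geometric = exp(mean(log(ratios))))
  list(mean_ratio = m, method = method, n = length(ratios),
       ratios = stats::setNames(ratios, subset))
}
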