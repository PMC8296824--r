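#' Categorize qualifying conditions
#'
#' Assigns each (jurisdiction, condition) row its category and domain from
#' the category map.  Conditions absent from the map are retained with
#' category and domain \code{"uncategorized"} and reported separately.
#' Assignment is deterministic and idempotent.
#'
#' @param conditions table from [read_conditions()].
#' @param map category map from [read_category_map()].
#' @return object of class \code{condition_records}: list with
#'   \code{records} (data.frame \code{jurisdiction}, \code{condition},
#'   \code{category}, \code{domain}) and \code{uncategorized} (character
#'   vector of condition names not covered by the map).
#' @export
categorize_conditions <- function(conditions, map) {
  check_category_map(map)
  idx <- match(conditions$condition, map$condition)
  records <- data.frame(
    jurisdiction = conditions$jurisdiction,
    condition = conditions$condition,
    category = ifelse(is.na(idx), "uncategorized", map$category[idx]),
    domain = ifelse(is.na(idx), "uncategorized", map$domain[idx]),
    stringsAsFactors = FALSE)
  structure(list(records = records,
                 uncategorized = sort(unique(records$condition[is.na(idx)]))),
            class = "condition_records")
}

#' @export
print.condition_records <- function(x, ...) {
  cat("Qualifying-condition records:", nrow(x$records), "rows,",
      length(unique(x$records$jurisdiction)), "jurisdictions\n")
  if (length(x$uncategorized)) {
    cat("Uncategorized conditions:", paste(x$uncategorized, collapse = ", "),
        "\n")
  }
  invisible(x)
}

cond_frame <- function(x) {
  if (inherits(x, "condition_records")) x$records else x
}

#' Category coverage across jurisdictions
#'
#' For each category, the number of jurisdictions listing at least one
#' condition in it (a jurisdiction counts once per category).  Categories
#' present in `all_categories` but listed by no jurisdiction are reported
#' with count 0.
#'
#' @param records a \code{condition_records} object or its records
#'   data.frame.
#' @param all_categories optional character vector of categories to report
#'   even at zero coverage (e.g. `unique(map$category)`).
#' @return data.frame \code{category}, \code{n_jurisdictions}, sorted
#'   descending then by category.
#' @export
category_coverage <- function(records, all_categories = NULL) {
  rec <- cond_frame(records)
  cats <- sort(unique(c(rec$category, all_categories)))
  out <- data.frame(
    category = cats,
    n_jurisdictions = vapply(cats, function(cl)
      length(unique(rec$jurisdiction[rec$category == cl])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_jurisdictions, out$category), ]
  rownames(out) <- NULL
  out
}

#' Distinct-condition totals per domain
#'
#' Counts distinct condition names once per domain and sums to a grand
#' total; since every condition maps to exactly one category and every
#' category to one domain, domains are disjoint and the grand total equals
#' the sum of the domain counts.  A condition observed under two domains
#' (possible only with an inconsistent map) is a validation error.
#'
#' @param records a \code{condition_records} object or its records
#'   data.frame.
#' @return list with \code{per_domain} (named integer vector) and
#'   \code{total}.
#' @export
domain_totals <- function(records) {
  rec <- cond_frame(records)
  if (nrow(rec) == 0L) {
    return(list(per_domain = integer(), total = 0L))
  }
  inv <- unique(rec[, c("condition", "domain")])
  dup <- inv$condition[duplicated(inv$condition)]
  if (length(dup)) {
    stop("condition mapped to more than one domain: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  per <- vapply(split(inv$condition, inv$domain), length, 0L)
  list(per_domain = per, total = sum(per))
}

#' Per-jurisdiction condition counts
#'
#' Distinct conditions listed by each jurisdiction, and the mean count.
#'
#' @param records a \code{condition_records} object or its records
#'   data.frame.
#' @param digits rounding applied to the reported mean (default 0, i.e.
#'   whole conditions).
#' @return list with \code{per_jurisdiction} (data.frame
#'   \code{jurisdiction}, \code{n_conditions}, descending) and
#'   \code{mean_conditions}.
#' @export
jurisdiction_summary <- function(records, digits = 0) {
  rec <- cond_frame(records)
  if (nrow(rec) == 0L) {
    return(list(per_jurisdiction = data.frame(jurisdiction = character(),
                                              n_conditions = integer(),
                                              stringsAsFactors = FALSE),
                mean_conditions = NaN))
  }
  per <- vapply(split(rec$condition, rec$jurisdiction),
                function(x) length(unique(x)), 0L)
  out <- data.frame(jurisdiction = names(per), n_conditions = as.integer(per),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_conditions, out$jurisdiction), ]
  rownames(out) <- NULL
  list(per_jurisdiction = out,
       mean_conditions = round(mean(per), digits))
}
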