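## Readers for the regulatory-analysis inputs: per-jurisdiction action
## levels, reference tolerances, qualifying-condition tables and the
## condition category map.  All are CSV with '#' comments tolerated.

#' Read a pesticide action-level table
#'
#' One row per (jurisdiction, pesticide, product type) action level, in
#' ppm.  An action level of exactly 0 ppm marks a zero-tolerance rule:
#' any residue at or above the laboratory's limit of quantitation (LOQ)
#' fails the sample, so such rows should carry \code{loq_ppm}.
#'
#' @param path CSV with columns \code{jurisdiction}, \code{pesticide},
#'   \code{class}, \code{product_type} (optional, default \code{"any"}),
#'   \code{action_level_ppm} and optional \code{loq_ppm}.
#' @return data.frame with columns \code{jurisdiction}, \code{pesticide}
#'   (case-normalized), \code{class}, \code{product_type},
#'   \code{action_level} (ppm), \code{loq} (ppm or NA) and
#'   \code{zero_tolerance}.
#' @export
read_action_level_table <- function(path) {
  df <- read_commented_delim(path, sep = ",")
  if (is.null(df)) {
    return(empty_action_levels())
  }
  jur <- trimws(require_column(df, "jurisdiction", path))
  pest <- tolower(trimws(require_column(df, "pesticide", path)))
  cls <- pick_column(df, "class")
  cls <- if (is.null(cls)) "other" else tolower(trimws(cls))
  ptype <- pick_column(df, "product_type")
  ptype <- if (is.null(ptype)) "any" else tolower(trimws(ptype))
  ptype[!nzchar(ptype)] <- "any"
  lev <- parse_ppm(require_column(df, "action_level_ppm", path),
                   "action_level_ppm", path)
  if (any(lev < 0)) {
    stop("negative action level in ", path, " (pesticide ",
         paste(unique(pest[lev < 0]), collapse = ", "), ")", call. = FALSE)
  }
  loq_raw <- pick_column(df, "loq_ppm")
  loq <- if (is.null(loq_raw)) NA_real_ else {
    loq_raw[!nzchar(trimws(loq_raw))] <- NA_character_
    parse_ppm(loq_raw, "loq_ppm", path, allow_na = TRUE)
  }
  if (any(!is.na(loq) & loq <= 0)) {
    stop("loq_ppm must be positive when present in ", path, call. = FALSE)
  }
  data.frame(jurisdiction = jur, pesticide = pest, class = cls,
             product_type = ptype, action_level = lev, loq = loq,
             zero_tolerance = lev == 0, stringsAsFactors = FALSE)
}

empty_action_levels <- function() {
  data.frame(jurisdiction = character(), pesticide = character(),
             class = character(), product_type = character(),
             action_level = numeric(), loq = numeric(),
             zero_tolerance = logical(), stringsAsFactors = FALSE)
}

parse_ppm <- function(x, column, path, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !(allow_na & is.na(x))
  if (any(bad)) {
    stop("non-numeric value in column '", column, "' of ", path, ": ",
         paste(utils::head(unique(x[bad]), 3L), collapse = ", "),
         call. = FALSE)
  }
  v
}

#' Read a reference-tolerance table
#'
#' The lowest (most stringent across commodities) reference tolerance per
#' pesticide, e.g. the lowest U.S. EPA food-commodity tolerance.  The table
#' is taken as given; commodity choice is not re-derived.
#'
#' @param path CSV with columns \code{pesticide},
#'   \code{lowest_tolerance_ppm} and optional \code{commodity}.
#' @return data.frame with columns \code{pesticide}, \code{lowest_tolerance},
#'   \code{commodity}.
#' @export
read_reference_tolerances <- function(path) {
  df <- read_commented_delim(path, sep = ",")
  if (is.null(df)) {
    return(data.frame(pesticide = character(), lowest_tolerance = numeric(),
                      commodity = character(), stringsAsFactors = FALSE))
  }
  pest <- tolower(trimws(require_column(df, "pesticide", path)))
  tol <- parse_ppm(require_column(df, "lowest_tolerance_ppm", path),
                   "lowest_tolerance_ppm", path)
  if (any(tol <= 0)) {
    stop("reference tolerances must be positive in ", path, call. = FALSE)
  }
  if (anyDuplicated(pest)) {
    stop("duplicate pesticide rows in reference tolerance table ", path,
         call. = FALSE)
  }
  com <- pick_column(df, "commodity")
  if (is.null(com)) com <- NA_character_
  data.frame(pesticide = pest, lowest_tolerance = tol,
             commodity = as.character(com), stringsAsFactors = FALSE)
}

#' Read a qualifying-conditions table
#'
#' One row per (jurisdiction, listed qualifying condition).
#'
#' @param path CSV with columns \code{jurisdiction}, \code{condition}.
#' @return data.frame with columns \code{jurisdiction}, \code{condition}
#'   (the normalized name) and \code{condition_raw}.
#' @export
read_conditions <- function(path) {
  df <- read_commented_delim(path, sep = ",")
  if (is.null(df)) {
    return(data.frame(jurisdiction = character(), condition = character(),
                      condition_raw = character(), stringsAsFactors = FALSE))
  }
  jur <- trimws(require_column(df, "jurisdiction", path))
  raw <- require_column(df, "condition", path)
  data.frame(jurisdiction = jur, condition = normalize_condition(raw),
             condition_raw = trimws(raw), stringsAsFactors = FALSE)
}

## Condition names are compared after lower-casing, stripping punctuation
## and collapsing whitespace, so cosmetic listing differences between
## jurisdictions do not split one condition into several.
normalize_condition <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Read a condition category map
#'
#' The mapping from qualifying-condition names to categories (and from
#' categories to their domain: neurological, psychological or
#' pain-and-injury) is data, not algorithm: it ships as an editable file.
#' A CSV map has columns \code{condition}, \code{category}, \code{domain};
#' a YAML map is a list of categories, each with a \code{domain} and a
#' \code{conditions} vector.
#'
#' @param path CSV or YAML file.
#' @return data.frame with columns \code{condition} (normalized),
#'   \code{category}, \code{domain}.
#' @export
read_category_map <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML category maps",
           call. = FALSE)
    }
    y <- yaml::read_yaml(path)
    map <- do.call(rbind, lapply(names(y), function(cat) {
      data.frame(condition = normalize_condition(y[[cat]]$conditions),
                 category = cat, domain = tolower(y[[cat]]$domain),
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- read_commented_delim(path, sep = ",")
    if (is.null(df)) stop("empty category map: ", path, call. = FALSE)
    map <- data.frame(
      condition = normalize_condition(require_column(df, "condition", path)),
      category = trimws(require_column(df, "category", path)),
      domain = tolower(trimws(require_column(df, "domain", path))),
      stringsAsFactors = FALSE)
  }
  check_category_map(map)
  map
}

check_category_map <- function(map) {
  ## each category must sit in exactly one domain
  per_cat <- tapply(map$domain, map$category, function(d) length(unique(d)))
  if (any(per_cat > 1L)) {
    stop("category mapped to more than one domain: ",
         paste(names(per_cat)[per_cat > 1L], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(map$condition)) {
    stop("condition mapped to more than one category: ",
         paste(unique(map$condition[duplicated(map$condition)]),
               collapse = ", "), call. = FALSE)
  }
  invisible(map)
}
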