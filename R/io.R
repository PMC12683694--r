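#' Read and validate a capture-records table
#'
#' Expects a CSV with columns `individual_id`, `site`, `date` (ISO 8601),
#' `sex` (`F`, `M`, or `U`, case-insensitive; `female`/`male`/`unknown`
#' accepted), and `svl_mm`.  Duplicate rows for the same individual on the
#' same date are collapsed to the first with a warning.  Snout-vent lengths
#' outside 50-1500 mm, unparseable dates, or missing columns raise an error
#' naming the offending row.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @return data frame of validated capture records with a `year` column
#'   added, classed `capture_records`.
#' @export
read_captures <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "site", "date", "sex", "svl_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("capture table is missing column(s): ",
                         paste(miss, collapse = ", "))
  dt <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- which(is.na(dt))
  if (length(bad)) stop("unparseable date in row ", bad[1],
                        " ('", df$date[bad[1]], "'); dates must be ISO 8601")
  svl <- suppressWarnings(as.numeric(df$svl_mm))
  bad <- which(is.na(svl) | svl < 50 | svl > 1500)
  if (length(bad)) stop("invalid svl_mm in row ", bad[1], " ('",
                        df$svl_mm[bad[1]], "'); must be a number in [50, 1500]")
  sx <- toupper(substr(trimws(as.character(df$sex)), 1, 1))
  bad <- which(!sx %in% c("F", "M", "U"))
  if (length(bad)) stop("invalid sex in row ", bad[1], " ('", df$sex[bad[1]],
                        "'); must be one of F, M, U")
  out <- data.frame(individual_id = as.character(df$individual_id),
                    site = as.character(df$site),
                    date = dt, sex = sx, svl_mm = svl,
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[c("individual_id", "date")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (individual, date) row(s) collapsed; ",
            "first measurement kept")
    out <- out[!dup, , drop = FALSE]
  }
  out$year <- as.integer(format(out$date, "%Y"))
  class(out) <- c("capture_records", class(out))
  out
}

#' Read a sampling-effort table
#'
#' One row per sampled trap-day: columns `site`, `year`, `date`.  Day
#' indices within a site-year (the secondary occasions) are assigned in
#' date order.
#'
#' @param path CSV file path or data frame.
#' @return data frame with columns `site`, `year`, `date`, `day` (occasion
#'   index within site-year).
#' @export
read_effort <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("effort table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df$site <- as.character(df$site)
  df$date <- as.Date(as.character(df$date))
  if (anyNA(df$date)) stop("effort table contains unparseable dates")
  df <- df[!duplicated(df[c("site", "year", "date")]), , drop = FALSE]
  df <- df[order(df$site, df$year, df$date), , drop = FALSE]
  df$day <- stats::ave(seq_len(nrow(df)),
                       paste(df$site, df$year), FUN = seq_along)
  df
}

#' Read a site-year drought index table
#'
#' Columns `site`, `year`, `spei06`: the 6-month standardized
#' precipitation-evapotranspiration index for each site and year (negative
#' values are drier than average).  The index is already standardized by
#' construction and is used as-is.
#'
#' @param path CSV file path or data frame.
#' @return data frame with columns `site`, `year`, `spei06`.
#' @export
read_spei <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "spei06")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SPEI table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df$site <- as.character(df$site)
  df$spei06 <- as.numeric(df$spei06)
  if (anyNA(df$spei06)) stop("SPEI values must be numeric")
  df
}

## site x year matrix of SPEI aligned to a ring_covariates object
spei_matrix <- function(spei, rings) {
  m <- matrix(NA_real_, length(rings$sites), length(rings$years),
              dimnames = list(rings$sites, rings$years))
  i <- match(spei$site, rings$sites)
  j <- match(as.character(spei$year), rings$years)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- spei$spei06[ok]
  if (anyNA(m)) stop("SPEI table does not cover every site-year")
  m
}
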