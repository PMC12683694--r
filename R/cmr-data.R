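#' Build robust-design capture histories
#'
#' Arranges capture records into the dense detection array used by the
#' robust-design model: years are primary periods (open between, closed
#' within) and sampled trap-days within a site-year are secondary occasions.
#' A detection recorded on a day that is not in the effort table for that
#' site-year is an error.  Within-year recaptures are retained (they inform
#' daily detection); a single size per individual-year (the first
#' measurement) is kept for the growth chain.
#'
#' @param records a `capture_records` data frame from [read_captures()].
#' @param effort effort table from [read_effort()].
#' @param include_unknown_sex keep individuals of unknown sex? The default
#'   drops them, as the model estimates sex-specific parameters.
#' @return object of class `cmr_data`: detection array `y`
#'   (individual x year x day), `day_mask` (site x year x day effort
#'   indicator), `n_days` (site x year), `first_year`/`first_day`, `svl_obs`
#'   (individual x year, NA when unmeasured), `sex`, `site`, `sites`,
#'   `years`, and a `counts` summary (individuals, between-year recaptures,
#'   recaptures by lag).
#' @export
build_capture_histories <- function(records, effort,
                                    include_unknown_sex = FALSE) {
  rec <- as.data.frame(records)
  if (!include_unknown_sex) rec <- rec[rec$sex != "U", , drop = FALSE]
  multi <- tapply(rec$site, rec$individual_id,
                  function(s) length(unique(s)))
  if (any(multi > 1L))
    stop("individual(s) observed at more than one site: ",
         paste(utils::head(names(multi)[multi > 1L], 3), collapse = ", "))
  sites <- sort(unique(effort$site))
  years <- sort(unique(effort$year))
  nyear <- length(years); nsite <- length(sites)
  maxday <- max(effort$day)
  n_days <- matrix(0L, nsite, nyear, dimnames = list(sites, years))
  day_mask <- array(0, c(nsite, nyear, maxday))
  si_e <- match(effort$site, sites); yi_e <- match(effort$year, years)
  for (r in seq_len(nrow(effort))) {
    day_mask[si_e[r], yi_e[r], effort$day[r]] <- 1
    n_days[si_e[r], yi_e[r]] <- max(n_days[si_e[r], yi_e[r]], effort$day[r])
  }
  ## map each capture to its occasion index
  key_e <- paste(effort$site, effort$year, effort$date)
  key_r <- paste(rec$site, rec$year, rec$date)
  occ <- effort$day[match(key_r, key_e)]
  if (anyNA(occ)) {
    bad <- which(is.na(occ))[1]
    stop("capture of '", rec$individual_id[bad], "' on ", rec$date[bad],
         " at site ", rec$site[bad], " is not a sampled effort day")
  }
  ids <- unique(rec$individual_id)
  nind <- length(ids)
  ii <- match(rec$individual_id, ids)
  yi <- match(rec$year, years)
  si <- match(rec$site, sites)
  if (anyNA(yi)) stop("capture year outside the effort table's year range")
  y <- array(0L, c(nind, nyear, maxday))
  y[cbind(ii, yi, occ)] <- 1L
  sex <- rec$sex[match(ids, rec$individual_id)]
  site <- si[match(ids, rec$individual_id)]
  ## first measurement per individual-year for the size chain
  rec <- rec[order(rec$individual_id, rec$date), , drop = FALSE]
  fm <- rec[!duplicated(rec[c("individual_id", "year")]), , drop = FALSE]
  svl_obs <- matrix(NA_real_, nind, nyear)
  svl_obs[cbind(match(fm$individual_id, ids), match(fm$year, years))] <-
    fm$svl_mm
  det_year <- apply(y, 1:2, max)
  first_year <- apply(det_year, 1L, function(v) which(v == 1L)[1])
  first_day <- vapply(seq_len(nind), function(i)
    which(y[i, first_year[i], ] == 1L)[1], integer(1))
  ## recapture bookkeeping
  lags <- unlist(lapply(seq_len(nind), function(i) {
    yrs <- which(det_year[i, ] == 1L)
    if (length(yrs) > 1L) yrs[-1] - first_year[i] else integer(0)
  }))
  counts <- list(individuals = nind,
                 recaptures_between_years = length(lags),
                 recaptured_individuals = sum(rowSums(det_year) > 1L),
                 by_lag = if (length(lags)) table(lags) else table(integer(0)))
  structure(list(y = y, day_mask = day_mask, n_days = n_days,
                 first_year = first_year, first_day = first_day,
                 svl_obs = svl_obs, sex = sex, site = site,
                 sites = sites, years = as.character(years),
                 counts = counts),
            class = "cmr_data")
}

#' @export
print.cmr_data <- function(x, ...) {
  cat(sprintf(paste0("Robust-design capture histories: %d individuals, ",
                     "%d sites, %d years\n"),
              x$counts$individuals, length(x$sites), length(x$years)))
  cat(sprintf("  %d between-year recaptures (%d individuals recaptured)\n",
              x$counts$recaptures_between_years,
              x$counts$recaptured_individuals))
  invisible(x)
}

#' Marginal log-likelihood of a small capture-history set
#'
#' Computes the exact likelihood of detection histories under the
#' robust-design model by marginalizing the latent alive and availability
#' states with a forward pass over a three-state chain (alive and on site,
#' alive but temporarily off site, dead), conditioning on first capture.
#' Intended as an oracle hook: instances larger than 4 individuals, 3 years,
#' or a number of secondary occasions above 3 are refused so results stay
#' directly checkable by exhaustive enumeration.
#'
#' @param y detection array, individual x year x day (0/1).
#' @param first first-capture year per individual.
#' @param first_day first-capture day within the first year per individual;
#'   only later days of the first year contribute to the likelihood.
#' @param phi annual survival: scalar, or matrix individual x (years - 1)
#'   (survival from year `t` to `t + 1`).
#' @param gamma availability: scalar or matrix individual x years (used for
#'   years after first capture).
#' @param p daily detection probability: scalar or matrix year x day.
#' @return scalar log-likelihood.
#' @export
joint_marginal_loglik <- function(y, first, first_day, phi, gamma, p) {
  dm <- dim(y)
  if (dm[1] > 4L || dm[2] > 3L || dm[3] > 3L)
    stop("instance too large to enumerate: at most 4 individuals x 3 years",
         " x 3 days")
  nind <- dm[1]; nyear <- dm[2]; nday <- dm[3]
  phi_m <- matrix(phi, nind, max(nyear - 1L, 1L))
  gam_m <- matrix(gamma, nind, nyear)
  p_m <- matrix(p, nyear, nday)
  obs_lik <- function(i, t, alive_avail, from_day = 0L) {
    js <- seq_len(nday)
    js <- js[js > from_day]
    if (!length(js)) return(1)
    yy <- y[i, t, js]
    if (alive_avail) prod(ifelse(yy == 1, p_m[t, js], 1 - p_m[t, js]))
    else as.numeric(all(yy == 0))
  }
  ll <- 0
  for (i in seq_len(nind)) {
    f <- first[i]
    ## state probs: (alive & avail, alive & unavail, dead)
    fw <- c(obs_lik(i, f, TRUE, from_day = first_day[i]), 0, 0)
    if (f < nyear) for (t in (f + 1L):nyear) {
      s <- phi_m[i, t - 1L]; g <- gam_m[i, t]
      alive <- fw[1] + fw[2]
      fw <- c(alive * s * g, alive * s * (1 - g), fw[3] + alive * (1 - s))
      fw <- fw * c(obs_lik(i, t, TRUE), obs_lik(i, t, FALSE),
                   obs_lik(i, t, FALSE))
    }
    ll <- ll + log(sum(fw))
  }
  ll
}
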