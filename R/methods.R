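#' @export
print.growsurv_fit <- function(x, ...) {
  lab <- switch(x$model, growth = "Hierarchical von Bertalanffy growth model",
                cmr = "Integrated robust-design growth-survival model")
  cat(lab, "\n")
  cat(sprintf("  %d posterior draws (%d chain(s), profile '%s'), seed %d\n",
              nrow(x$draws), x$mcmc$chains, x$mcmc$profile, x$seed))
  if (isTRUE(x$convergence$flag))
    cat("  WARNING: convergence flag raised (R-hat > 1.01)\n")
  core <- utils::head(x$summary, 12)
  print(core, digits = 3, row.names = FALSE)
  if (nrow(x$summary) > 12) cat("  ...", nrow(x$summary) - 12, "more rows\n")
  invisible(x)
}

#' @export
summary.growsurv_fit <- function(object, ...) {
  out <- object$summary
  if (object$model == "growth") {
    attr(out, "scales") <- object$scales$summary
  } else {
    attr(out, "scales_phi") <- object$scales_phi$summary
    attr(out, "scales_k") <- object$scales_k$summary
    attr(out, "sex_contrasts") <- object$sex_contrasts
  }
  out
}

#' @export
coef.growsurv_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Expected lengths and residuals for a growth fit
#'
#' `fitted()` returns the posterior-mean expected length for each interval
#' (requires the fit to have been run with `gof = TRUE`); `residuals()`
#' the observed minus fitted end-of-interval lengths.
#'
#' @param object a `growth_fit`.
#' @param ... unused.
#' @return numeric vector, one value per growth interval.
#' @export
fitted.growth_fit <- function(object, ...) {
  el_cols <- grep("^EL\\[", colnames(object$draws))
  if (!length(el_cols)) stop("re-run fit_growth(gof = TRUE) to store ",
                             "expected lengths")
  idx <- as.integer(sub("^EL\\[(\\d+)\\]$", "\\1",
                        colnames(object$draws)[el_cols]))
  colMeans(object$draws[, el_cols[order(idx)], drop = FALSE])
}

#' @rdname fitted.growth_fit
#' @export
residuals.growth_fit <- function(object, ...) {
  object$intervals$L1 - fitted(object)
}

#' Predict expected length for new intervals
#'
#' Population-level prediction (random effects at zero): expected SVL one
#' year ahead for given starting length, sex, and covariate values, with
#' equal-tailed credible intervals from the posterior draws.
#'
#' @param object a `growth_fit`.
#' @param newdata data frame with columns `L0`, `sex` (`"F"`/`"M"`) and
#'   optionally `R_w`, `spei` (default 0) and `dt` (default 1).
#' @param ... unused.
#' @return data frame with `mean`, `q2.5`, `q97.5` expected lengths (mm).
#' @export
predict.growth_fit <- function(object, newdata, ...) {
  d <- object$draws
  sx <- ifelse(newdata$sex == "F", 1, 2)
  Rw <- newdata$R_w %||% rep(0, nrow(newdata))
  sp <- newdata$spei %||% rep(0, nrow(newdata))
  dt <- newdata$dt %||% rep(1, nrow(newdata))
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    a <- d[, paste0("eps_a[", sx[i], "]")]
    k <- exp(d[, paste0("mu_k[", sx[i], "]")] + d[, "b_rice"] * Rw[i] +
             d[, "b_dr"] * sp[i])
    el <- expected_length(a, k, newdata$L0[i], dt[i])
    c(mean = mean(el), stats::quantile(el, c(0.025, 0.975)))
  })
  out <- as.data.frame(do.call(rbind, out))
  names(out) <- c("mean", "q2.5", "q97.5")
  out
}

#' Plot methods for fitted models
#'
#' For a growth fit, plots the posterior-mean distance-weight kernel with
#' the derived spatial scales.  For an integrated fit, plots the posterior
#' size-survival spline with its 95% credible band.
#'
#' @param x a fitted model object.
#' @param ... passed to the underlying plot call.
#' @return the object, invisibly.
#' @export
plot.growth_fit <- function(x, ...) {
  grid <- x$rings$grid
  w <- kernel_weights(mean(x$draws[, "sig_rice"]), grid)
  plot(grid$midpoints, w / grid$cell_counts /
         max(w / grid$cell_counts), type = "l",
       xlab = "Distance (km)", ylab = "Relative weight per unit area",
       main = "Landscape weighting (growth)", ...)
  abline(v = x$scales$summary$mean[2:3], lty = c(2, 3))
  legend("topright", legend = c("scale_max", "scale_90"), lty = c(2, 3),
         bty = "n")
  invisible(x)
}

#' @rdname plot.growth_fit
#' @export
plot.cmr_fit <- function(x, ...) {
  fcols <- grep("^fg\\[", colnames(x$draws))
  idx <- as.integer(sub("^fg\\[(\\d+)\\]$", "\\1", colnames(x$draws)[fcols]))
  fd <- x$draws[, fcols[order(idx)], drop = FALSE]
  xg <- x$size_grid
  m <- colMeans(fd)
  lo <- apply(fd, 2, stats::quantile, 0.025)
  hi <- apply(fd, 2, stats::quantile, 0.975)
  plot(xg, m, type = "l", ylim = range(lo, hi),
       xlab = "SVL (mm)", ylab = "Size effect on survival (logit)",
       main = "Size-survival spline", ...)
  graphics::polygon(c(xg, rev(xg)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(xg, m)
  invisible(x)
}

#' Export posterior draws and a JSON summary
#'
#' Writes the monitored draws as CSV and a JSON summary (mean, SD,
#' 2.5%/97.5%, R-hat when available, effective sample size) keyed by
#' parameter name, plus the seed and MCMC settings needed to reproduce the
#' fit.
#'
#' @param fit a `growsurv_fit`.
#' @param dir output directory.
#' @param draws also write the full draw matrix?
#' @return `dir`, invisibly.
#' @export
export_posterior <- function(fit, dir, draws = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (draws)
    utils::write.csv(as.data.frame(fit$draws),
                     file.path(dir, paste0(fit$model, "_draws.csv")),
                     row.names = FALSE)
  summ <- fit$summary
  entries <- stats::setNames(lapply(seq_len(nrow(summ)), function(i)
    as.list(summ[i, setdiff(names(summ), "parameter")])),
    summ$parameter)
  jsonlite::write_json(
    list(model = fit$model, seed = fit$seed,
         mcmc = fit$mcmc[c("chains", "n_adapt", "n_burn", "n_iter",
                           "thin", "profile")],
         parameters = entries),
    file.path(dir, paste0(fit$model, "_summary.json")),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(summ, file.path(dir, paste0(fit$model, "_summary.csv")),
                   row.names = FALSE)
  invisible(dir)
}
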