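## Independent oracle implementations used to cross-check the package.
## These deliberately use different algorithms from the package internals.

## Exhaustive-enumeration marginal likelihood for tiny robust-design
## instances: sums over every alive x available configuration.
enum_marginal_loglik <- function(y, first, first_day, phi, gamma, p) {
  dm <- dim(y)
  nind <- dm[1]; nyear <- dm[2]; nday <- dm[3]
  phi_m <- matrix(phi, nind, max(nyear - 1L, 1L))
  gam_m <- matrix(gamma, nind, nyear)
  p_m <- matrix(p, nyear, nday)
  day_lik <- function(i, t, present, from_day = 0L) {
    js <- seq_len(nday); js <- js[js > from_day]
    if (!length(js)) return(1)
    yy <- y[i, t, js]
    if (present) prod(ifelse(yy == 1, p_m[t, js], 1 - p_m[t, js]))
    else as.numeric(all(yy == 0))
  }
  total_ll <- 0
  for (i in seq_len(nind)) {
    f <- first[i]
    later <- if (f < nyear) (f + 1L):nyear else integer(0)
    k <- length(later)
    lik <- 0
    ## enumerate z (alive) and w (available) jointly over later years
    for (code in seq_len(max(4L^k, 1L)) - 1L) {
      digs <- (code %/% 4L^(seq_len(k) - 1L)) %% 4L
      z <- digs %/% 2L; w <- digs %% 2L   # per later year
      ## dead stays dead
      if (k > 1 && any(diff(z) > 0)) next
      pr <- day_lik(i, f, TRUE, from_day = first_day[i])
      alive_prev <- 1
      for (j in seq_len(k)) {
        t <- later[j]
        s <- phi_m[i, t - 1L]; g <- gam_m[i, t]
        pr <- pr * if (z[j] == 1) alive_prev * s else
          (if (alive_prev == 1) 1 - s else 1)
        if (z[j] == 1) pr <- pr * (if (w[j] == 1) g else 1 - g)
        else if (w[j] == 1) pr <- pr * 0   # availability undefined when dead
        present <- z[j] == 1 && w[j] == 1
        pr <- pr * day_lik(i, t, present)
        alive_prev <- z[j]
        if (pr == 0) break
      }
      lik <- lik + pr
    }
    total_ll <- total_ll + log(lik)
  }
  total_ll
}

## Cox-de Boor recursion for a single B-spline basis function
coxdeboor <- function(x, knots, i, d) {
  if (d == 0)
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  denom1 <- knots[i + d] - knots[i]
  denom2 <- knots[i + d + 1] - knots[i + 1]
  a <- if (denom1 > 0) (x - knots[i]) / denom1 * coxdeboor(x, knots, i, d - 1) else 0
  b <- if (denom2 > 0) (knots[i + d + 1] - x) / denom2 *
         coxdeboor(x, knots, i + 1, d - 1) else 0
  a + b
}

## d-separation oracle via moralized ancestral graph reachability
## (independent of the package's path-enumeration approach)
moral_dsep <- function(edges, a, b, Z, nodes) {
  keep <- unique(c(a, b, Z))
  ## ancestral set
  anc <- keep
  repeat {
    par <- unique(edges[edges[, 2] %in% anc, 1])
    new <- setdiff(par, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  e <- edges[edges[, 1] %in% anc & edges[, 2] %in% anc, , drop = FALSE]
  ## moralize: undirected edges plus marriages of co-parents
  und <- rbind(e, e[, 2:1, drop = FALSE])
  for (v in anc) {
    pa <- e[e[, 2] == v, 1]
    if (length(pa) > 1) {
      prs <- t(utils::combn(pa, 2))
      und <- rbind(und, prs, prs[, 2:1, drop = FALSE])
    }
  }
  ## remove Z and test connectivity a -- b
  und <- und[!(und[, 1] %in% Z) & !(und[, 2] %in% Z), , drop = FALSE]
  reach <- a
  repeat {
    nxt <- setdiff(und[und[, 1] %in% reach, 2], reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  !(b %in% reach)
}

## random DAG on n labelled nodes: upper-triangular edge inclusion
random_dag_edges <- function(n, p_edge = 0.4) {
  nodes <- LETTERS[seq_len(n)]
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) out <- rbind(out, c(nodes[i], nodes[j]))
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  out
}

## small capture-record and effort fixtures built in code
tiny_captures <- function() {
  data.frame(
    individual_id = c("a1", "a1", "a2", "a3", "a3", "a3"),
    site = c("S1", "S1", "S1", "S2", "S2", "S2"),
    date = c("2018-06-02", "2019-06-03", "2018-06-02",
             "2018-06-04", "2019-06-02", "2021-06-02"),
    sex = c("F", "F", "M", "F", "F", "F"),
    svl_mm = c(500, 560, 430, 610, 650, 700),
    stringsAsFactors = FALSE)
}

tiny_effort <- function(years = 2018:2021, sites = c("S1", "S2"),
                        n_days = 5) {
  do.call(rbind, lapply(sites, function(s)
    do.call(rbind, lapply(years, function(y)
      data.frame(site = s, year = y,
                 date = as.Date(sprintf("%d-06-01", y)) + seq_len(n_days),
                 stringsAsFactors = FALSE)))))
}

## short MCMC settings for unit-test fits
test_mcmc <- function(n_iter = 600)
  mcmc_profile("test", chains = 1, n_adapt = 150, n_burn = 150,
               n_iter = n_iter)
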