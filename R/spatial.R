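# Geographic distances between reefs, isolation-by-distance and temperature
# regressions over reef pairs, and molecular-rate arithmetic.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (mean Earth
#' radius). Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180)) stop("longitude outside [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Per-reef-pair genetic and geographic summaries
#'
#' Builds one row per unordered reef pair: great-circle distance (km)
#' between reef coordinates (mean of member-colony coordinates), mean
#' between-reef nucleotide distance (mean d over cross-reef colony pairs),
#' the fraction of cross-reef colony pairs sharing a haplogroup, the same
#' fraction restricted to rare groups (sizes in \code{rare_range}), and the
#' absolute difference in heat-exposure fraction (NA when absent).
#'
#' @param dm a \code{mito_dist}.
#' @param h a \code{mito_haplogroups}.
#' @param m a \code{mito_metadata}.
#' @param rare_range inclusive size range defining rare groups.
#' @return data frame of class \code{reef_pair_table}: reef1, reef2,
#'   geo_km, nuc_dist, share, share_rare, heat_diff.
#' @export
reef_pair_table <- function(dm, h, m, rare_range = c(2, 10)) {
  stopifnot(inherits(dm, "mito_dist"), inherits(h, "mito_haplogroups"),
            inherits(m, "mito_metadata"))
  idx <- match(dm$ids, m$colony)
  reef <- m$reef[idx]
  reefs <- sort(unique(reef))
  if (length(reefs) < 2L) stop("need at least 2 reefs")

  lat <- tapply(m$lat[idx], reef, mean)
  lon <- tapply(m$lon[idx], reef, mean)
  bad <- reefs[!is.finite(lat[reefs]) | !is.finite(lon[reefs])]
  if (length(bad)) {
    warning("reef(s) without usable coordinates dropped: ",
            paste(bad, collapse = ", "))
    reefs <- setdiff(reefs, bad)
    if (length(reefs) < 2L) stop("fewer than 2 reefs with coordinates")
  }
  heat <- if ("heat_fraction" %in% names(m)) {
    tapply(m$heat_fraction[idx], reef, mean)
  } else NULL

  rf <- factor(reef, levels = reefs)
  keep_r <- !is.na(rf)
  nr <- as.vector(table(rf))
  # cross-reef pair sums of d via grouped matrix
  A <- rowsum(dm$D[keep_r, keep_r, drop = FALSE] * 1.0, rf[keep_r])
  S <- rowsum(t(A), rf[keep_r])          # reef x reef sums of d
  # haplogroup sharing via the group-by-reef count table
  grp <- h$assignment$group[match(dm$ids, h$assignment$colony)]
  K <- table(factor(grp[keep_r]), rf[keep_r])
  shared <- t(K) %*% K                    # cross pairs in the same group
  sizes <- rowSums(K)
  rare <- sizes >= rare_range[1L] & sizes <= rare_range[2L]
  Kr <- K[rare, , drop = FALSE]
  shared_rare <- if (nrow(Kr)) t(Kr) %*% Kr else
    matrix(0, length(reefs), length(reefs))

  pairs <- utils::combn(seq_along(reefs), 2L)
  r1 <- pairs[1L, ]; r2 <- pairs[2L, ]
  npair <- nr[r1] * nr[r2]
  out <- data.frame(
    reef1 = reefs[r1], reef2 = reefs[r2],
    geo_km = haversine_km(lat[reefs[r1]], lon[reefs[r1]],
                          lat[reefs[r2]], lon[reefs[r2]]),
    nuc_dist = S[cbind(r1, r2)] / npair,
    share = shared[cbind(r1, r2)] / npair,
    share_rare = shared_rare[cbind(r1, r2)] / npair,
    heat_diff = if (is.null(heat)) NA_real_ else
      abs(heat[reefs[r1]] - heat[reefs[r2]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reef_pair_table", "data.frame")
  out
}

#' Isolation-by-distance / temperature regression over reef pairs
#'
#' Ordinary least squares with intercept of one reef-pair summary on one or
#' more others (e.g. nucleotide distance on geographic distance, or on
#' geographic distance plus heat-exposure difference). Reef-pair rows are
#' not independent; an optional Mantel-style permutation p (permuting reef
#' identities and rebuilding the pair covariates) is available for the
#' overall fit.
#'
#' @param t a \code{reef_pair_table} (or data frame with the columns named).
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param mantel if \code{TRUE}, adds a permutation p-value for R^2 from
#'   \code{mantel_B} random relabelings of the reefs.
#' @param mantel_B permutation count.
#' @param seed optional seed for the Mantel permutations.
#' @return An object of class \code{ibd_regression}: list with
#'   \code{coefficients} (estimate, SE, t, p per term), \code{r_squared},
#'   \code{adj_r_squared}, \code{overall_p} (F-test), \code{n},
#'   \code{mantel_p} (or NA), \code{fit} (the underlying \code{lm}).
#' @export
ibd_regression <- function(t, response = "nuc_dist", predictors = "geo_km",
                           mantel = FALSE, mantel_B = 999, seed = NULL) {
  stopifnot(is.data.frame(t))
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(t))
  if (length(missing_cols)) stop("column(s) not in table: ",
                                 paste(missing_cols, collapse = ", "))
  dat <- t[, cols, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3L) stop("need at least 3 complete reef pairs")
  zerovar <- predictors[vapply(dat[predictors], stats::var, numeric(1)) == 0]
  if (length(zerovar)) stop("zero-variance predictor(s): ",
                            paste(zerovar, collapse = ", "))
  if (length(predictors) > 1L) {
    X <- scale(as.matrix(dat[predictors]))
    if (kappa(X) > 30) warning("predictors nearly collinear (condition number ",
                               round(kappa(X), 1), ")")
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)

  mantel_p <- NA_real_
  if (mantel) {
    if (!all(c("reef1", "reef2") %in% names(t)))
      stop("mantel = TRUE requires reef1/reef2 columns")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    reefs <- sort(unique(c(t$reef1, t$reef2)))
    r2_obs <- sm$r.squared
    exceed <- 0L
    for (b in seq_len(mantel_B)) {
      relab <- stats::setNames(sample(reefs), reefs)
      # permute the response by relabeling reefs, keep covariate geometry
      key_obs <- paste(pmin(t$reef1, t$reef2), pmax(t$reef1, t$reef2))
      p1 <- relab[t$reef1]; p2 <- relab[t$reef2]
      key_perm <- paste(pmin(p1, p2), pmax(p1, p2))
      dat_b <- t[, cols, drop = FALSE]
      dat_b[[response]] <- t[[response]][match(key_perm, key_obs)]
      dat_b <- dat_b[stats::complete.cases(dat_b), , drop = FALSE]
      r2_b <- summary(stats::lm(fml, data = dat_b))$r.squared
      if (r2_b >= r2_obs - 1e-12) exceed <- exceed + 1L
    }
    mantel_p <- (1 + exceed) / (mantel_B + 1)
  }

  structure(list(coefficients = sm$coefficients,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 overall_p = unname(overall_p),
                 n = nrow(dat), response = response, predictors = predictors,
                 mantel_p = mantel_p, fit = fit),
            class = "ibd_regression")
}

#' @export
print.ibd_regression <- function(x, digits = 4, ...) {
  cat("Reef-pair regression: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "  (n = ", x$n, " pairs)\n",
      sep = "")
  print(round(x$coefficients, digits))
  cat("R-squared = ", formatC(x$r_squared, digits = digits, format = "g"),
      ", adjusted = ", formatC(x$adj_r_squared, digits = digits, format = "g"),
      ", overall p = ", formatC(x$overall_p, digits = 3, format = "g"),
      "\n", sep = "")
  if (!is.na(x$mantel_p))
    cat("Mantel permutation p (R-squared) = ",
        format(x$mantel_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Expected wait time for one mitogenome mutation
#'
#' With a divergence rate quoted in percent per million years, the per-site
#' per-year rate is \code{rate/100/1e6}; over a genome of \code{L} bases a
#' mutation appears on average every \code{1/(L * rate_site_year)} years.
#' The default treats the quoted rate as pairwise divergence accumulation
#' (the convention under which 0.1\%/Myr over an 18,642-base genome gives a
#' wait of about 54,000 years); \code{convention = "lineage"} halves the
#' rate, doubling the wait.
#'
#' @param L genome length in bases.
#' @param rate_pct_per_myr divergence rate, percent per million years.
#' @param convention \code{"pairwise"} (default) or \code{"lineage"}.
#' @return wait time in years.
#' @export
mutation_wait_time <- function(L, rate_pct_per_myr,
                               convention = c("pairwise", "lineage")) {
  convention <- match.arg(convention)
  if (any(L <= 0) || any(rate_pct_per_myr <= 0))
    stop("L and rate must be positive")
  r <- rate_pct_per_myr / 100 / 1e6
  if (convention == "lineage") r <- r / 2
  1 / (L * r)
}

#' Divergence time from percent sequence divergence
#'
#' Time = divergence / rate, with both quoted on the pairwise scale
#' (e.g. clades 0.2\% apart at 0.1\% per million years diverged about
#' 2 Myr ago). \code{convention = "lineage"} treats the rate as per lineage,
#' so pairwise divergence accumulates at twice the rate and the time halves.
#'
#' @param pct_divergence percent sequence divergence between two clades.
#' @param rate_pct_per_myr divergence rate, percent per million years.
#' @param convention \code{"pairwise"} (default) or \code{"lineage"}.
#' @return time in million years.
#' @export
divergence_time <- function(pct_divergence, rate_pct_per_myr,
                            convention = c("pairwise", "lineage")) {
  convention <- match.arg(convention)
  if (any(pct_divergence < 0)) stop("divergence must be non-negative")
  if (any(rate_pct_per_myr <= 0)) stop("rate must be positive")
  denom <- if (convention == "lineage") 2 * rate_pct_per_myr else rate_pct_per_myr
  pct_divergence / denom
}
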