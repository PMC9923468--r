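# Hierarchical (three-level) analysis of molecular variance on inter-colony
# nucleotide distances: regions / reefs within regions / colonies within
# reefs, with Phi fixation indices and permutation p-values.
#
# Squared distances default to the raw site counts d_ij (the haplotypic
# convention for sequence data, under which PhiST is the FST analog);
# delta2 = d^2 is available for sensitivity checks.

# sum over unordered pairs inside each level of f, divided by level size:
# SS(S) = (1/|S|) * sum_{i<j in S} delta2_ij, summed over levels of f
ss_within_levels <- function(delta2, f) {
  f <- as.factor(f)
  A <- rowsum(delta2, f, reorder = TRUE)
  B <- rowsum(t(A), f, reorder = TRUE)       # level x level pair sums (x2)
  sum(diag(as.matrix(B)) / (2 * as.vector(table(f))))
}

amova_core <- function(delta2, reef, region) {
  n <- nrow(delta2)
  reef <- as.character(reef); region <- as.character(region)
  n_by_reef <- table(reef)
  n_by_region <- table(region)
  P <- length(n_by_reef); R <- length(n_by_region)

  ss_total <- sum(delta2) / (2 * n)
  ss_within <- ss_within_levels(delta2, reef)
  ss_regionlvl <- ss_within_levels(delta2, region)
  ss_reefs <- ss_regionlvl - ss_within
  ss_regions <- ss_total - ss_regionlvl

  df_a <- R - 1L; df_b <- P - R; df_c <- n - P
  ms_c <- ss_within / df_c

  # unequal-size coefficients of the nested expected mean squares
  reef_region <- tapply(region, reef, `[`, 1L)      # reef -> its region
  nig2_by_region <- tapply(as.vector(n_by_reef)^2, reef_region[names(n_by_reef)], sum)
  sum_nig2_over_Ng <- sum(nig2_by_region / as.vector(n_by_region[names(nig2_by_region)]))
  sum_nig2_over_N <- sum(as.vector(n_by_reef)^2) / n
  sum_Ng2_over_N <- sum(as.vector(n_by_region)^2) / n

  two_level <- df_b == 0L
  if (two_level) {
    # each region holds a single reef: among-reefs stratum vanishes
    ms_b <- NA_real_; sig_b <- NA_real_
    ms_a <- ss_regions / df_a
    n3 <- (n - sum_Ng2_over_N) / df_a
    sig_c <- ms_c
    sig_a <- (ms_a - sig_c) / n3
    coef <- c(n1 = NA_real_, n2 = NA_real_, n3 = n3)
  } else {
    ms_b <- ss_reefs / df_b
    ms_a <- ss_regions / df_a
    n1 <- (n - sum_nig2_over_Ng) / df_b
    n2 <- (sum_nig2_over_Ng - sum_nig2_over_N) / df_a
    n3 <- (n - sum_Ng2_over_N) / df_a
    sig_c <- ms_c
    sig_b <- (ms_b - sig_c) / n1
    sig_a <- (ms_a - sig_c - n2 * sig_b) / n3
    coef <- c(n1 = n1, n2 = n2, n3 = n3)
  }

  sig <- c(regions = sig_a, reefs = sig_b, within = sig_c)
  raw_total <- sum(sig, na.rm = TRUE)
  degenerate <- isTRUE(all.equal(raw_total, 0)) || raw_total <= 0
  if (degenerate) {
    phi <- c(PhiRT = NA_real_, PhiPR = NA_real_, PhiST = NA_real_)
  } else if (two_level) {
    phi <- c(PhiRT = sig_a / (sig_a + sig_c),
             PhiPR = NA_real_,
             PhiST = sig_a / (sig_a + sig_c))
  } else {
    phi <- c(PhiRT = sig_a / raw_total,
             PhiPR = sig_b / (sig_b + sig_c),
             PhiST = (sig_a + sig_b) / raw_total)
  }
  list(tab = data.frame(
         source = c("Among regions", "Among reefs within regions",
                    "Within reefs", "Total"),
         df = c(df_a, df_b, df_c, n - 1L),
         SS = c(ss_regions, ss_reefs, ss_within, ss_total),
         MS = c(ms_a, ms_b, ms_c, NA_real_),
         stringsAsFactors = FALSE),
       sigma = sig, phi = phi, coef = coef,
       two_level = two_level, degenerate = degenerate)
}

#' Three-level AMOVA with Phi statistics
#'
#' Partitions the squared inter-colony distances across nested strata
#' (among regions; among reefs within regions; within reefs) by the
#' standard expected-mean-squares decomposition with unequal-sample-size
#' coefficients, and reports the Phi fixation indices
#' \deqn{\Phi_{RT} = \sigma^2_a/\sigma^2_T,\quad
#'       \Phi_{PR} = \sigma^2_b/(\sigma^2_b+\sigma^2_c),\quad
#'       \Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T.}
#' Phi statistics use the raw (possibly negative) variance components;
#' components are truncated at zero only for the percent-of-total column.
#'
#' Permutation p-values (when \code{permutations > 0}) follow the scheme
#' standard for nested sequence AMOVA: \code{PhiRT} permutes whole reefs
#' among regions, \code{PhiPR} permutes colonies among reefs within their
#' region, \code{PhiST} permutes colonies among all reefs. Each p-value is
#' \code{(1 + #(Phi* >= Phi_obs)) / (B + 1)}.
#'
#' @param dm a \code{mito_dist}.
#' @param m a \code{mito_metadata} covering all colonies in \code{dm}.
#' @param distance \code{"counts"} uses the site-count differences d as the
#'   squared distances (the haplotypic convention); \code{"squared"} uses
#'   d^2.
#' @param permutations number of permutation replicates B (0 = none).
#' @param seed optional integer seed for the permutations.
#' @return An object of class \code{amova}: list with \code{tab} (df, SS,
#'   MS, est. var., percent per stratum), \code{sigma} (raw components),
#'   \code{phi}, \code{p} (permutation p-values), \code{permutations},
#'   \code{seed}, \code{two_level}, \code{degenerate}.
#' @export
amova <- function(dm, m, distance = c("counts", "squared"),
                  permutations = 999, seed = NULL) {
  stopifnot(inherits(dm, "mito_dist"), inherits(m, "mito_metadata"))
  distance <- match.arg(distance)
  idx <- match(dm$ids, m$colony)
  if (anyNA(idx)) stop("metadata missing colonies: ",
                       paste(dm$ids[is.na(idx)], collapse = ", "))
  reef <- m$reef[idx]; region <- m$region[idx]
  if (length(unique(region)) < 2L) stop("need at least 2 regions")
  if (length(unique(reef)) < 2L) stop("need at least 2 reefs")
  delta2 <- if (distance == "counts") dm$D * 1.0 else dm$D^2

  obs <- amova_core(delta2, reef, region)

  # percent of total from zero-truncated components
  trunc <- pmax(obs$sigma, 0)
  tot <- sum(trunc, na.rm = TRUE)
  pct <- if (tot > 0) 100 * trunc / tot else c(0, 0, 0) * trunc
  est <- obs$sigma
  tab <- obs$tab
  tab$est_var <- c(est, sum(trunc, na.rm = TRUE))
  tab$pct <- c(pct, if (tot > 0) 100 else 0)

  p <- c(PhiRT = NA_real_, PhiPR = NA_real_, PhiST = NA_real_)
  B <- as.integer(permutations)
  if (B > 0 && !obs$degenerate) {
    if (B < 99) warning("permutations < 99: p-values will be coarse")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    reef_region <- tapply(region, reef, `[`, 1L)
    reefs <- names(reef_region)
    n <- length(reef)
    exc <- c(PhiRT = 0L, PhiPR = 0L, PhiST = 0L)
    for (b in seq_len(B)) {
      # PhiST: colonies among all reefs (regions follow the reef map)
      perm <- sample.int(n)
      r_st <- reef[perm]
      st <- amova_core(delta2, r_st, as.character(reef_region[r_st]))
      if (!is.na(st$phi["PhiST"]) && st$phi["PhiST"] >= obs$phi["PhiST"] - 1e-12)
        exc["PhiST"] <- exc["PhiST"] + 1L

      # PhiPR: colonies among reefs within their region
      r_pr <- reef
      for (g in unique(region)) {
        in_g <- which(region == g)
        r_pr[in_g] <- reef[in_g][sample.int(length(in_g))]
      }
      pr <- amova_core(delta2, r_pr, region)
      if (!obs$two_level && !is.na(pr$phi["PhiPR"]) &&
          pr$phi["PhiPR"] >= obs$phi["PhiPR"] - 1e-12)
        exc["PhiPR"] <- exc["PhiPR"] + 1L

      # PhiRT: whole reefs among regions (reef->region map permuted)
      map_rt <- stats::setNames(sample(as.character(reef_region)), reefs)
      rt <- amova_core(delta2, reef, map_rt[reef])
      if (!is.na(rt$phi["PhiRT"]) && rt$phi["PhiRT"] >= obs$phi["PhiRT"] - 1e-12)
        exc["PhiRT"] <- exc["PhiRT"] + 1L
    }
    p <- (1 + exc) / (B + 1)
    if (obs$two_level) p["PhiPR"] <- NA_real_
  }

  structure(list(tab = tab, sigma = obs$sigma, phi = obs$phi, p = p,
                 permutations = B, seed = seed, distance = distance,
                 coef = obs$coef, two_level = obs$two_level,
                 degenerate = obs$degenerate, n = nrow(delta2)),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  cat("Hierarchical AMOVA (", x$n, " colonies; squared distances: ",
      if (x$distance == "counts") "site counts" else "squared site counts",
      ")\n\n", sep = "")
  tab <- x$tab
  tab$SS <- round(tab$SS, digits); tab$MS <- round(tab$MS, digits)
  tab$est_var <- round(tab$est_var, digits); tab$pct <- round(tab$pct, 1)
  names(tab) <- c("Source", "df", "SS", "MS", "Est. var.", "%")
  print(tab, row.names = FALSE)
  cat("\nPhi statistics")
  if (x$degenerate) {
    cat(": undefined (no molecular variance in the data)\n")
  } else {
    cat(":\n")
    for (k in names(x$phi)) {
      cat("  ", k, " = ", formatC(x$phi[[k]], digits = digits, format = "f"),
          if (!is.na(x$p[[k]])) paste0("  (p = ",
            formatC(x$p[[k]], digits = 3, format = "g"), ", B = ",
            x$permutations, ")") else "", "\n", sep = "")
    }
    if (x$two_level)
      cat("  two-level design: PhiPR undefined, PhiST = PhiRT\n")
  }
  invisible(x)
}

#' Per-haplogroup chi-square test of regional homogeneity
#'
#' For each haplogroup, compares the observed distribution of its members
#' across regions with expectation proportional to regional sample sizes
#' (all colonies in the metadata), via a one-way chi-square goodness-of-fit
#' test, with multiple-testing correction across groups.
#'
#' @param h a \code{mito_haplogroups}.
#' @param m a \code{mito_metadata}.
#' @param method correction method passed to [stats::p.adjust()]
#'   (default Benjamini-Hochberg; \code{"bonferroni"} available).
#' @param alpha significance level after correction.
#' @return data frame: group, size, statistic, df, p, p_adj, significant,
#'   min_expected, low_expected (any expected cell below 5).
#' @export
chisq_regional_homogeneity <- function(h, m, method = "BH", alpha = 0.05) {
  stopifnot(inherits(h, "mito_haplogroups"), inherits(m, "mito_metadata"))
  regions <- sort(unique(m$region))
  totals <- table(factor(m$region, levels = regions))
  pr <- as.vector(totals) / sum(totals)
  asg <- h$assignment
  rows <- lapply(seq_len(h$n_groups), function(g) {
    members <- asg$colony[!is.na(asg$group) & asg$group == g]
    obs <- table(factor(m$region[match(members, m$colony)], levels = regions))
    expd <- length(members) * pr
    ct <- suppressWarnings(stats::chisq.test(as.vector(obs), p = pr))
    data.frame(group = g, size = length(members),
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value, min_expected = min(expd),
               low_expected = any(expd < 5))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$significant <- out$p_adj < alpha
  out[, c("group", "size", "statistic", "df", "p", "p_adj",
          "significant", "min_expected", "low_expected")]
}

#' Write an AMOVA table as TSV
#'
#' Columns mirror the conventional AMOVA report (Source, df, SS, MS,
#' Est. var., \%).
#'
#' @param x an \code{amova}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_amova <- function(x, path) {
  tab <- x$tab
  names(tab) <- c("Source", "df", "SS", "MS", "Est.var", "Pct")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
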