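# Reef-metapopulation simulator: founder mitogenome haplotypes scattered on
# a random genealogy, colonies placed reef by reef with a tunable
# local-retention probability, single-base transmission mutations, and
# i.i.d. uncalled bases. Ground truth (founder class per colony) is kept for
# recovery tests.

#' Simulation configuration
#'
#' Defaults emulate the Palau study design: 7 regions holding 39 patch
#' reefs, 7 colonies per reef (273 colonies), 18,482 aligned bases,
#' 45 founder haplotypes with a long-tailed frequency spectrum (symmetric
#' Dirichlet, concentration 0.4), a divergent minority clade about 0.2\%
#' from the main stock whose frequency is up-weighted in the first two
#' regions, a per-transmission single-base mutation probability of 0.11
#' (about one folded variant per nine colonies), and an uncalled-base rate
#' of 50/18,482 per site.
#'
#' @param n_regions number of regions.
#' @param reefs_per_region integer vector (recycled to \code{n_regions}).
#' @param colonies_per_reef colonies sampled per reef (scalar or one per
#'   reef).
#' @param L alignment length in bases.
#' @param n_founders number of founder haplotypes.
#' @param founder_alpha symmetric Dirichlet concentration for founder
#'   frequencies (small = long-tailed spectrum).
#' @param founder_mut_lambda Poisson mean of extra mutations per founder
#'   lineage split (plus one, so distances stay distinct).
#' @param divergent_n founders forming the divergent clade.
#' @param divergent_pct clade divergence from the main stock, percent.
#' @param clade_region_weights per-region multiplicative weight on the
#'   divergent clade's frequency (recycled; all equal = no regional
#'   structure).
#' @param retention local-retention probability rho in [0,1]: chance a new
#'   colony copies the haplotype of a previously placed colony on the same
#'   reef instead of drawing from the founder pool.
#' @param mutation_prob probability a transmitted haplotype mutates at one
#'   random site.
#' @param missing_rate per-site probability of an uncalled base (N).
#' @param seed integer seed; the whole dataset is deterministic given the
#'   config.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_regions = 7,
                       reefs_per_region = c(6, 6, 6, 6, 5, 5, 5),
                       colonies_per_reef = 7,
                       L = 18482,
                       n_founders = 45,
                       founder_alpha = 0.4,
                       founder_mut_lambda = 1,
                       divergent_n = 7,
                       divergent_pct = 0.2,
                       clade_region_weights = c(1.5, 1.5, 0.15, 0.15, 0.15, 0.15, 0.15),
                       retention = 0,
                       mutation_prob = 0.11,
                       missing_rate = 50 / 18482,
                       seed = 1) {
  cfg <- list(n_regions = as.integer(n_regions),
              reefs_per_region = rep_len(as.integer(reefs_per_region), n_regions),
              colonies_per_reef = as.integer(colonies_per_reef),
              L = as.integer(L), n_founders = as.integer(n_founders),
              founder_alpha = founder_alpha,
              founder_mut_lambda = founder_mut_lambda,
              divergent_n = as.integer(divergent_n),
              divergent_pct = divergent_pct,
              clade_region_weights = rep_len(clade_region_weights, n_regions),
              retention = retention, mutation_prob = mutation_prob,
              missing_rate = missing_rate, seed = as.integer(seed))
  with(cfg, {
    if (n_regions < 1L || any(reefs_per_region < 1L) ||
        any(colonies_per_reef < 1L) || L < 1L || n_founders < 1L)
      stop("sim_config: counts must be positive")
    if (retention < 0 || retention > 1)
      stop("sim_config: retention must be in [0, 1]")
    if (mutation_prob < 0 || mutation_prob > 1 ||
        missing_rate < 0 || missing_rate > 1)
      stop("sim_config: probabilities must be in [0, 1]")
    if (divergent_n >= n_founders)
      stop("sim_config: divergent_n must be smaller than n_founders")
    if (founder_alpha <= 0 || any(clade_region_weights < 0))
      stop("sim_config: founder_alpha must be positive, weights non-negative")
  })
  structure(cfg, class = "sim_config")
}

# mutate `k` fresh sites of integer sequence s to a different base
mutate_sites <- function(s, sites) {
  for (j in sites) s[j] <- sample(setdiff(1:4, s[j]), 1L)
  s
}

#' Simulate a reef-metapopulation mitogenome dataset
#'
#' Founder haplotypes are built on a random genealogy: each new founder
#' copies an earlier one and gains \code{1 + Poisson(founder_mut_lambda)}
#' mutations at fresh sites, so founders are pairwise distinct; the
#' divergent clade descends from an ancestor \code{divergent_pct}\% away
#' from the main stock. Colonies are then placed reef by reef: with
#' probability \code{retention} a colony copies the haplotype of a
#' uniformly chosen earlier colony on the same reef, otherwise it draws a
#' founder from the (region-weighted) frequency spectrum. Each transmitted
#' haplotype mutates at one random site with probability
#' \code{mutation_prob}, creating single-base variants; uncalled bases (N)
#' are injected i.i.d. at \code{missing_rate}.
#'
#' @param config a \code{sim_config}.
#' @return list of class \code{mito_sim} with elements \code{alignment}
#'   (a \code{mito_alignment}), \code{metadata} (a \code{mito_metadata})
#'   and \code{truth} (class \code{sim_truth}: per-colony founder label,
#'   founder sequences, realised group-size spectrum, config echo).
#' @export
simulate_reefs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  cf <- config
  nf <- cf$n_founders
  n_main <- nf - cf$divergent_n
  L <- cf$L

  # founder genealogy
  fdr <- matrix(NA_integer_, nf, L)
  fdr[1L, ] <- sample.int(4L, L, replace = TRUE)
  used_sites <- integer(0)
  fresh_sites <- function(k) {
    s <- sample(setdiff(seq_len(L), used_sites), k)
    used_sites <<- c(used_sites, s)
    s
  }
  for (k in seq_len(n_main)[-1L]) {
    parent <- sample.int(k - 1L, 1L)
    nm <- 1L + stats::rpois(1L, cf$founder_mut_lambda)
    fdr[k, ] <- mutate_sites(fdr[parent, ], fresh_sites(nm))
  }
  if (cf$divergent_n > 0L) {
    n_div_mut <- max(1L, round(cf$divergent_pct / 100 * L))
    anc <- mutate_sites(fdr[1L, ], fresh_sites(n_div_mut))
    fdr[n_main + 1L, ] <- mutate_sites(anc, fresh_sites(1L + stats::rpois(1L, cf$founder_mut_lambda)))
    for (k in seq_len(cf$divergent_n)[-1L]) {
      parent <- n_main + sample.int(k - 1L, 1L)
      nm <- 1L + stats::rpois(1L, cf$founder_mut_lambda)
      fdr[n_main + k, ] <- mutate_sites(fdr[parent, ], fresh_sites(nm))
    }
  }
  clade <- seq_len(nf) > n_main

  # long-tailed founder frequencies
  p0 <- stats::rgamma(nf, shape = cf$founder_alpha)
  p0 <- p0 / sum(p0)

  # geography: region centres then reef jitter, around a Palau-like box
  nR <- sum(cf$reefs_per_region)
  region_of_reef <- rep(seq_len(cf$n_regions), cf$reefs_per_region)
  centre_lat <- stats::runif(cf$n_regions, 7.0, 7.6)
  centre_lon <- stats::runif(cf$n_regions, 134.2, 134.7)
  reef_lat <- centre_lat[region_of_reef] + stats::runif(nR, -0.03, 0.03)
  reef_lon <- centre_lon[region_of_reef] + stats::runif(nR, -0.03, 0.03)
  region_heat <- stats::runif(cf$n_regions, 0.05, 0.25)
  reef_heat <- pmin(pmax(region_heat[region_of_reef] +
                           stats::runif(nR, -0.05, 0.05), 0), 1)
  cpr <- rep_len(cf$colonies_per_reef, nR)
  n <- sum(cpr)

  # placement bookkeeping first (founder label + mutation events per
  # colony); sequences are materialised in one indexing step afterwards
  founder_label <- integer(n)
  muts <- vector("list", n)            # 2-column matrices: site, new base
  reef_id <- character(n)
  region_id <- character(n)
  lat <- numeric(n); lon <- numeric(n); heat <- numeric(n)
  base_at <- function(i, site) {
    b <- fdr[founder_label[i], site]
    mm <- muts[[i]]
    if (!is.null(mm)) {
      hit <- which(mm[, 1L] == site)
      if (length(hit)) b <- mm[hit[length(hit)], 2L]
    }
    b
  }
  row <- 0L
  for (r in seq_len(nR)) {
    g <- region_of_reef[r]
    w <- ifelse(clade, cf$clade_region_weights[g], 1)
    p_region <- p0 * w
    p_region <- p_region / sum(p_region)
    first_row <- row + 1L
    for (k in seq_len(cpr[r])) {
      row <- row + 1L
      copy_local <- row > first_row && stats::runif(1L) < cf$retention
      if (copy_local) {
        src <- first_row + sample.int(row - first_row, 1L) - 1L
        founder_label[row] <- founder_label[src]
        muts[row] <- muts[src]   # single bracket: a NULL entry must copy, not delete
      } else {
        founder_label[row] <- sample.int(nf, 1L, prob = p_region)
      }
      if (stats::runif(1L) < cf$mutation_prob) {
        site <- sample.int(L, 1L)
        new_base <- sample(setdiff(1:4, base_at(row, site)), 1L)
        muts[[row]] <- rbind(muts[[row]], c(site, new_base))
      }
      reef_id[row] <- sprintf("R%02d", r)
      region_id[row] <- sprintf("G%d", g)
      lat[row] <- reef_lat[r]; lon[row] <- reef_lon[r]
      heat[row] <- reef_heat[r]
    }
  }
  seqs <- fdr[founder_label, , drop = FALSE]
  for (i in which(!vapply(muts, is.null, logical(1)))) {
    seqs[i, muts[[i]][, 1L]] <- muts[[i]][, 2L]
  }

  # uncalled bases: per-colony binomial count, then positions
  if (cf$missing_rate > 0) {
    n_miss <- stats::rbinom(n, L, cf$missing_rate)
    for (i in which(n_miss > 0L)) {
      seqs[i, sample.int(L, n_miss[i])] <- NA_integer_
    }
  }
  chars <- matrix(c("A", "C", "G", "T")[seqs], n, L)
  chars[is.na(chars)] <- "N"
  ids <- sprintf("COL%03d", seq_len(n))
  rownames(chars) <- ids
  rownames(seqs) <- ids
  alignment <- structure(list(ids = ids, seq = chars, n = n, L = L),
                         class = "mito_alignment")
  attr(alignment, "encoded") <- seqs
  metadata <- as_metadata(data.frame(
    colony = ids, reef = reef_id, region = region_id,
    lat = lat, lon = lon,
    date = format(as.Date("2017-07-01") + (match(reef_id, unique(reef_id)) - 1L)),
    heat_fraction = heat, stringsAsFactors = FALSE))
  truth <- structure(list(
    founder_label = stats::setNames(founder_label, ids),
    founder_seq = matrix(c("A", "C", "G", "T")[fdr], nf, L),
    clade = clade,
    spectrum = as.vector(table(factor(founder_label, levels = seq_len(nf)))),
    config = cf), class = "sim_truth")
  structure(list(alignment = alignment, metadata = metadata, truth = truth),
            class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  cf <- x$truth$config
  cat("Simulated reef metapopulation:", x$alignment$n, "colonies,",
      sum(cf$reefs_per_region), "reefs,", cf$n_regions, "regions\n")
  cat("  retention rho =", cf$retention, "; founders =", cf$n_founders,
      "; seed =", cf$seed, "\n")
  cat("  realised founder-class sizes:",
      paste(sort(x$truth$spectrum[x$truth$spectrum > 0], decreasing = TRUE),
            collapse = " "), "\n")
  invisible(x)
}

#' Compare an inferred haplogroup assignment with simulation truth
#'
#' Pair-level agreement of group co-membership: a colony pair counts as
#' positive in the inference when both are grouped with the same label, and
#' positive in truth when both carry the same founder label. Precision is
#' TP / inferred-positive pairs, recall TP / true-positive pairs. Scores
#' are invariant to any relabeling of the inferred groups.
#'
#' @param h a \code{mito_haplogroups}.
#' @param truth a \code{sim_truth}.
#' @return list: precision, recall, tp, inferred_pairs, truth_pairs.
#' @export
truth_comparison <- function(h, truth) {
  stopifnot(inherits(h, "mito_haplogroups"), inherits(truth, "sim_truth"))
  asg <- h$assignment
  if (!setequal(asg$colony, names(truth$founder_label)))
    stop("colony ids differ between assignment and truth")
  tl <- truth$founder_label[asg$colony]
  il <- asg$group
  grouped <- !is.na(il)
  pairs_of <- function(x) sum(choose(table(x), 2))
  tp <- sum(choose(table(il[grouped], tl[grouped]), 2))
  inferred_pairs <- pairs_of(il[grouped])
  truth_pairs <- pairs_of(tl)
  list(precision = if (inferred_pairs > 0) tp / inferred_pairs else NA_real_,
       recall = if (truth_pairs > 0) tp / truth_pairs else NA_real_,
       tp = tp, inferred_pairs = inferred_pairs, truth_pairs = truth_pairs)
}
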