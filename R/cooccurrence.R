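# Excess co-location of same-haplogroup colonies on the same reef, tested
# against a constrained permutation null that shuffles colonies among reef
# slots while keeping reef sample sizes and the group-size spectrum fixed.

# group-by-reef count table for grouped colonies; ungrouped colonies hold
# reef slots but contribute no pairs
group_reef_table <- function(group, reef) {
  keep <- !is.na(group)
  table(factor(group[keep]), factor(reef[keep], levels = sort(unique(reef))))
}

stat_from_table <- function(K, statistic, counting, rare_sizes = NULL) {
  if (statistic == "pairs") {
    if (counting == "pairs") sum(choose(K, 2)) else sum(pmax(K - 1L, 0L))
  } else { # rare-group count: groups in the size range with a same-reef pair
    if (is.null(rare_sizes)) stop("rare_sizes required for the rare statistic")
    sum(apply(K[rare_sizes, , drop = FALSE] >= 2L, 1L, any))
  }
}

aligned_group_reef <- function(h, m) {
  asg <- h$assignment
  idx <- match(asg$colony, m$colony)
  if (anyNA(idx)) stop("metadata missing colonies: ",
                       paste(asg$colony[is.na(idx)], collapse = ", "))
  list(group = asg$group, reef = m$reef[idx])
}

#' Same-reef, same-haplogroup pair count
#'
#' The observed co-occurrence statistic: over every (group g, reef r) cell
#' with k members, unordered pairs contribute \code{choose(k, 2)} (default),
#' or \code{max(k - 1, 0)} under the alternative "instances" counting.
#' Folded members count toward their group; ungrouped colonies contribute
#' nothing.
#'
#' @param h a \code{mito_haplogroups}.
#' @param m a \code{mito_metadata}.
#' @param counting \code{"pairs"} (default) or \code{"instances"}.
#' @return integer count.
#' @export
pair_count <- function(h, m, counting = c("pairs", "instances")) {
  counting <- match.arg(counting)
  gr <- aligned_group_reef(h, m)
  K <- group_reef_table(gr$group, gr$reef)
  as.integer(stat_from_table(K, "pairs", counting))
}

#' Number of rare haplogroups with a same-reef pair
#'
#' Counts groups whose total size lies in \code{size_range} (inclusive) and
#' which place at least two members on some single reef.
#'
#' @param h a \code{mito_haplogroups}.
#' @param m a \code{mito_metadata}.
#' @param size_range inclusive size range defining "rare", default 2-10.
#' @return integer count.
#' @export
rare_group_count <- function(h, m, size_range = c(2, 10)) {
  if (length(size_range) != 2L || size_range[1L] > size_range[2L]) {
    stop("size_range must be a non-empty inclusive range c(lo, hi)")
  }
  gr <- aligned_group_reef(h, m)
  K <- group_reef_table(gr$group, gr$reef)
  sizes <- rowSums(K)
  rare <- which(sizes >= size_range[1L] & sizes <= size_range[2L])
  if (!length(rare)) return(0L)
  as.integer(stat_from_table(K, "rare", "pairs", rare_sizes = rare))
}

#' Constrained permutation test for reef co-occurrence
#'
#' Each replicate redraws the colony-to-reef assignment as a uniform random
#' permutation of the observed reef-label multiset, so the number of
#' haplogroups, the group-size spectrum, and the number of colonies per reef
#' all stay exactly as observed; only the pairing of colonies with reefs is
#' randomized. The one-tailed p-value is
#' \code{(1 + #(null >= observed)) / (B + 1)}.
#'
#' @param h a \code{mito_haplogroups}.
#' @param m a \code{mito_metadata}.
#' @param statistic \code{"pairs"} (total same-reef same-group pairs) or
#'   \code{"rare"} (rare groups with a same-reef pair).
#' @param counting pair-counting convention for \code{statistic = "pairs"}:
#'   \code{"pairs"} or \code{"instances"}.
#' @param B number of permutation replicates.
#' @param seed optional integer seed.
#' @param size_range rare-group size range (used by \code{"rare"}).
#' @return An object of class \code{cooccur}: list with \code{mode},
#'   \code{statistic}, \code{counting}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{p}, \code{B}, \code{seed}, \code{replicates}.
#' @export
cooccur_test <- function(h, m, statistic = c("pairs", "rare"),
                         counting = c("pairs", "instances"),
                         B = 1000, seed = NULL, size_range = c(2, 10)) {
  statistic <- match.arg(statistic)
  counting <- match.arg(counting)
  B <- as.integer(B)
  if (B < 1L) stop("B must be a positive integer")
  gr <- aligned_group_reef(h, m)
  if (length(unique(gr$reef)) < 1L) stop("no reefs in metadata")
  keep <- !is.na(gr$group)
  group_f <- factor(gr$group[keep])
  reef_levels <- sort(unique(gr$reef))
  sizes <- as.vector(table(group_f))
  rare <- if (statistic == "rare") {
    which(sizes >= size_range[1L] & sizes <= size_range[2L])
  } else NULL
  if (statistic == "rare" &&
      (length(size_range) != 2L || size_range[1L] > size_range[2L])) {
    stop("size_range must be a non-empty inclusive range c(lo, hi)")
  }

  tab <- function(reef_all) {
    table(group_f, factor(reef_all[keep], levels = reef_levels))
  }
  observed <- as.integer(stat_from_table(tab(gr$reef), statistic, counting, rare))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  reps <- integer(B)
  for (b in seq_len(B)) {
    reps[b] <- stat_from_table(tab(sample(gr$reef)), statistic, counting, rare)
  }
  structure(list(mode = h$mode, statistic = statistic, counting = counting,
                 observed = observed,
                 null_mean = mean(reps), null_sd = stats::sd(reps),
                 p = (1 + sum(reps >= observed)) / (B + 1),
                 B = B, seed = seed, replicates = reps),
            class = "cooccur")
}

#' @export
print.cooccur <- function(x, ...) {
  what <- if (x$statistic == "pairs") {
    paste0("same-reef same-group ",
           if (x$counting == "pairs") "pairs" else "instances")
  } else "rare groups with a same-reef pair"
  cat("Reef co-occurrence test (", x$mode, " mode; ", what, ")\n", sep = "")
  cat("  observed: ", x$observed, "   null: ",
      round(x$null_mean, 2), " (SD ", round(x$null_sd, 2), ")\n", sep = "")
  cat("  one-tailed p = ", format(x$p, digits = 3), "  (B = ", x$B,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.cooccur <- function(x, ...) {
  graphics::hist(x$replicates,
                 breaks = seq(min(c(x$replicates, x$observed)) - 0.5,
                              max(c(x$replicates, x$observed)) + 0.5),
                 main = "Co-occurrence permutation null",
                 xlab = "same-reef same-group count", col = "grey80",
                 border = "white", ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  graphics::mtext(paste0("observed = ", x$observed, ", p = ",
                         format(x$p, digits = 3)), side = 3, line = 0.2)
  invisible(x)
}

#' Four-way co-occurrence report
#'
#' Runs the co-occurrence test in both haplogroup mode (folded variants
#' included) and strict-identity mode, for both the total pair count and the
#' rare-group count: the four observed/null/p triples of the analysis.
#'
#' @param h_full haplogroup-mode \code{mito_haplogroups}.
#' @param h_strict strict-mode \code{mito_haplogroups}.
#' @param m a \code{mito_metadata}.
#' @param B replicates per test.
#' @param seed optional integer seed; the four tests use \code{seed + 0:3}.
#' @param counting pair-counting convention.
#' @return An object of class \code{cooccur_report}: named list of four
#'   \code{cooccur} objects (\code{full_pairs}, \code{full_rare},
#'   \code{strict_pairs}, \code{strict_rare}).
#' @export
cooccurrence_report <- function(h_full, h_strict, m, B = 1000, seed = NULL,
                                counting = c("pairs", "instances")) {
  counting <- match.arg(counting)
  s <- function(k) if (is.null(seed)) NULL else seed + k
  out <- list(
    full_pairs   = cooccur_test(h_full, m, "pairs", counting, B, s(0L)),
    full_rare    = cooccur_test(h_full, m, "rare", counting, B, s(1L)),
    strict_pairs = cooccur_test(h_strict, m, "pairs", counting, B, s(2L)),
    strict_rare  = cooccur_test(h_strict, m, "rare", counting, B, s(3L)))
  class(out) <- "cooccur_report"
  out
}

#' @export
print.cooccur_report <- function(x, ...) {
  cat("Co-occurrence report (observed vs permutation null)\n")
  for (nm in names(x)) {
    t <- x[[nm]]
    cat(sprintf("  %-12s obs %4d  null %6.2f (SD %.2f)  p = %s\n",
                nm, t$observed, t$null_mean, t$null_sd,
                format(t$p, digits = 3)))
  }
  invisible(x)
}

#' Write a permutation null distribution as TSV
#'
#' Two columns (replicate, value), suitable for re-plotting the null
#' histogram.
#'
#' @param x a \code{cooccur}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_null_distribution <- function(x, path) {
  utils::write.table(data.frame(replicate = seq_along(x$replicates),
                                value = x$replicates),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
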