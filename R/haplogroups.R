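# Haplogroup construction: clusters of identical genomes (zero pairwise
# differences over jointly called sites), then singletons one base away from
# a group consensus folded into that group.

#' Cluster colonies into identity groups
#'
#' Builds the graph whose edges join colonies with zero nucleotide
#' differences (over jointly called sites) and takes connected components.
#' Components of size >= 2 become candidate haplogroups; size-1 components
#' are provisional singletons that [fold_single_base_variants()] may later
#' absorb.
#'
#' Missing data can make zero-distance intransitive (A identical to B, B to
#' C, but A differs from C). Such components are still kept whole — the
#' component is the defined resolution — and every violating pair is
#' recorded in \code{$violations}.
#'
#' Group labels are deterministic: groups are numbered by decreasing size,
#' ties broken by the lexicographically smallest member id, so any input
#' ordering of the sequences yields the same labels.
#'
#' @param dm a \code{mito_dist}.
#' @return An object of class \code{identity_groups}: list with
#'   \code{membership} (integer per colony, NA for singletons),
#'   \code{groups} (list of member-id character vectors), \code{singletons}
#'   (character), \code{violations} (data frame of intransitive pairs).
#' @export
build_identity_groups <- function(dm) {
  stopifnot(inherits(dm, "mito_dist"))
  n <- length(dm$ids)
  adj <- dm$D == 0L
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  sizes <- tabulate(comp)
  multi <- which(sizes >= 2L)
  members <- lapply(multi, function(k) sort(dm$ids[comp == k]))
  # deterministic labels: size desc, then smallest member id
  ord <- order(-sizes[multi], vapply(members, `[`, character(1), 1L))
  members <- members[ord]
  membership <- rep(NA_integer_, n)
  names(membership) <- dm$ids
  for (g in seq_along(members)) membership[members[[g]]] <- g

  # intransitivity: nonzero distances inside a component
  viol <- NULL
  for (k in multi) {
    idx <- which(comp == k)
    sub <- dm$D[idx, idx, drop = FALSE]
    bad <- which(sub > 0L & upper.tri(sub), arr.ind = TRUE)
    if (nrow(bad)) {
      viol <- rbind(viol, data.frame(
        colony1 = dm$ids[idx[bad[, 1L]]],
        colony2 = dm$ids[idx[bad[, 2L]]],
        d = sub[bad], stringsAsFactors = FALSE))
    }
  }
  if (is.null(viol)) {
    viol <- data.frame(colony1 = character(), colony2 = character(),
                       d = integer(), stringsAsFactors = FALSE)
  }
  structure(list(membership = membership,
                 groups = members,
                 singletons = dm$ids[is.na(membership)],
                 violations = viol),
            class = "identity_groups")
}

# Per-group consensus: per-column majority base over core members (called
# bases only); N where no member carries a called base. Core members agree
# wherever jointly called, so unless missing data made zero-distance
# intransitive the majority equals a simple fill across members (fast
# path); groups touched by a violation use the full majority count.
group_consensus <- function(groups, a, M = NULL) {
  if (is.null(M)) M <- encode_alignment(a)
  viol_g <- unique(groups$membership[c(groups$violations$colony1,
                                       groups$violations$colony2)])
  cons <- matrix(NA_integer_, length(groups$groups), a$L)
  for (g in seq_along(groups$groups)) {
    members <- groups$groups[[g]]
    if (g %in% viol_g) {
      sub <- M[members, , drop = FALSE]
      cnt <- vapply(1:4, function(b) colSums(sub == b, na.rm = TRUE),
                    numeric(a$L))
      top <- max.col(cnt, ties.method = "first")
      top[rowSums(cnt) == 0] <- NA_integer_
      cons[g, ] <- top
    } else {
      cc <- M[members[1L], ]
      for (id in members[-1L]) {
        na <- which(is.na(cc))
        if (!length(na)) break
        cc[na] <- M[id, na]
      }
      cons[g, ] <- cc
    }
  }
  cons
}

# d and c between one encoded sequence and one consensus row
seq_vs_consensus <- function(s, cons_row) {
  both <- !is.na(s) & !is.na(cons_row)
  c(d = sum(s[both] != cons_row[both]), c = sum(both))
}

#' Fold single-base variants into identity groups
#'
#' Completes haplogroup construction: every provisional singleton whose
#' genome is exactly one called base away from a group consensus is folded
#' into that group (kind \code{"folded"}). A singleton one base from several
#' consensuses goes to the largest such group (ties to the lowest label) and
#' the ambiguity is logged. All other singletons become \code{"ungrouped"}.
#'
#' Whether the variant allele is unique in the whole dataset is computed and
#' logged per folded colony (\code{$fold_log$allele_unique}) but not
#' enforced: folding requires only distance one to the consensus.
#'
#' @param groups an \code{identity_groups}.
#' @param dm the \code{mito_dist} the groups were built from.
#' @param a the \code{mito_alignment}.
#' @return An object of class \code{mito_haplogroups}: list with
#'   \code{assignment} (data frame: colony, group, kind, d_to_consensus),
#'   \code{sizes} (per-group member counts including folded),
#'   \code{consensus} (integer matrix), \code{mode = "haplogroup"},
#'   \code{fold_log}, \code{violations}.
#' @export
fold_single_base_variants <- function(groups, dm, a) {
  stopifnot(inherits(groups, "identity_groups"),
            inherits(dm, "mito_dist"), inherits(a, "mito_alignment"))
  M <- encode_alignment(a)
  cons <- group_consensus(groups, a, M)
  G <- length(groups$groups)
  core_sizes <- lengths(groups$groups)

  assignment <- data.frame(colony = a$ids,
                           group = unname(groups$membership[a$ids]),
                           kind = ifelse(is.na(groups$membership[a$ids]),
                                         "ungrouped", "core"),
                           d_to_consensus = NA_real_,
                           stringsAsFactors = FALSE)
  rownames(assignment) <- assignment$colony
  # core members agree with their consensus wherever jointly called, so
  # d = 0 except in groups carrying an intransitivity violation
  assignment$d_to_consensus[assignment$kind == "core"] <- 0
  viol_g <- unique(groups$membership[c(groups$violations$colony1,
                                       groups$violations$colony2)])
  for (g in viol_g) {
    for (id in groups$groups[[g]]) {
      assignment[id, "d_to_consensus"] <-
        seq_vs_consensus(M[id, ], cons[g, ])[["d"]]
    }
  }

  # sequences can disagree with a consensus only at variable columns, so
  # singleton-vs-consensus distances are computed over those columns alone
  vc <- if (is.null(dm$var_cols)) seq_len(a$L) else dm$var_cols
  consV <- cons[, vc, drop = FALSE]
  fold_log <- NULL
  for (id in groups$singletons) {
    sv <- M[id, vc]
    mism <- consV != matrix(sv, G, length(vc), byrow = TRUE)
    mism[is.na(mism)] <- FALSE
    dvec <- rowSums(mism)
    hits <- which(dvec == 1)
    if (length(hits) == 0L) next
    if (length(hits) == 1L) {
      target <- hits
      ambiguous <- FALSE
    } else {
      target <- hits[order(-core_sizes[hits], hits)][1L]
      ambiguous <- TRUE
    }
    # is the single differing allele unique in the dataset?
    diff_site <- vc[which(mism[target, ])[1L]]
    allele <- M[id, diff_site]
    allele_unique <- sum(M[, diff_site] == allele, na.rm = TRUE) == 1L
    assignment[id, "group"] <- target
    assignment[id, "kind"] <- "folded"
    assignment[id, "d_to_consensus"] <- 1
    fold_log <- rbind(fold_log, data.frame(
      colony = id, group = target, n_candidates = length(hits),
      ambiguous = ambiguous, site = diff_site,
      allele = c("A", "C", "G", "T")[allele],
      allele_unique = allele_unique, stringsAsFactors = FALSE))
  }
  if (is.null(fold_log)) {
    fold_log <- data.frame(colony = character(), group = integer(),
                           n_candidates = integer(), ambiguous = logical(),
                           site = integer(), allele = character(),
                           allele_unique = logical(), stringsAsFactors = FALSE)
  }
  sizes <- tabulate(assignment$group, nbins = G)
  structure(list(assignment = assignment, sizes = sizes,
                 n_groups = G, consensus = cons, mode = "haplogroup",
                 fold_log = fold_log, violations = groups$violations),
            class = "mito_haplogroups")
}

#' Haplogroup assignment in one call
#'
#' Convenience wrapper: [build_identity_groups()] then
#' [fold_single_base_variants()] (mode \code{"haplogroup"}), or the
#' strict-identity restriction (mode \code{"strict"}).
#'
#' @param a a \code{mito_alignment}.
#' @param dm optional precomputed \code{mito_dist}.
#' @param mode \code{"haplogroup"} (identical genomes plus folded
#'   single-base variants) or \code{"strict"} (identical genomes only).
#' @return a \code{mito_haplogroups}.
#' @export
assign_haplogroups <- function(a, dm = NULL, mode = c("haplogroup", "strict")) {
  mode <- match.arg(mode)
  if (is.null(dm)) dm <- pairwise_difference_matrix(a)
  groups <- build_identity_groups(dm)
  if (mode == "haplogroup") {
    fold_single_base_variants(groups, dm, a)
  } else {
    strict_identity_assignment(groups, a)
  }
}

#' Strict-identity assignment
#'
#' Restricts the analysis to exactly identical genomes: only core members of
#' multi-member identity groups are retained; folded single-base variants
#' and singletons are excluded (kind \code{"ungrouped"}).
#'
#' @param groups an \code{identity_groups}.
#' @param a the \code{mito_alignment} (used for the consensus sequences).
#' @return a \code{mito_haplogroups} with \code{mode = "strict"}.
#' @export
strict_identity_assignment <- function(groups, a) {
  stopifnot(inherits(groups, "identity_groups"))
  cons <- group_consensus(groups, a)
  assignment <- data.frame(colony = a$ids,
                           group = unname(groups$membership[a$ids]),
                           kind = ifelse(is.na(groups$membership[a$ids]),
                                         "ungrouped", "core"),
                           d_to_consensus = NA_real_,
                           stringsAsFactors = FALSE)
  rownames(assignment) <- assignment$colony
  assignment$d_to_consensus[assignment$kind == "core"] <- 0
  sizes <- tabulate(assignment$group, nbins = length(groups$groups))
  structure(list(assignment = assignment, sizes = sizes,
                 n_groups = length(groups$groups), consensus = cons,
                 mode = "strict",
                 fold_log = NULL, violations = groups$violations),
            class = "mito_haplogroups")
}

#' Group-size spectrum with rare-group flags
#'
#' Sizes include folded members (in haplogroup mode). A group is "rare" when
#' its size lies in \code{rare_range}, inclusive on both ends.
#'
#' @param h a \code{mito_haplogroups}.
#' @param rare_range inclusive integer range, default \code{c(2, 10)}.
#' @return data frame: group, size, rare.
#' @export
group_size_spectrum <- function(h, rare_range = c(2, 10)) {
  stopifnot(inherits(h, "mito_haplogroups"))
  if (length(rare_range) != 2L || rare_range[1L] > rare_range[2L]) {
    stop("rare_range must be a non-empty inclusive range c(lo, hi)")
  }
  data.frame(group = seq_len(h$n_groups),
             size = h$sizes,
             rare = h$sizes >= rare_range[1L] & h$sizes <= rare_range[2L])
}

#' @export
print.mito_haplogroups <- function(x, ...) {
  k <- table(factor(x$assignment$kind,
                    levels = c("core", "folded", "ungrouped")))
  cat("Haplogroup assignment (mode: ", x$mode, ")\n", sep = "")
  cat(" ", x$n_groups, "groups;", k[["core"]], "core,",
      k[["folded"]], "folded,", k[["ungrouped"]], "ungrouped colonies\n")
  if (x$n_groups > 0) {
    cat("  group sizes:", paste(sort(x$sizes, decreasing = TRUE),
                                collapse = " "), "\n")
  }
  if (nrow(x$violations)) {
    cat("  note:", nrow(x$violations),
        "intransitive zero-distance pair(s) (missing data); see $violations\n")
  }
  invisible(x)
}

#' @export
summary.mito_haplogroups <- function(object, ...) {
  spec <- group_size_spectrum(object)
  out <- list(mode = object$mode, n_groups = object$n_groups,
              spectrum = spec,
              n_core = sum(object$assignment$kind == "core"),
              n_folded = sum(object$assignment$kind == "folded"),
              n_ungrouped = sum(object$assignment$kind == "ungrouped"),
              n_rare = sum(spec$rare),
              largest = if (object$n_groups) max(object$sizes) else 0L)
  class(out) <- "summary.mito_haplogroups"
  out
}

#' @export
print.summary.mito_haplogroups <- function(x, ...) {
  cat("Haplogroups (", x$mode, "): ", x$n_groups, " groups, largest ",
      x$largest, "\n", sep = "")
  cat("  core ", x$n_core, ", folded ", x$n_folded, ", ungrouped ",
      x$n_ungrouped, "; rare (2-10) groups: ", x$n_rare, "\n", sep = "")
  invisible(x)
}

#' Write a haplogroup assignment as TSV
#'
#' @param h a \code{mito_haplogroups}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_haplogroups <- function(h, path) {
  utils::write.table(h$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
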