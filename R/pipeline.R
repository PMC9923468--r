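# End-to-end orchestration: validate -> distances -> haplogroups -> AMOVA ->
# co-occurrence -> reef-pair regressions, writing a manifest of artifacts.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on an alignment + metadata pair (file paths or
#' in-memory objects) and writes the result bundle to \code{out_dir}:
#' validation report, distance matrix, haplogroup assignment and summary,
#' AMOVA table and Phi statistics, the four-way co-occurrence report with
#' null distributions, the reef-pair table with isolation-by-distance and
#' temperature regressions, and a \code{manifest.json} listing all
#' artifacts with the seed and package version. All randomized stages are
#' seeded deterministically from \code{seed}, so a repeated run writes
#' identical outputs.
#'
#' @param alignment a \code{mito_alignment} or a FASTA path.
#' @param metadata a \code{mito_metadata} or a CSV/TSV path.
#' @param out_dir output directory (created if needed).
#' @param B permutation replicates for AMOVA and co-occurrence.
#' @param seed integer seed; stage seeds are \code{seed + 0:9}.
#' @param counting co-occurrence counting convention
#'   (\code{"pairs"}/\code{"instances"}).
#' @param distance AMOVA squared-distance convention
#'   (\code{"counts"}/\code{"squared"}).
#' @return invisibly, a list with every stage result plus \code{manifest}.
#' @export
run_all <- function(alignment, metadata, out_dir, B = 1000, seed = 1,
                    counting = c("pairs", "instances"),
                    distance = c("counts", "squared")) {
  counting <- match.arg(counting)
  distance <- match.arg(distance)
  a <- run_stage("seqio", {
    if (inherits(alignment, "mito_alignment")) alignment
    else read_alignment(alignment)
  })
  m <- run_stage("seqio", {
    if (inherits(metadata, "mito_metadata")) metadata
    else read_metadata(metadata)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  val <- run_stage("validate", validate_dataset(a, m))
  if (!val$pass) stop("pipeline stage 'validate' failed: ",
                      paste(val$problems, collapse = "; "), call. = FALSE)
  dm <- run_stage("distances", pairwise_difference_matrix(a))
  groups <- run_stage("haplogroups", build_identity_groups(dm))
  h_full <- run_stage("haplogroups", fold_single_base_variants(groups, dm, a))
  h_strict <- run_stage("haplogroups", strict_identity_assignment(groups, a))
  am <- run_stage("amova", amova(dm, m, distance = distance,
                                 permutations = B, seed = seed + 0L))
  chi <- run_stage("amova", chisq_regional_homogeneity(h_full, m))
  cor <- run_stage("cooccurrence",
                   cooccurrence_report(h_full, h_strict, m, B = B,
                                       seed = seed + 1L, counting = counting))
  rpt <- run_stage("spatial", reef_pair_table(dm, h_full, m))
  ibd_nuc <- run_stage("spatial", ibd_regression(rpt, "nuc_dist", "geo_km"))
  ibd_share <- run_stage("spatial", ibd_regression(rpt, "share", "geo_km"))
  ibd_heat <- if (all(is.finite(rpt$heat_diff))) {
    run_stage("spatial",
              ibd_regression(rpt, "nuc_dist", c("geo_km", "heat_diff")))
  } else NULL

  reg_json <- function(x) if (is.null(x)) NULL else list(
    response = x$response, predictors = x$predictors,
    coefficients = as.data.frame(x$coefficients),
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    overall_p = x$overall_p, n = x$n)

  # artifacts
  write_json <- function(x, f) jsonlite::write_json(
    x, path(f), auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  write_json(list(pass = val$pass, problems = val$problems,
                  mean_uncalled = val$mean_uncalled,
                  n_colonies = val$n_colonies, L = val$L,
                  reef_counts = as.list(val$reef_counts)),
             "validation.json")
  write_distance_matrix(dm, path("distances.tsv"))
  write_haplogroups(h_full, path("haplogroups.tsv"))
  spec <- group_size_spectrum(h_full)
  write_json(list(mode = h_full$mode, n_groups = h_full$n_groups,
                  sizes = h_full$sizes, rare = spec$rare,
                  n_core = sum(h_full$assignment$kind == "core"),
                  n_folded = sum(h_full$assignment$kind == "folded"),
                  n_ungrouped = sum(h_full$assignment$kind == "ungrouped")),
             "group_summary.json")
  write_amova(am, path("amova.tsv"))
  write_json(list(phi = as.list(am$phi), p = as.list(am$p),
                  permutations = am$permutations, seed = am$seed),
             "phi.json")
  utils::write.table(chi, path("chisq_regional.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json(lapply(cor, function(t) list(
    mode = t$mode, statistic = t$statistic, counting = t$counting,
    observed = t$observed, null_mean = t$null_mean, null_sd = t$null_sd,
    p = t$p, B = t$B, seed = t$seed)), "cooccurrence.json")
  for (nm in names(cor)) {
    write_null_distribution(cor[[nm]], path(paste0("null_", nm, ".tsv")))
  }
  utils::write.table(rpt, path("reef_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json(Filter(Negate(is.null),
                    list(nuc_dist_vs_geo = reg_json(ibd_nuc),
                         share_vs_geo = reg_json(ibd_share),
                         nuc_dist_vs_geo_heat = reg_json(ibd_heat))),
             "regressions.json")

  files <- c("validation.json", "distances.tsv", "haplogroups.tsv",
             "group_summary.json", "amova.tsv", "phi.json",
             "chisq_regional.tsv", "cooccurrence.json",
             paste0("null_", names(cor), ".tsv"),
             "reef_pairs.tsv", "regressions.json")
  manifest <- list(
    package = "mitoreef",
    version = as.character(utils::packageVersion("mitoreef")),
    seed = seed, B = B, counting = counting, distance = distance,
    n_colonies = a$n, L = a$L,
    files = files)
  write_json(manifest, "manifest.json")

  invisible(list(validation = val, distances = dm, haplogroups = h_full,
                 strict = h_strict, amova = am, chisq = chi,
                 cooccurrence = cor, reef_pairs = rpt,
                 regressions = list(nuc_dist_vs_geo = ibd_nuc,
                                    share_vs_geo = ibd_share,
                                    nuc_dist_vs_geo_heat = ibd_heat),
                 manifest = manifest))
}
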