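#' Read an aligned set of mitochondrial genomes from FASTA
#'
#' Reads a multiple alignment of whole mitochondrial genomes. All records
#' must have the same length; sequences may contain \code{A C G T} plus
#' \code{N} (uncalled base) and \code{-} (alignment gap). Both \code{N} and
#' \code{-} are treated downstream as "not called". Other IUPAC ambiguity
#' codes are rejected: haploid consensus genomes should not contain them.
#'
#' FASTA headers are split on the first whitespace; the leading token is the
#' colony id, anything after it is ignored (supplement-style headers often
#' carry extra metadata).
#'
#' @param path path to a FASTA file.
#' @return An object of class \code{mito_alignment}: a list with elements
#'   \code{ids} (character), \code{seq} (character matrix, one row per
#'   colony, one column per alignment position, upper case), \code{n}
#'   (number of colonies) and \code{L} (alignment length).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(dna), "[ \t]+"), `[`, character(1), 1L)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    bad <- ids[which(lens != lens[1L])[1L]]
    stop("alignment shape error: record '", bad, "' has length ",
         lens[ids == bad][1L], " but the first record has length ", lens[1L])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate colony ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- toupper(do.call(rbind, as.character(dna)))
  rownames(m) <- ids
  new_alignment(ids, m)
}

# construct + validate the alignment container
new_alignment <- function(ids, seq_matrix) {
  ok <- seq_matrix %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) {
    bad <- unique(seq_matrix[!ok])
    stop("alphabet violation: character(s) ",
         paste(sQuote(bad), collapse = ", "),
         " outside {A,C,G,T,N,-} (ambiguity codes are rejected)")
  }
  structure(list(ids = ids, seq = seq_matrix,
                 n = nrow(seq_matrix), L = ncol(seq_matrix)),
            class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("Aligned mitochondrial genomes:", x$n, "colonies x", x$L, "bases\n")
  nc <- rowSums(x$seq == "N" | x$seq == "-")
  cat("Uncalled bases per genome: mean", round(mean(nc), 1),
      "range", min(nc), "-", max(nc), "\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()]; sequences round-trip byte-identically.
#'
#' @param a a \code{mito_alignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(a, path) {
  stopifnot(inherits(a, "mito_alignment"))
  lines <- character(2L * a$n)
  lines[seq(1L, by = 2L, length.out = a$n)] <- paste0(">", a$ids)
  lines[seq(2L, by = 2L, length.out = a$n)] <-
    apply(a$seq, 1L, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the colony metadata table
#'
#' Reads a delimited table (comma or tab, auto-detected from the header
#' line) with one row per colony. Required columns: \code{colony},
#' \code{reef}, \code{region}, \code{lat}, \code{lon}, \code{date}.
#' Optional: \code{heat_fraction}, the fraction of temperature-logger time
#' intervals above 31 degrees C at the colony's reef (in [0,1]).
#'
#' @param path path to a CSV/TSV file.
#' @return A \code{data.frame} of class \code{mito_metadata}.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  as_metadata(df)
}

#' Validate a colony metadata data frame
#'
#' @param df data frame with the columns documented in [read_metadata()].
#' @return the validated \code{mito_metadata}.
#' @export
as_metadata <- function(df) {
  required <- c("colony", "reef", "region", "lat", "lon", "date")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("metadata validation error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$colony <- as.character(df$colony)
  df$reef <- as.character(df$reef)
  df$region <- as.character(df$region)
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  if (anyDuplicated(df$colony)) {
    stop("metadata validation error: duplicate colony id(s): ",
         paste(unique(df$colony[duplicated(df$colony)]), collapse = ", "))
  }
  # a reef belongs to exactly one region
  rr <- unique(df[, c("reef", "region")])
  if (anyDuplicated(rr$reef)) {
    bad <- unique(rr$reef[duplicated(rr$reef)])
    stop("metadata validation error: reef(s) mapped to multiple regions: ",
         paste(bad, collapse = ", "))
  }
  if (any(!is.finite(df$lat)) || any(df$lat < -90 | df$lat > 90)) {
    stop("metadata validation error: latitude outside [-90, 90]")
  }
  if (any(!is.finite(df$lon)) || any(df$lon < -180 | df$lon > 180)) {
    stop("metadata validation error: longitude outside [-180, 180]")
  }
  if ("heat_fraction" %in% names(df)) {
    hf <- as.numeric(df$heat_fraction)
    if (any(!is.na(hf) & (hf < 0 | hf > 1))) {
      stop("metadata validation error: heat_fraction outside [0, 1]")
    }
    df$heat_fraction <- hf
  }
  class(df) <- c("mito_metadata", "data.frame")
  df
}

#' Write the colony metadata table
#'
#' @param m a \code{mito_metadata}.
#' @param path output path; extension \code{.tsv} selects tab delimiting,
#'   anything else comma.
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate an alignment against its metadata
#'
#' Checks that the alignment and the metadata describe the same colonies and
#' summarises the dataset: uncalled bases per genome, colonies per reef,
#' and the reef roster per region.
#'
#' @param a a \code{mito_alignment}.
#' @param m a \code{mito_metadata}.
#' @return An object of class \code{mito_validation}: list with \code{pass}
#'   (logical), \code{problems} (character), \code{n_uncalled} (named
#'   integer per colony), \code{reef_counts}, \code{region_roster}.
#' @export
validate_dataset <- function(a, m) {
  stopifnot(inherits(a, "mito_alignment"), inherits(m, "mito_metadata"))
  problems <- character()
  only_a <- setdiff(a$ids, m$colony)
  only_m <- setdiff(m$colony, a$ids)
  if (length(only_a)) {
    problems <- c(problems, paste0("colonies in alignment but not metadata: ",
                                   paste(only_a, collapse = ", ")))
  }
  if (length(only_m)) {
    problems <- c(problems, paste0("colonies in metadata but not alignment: ",
                                   paste(only_m, collapse = ", ")))
  }
  n_uncalled <- rowSums(a$seq == "N" | a$seq == "-")
  names(n_uncalled) <- a$ids
  reef_counts <- table(m$reef)
  roster <- tapply(m$reef, m$region, function(r) sort(unique(r)))
  structure(list(pass = length(problems) == 0L,
                 problems = problems,
                 n_uncalled = n_uncalled,
                 mean_uncalled = mean(n_uncalled),
                 reef_counts = reef_counts,
                 region_roster = roster,
                 n_colonies = a$n, L = a$L),
            class = "mito_validation")
}

#' @export
print.mito_validation <- function(x, ...) {
  cat("Dataset validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(" ", x$n_colonies, "colonies,", x$L, "aligned bases,",
      length(x$reef_counts), "reefs,", length(x$region_roster), "regions\n")
  cat("  mean uncalled bases per genome:", round(x$mean_uncalled, 1), "\n")
  if (!x$pass) cat(paste0("  problem: ", x$problems, "\n"), sep = "")
  invisible(x)
}
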