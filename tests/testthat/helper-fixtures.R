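# Fixtures are built in code: toy alignments go through a temporary FASTA
# file so tests exercise the real I/O path.

toy_alignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  f <- tempfile(fileext = ".fasta")
  writeLines(c(rbind(paste0(">", ids), unname(seqs))), f)
  read_alignment(f)
}

toy_metadata <- function(colony, reef, region = NULL,
                         lat = NULL, lon = NULL, heat = NULL) {
  if (is.null(region)) region <- rep("G1", length(colony))
  reefs <- sort(unique(reef))
  if (is.null(lat)) lat <- (match(reef, reefs) - 1) * 0.1
  if (is.null(lon)) lon <- 134 + (match(reef, reefs) - 1) * 0.05
  df <- data.frame(colony = colony, reef = reef, region = region,
                   lat = lat, lon = lon, date = "2017-07-01",
                   stringsAsFactors = FALSE)
  if (!is.null(heat)) df$heat_fraction <- heat
  as_metadata(df)
}

# random toy alignment over A/C/G/T with optional N's, as character vector
random_seqs <- function(n, L, p_n = 0, bases = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    s <- sample(bases, L, replace = TRUE)
    if (p_n > 0) s[stats::runif(L) < p_n] <- "N"
    paste0(s, collapse = "")
  }, character(1))
}

# small simulation config for fast end-to-end tests
quick_config <- function(...) {
  defaults <- list(n_regions = 3, reefs_per_region = 2,
                   colonies_per_reef = 5, L = 600, n_founders = 8,
                   divergent_n = 2, clade_region_weights = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
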