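#' Coerce and validate a binary occurrence matrix
#'
#' The canonical community object throughout islecomm is a plain integer
#' matrix with species as rows and islands as columns, cells in \{0, 1\}
#' (1 = species recorded on that island), and unique dimnames on both
#' margins.
#'
#' @param x matrix or data frame coercible to a numeric matrix.
#' @return integer matrix, species x islands, validated.
#' @export
as_occurrence_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("occurrence matrix contains missing values")
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-binary cell at species '%s', island '%s' (value %s)",
      rownames(m)[bad[1, 1]] %||% bad[1, 1],
      colnames(m)[bad[1, 2]] %||% bad[1, 2],
      m[bad[1, 1], bad[1, 2]]
    ))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("sp", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("isl", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate species labels")
  if (anyDuplicated(colnames(m))) stop("duplicate island labels")
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a species-by-island occurrence matrix from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line)
#' with a header row and a leading label column, and returns the matrix in
#' canonical species-rows orientation regardless of the orientation on disk.
#'
#' @param path file path.
#' @param orientation `"species_rows"` (default) if rows of the file are
#'   species, `"islands_rows"` if rows are islands (the matrix is transposed
#'   on read).
#' @param blank_as_zero treat empty cells as absences instead of an error.
#' @return integer occurrence matrix (species x islands).
#' @seealso [write_occurrence_matrix()]
#' @export
read_occurrence_matrix <- function(path,
                                   orientation = c("species_rows", "islands_rows"),
                                   blank_as_zero = FALSE) {
  orientation <- match.arg(orientation)
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  m <- as.matrix(df)
  if (blank_as_zero) m[m == "" | is.na(m)] <- "0"
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("cell at row '%s', column '%s' does not parse to 0/1",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (orientation == "islands_rows") num <- t(num)
  as_occurrence_matrix(num)
}

#' Write an occurrence matrix to delimited text
#'
#' @param matrix occurrence matrix (species x islands).
#' @param path output path; a `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @param orientation orientation to write, as in [read_occurrence_matrix()].
#' @return `path`, invisibly.
#' @export
write_occurrence_matrix <- function(matrix, path,
                                    orientation = c("species_rows", "islands_rows")) {
  orientation <- match.arg(orientation)
  m <- as_occurrence_matrix(matrix)
  if (orientation == "islands_rows") m <- t(m)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- ""
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an island attribute table
#'
#' Expects columns `island_id, lon, lat, area_m2, elevation_m, perimeter_m,
#' habitat_richness, veg_coverage` and optionally `isw, isd_m`.
#'
#' @param path CSV/TSV path.
#' @return data frame with one row per island.
#' @export
read_island_table <- function(path) {
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  required <- c("island_id", "lon", "lat", "area_m2", "elevation_m",
                "perimeter_m", "habitat_richness", "veg_coverage")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("island table missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$island_id)) stop("duplicate island_id in island table")
  if (any(df$area_m2 <= 0)) stop("island areas must be positive")
  if (any(df$perimeter_m <= 0)) stop("island perimeters must be positive")
  frac <- intersect(c("veg_coverage", "isw"), names(df))
  for (v in frac) {
    if (any(df[[v]] < 0 | df[[v]] > 1, na.rm = TRUE)) {
      stop(sprintf("column '%s' must lie in [0, 1]", v))
    }
  }
  df
}

#' Read a taxon map
#'
#' Expects columns `species_id, family, division, growth_form` with
#' `division` in moss/liverwort/hornwort and `growth_form` in
#' acrocarpous/pleurocarpous/not_applicable (the latter for non-mosses).
#'
#' @param path CSV/TSV path.
#' @return data frame with one row per species.
#' @export
read_taxon_map <- function(path) {
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  required <- c("species_id", "family", "division", "growth_form")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("taxon map missing columns: ",
                            paste(missing, collapse = ", "))
  validate_taxa(df)
  df
}

validate_taxa <- function(taxa) {
  if (anyDuplicated(taxa$species_id)) stop("duplicate species_id in taxon map")
  bad_div <- setdiff(unique(taxa$division), c("moss", "liverwort", "hornwort"))
  if (length(bad_div)) stop("unknown division: ", paste(bad_div, collapse = ", "))
  bad_gf <- setdiff(unique(taxa$growth_form),
                    c("acrocarpous", "pleurocarpous", "not_applicable"))
  if (length(bad_gf)) stop("unknown growth_form: ", paste(bad_gf, collapse = ", "))
  inconsistent <- (taxa$division == "moss") == (taxa$growth_form == "not_applicable")
  if (any(inconsistent)) {
    stop("growth_form must be not_applicable exactly for non-mosses; offending species: ",
         paste(head(taxa$species_id[inconsistent], 5), collapse = ", "))
  }
  invisible(taxa)
}

#' Taxon category selectors
#'
#' The five standard bryophyte categories used throughout the package. A
#' selector passed to [subset_taxon()] may also be any family name present
#' in the taxon map. Hornworts are included only in `"bryophytes"`.
#'
#' @export
taxon_categories <- function() {
  c("bryophytes", "mosses", "liverworts", "acrocarpous", "pleurocarpous")
}

#' Subset an occurrence matrix by taxonomic category or family
#'
#' Restricts the species rows of an occurrence matrix to a category
#' (see [taxon_categories()]) or a family label. All islands are retained;
#' islands left without any species are recorded in the `"empty_islands"`
#' attribute of the result rather than dropped.
#'
#' @param matrix occurrence matrix (species x islands).
#' @param taxa taxon map data frame (see [read_taxon_map()]).
#' @param selector category name or family label.
#' @return occurrence matrix restricted to the matching species.
#' @export
subset_taxon <- function(matrix, taxa, selector) {
  m <- as_occurrence_matrix(matrix)
  validate_taxa(taxa)
  missing_sp <- setdiff(rownames(m), taxa$species_id)
  if (length(missing_sp)) {
    stop("species absent from taxon map: ",
         paste(head(missing_sp, 5), collapse = ", "))
  }
  t2 <- taxa[match(rownames(m), taxa$species_id), ]
  keep <- switch(selector,
    bryophytes   = rep(TRUE, nrow(m)),
    mosses       = t2$division == "moss",
    liverworts   = t2$division == "liverwort",
    acrocarpous  = t2$division == "moss" & t2$growth_form == "acrocarpous",
    pleurocarpous = t2$division == "moss" & t2$growth_form == "pleurocarpous",
    t2$family == selector
  )
  if (!any(keep)) stop(sprintf("selector '%s' matches no species", selector))
  out <- m[keep, , drop = FALSE]
  attr(out, "empty_islands") <- colnames(out)[colSums(out) == 0]
  out
}

#' Cross-validate an occurrence matrix, island table and taxon map
#'
#' Reporting-only consistency check: label mismatches between the three
#' inputs, all-zero species rows and island columns, and out-of-range island
#' attributes are listed. A clean bundle yields a zero-row report.
#'
#' @param matrix occurrence matrix.
#' @param islands island attribute table.
#' @param taxa taxon map.
#' @return data frame with columns `component`, `issue`, `detail`
#'   (zero rows when the bundle is consistent).
#' @export
validate_bundle <- function(matrix, islands, taxa) {
  m <- as_occurrence_matrix(matrix)
  issues <- list()
  add <- function(component, issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      component = component, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (i in setdiff(colnames(m), islands$island_id)) {
    add("islands", "island_missing_from_table", i)
  }
  for (i in setdiff(islands$island_id, colnames(m))) {
    add("islands", "island_missing_from_matrix", i)
  }
  for (s in setdiff(rownames(m), taxa$species_id)) {
    add("taxa", "species_missing_from_map", s)
  }
  for (s in rownames(m)[rowSums(m) == 0]) {
    add("matrix", "species_unobserved", s)
  }
  for (i in colnames(m)[colSums(m) == 0]) {
    add("matrix", "island_empty", i)
  }
  num_checks <- list(
    c("area_m2", "nonpositive"), c("perimeter_m", "nonpositive")
  )
  for (chk in num_checks) {
    v <- chk[1]
    if (v %in% names(islands)) {
      for (i in islands$island_id[islands[[v]] <= 0]) {
        add("islands", paste0(v, "_", chk[2]), i)
      }
    }
  }
  for (v in intersect(c("veg_coverage", "isw"), names(islands))) {
    out_of_range <- islands[[v]] < 0 | islands[[v]] > 1
    for (i in islands$island_id[which(out_of_range)]) {
      add("islands", paste0(v, "_out_of_range"), i)
    }
  }
  if (length(issues) == 0) {
    return(data.frame(component = character(), issue = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
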