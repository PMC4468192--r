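occurrence_columns <- c("species_id", "segment_id", "basin", "year", "source")

#' Read presence-only occurrence records
#'
#' Reads a table of historical presence records, one row per record, with
#' required columns \code{species_id, segment_id, basin, year, source};
#' additional columns are preserved. Accepts CSV, or a spreadsheet
#' (\code{.xlsx}, via readxl when installed) with an optional
#' \code{col_map} renaming the sheet's headers onto the required schema.
#' Duplicate records are kept — they collapse only when the incidence
#' matrix is built, so provenance stays intact. Rows with missing species
#' or segment identifiers are dropped with a warning naming their line
#' numbers.
#'
#' @param path file path
#' @param col_map optional named character vector mapping required column
#'   names to the column names found in the file, e.g.
#'   \code{c(species_id = "Species")}
#' @param sheet sheet name/index for spreadsheet input
#' @return data frame of occurrence records
#' @export
read_occurrences <- function(path, col_map = NULL, sheet = 1) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_arg("reading spreadsheets requires the 'readxl' package")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(col_map)) {
    for (target in names(col_map)) {
      j <- match(col_map[[target]], names(df))
      if (is.na(j)) stop_arg("col_map column not in file: ", col_map[[target]])
      names(df)[j] <- target
    }
  }
  missing_cols <- setdiff(occurrence_columns, names(df))
  if (length(missing_cols)) {
    stop_arg("occurrence table is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(df$species_id) | df$species_id == "" |
                 is.na(df$segment_id) | df$segment_id == "")
  if (length(bad)) {
    warning(sprintf("dropping %d malformed row(s) at line(s): %s",
                    length(bad),
                    paste(utils::head(bad + 1L, 10), collapse = ", ")),
            call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  df$species_id <- as.character(df$species_id)
  df$segment_id <- as.character(df$segment_id)
  rownames(df) <- NULL
  df
}

#' Write occurrence records to CSV
#'
#' @param records occurrence data frame
#' @param path output path
#' @export
write_occurrences <- function(records, path) {
  missing_cols <- setdiff(occurrence_columns, names(records))
  if (length(missing_cols)) {
    stop_arg("records missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Summarize an occurrence record table
#'
#' Record-count summaries of the kind reported for historical atlas
#' compilations: total records, distinct segments and species, records per
#' basin, and the family count when species metadata are supplied.
#'
#' @param records occurrence data frame
#' @param species_meta optional data frame with species_id, family_number
#' @return list of summary counts
#' @export
summarize_records <- function(records, species_meta = NULL) {
  out <- list(
    n_records = nrow(records),
    n_segments = length(unique(records$segment_id)),
    n_species = length(unique(records$species_id)),
    records_per_basin = table(records$basin)
  )
  if (!is.null(species_meta)) {
    keep <- species_meta$species_id %in% records$species_id
    out$n_families <- length(unique(species_meta$family_number[keep]))
  }
  out
}

#' Build a metacommunity incidence matrix from presence records
#'
#' Collates accumulated presence records from all sources into a binary
#' segment x species matrix: an entry is 1 when at least one historical
#' record of the species exists at the segment. Duplicate records collapse
#' here. This matrix is the community evidence from which focal-species
#' absences are inferred.
#'
#' @param records occurrence data frame
#' @param species_meta data frame with species_id, family_number, is_game
#'   covering every species in the records
#' @return object of class \code{metacommunity}: list with binary
#'   \code{incidence} matrix (segment rows, species columns),
#'   \code{species_meta}, and \code{segment_basin} lookup
#' @export
build_incidence <- function(records, species_meta) {
  if (nrow(records) == 0) stop_arg("no occurrence records supplied")
  unknown <- setdiff(unique(records$species_id), species_meta$species_id)
  if (length(unknown)) {
    stop_arg("species missing from species_meta: ",
             paste(unknown, collapse = ", "))
  }
  segments <- sort(unique(records$segment_id))
  species <- sort(unique(records$species_id))
  incidence <- matrix(0L, length(segments), length(species),
                      dimnames = list(segments, species))
  incidence[cbind(match(records$segment_id, segments),
                  match(records$species_id, species))] <- 1L
  segment_basin <- records$basin[match(segments, records$segment_id)]
  names(segment_basin) <- segments
  structure(list(
    incidence = incidence,
    species_meta = species_meta[match(species, species_meta$species_id), ,
                                drop = FALSE],
    segment_basin = segment_basin
  ), class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("Metacommunity incidence:", nrow(x$incidence), "segments x",
      ncol(x$incidence), "species;",
      sum(x$incidence), "presences\n")
  invisible(x)
}

#' Infer focal-species absences from community presence evidence
#'
#' Implements the community-based absence rule: a segment is labeled absent
#' (0) for the focal species when the focal species was never recorded
#' there but at least \code{min_other_nongame} other species were — other
#' species' presences evidence that the community was sampled. Game species
#' are excluded from that evidence by default, because their presences
#' often reflect stocking rather than community sampling. Segments with
#' focal records are labeled present (1) regardless of other evidence;
#' segments with insufficient community evidence stay unlabeled (they are
#' not absences — treating unsampled sites as absences is exactly the false
#' -absence pathology this rule avoids).
#'
#' @param metacommunity a \code{metacommunity} object
#' @param focal focal species id
#' @param min_other_nongame minimum count of other (non-game) species
#'   recorded at a segment for it to count as community-sampled
#' @param exclude_game whether game species are excluded from the evidence
#' @return data frame with segment_id, basin, label (1/0) for labeled
#'   segments only
#' @export
infer_absences <- function(metacommunity, focal, min_other_nongame = 1L,
                           exclude_game = TRUE) {
  stopifnot(inherits(metacommunity, "metacommunity"))
  inc <- metacommunity$incidence
  if (!(focal %in% colnames(inc))) {
    stop_arg("focal species not in metacommunity: ", focal)
  }
  if (min_other_nongame < 1) stop_arg("min_other_nongame must be >= 1")
  others <- setdiff(colnames(inc), focal)
  if (exclude_game) {
    meta <- metacommunity$species_meta
    game <- meta$species_id[meta$is_game]
    others <- setdiff(others, game)
  }
  other_count <- if (length(others)) {
    rowSums(inc[, others, drop = FALSE])
  } else {
    rep(0L, nrow(inc))
  }
  present <- inc[, focal] == 1L
  absent <- !present & other_count >= min_other_nongame
  keep <- present | absent
  data.frame(
    segment_id = rownames(inc)[keep],
    basin = unname(metacommunity$segment_basin[rownames(inc)[keep]]),
    label = as.integer(present[keep]),
    stringsAsFactors = FALSE
  )
}

#' Drop collinear habitat variables
#'
#' Within each connected set of variables pairwise linked by
#' \eqn{|r| > } \code{r_threshold} (Pearson), exactly one variable is kept —
#' the first in \code{priority} order (default: column order). Constant
#' variables are dropped first with a warning, since their correlation is
#' undefined. After pruning, no retained pair exceeds the threshold.
#'
#' @param habitat numeric matrix, segments x variables
#' @param r_threshold absolute Pearson correlation above which two
#'   variables are considered collinear
#' @param priority optional character vector; earlier variables win
#' @return list with \code{habitat} (pruned matrix) and \code{dropped}
#'   (data frame: variable, kept_instead)
#' @export
prune_collinear <- function(habitat, r_threshold = 0.8, priority = NULL) {
  if (ncol(habitat) < 2) stop_arg("need >= 2 variables")
  if (r_threshold <= 0 || r_threshold >= 1) stop_arg("r_threshold must be in (0,1)")
  vars <- colnames(habitat)
  const <- vars[apply(habitat, 2, stats::sd) == 0]
  dropped <- data.frame(variable = character(), kept_instead = character(),
                        stringsAsFactors = FALSE)
  if (length(const)) {
    warning("dropping constant variable(s): ", paste(const, collapse = ", "),
            call. = FALSE)
    dropped <- rbind(dropped, data.frame(variable = const,
                                         kept_instead = NA_character_))
    habitat <- habitat[, setdiff(vars, const), drop = FALSE]
    vars <- colnames(habitat)
  }
  ord <- if (is.null(priority)) vars else {
    c(intersect(priority, vars), setdiff(vars, priority))
  }
  r <- stats::cor(habitat)
  adj <- abs(r) > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- vapply(split(names(comp), comp), function(members) {
    members[order(match(members, ord))][1]
  }, "")
  keep <- vars[vars %in% keep]   # preserve original column order
  for (v in setdiff(vars, keep)) {
    rep_v <- keep[comp[keep] == comp[v]][1]
    dropped <- rbind(dropped, data.frame(variable = v, kept_instead = rep_v))
  }
  list(habitat = habitat[, keep, drop = FALSE], dropped = dropped)
}

#' Coarsen segment-level data to watershed units
#'
#' Aggregates a metacommunity and its habitat matrix from stream-segment
#' resolution to a coarser watershed-unit resolution: unit incidence is the
#' logical OR of member segments (a species present anywhere in the unit is
#' present in the unit), unit habitat the (optionally weighted) mean, and
#' unit coordinates the member centroid.
#'
#' @param metacommunity a \code{metacommunity}
#' @param habitat segments x variables matrix with rownames matching the
#'   incidence rows
#' @param unit_mapping named character vector segment_id -> unit_id covering
#'   every segment
#' @param coords optional segments x 2 coordinate matrix (rownames =
#'   segment ids) to aggregate to unit centroids
#' @param weights optional per-segment aggregation weights
#' @return list with \code{metacommunity}, \code{habitat}, and (if coords
#'   given) \code{coords}, all at unit resolution
#' @export
coarsen <- function(metacommunity, habitat, unit_mapping,
                    coords = NULL, weights = NULL) {
  stopifnot(inherits(metacommunity, "metacommunity"))
  inc <- metacommunity$incidence
  segs <- rownames(inc)
  unmapped <- setdiff(segs, names(unit_mapping))
  if (length(unmapped)) {
    stop_arg("segments missing from unit_mapping: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
  }
  units <- unit_mapping[segs]
  w <- if (is.null(weights)) rep(1, length(segs)) else rep_len(weights, length(segs))

  agg_mean <- function(m) {
    t(vapply(split(seq_along(segs), units), function(idx) {
      colSums(m[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
    }, numeric(ncol(m))))
  }
  unit_inc_raw <- t(vapply(split(seq_along(segs), units), function(idx) {
    as.integer(colSums(inc[idx, , drop = FALSE]) > 0)
  }, integer(ncol(inc))))
  colnames(unit_inc_raw) <- colnames(inc)

  unit_hab <- agg_mean(habitat[segs, , drop = FALSE])
  colnames(unit_hab) <- colnames(habitat)

  unit_basin <- vapply(split(seq_along(segs), units), function(idx) {
    names(which.max(table(metacommunity$segment_basin[segs[idx]])))
  }, "")

  meta_unit <- structure(list(
    incidence = unit_inc_raw,
    species_meta = metacommunity$species_meta,
    segment_basin = unit_basin
  ), class = "metacommunity")

  out <- list(metacommunity = meta_unit, habitat = unit_hab)
  if (!is.null(coords)) {
    out$coords <- agg_mean(as.matrix(coords[segs, , drop = FALSE]))
  }
  out
}
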