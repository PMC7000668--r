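#' Read and cross-validate a grazing-survey dataset
#'
#' Reads the three CSV tables the pipeline consumes and enforces their
#' invariants: quadrats (`quadrat_id,pair_id,treatment,openness_pct,
#' slope_deg`), long-format occurrences (`quadrat_id,species_id,layer,
#' present`) and a species palatability lookup (`species_id,palatable`).
#' Every referential-integrity violation is reported with the offending row
#' number.
#'
#' @param quadrat_path,occurrence_path,species_path Paths to the CSV tables.
#' @param quiet Suppress the row-count log message.
#' @return A validated list of class `occu_data` with elements `quadrats`,
#'   `occurrences`, `species`.
#' @export
read_dataset <- function(quadrat_path, occurrence_path, species_path,
                         quiet = FALSE) {
  quadrats <- read_table_checked(quadrat_path,
    c("quadrat_id", "pair_id", "treatment", "openness_pct", "slope_deg"))
  occurrences <- read_table_checked(occurrence_path,
    c("quadrat_id", "species_id", "layer", "present"))
  species <- read_table_checked(species_path, c("species_id", "palatable"))
  ds <- validate_dataset(quadrats, occurrences, species)
  if (!quiet) {
    message(sprintf("read %d quadrats, %d occurrence records, %d species",
                    nrow(ds$quadrats), nrow(ds$occurrences),
                    nrow(ds$species)))
  }
  ds
}

read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab[required_cols]
}

#' Validate the three survey tables against their invariants
#'
#' Checks level sets, value ranges, key uniqueness and referential integrity.
#' Accepts in-memory data frames (e.g. from [simulate_occurrence()]), so the
#' same rules guard both file and simulated inputs.
#'
#' @param quadrats,occurrences,species Data frames with the schemas of
#'   [read_dataset()].
#' @return A list of class `occu_data`.
#' @export
validate_dataset <- function(quadrats, occurrences, species) {
  bad_treat <- which(!quadrats$treatment %in% c("exclosure", "grazing"))
  if (length(bad_treat)) {
    stop("quadrats: unknown treatment level at row ", bad_treat[1],
         " ('", quadrats$treatment[bad_treat[1]], "')", call. = FALSE)
  }
  bad_open <- which(quadrats$openness_pct < 0 | quadrats$openness_pct > 100 |
                      is.na(quadrats$openness_pct))
  if (length(bad_open)) {
    stop("quadrats: openness_pct outside [0,100] at row ", bad_open[1],
         call. = FALSE)
  }
  bad_slope <- which(quadrats$slope_deg < 0 | is.na(quadrats$slope_deg))
  if (length(bad_slope)) {
    stop("quadrats: negative or missing slope_deg at row ", bad_slope[1],
         call. = FALSE)
  }
  dup_q <- which(duplicated(quadrats$quadrat_id))
  if (length(dup_q)) {
    stop("quadrats: duplicate quadrat_id at row ", dup_q[1],
         " ('", quadrats$quadrat_id[dup_q[1]], "')", call. = FALSE)
  }
  dup_s <- which(duplicated(species$species_id))
  if (length(dup_s)) {
    stop("species: duplicate species_id at row ", dup_s[1], call. = FALSE)
  }
  if (!all(species$palatable %in% c(0L, 1L))) {
    stop("species: palatable must be 0 or 1", call. = FALSE)
  }
  bad_layer <- which(!occurrences$layer %in% c("seedbank", "aboveground"))
  if (length(bad_layer)) {
    stop("occurrences: unknown layer at row ", bad_layer[1],
         " ('", occurrences$layer[bad_layer[1]], "')", call. = FALSE)
  }
  if (!all(occurrences$present %in% c(0L, 1L))) {
    bad <- which(!occurrences$present %in% c(0L, 1L))[1]
    stop("occurrences: present must be 0 or 1 (row ", bad, ")", call. = FALSE)
  }
  orphan_q <- which(!occurrences$quadrat_id %in% quadrats$quadrat_id)
  if (length(orphan_q)) {
    stop("occurrences: row ", orphan_q[1], " references unknown quadrat '",
         occurrences$quadrat_id[orphan_q[1]], "'", call. = FALSE)
  }
  orphan_s <- which(!occurrences$species_id %in% species$species_id)
  if (length(orphan_s)) {
    stop("occurrences: row ", orphan_s[1], " references unknown species '",
         occurrences$species_id[orphan_s[1]], "'", call. = FALSE)
  }
  key <- paste(occurrences$quadrat_id, occurrences$species_id,
               occurrences$layer)
  dup_o <- which(duplicated(key))
  if (length(dup_o)) {
    stop("occurrences: duplicate (quadrat, species, layer) key at row ",
         dup_o[1], call. = FALSE)
  }
  structure(list(quadrats = quadrats, occurrences = occurrences,
                 species = species),
            class = "occu_data")
}

#' Write a dataset to the three CSV schemas
#'
#' Writes `quadrats.csv`, `occurrences.csv` and `species.csv` under `dir`,
#' each sorted by primary key for reproducible diffs. For a
#' `synthetic_dataset` the generative truth is written alongside as a flat
#' `truth.txt` key=value file so recovery runs can find it.
#'
#' @param dataset An `occu_data` or `synthetic_dataset` object, or a plain
#'   list with `quadrats`, `occurrences`, `species`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- dataset$quadrats[order(dataset$quadrats$quadrat_id), , drop = FALSE]
  o <- dataset$occurrences
  o <- o[order(o$layer, o$species_id, o$quadrat_id), , drop = FALSE]
  s <- dataset$species[order(dataset$species$species_id), , drop = FALSE]
  paths <- c(quadrats = file.path(dir, "quadrats.csv"),
             occurrences = file.path(dir, "occurrences.csv"),
             species = file.path(dir, "species.csv"))
  write.csv(q, paths[["quadrats"]], row.names = FALSE, quote = FALSE)
  write.csv(o, paths[["occurrences"]], row.names = FALSE, quote = FALSE)
  write.csv(s, paths[["species"]], row.names = FALSE, quote = FALSE)
  if (inherits(dataset, "synthetic_dataset")) {
    tp <- file.path(dir, "truth.txt")
    write_truth(dataset$truth, dataset$seed, tp)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

write_truth <- function(truth, seed, path) {
  lines <- c(sprintf("beta_%s=%.17g", names(truth$beta), truth$beta),
             sprintf("sigma_pair=%.17g", truth$sigma_pair),
             sprintf("sigma_species=%.17g", truth$sigma_species),
             paste0("treatment_coding=", truth$treatment_coding),
             sprintf("seed=%d", seed))
  writeLines(lines, path)
}

#' Restrict occurrences to palatable species
#'
#' Ungulates preferentially graze palatable species, so the occurrence
#' analysis is confined to them: only records whose species has
#' `palatable = 1` are retained. Idempotent; never invents records.
#'
#' @param occurrences Occurrence table.
#' @param species Species lookup with a 0/1 `palatable` column.
#' @param quiet Suppress the retained-count log message.
#' @return The filtered occurrence table. Warns if the result is empty (a
#'   model cannot be fitted to zero species).
#' @export
#' @examples
#' sp <- data.frame(species_id = c("a", "b", "c"), palatable = c(1, 0, 1))
#' occ <- data.frame(quadrat_id = "q1", species_id = c("a", "b", "c"),
#'                   layer = "seedbank", present = c(1, 0, 1))
#' filter_palatable(occ, sp, quiet = TRUE)
filter_palatable <- function(occurrences, species, quiet = FALSE) {
  palatable_ids <- species$species_id[species$palatable == 1]
  out <- occurrences[occurrences$species_id %in% palatable_ids, , drop = FALSE]
  rownames(out) <- NULL
  n_sp <- length(unique(out$species_id))
  if (nrow(out) == 0) {
    warning("no palatable-species records remain; the occurrence model ",
            "cannot be fitted to zero species", call. = FALSE)
  } else if (!quiet) {
    message(sprintf("palatability filter retained %d species, %d records",
                    n_sp, nrow(out)))
  }
  out
}
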