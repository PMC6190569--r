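#' Write and read pedigree tables
#'
#' Pedigrees are serialized as tab-separated tables in the `rv_ped` column
#' layout (a column-compatible superset of the usual pre-makeped pedigree
#' layout), one row per member, with missing values written as empty
#' fields. Rows are ordered by family, then ID (IDs are assigned in
#' creation order, so parents precede offspring). `write_pedigrees()`
#' writes a study as two files, `full_peds.tsv` and `ascertained_peds.tsv`;
#' `write_ped_table()` / `read_ped_table()` handle a single table.
#'
#' @param study a list of `rv_ped_pair` objects from [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `write_pedigrees()` invisibly returns the two file paths;
#'   `read_pedigrees()` returns a list of validated `rv_ped` data frames,
#'   one per family.
#' @export
write_pedigrees <- function(study, dir) {
  stopifnot(length(study) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  full <- do.call(rbind, lapply(study, `[[`, "full_ped"))
  asc <- do.call(rbind, lapply(study, `[[`, "ascertained_ped"))
  paths <- c(full = file.path(dir, "full_peds.tsv"),
             ascertained = file.path(dir, "ascertained_peds.tsv"))
  write_ped_table(full, paths["full"])
  write_ped_table(asc, paths["ascertained"])
  invisible(paths)
}

#' @rdname write_pedigrees
#' @param ped an `rv_ped` (possibly several families row-bound).
#' @param path file path of a single pedigree table.
#' @export
write_ped_table <- function(ped, path) {
  ped <- ped[order(ped$FamID, ped$ID), ped_columns()]
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pedigrees
#' @export
read_ped_table <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.delim(path, na.strings = "",
                          colClasses = c(
                            FamID = "integer", ID = "integer",
                            sex = "integer", dadID = "integer",
                            momID = "integer", affected = "integer",
                            DA = "integer", birthYr = "integer",
                            onsetYr = "integer", deathYr = "integer",
                            RR = "numeric", available = "logical",
                            proband = "logical"))
  if (nrow(df) == 0L) return(as_rv_ped(df[ped_columns()], validate = FALSE))
  as_rv_ped(df)
}

#' @rdname write_pedigrees
#' @export
read_pedigrees <- function(path) {
  ped <- read_ped_table(path)
  lapply(split(ped, ped$FamID), function(fam) {
    rownames(fam) <- NULL
    class(fam) <- c("rv_ped", "data.frame")
    fam
  })
}

#' Write study summary tables
#'
#' Writes `family_info.tsv` and `affected_info.tsv` (see
#' [summarize_study()]), the anticipation tables (onset ages and the
#' unaffected death-age negative control, by assigned generation), and a
#' one-line `proportion_segregating.tsv`.
#'
#' @param study a list of `rv_ped_pair` objects or `rv_ped` data frames.
#' @param dir output directory (created if absent).
#' @param min_affected threshold for [proportion_segregating()].
#' @return Invisibly, the paths written.
#' @export
write_summary_tables <- function(study, dir, min_affected = 2) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summarize_study(study)
  ant <- anticipation_tables(study)
  prop <- suppressWarnings(proportion_segregating(study, min_affected))
  paths <- file.path(dir, c("family_info.tsv", "affected_info.tsv",
                            "anticipation_onset.tsv",
                            "anticipation_death_control.tsv",
                            "proportion_segregating.tsv"))
  utils::write.table(s$family_info, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(s$affected_info, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(ant$onset, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(ant$death_control, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(
    data.frame(min_affected = min_affected, proportion = prop),
    paths[5], sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(paths)
}
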