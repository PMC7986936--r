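# Tabular cohort I/O: two tidy TSVs with a fixed, documented column order.
# subjects.tsv: id, group, cag, gender, age, tiv, site (empty cag = control)
# visits.tsv:   id, time_years, 55 region columns, [tms, sdmt]

#' Write a cohort to two TSV tables
#'
#' @param cohort An `hd_cohort` (or compatible list).
#' @param subjects_path,visits_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort,
                         subjects_path = "subjects.tsv",
                         visits_path = "visits.tsv") {
  utils::write.table(cohort$subjects, subjects_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$visits, visits_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(c(subjects = subjects_path, visits = visits_path))
}

#' Read and validate a cohort from TSV tables
#'
#' Performs hard validation of the documented schema: required columns, no
#' duplicate subject-visit rows, strictly increasing visit times per subject
#' (irregular spacing is accepted), strictly positive volumes, behavioural
#' scores inside `[0, 100]`.
#'
#' @param subjects_path,visits_path Input file paths.
#' @return An object of class `hd_cohort` (without generative `truth`).
#' @export
read_cohort <- function(subjects_path, visits_path) {
  subjects <- utils::read.delim(subjects_path, sep = "\t",
                                stringsAsFactors = FALSE, na.strings = "")
  visits <- utils::read.delim(visits_path, sep = "\t",
                              stringsAsFactors = FALSE, na.strings = "")
  need_s <- c("id", "group", "cag", "gender", "age", "tiv", "site")
  miss <- setdiff(need_s, names(subjects))
  if (length(miss))
    stop("subjects table is missing column(s): ", paste(miss, collapse = ", "))
  regions <- hd_region_table()$region
  miss <- setdiff(c("id", "time_years", regions), names(visits))
  if (length(miss))
    stop("visits table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(visits[, c("id", "time_years")]))
    stop("duplicate subject-visit rows in visits table")
  if (any(!visits$id %in% subjects$id))
    stop("visits reference unknown subject id")
  for (id in unique(visits$id)) {
    tt <- visits$time_years[visits$id == id]
    if (any(diff(tt) <= 0))
      stop("visit times not strictly increasing for subject ", id)
  }
  vols <- as.matrix(visits[, regions])
  if (any(!is.finite(vols)))
    stop("non-finite volume values in visits table")
  if (any(vols <= 0)) {
    bad <- which(vols <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive volume in region '%s', row %d",
                 regions[bad[2]], bad[1]))
  }
  for (ch in intersect(c("tms", "sdmt"), names(visits))) {
    v <- visits[[ch]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("behavioural scores must lie in [0, 100] (column ", ch, ")")
  }
  structure(list(subjects = subjects, visits = visits,
                 truth = NULL, config = NULL),
            class = "hd_cohort")
}
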