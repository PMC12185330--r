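## Reading and writing registry bundles as headered CSV files.
##
## Schema (ages/times are 0-based months from birth; missing = empty field):
##   persons.csv : id, sex, yob, county, death_month, emig_month,
##                 ea_z, iq_z, res_z
##   pedigree.csv: id, father_id, mother_id
##   events.csv  : id, disorder, age_months
##   cohab.csv   : id_a, id_b, years

.BUNDLE_SCHEMA <- list(
  persons = c("id", "sex", "yob", "county", "death_month", "emig_month",
              "ea_z", "iq_z", "res_z"),
  pedigree = c("id", "father_id", "mother_id"),
  events = c("id", "disorder", "age_months"),
  cohab = c("id_a", "id_b", "years")
)

#' Write a registry bundle to a directory of CSV files
#'
#' @param bundle A `registry_bundle`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "registry_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (part in names(.BUNDLE_SCHEMA)) {
    path <- file.path(directory, paste0(part, ".csv"))
    fwrite(bundle[[part]][, .BUNDLE_SCHEMA[[part]], with = FALSE], path,
           na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a registry bundle from a directory of CSV files
#'
#' Validates the header schema of each file and the bundle invariants
#' (parents present, event ids known, event ages within follow-up, one
#' event per person and disorder).
#'
#' @param directory Directory holding persons.csv, pedigree.csv, events.csv
#'   and cohab.csv.
#' @param cohort_range Optional two-element birth-year range recorded in
#'   the bundle metadata (the analysis cohort).
#' @return A `registry_bundle`.
#' @export
read_bundle <- function(directory, cohort_range = NULL) {
  parts <- list()
  for (part in names(.BUNDLE_SCHEMA)) {
    path <- file.path(directory, paste0(part, ".csv"))
    if (!file.exists(path)) stop("missing bundle file: ", path)
    dt <- fread(path, na.strings = "")
    missing_cols <- setdiff(.BUNDLE_SCHEMA[[part]], names(dt))
    if (length(missing_cols))
      stop("schema mismatch in ", part, ".csv: missing columns ",
           paste(missing_cols, collapse = ", "))
    parts[[part]] <- dt[, .BUNDLE_SCHEMA[[part]], with = FALSE]
  }
  ## empty files may come back with wrong column classes
  if (nrow(parts$events) == 0L)
    parts$events <- data.table(id = integer(), disorder = character(),
                               age_months = integer())
  bundle <- structure(c(parts,
                        list(truth = NULL,
                             meta = list(cohort_range = cohort_range))),
                      class = "registry_bundle")
  validate_bundle(bundle)
  bundle
}

#' Validate registry bundle invariants
#'
#' Checks that every non-founder has both parents present in the persons
#' table, every event id exists, event ages are at or after the start of
#' follow-up (age 17 = 204 months), no event follows the person's censoring
#' month, and no person has two events for the same disorder.
#'
#' @param bundle A `registry_bundle`.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_bundle <- function(bundle) {
  persons <- bundle$persons
  ped <- bundle$pedigree
  events <- bundle$events
  if (anyDuplicated(persons$id)) stop("duplicate person ids")
  known <- persons$id
  nonfounder <- !is.na(ped$father_id) | !is.na(ped$mother_id)
  bad <- nonfounder & (is.na(ped$father_id) | is.na(ped$mother_id) |
                         !(ped$father_id %in% known) |
                         !(ped$mother_id %in% known))
  if (any(bad))
    stop("pedigree invariant violated: ", sum(bad),
         " non-founders lack both parents in the persons table")
  if (nrow(events)) {
    if (!all(events$id %in% known))
      stop("events reference unknown person ids")
    if (any(events$age_months < FOLLOWUP_START_MONTHS))
      stop("event ages before the start of follow-up (204 months)")
    if (anyDuplicated(events[, .(id, disorder)]))
      stop("a person has two events for the same disorder")
    cm <- censor_month(persons,
                       bundle$meta$admin_end_year %||% 2018L)
    names(cm) <- persons$id
    if (any(events$age_months > cm[as.character(events$id)]))
      stop("an event occurs after the person's censoring month")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
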