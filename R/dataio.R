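#' Read a NONMEM-flavoured event dataset
#'
#' Long-format event records with columns `ID`, `TIME` (months), `EVID`
#' (1 = dose, 0 = observation), `AMT` (dose amount in ng, dose rows only),
#' `DV` (observed BMD in g/cm^2, observation rows only), `MDV` (missing-DV
#' flag) and `N` (arm size, constant per id). Validation is strict and
#' errors carry row numbers.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `kpd_dataset` in canonical order
#'   (ID, TIME, observations before doses at the same time).
#' @export
read_event_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty dataset: ", path, " has no content", call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("empty dataset: ", path, " contains no records", call. = FALSE)
  as_event_dataset(df)
}

#' Coerce and validate an event dataset
#'
#' @param df A data frame with the event-record columns (see
#'   [read_event_dataset()]).
#' @return A validated `kpd_dataset` in canonical order.
#' @export
as_event_dataset <- function(df) {
  validate_event_dataset(df)
  df <- df[order(df$ID, df$TIME, df$EVID), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("kpd_dataset", "data.frame")
  df
}

#' Validate event-dataset invariants
#'
#' Checks the structural invariants of the event-record format; errors
#' identify offending rows by number. Called by [read_event_dataset()] and
#' before any fit.
#'
#' @param df A data frame of event records.
#' @return `df`, invisibly, if valid.
#' @export
validate_event_dataset <- function(df) {
  req <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "N")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("event dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: no records", call. = FALSE)
  rows <- function(i) paste(i, collapse = ", ")
  num_ok <- function(x) is.numeric(x) | is.integer(x)
  for (cl in c("TIME", "EVID", "MDV"))
    if (!num_ok(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("column ", cl, " must be finite numeric", call. = FALSE)
  if (any(df$TIME < 0))
    stop("negative TIME in row(s): ", rows(which(df$TIME < 0)), call. = FALSE)
  if (!all(df$EVID %in% c(0, 1)))
    stop("EVID must be 0 or 1 in row(s): ",
         rows(which(!df$EVID %in% c(0, 1))), call. = FALSE)

  dose <- df$EVID == 1
  obs <- df$EVID == 0
  bad <- which(dose & !is.na(df$DV))
  if (length(bad))
    stop("DV present on dose row(s): ", rows(bad), call. = FALSE)
  bad <- which(dose & (is.na(df$AMT) | df$AMT <= 0))
  if (length(bad))
    stop("dose row(s) need AMT > 0 (ng): ", rows(bad), call. = FALSE)
  bad <- which(dose & df$MDV != 1)
  if (length(bad))
    stop("dose row(s) must have MDV = 1: ", rows(bad), call. = FALSE)
  bad <- which(obs & df$MDV == 0 & (is.na(df$DV) | df$DV <= 0))
  if (length(bad))
    stop("observation row(s) need DV > 0 where MDV = 0: ", rows(bad),
         call. = FALSE)
  if (any(!is.finite(df$N) | df$N < 1))
    stop("N (arm size) must be >= 1 in row(s): ",
         rows(which(!is.finite(df$N) | df$N < 1)), call. = FALSE)

  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, , drop = FALSE]
    if (!any(sub$EVID == 1))
      stop("id ", id, " has no dose record (orphan id)", call. = FALSE)
    if (!any(sub$EVID == 0 & sub$MDV == 0))
      stop("id ", id, " has no observation record", call. = FALSE)
    first_dose <- min(sub$TIME[sub$EVID == 1])
    ot <- sub$TIME[sub$EVID == 0 & sub$MDV == 0]
    if (!any(ot <= first_dose))
      stop("id ", id, " lacks a baseline observation at or before its ",
           "first dose", call. = FALSE)
    if (length(unique(sub$N)) != 1L)
      stop("id ", id, " has inconsistent N values", call. = FALSE)
  }
  invisible(df)
}

#' Write an event dataset as CSV
#'
#' Writes the canonical form so that write-then-read is the identity.
#'
#' @param data A `kpd_dataset` (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_dataset <- function(data, path) {
  data <- as_event_dataset(as.data.frame(data))
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dosing regimen from CSV
#'
#' Columns `time_month` and `dose_mg`; doses are converted to ng internally.
#'
#' @param path Path to a CSV file.
#' @return A [kpd_regimen()].
#' @export
read_regimen_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time_month", "dose_mg"), names(df))
  if (length(miss))
    stop("regimen CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  kpd_regimen(df$time_month, df$dose_mg, units = "mg")
}

# expected checksums of the packaged fixture tables
.FIXTURE_MD5 <- c(
  study_designs.csv        = "f5b22d1f86664fed0d4e78ffb905a04b",
  published_parameters.csv = "37a0d21e38887b2b3f092c02ddbda256",
  apr_counts.csv           = "ccc0e357107e84a0305fbd7fec8c35e7"
)

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "kpdbmd")
  if (p == "") stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' Load the packaged study fixtures
#'
#' Returns the transcribed study-design table (10 trial arms: regimen,
#' arm size, baseline vertebral BMD), the published population parameter
#' estimates, and the acute-phase-reaction counts by dose group (with the
#' internally inconsistent row flagged). File checksums are verified so a
#' corrupted installation fails loudly.
#'
#' @return A list with elements `designs` (list of [arm_design()]), `pop`
#'   (a [population_model()]), `apr` (a validated APR table, see
#'   [read_apr_table()]), and `tables` (the three raw data frames).
#' @export
load_fixtures <- function() {
  paths <- vapply(names(.FIXTURE_MD5), .fixture_path, character(1))
  sums <- md5sum(paths)
  mismatch <- sums != .FIXTURE_MD5
  if (any(mismatch))
    stop("fixture checksum mismatch: ",
         paste(names(.FIXTURE_MD5)[mismatch], collapse = ", "), call. = FALSE)

  t1 <- read.csv(paths[1], stringsAsFactors = FALSE)
  t2 <- read.csv(paths[2], stringsAsFactors = FALSE)
  apr <- read_apr_table(paths[3])

  p <- setNames(t2$estimate, t2$parameter)
  pop <- population_model(p["kde"], p["kd"], p["edk50"], p["k_tol"],
                          p["omega2_edk50"], p["sigma2"])

  designs <- lapply(seq_len(nrow(t1)), function(i) {
    r <- t1[i, ]
    dose_times <- seq(0, by = r$interval_month, length.out = r$n_doses)
    arm_design(label = r$label,
               n_subjects = r$n_subjects,
               baseline_bmd = r$baseline_bmd,
               regimen = kpd_regimen(dose_times, rep(r$dose_mg, r$n_doses),
                                     units = "mg"),
               observation_times = seq(0, r$followup_month, by = 6))
  })
  list(designs = designs, pop = pop, apr = apr,
       tables = list(designs = t1, parameters = t2,
                     apr = as.data.frame(apr)))
}
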