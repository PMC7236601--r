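# Column schemas for the two flat tables. Order matters: write_cohort emits
# exactly these columns and read_cohort requires them.
PATIENT_COLS <- c("id", "sex", "ethnicity", "smoking", "age", "weight_kg",
                  "tshrab_u_ml", "tpoab_u_ml", "relapsed", "relapse_day")
VISIT_COLS <- c("patient_id", "day", "ft4_pmol_l", "ft3_pmol_l", "tsh_mu_l",
                "dose_mg", "split_dose")

SEX_LEVELS <- c("M", "F")
ETHNICITY_LEVELS <- c("Asian", "Black", "White", "Mixed", "Other", "Unknown")
SMOKING_LEVELS <- c("never", "ex", "current")

#' Allowed daily carbimazole doses
#'
#' The dose set used for validation and for dose recommendation, in mg/day.
#' @return Numeric vector of permitted daily doses.
#' @export
allowed_doses <- function() c(0, 5, 10, 15, 20, 25, 30, 40)

#' Laboratory reference ranges for thyroid function tests
#'
#' Bounds used to classify thyroid status. TSH in mU/L, fT4 and fT3 in
#' pmol/L. Only the upper fT3 bound is used for classification; a lower fT3
#' bound may be supplied but defaults to \code{NA} (euthyroid classification
#' then ignores it).
#'
#' @param tsh_low,tsh_high TSH reference interval (mU/L).
#' @param ft4_low,ft4_high fT4 reference interval (pmol/L).
#' @param ft3_high Upper fT3 bound (pmol/L).
#' @param ft3_low Optional lower fT3 bound (pmol/L); \code{NA} to ignore.
#' @return A list of class \code{"thyro_ranges"}.
#' @export
reference_ranges <- function(tsh_low = 0.3, tsh_high = 4.2,
                             ft4_low = 9, ft4_high = 23.0,
                             ft3_high = 5.7, ft3_low = NA_real_) {
  stopifnot(tsh_low < tsh_high, ft4_low < ft4_high)
  if (!is.na(ft3_low)) stopifnot(ft3_low < ft3_high)
  structure(list(tsh_low = tsh_low, tsh_high = tsh_high,
                 ft4_low = ft4_low, ft4_high = ft4_high,
                 ft3_high = ft3_high, ft3_low = ft3_low),
            class = "thyro_ranges")
}

#' Assay detection limits
#'
#' Lower limits of detection of the hormone immunoassays, used as floors for
#' simulated and modelled levels (pmol/L).
#' @return Named list with \code{ft4} and \code{ft3}.
#' @export
assay_floors <- function() list(ft4 = 5.15, ft3 = 1.536)

#' Construct a validated cohort
#'
#' Bundles a patient table and a visit table into a cohort object after
#' validating both against the schema invariants. Validation rejects, with
#' row-numbered messages, exactly the rows that violate an invariant; it
#' never silently drops data.
#'
#' @param patients data.frame with columns \code{id, sex, ethnicity, smoking,
#'   age, weight_kg, tshrab_u_ml, tpoab_u_ml, relapsed, relapse_day}.
#' @param visits data.frame with columns \code{patient_id, day, ft4_pmol_l,
#'   ft3_pmol_l, tsh_mu_l, dose_mg, split_dose}.
#' @param check_doses If TRUE (default), require every \code{dose_mg} to be in
#'   \code{\link{allowed_doses}}.
#' @return An object of class \code{"thyro_cohort"}: a list with elements
#'   \code{patients} and \code{visits}.
#' @export
cohort <- function(patients, visits, check_doses = TRUE) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)

  missing_p <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_p))
    stop("patients table missing column(s): ", paste(missing_p, collapse = ", "))
  missing_v <- setdiff(VISIT_COLS, names(visits))
  if (length(missing_v))
    stop("visits table missing column(s): ", paste(missing_v, collapse = ", "))
  patients <- patients[PATIENT_COLS]
  visits <- visits[VISIT_COLS]

  problems <- character(0)
  note <- function(rows, table, what) {
    if (length(rows))
      problems <<- c(problems, sprintf("%s row %d: %s", table, rows, what))
  }

  if (anyDuplicated(patients$id))
    note(which(duplicated(patients$id)), "patients", "duplicate patient id")
  note(which(!patients$sex %in% SEX_LEVELS), "patients", "invalid sex")
  note(which(!patients$ethnicity %in% ETHNICITY_LEVELS), "patients",
       "invalid ethnicity")
  note(which(!patients$smoking %in% SMOKING_LEVELS), "patients",
       "invalid smoking status")
  note(which(is.na(patients$age) | patients$age < 16 | patients$age > 100),
       "patients", "age outside 16-100")
  note(which(!is.na(patients$weight_kg) & patients$weight_kg <= 0),
       "patients", "non-positive weight_kg")
  note(which(is.na(patients$tshrab_u_ml) | patients$tshrab_u_ml < 0),
       "patients", "negative or missing tshrab_u_ml")
  note(which(!is.na(patients$tpoab_u_ml) & patients$tpoab_u_ml < 0),
       "patients", "negative tpoab_u_ml")
  note(which(!is.na(patients$relapse_day) &
               (is.na(patients$relapsed) | !patients$relapsed)),
       "patients", "relapse_day present but relapsed is not TRUE")

  orphan <- !visits$patient_id %in% patients$id
  if (any(orphan))
    note(which(orphan), "visits",
         sprintf("orphan visit (unknown patient_id %s)",
                 visits$patient_id[orphan]))
  key <- paste(visits$patient_id, visits$day)
  note(which(duplicated(key)), "visits", "duplicate (patient_id, day)")
  note(which(is.na(visits$day) | visits$day < 0), "visits", "negative day")
  note(which(is.na(visits$ft4_pmol_l) | visits$ft4_pmol_l <= 0),
       "visits", "non-positive ft4_pmol_l")
  note(which(!is.na(visits$ft3_pmol_l) & visits$ft3_pmol_l <= 0),
       "visits", "non-positive ft3_pmol_l")
  note(which(!is.na(visits$tsh_mu_l) & visits$tsh_mu_l < 0),
       "visits", "negative tsh_mu_l")
  if (check_doses)
    note(which(!visits$dose_mg %in% allowed_doses()), "visits",
         "dose_mg not in allowed dose set")

  # Per-patient ordering constraints
  treated <- unique(visits$patient_id[!orphan])
  for (pid in treated) {
    idx <- which(visits$patient_id == pid)
    d <- visits$day[idx]
    if (anyNA(d)) next  # already reported above
    if (is.unsorted(d, strictly = TRUE))
      note(idx[1], "visits",
           sprintf("visits for patient %s not in strictly increasing day order", pid))
    if (sum(d == 0) != 1)
      note(idx[1], "visits",
           sprintf("patient %s must have exactly one day-0 visit", pid))
  }

  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))

  rownames(patients) <- NULL
  rownames(visits) <- NULL
  structure(list(patients = patients, visits = visits), class = "thyro_cohort")
}

#' @export
print.thyro_cohort <- function(x, ...) {
  cat(sprintf("<thyro_cohort> %d patients, %d visits\n",
              nrow(x$patients), nrow(x$visits)))
  invisible(x)
}

#' Read a cohort from the two-table CSV representation
#'
#' Reads the documented CSV dialect (UTF-8, comma separated, header row,
#' empty string = missing) and returns a validated cohort. Rows with
#' unparseable numeric fields are reported with their row numbers.
#'
#' @param patients_path,visits_path Paths to the patient and visit CSVs.
#' @return A \code{"thyro_cohort"} object.
#' @seealso \code{\link{write_cohort}}, which this function inverts exactly.
#' @export
read_cohort <- function(patients_path, visits_path) {
  for (p in c(patients_path, visits_path))
    if (!file.exists(p)) stop("file not found: ", p)
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                              colClasses = "character", na.strings = NULL,
                              fileEncoding = "UTF-8")
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = NULL,
                            fileEncoding = "UTF-8")

  num <- function(x, col, table) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("%s: unparseable numeric in column '%s' at row(s) %s",
                   table, col, paste(bad, collapse = ", ")))
    out
  }
  lgl <- function(x, col, table) {
    x[x == ""] <- NA_character_
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "T", "1")] <- TRUE
    out[x %in% c("FALSE", "false", "F", "0")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("%s: unparseable logical in column '%s' at row(s) %s",
                   table, col, paste(bad, collapse = ", ")))
    out
  }
  chr <- function(x) { x[x == ""] <- NA_character_; x }

  missing_p <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_p))
    stop("patients file missing column(s): ", paste(missing_p, collapse = ", "))
  missing_v <- setdiff(VISIT_COLS, names(visits))
  if (length(missing_v))
    stop("visits file missing column(s): ", paste(missing_v, collapse = ", "))

  patients <- data.frame(
    id = patients$id,
    sex = patients$sex,
    ethnicity = patients$ethnicity,
    smoking = patients$smoking,
    age = as.integer(num(patients$age, "age", "patients")),
    weight_kg = num(patients$weight_kg, "weight_kg", "patients"),
    tshrab_u_ml = num(patients$tshrab_u_ml, "tshrab_u_ml", "patients"),
    tpoab_u_ml = num(patients$tpoab_u_ml, "tpoab_u_ml", "patients"),
    relapsed = lgl(patients$relapsed, "relapsed", "patients"),
    relapse_day = as.integer(num(patients$relapse_day, "relapse_day", "patients")),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    patient_id = visits$patient_id,
    day = as.integer(num(visits$day, "day", "visits")),
    ft4_pmol_l = num(visits$ft4_pmol_l, "ft4_pmol_l", "visits"),
    ft3_pmol_l = num(visits$ft3_pmol_l, "ft3_pmol_l", "visits"),
    tsh_mu_l = num(visits$tsh_mu_l, "tsh_mu_l", "visits"),
    dose_mg = num(visits$dose_mg, "dose_mg", "visits"),
    split_dose = lgl(visits$split_dose, "split_dose", "visits"),
    stringsAsFactors = FALSE)
  patients$id <- chr(patients$id)
  visits$patient_id <- chr(visits$patient_id)

  cohort(patients, visits)
}

#' Write a cohort to the two-table CSV representation
#'
#' Emits the documented CSV dialect; optional fields that are missing are
#' written as empty cells, never as sentinel numbers. \code{read_cohort}
#' inverts this exactly (field-for-field equality).
#'
#' @param x A \code{"thyro_cohort"} object.
#' @param patients_path,visits_path Output paths.
#' @export
write_cohort <- function(x, patients_path, visits_path) {
  stopifnot(inherits(x, "thyro_cohort"))
  fmt <- function(df) {
    out <- df
    for (j in seq_along(out)) {
      v <- out[[j]]
      if (is.numeric(v)) v <- ifelse(is.na(v), "", sprintf("%.17g", v))
      else if (is.logical(v)) v <- ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE"))
      else v <- ifelse(is.na(v), "", as.character(v))
      out[[j]] <- v
    }
    out
  }
  utils::write.csv(fmt(x$patients), patients_path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(fmt(x$visits), visits_path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Classify thyroid status from a set of thyroid function tests
#'
#' Applies the monitoring rules used throughout the pipeline, in this
#' precedence order: \emph{overtreated} (TSH above range or fT4 below range)
#' is checked first because it is the safety-relevant flag during antithyroid
#' treatment; then \emph{hyperthyroid} (suppressed TSH with elevated fT4 or
#' fT3); then \emph{euthyroid} (every supplied analyte within bounds);
#' anything else, including cases where too few analytes are supplied to
#' decide, is \emph{indeterminate}. Classification degrades gracefully to the
#' analytes present rather than guessing. Vectorised over its inputs.
#'
#' @param tsh TSH (mU/L), may be NA.
#' @param ft4 fT4 (pmol/L), required and positive.
#' @param ft3 fT3 (pmol/L), may be NA.
#' @param ranges A \code{\link{reference_ranges}} object.
#' @return Character vector with levels
#'   \code{hyperthyroid, euthyroid, overtreated, indeterminate}.
#' @export
classify_status <- function(tsh = NA_real_, ft4, ft3 = NA_real_,
                            ranges = reference_ranges()) {
  n <- max(length(tsh), length(ft4), length(ft3))
  tsh <- rep_len(tsh, n); ft4 <- rep_len(ft4, n); ft3 <- rep_len(ft3, n)
  if (any(is.na(ft4) | ft4 <= 0)) stop("ft4 must be present and positive")

  over <- (!is.na(tsh) & tsh > ranges$tsh_high) | ft4 < ranges$ft4_low
  hyper <- !is.na(tsh) & tsh < ranges$tsh_low &
    (ft4 > ranges$ft4_high | (!is.na(ft3) & ft3 > ranges$ft3_high))

  tsh_ok <- !is.na(tsh) & tsh >= ranges$tsh_low & tsh <= ranges$tsh_high
  ft4_ok <- ft4 >= ranges$ft4_low & ft4 <= ranges$ft4_high
  ft3_ok <- is.na(ft3) |
    (ft3 <= ranges$ft3_high &
       (is.na(ranges$ft3_low) | ft3 >= ranges$ft3_low))
  # Euthyroid needs TSH: with TSH absent and levels in range the record is
  # indeterminate rather than assumed normal.
  eu <- tsh_ok & ft4_ok & ft3_ok

  out <- rep("indeterminate", n)
  out[eu] <- "euthyroid"
  out[hyper] <- "hyperthyroid"
  if (any(over & hyper))
    warning("record(s) satisfy both overtreated and hyperthyroid bounds; ",
            "classifying as overtreated")
  out[over] <- "overtreated"
  out
}
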