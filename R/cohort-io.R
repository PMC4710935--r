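# Patient-level cohort I/O.
#
# A cohort is a data.frame with one row per patient x treatment phase:
#   patient_id, arm ("EPOB"/"CERA"), hb_1..hb_6 (g/dL), dose_1..dose_6
#   (IU/week for EpoB, ug/month for CERA), cost_1..cost_6 (currency),
#   and optional ferritin (ng/mL), tsat (%).
# Exactly six monthly measures per phase is a protocol invariant: the phase
# classification uses the mean of six consecutive monthly Hb values.

arm_levels <- c("EPOB", "CERA")

cohort_required_cols <- function() {
  c("patient_id", "arm",
    paste0("hb_", 1:6), paste0("dose_", 1:6), paste0("cost_", 1:6))
}

#' Assemble a patient-phase cohort data frame
#'
#' Builds (and validates) the canonical wide cohort layout from its pieces.
#' Mostly useful in tests and simulators; files are read with
#' [read_cohort()].
#'
#' @param patient_id vector of patient identifiers.
#' @param arm character vector, `"EPOB"` or `"CERA"`.
#' @param hb n x 6 matrix of monthly haemoglobin values, g/dL.
#' @param dose n x 6 matrix of monthly doses (IU/week for EpoB rows,
#'   ug/month for CERA rows).
#' @param cost n x 6 matrix of monthly drug-acquisition costs.
#' @param ferritin,tsat optional per-row iron-status markers.
#' @return a validated cohort `data.frame`.
#' @export
cohort <- function(patient_id, arm, hb, dose, cost,
                   ferritin = NULL, tsat = NULL) {
  hb <- as.matrix(hb); dose <- as.matrix(dose); cost <- as.matrix(cost)
  n <- length(patient_id)
  stopifnot(length(arm) == n, nrow(hb) == n, nrow(dose) == n, nrow(cost) == n)
  df <- data.frame(patient_id = patient_id, arm = as.character(arm),
                   stringsAsFactors = FALSE)
  colnames(hb) <- paste0("hb_", 1:6)
  colnames(dose) <- paste0("dose_", 1:6)
  colnames(cost) <- paste0("cost_", 1:6)
  df <- cbind(df, hb, dose, cost)
  if (!is.null(ferritin)) df$ferritin <- ferritin
  if (!is.null(tsat)) df$tsat <- tsat
  validate_cohort(df)
}

#' Validate a patient-phase cohort
#'
#' Checks the structural invariants of the cohort layout: required columns
#' present, six numeric Hb values per phase in the physiologically plausible
#' (3, 20) g/dL window, non-negative doses and costs, recognised arm labels,
#' and no duplicated (patient, arm) pair.
#'
#' @param df a data.frame in the wide cohort layout.
#' @return `df` invisibly coerced (arm upper-cased), or an error describing
#'   the first violation found, naming the offending column or row.
#' @export
validate_cohort <- function(df) {
  req <- cohort_required_cols()
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("cohort format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(req, c("patient_id", "arm"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("cohort parse error: non-numeric value in column '%s', row %d",
                     cl, bad[1]), call. = FALSE)
      df[[cl]] <- coerced
    }
    bad_na <- which(is.na(df[[cl]]))
    if (length(bad_na) > 0)
      stop(sprintf("cohort format error: missing value in column '%s', row %d",
                   cl, bad_na[1]), call. = FALSE)
  }
  df$arm <- toupper(as.character(df$arm))
  bad_arm <- which(!df$arm %in% arm_levels)
  if (length(bad_arm) > 0)
    stop(sprintf("cohort format error: unknown arm '%s' in row %d (expected EPOB or CERA)",
                 df$arm[bad_arm[1]], bad_arm[1]), call. = FALSE)
  hb <- as.matrix(df[paste0("hb_", 1:6)])
  out <- which(hb <= 3 | hb >= 20, arr.ind = TRUE)
  if (nrow(out) > 0)
    stop(sprintf("cohort range error: Hb value %.2f g/dL outside (3, 20) for patient %s, month %d",
                 hb[out[1, 1], out[1, 2]], df$patient_id[out[1, 1]], out[1, 2]),
         call. = FALSE)
  for (pre in c("dose_", "cost_")) {
    m <- as.matrix(df[paste0(pre, 1:6)])
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop(sprintf("cohort range error: negative %s for patient %s, month %d",
                   sub("_$", "", pre), df$patient_id[neg[1, 1]], neg[1, 2]),
           call. = FALSE)
  }
  key <- paste(df$patient_id, df$arm)
  if (anyDuplicated(key))
    stop("cohort format error: duplicated (patient_id, arm) pair: ",
         key[which(duplicated(key))[1]], call. = FALSE)
  df
}

#' Read a patient-level cohort from delimited text
#'
#' @param path path to a delimited text file with a header row naming the
#'   columns `patient_id, arm, hb_1..hb_6, dose_1..dose_6, cost_1..cost_6`
#'   (optional `ferritin`, `tsat`).
#' @param sep field delimiter (default comma).
#' @return a validated cohort `data.frame`, one row per patient-phase.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' co <- simulate_cohort(sim_params(n_patients = 5, seed = 1))
#' write_cohort(co, path)
#' nrow(read_cohort(path)) # 10: 5 patients x 2 phases
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if ("patient_id" %in% names(df))
    df$patient_id <- as.character(df$patient_id)
  validate_cohort(df)
}

#' Write a patient-level cohort to delimited text
#'
#' @param df a cohort `data.frame` (validated before writing).
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path, sep = ",") {
  df <- validate_cohort(df)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
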