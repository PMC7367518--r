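#' Encode the medicine item as two exclusive binary indicators
#'
#' The medicine answer is categorical by design (taken, not taken, taken with
#' changes) and is encoded as two mutually exclusive dummies: medicine
#' omitted (not taken) and medicine changed (taken with changes); taken maps
#' to (0, 0).
#'
#' @param raw Character vector of medicine categories.
#' @return A data.frame with columns \code{medicine_omitted} and
#'   \code{medicine_changed} (0/1, never both 1).
#' @export
encode_medicine <- function(raw) {
  bad <- setdiff(unique(raw), medicine_categories())
  if (length(bad))
    stop(sprintf("unknown medicine category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  data.frame(
    medicine_omitted = as.numeric(raw == "not_taken"),
    medicine_changed = as.numeric(raw == "taken_with_changes")
  )
}

#' Split sleep into negative and positive deviations from the patient mean
#'
#' Sleep duration is not expected to act linearly on mood, so each patient's
#' sleep hours are centred on that patient's own mean and split into a
#' non-positive and a non-negative component: with d = sleep - mean(sleep),
#' sleep_negative = min(d, 0) and sleep_positive = max(d, 0), so the two
#' components always sum back to d.
#'
#' @param data A \code{selfassessment} data frame.
#' @param patient_means Optional named numeric vector of per-patient mean
#'   sleep (names are patient ids), e.g. computed from training-visible
#'   records only. Defaults to each patient's mean over the records in
#'   \code{data}.
#' @return \code{data} with extra numeric columns \code{sleep_negative}
#'   (<= 0) and \code{sleep_positive} (>= 0), in hours.
#' @export
split_sleep <- function(data, patient_means = NULL) {
  if (is.null(data$sleep) || all(is.na(data$sleep)))
    stop("split_sleep: no sleep observations", call. = FALSE)
  if (is.null(patient_means)) {
    patient_means <- tapply(data$sleep, data$patient_id, mean, na.rm = TRUE)
  }
  miss <- setdiff(unique(data$patient_id), names(patient_means))
  if (length(miss))
    stop(sprintf("split_sleep: no sleep mean for patient(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  d <- data$sleep -
    as.numeric(patient_means[as.character(data$patient_id)])
  data$sleep_negative <- pmin(d, 0)
  data$sleep_positive <- pmax(d, 0)
  data
}

# Allowed ranges used for normalisation. Predictor mood shares the
# questionnaire range; the split sleep components use a fixed symmetric
# +/- 12 h range around the patient mean so the transform does not depend
# on the data split. Binary items pass through unchanged.
normalization_ranges <- function() {
  list(
    mood = c(-3, 3), activity = c(-3, 3), alcohol = c(0, 10),
    anxiety = c(0, 2), irritable = c(0, 2), cognitive_difficulty = c(0, 2),
    medicine_omitted = c(0, 1), medicine_changed = c(0, 1),
    mixed_mood = c(0, 1), sleep_negative = c(-12, 0),
    sleep_positive = c(0, 12), stress = c(0, 2)
  )
}

#' Min-max normalise questionnaire items to [0, 1]
#'
#' Each item is mapped affinely by its allowed minimum and maximum:
#' x -> (x - min) / (max - min). Binary indicators are unchanged by
#' construction. Values outside the allowed range raise a validation error
#' (which also guards against accidentally normalising twice).
#'
#' @param values Numeric vector.
#' @param item Item name (one of the names of the preprocessed predictor
#'   set: mood, activity, alcohol, anxiety, irritable, cognitive_difficulty,
#'   medicine_omitted, medicine_changed, mixed_mood, sleep_negative,
#'   sleep_positive, stress).
#' @return Numeric vector in [0, 1].
#' @export
normalize_items <- function(values, item) {
  rng <- normalization_ranges()[[item]]
  if (is.null(rng)) stop(sprintf("unknown item '%s'", item), call. = FALSE)
  bad <- !is.na(values) & (values < rng[1] | values > rng[2])
  if (any(bad))
    stop(sprintf("'%s' outside allowed range [%g, %g]: %s",
                 item, rng[1], rng[2],
                 paste(utils::head(values[bad], 3), collapse = ", ")),
         call. = FALSE)
  (values - rng[1]) / (rng[2] - rng[1])
}

# Canonical per-day predictor order; lag 0 is the newest day of the window.
predictor_items <- function() {
  c("mood", "activity", "alcohol", "anxiety", "irritable",
    "cognitive_difficulty", "medicine_omitted", "medicine_changed",
    "mixed_mood", "sleep_negative", "sleep_positive", "stress")
}

#' Build the windowed forecast design matrix
#'
#' Emits one example per (patient, anchor day t) such that all w history
#' days t-w+1..t and the target day t+h are observed; missing days are never
#' imputed, so a gap anywhere in the window or at the target drops the
#' candidate anchor. Features are the preprocessed predictors
#' (\code{\link{encode_medicine}}, \code{\link{split_sleep}},
#' \code{\link{normalize_items}}) of the w history days, ordered oldest to
#' newest, 12 predictors per day; the target is the raw mood (scale -3..3)
#' at day t+h. Patients contributing no examples are excluded and J counts
#' retained patients only.
#'
#' @param data A \code{selfassessment} data frame.
#' @param w Window size in days (>= 1).
#' @param h Forecast horizon in days (>= 1).
#' @param sleep_means Optional named per-patient mean sleep passed to
#'   \code{\link{split_sleep}} (e.g. training-visible means inside CV).
#' @return An object of class \code{forecast_dataset}: a list with the
#'   N x (12 w) feature matrix \code{X} (columns named \code{item@lag},
#'   lag w-1 first, lag 0 last), target vector \code{y}, \code{patient_id},
#'   \code{patient_index} (1..J), \code{anchor_date}, \code{target_date},
#'   \code{patients}, \code{feature_names}, and scalars \code{w}, \code{h},
#'   \code{J}, \code{N}.
#' @export
build_windows <- function(data, w, h, sleep_means = NULL) {
  if (!is.numeric(w) || length(w) != 1 || w < 1)
    stop("invalid 'w': window size must be >= 1", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1 || h < 1)
    stop("invalid 'h': horizon must be >= 1", call. = FALSE)
  w <- as.integer(w); h <- as.integer(h)

  data <- data[order(data$patient_id, data$date), , drop = FALSE]
  data <- split_sleep(data, sleep_means)
  med <- encode_medicine(data$medicine)
  data$medicine_omitted <- med$medicine_omitted
  data$medicine_changed <- med$medicine_changed

  items <- predictor_items()
  norm <- matrix(NA_real_, nrow(data), length(items),
                 dimnames = list(NULL, items))
  for (it in items) norm[, it] <- normalize_items(data[[it]], it)

  feature_names <- as.vector(vapply((w - 1):0, function(l)
    paste0(items, "@", l), character(length(items))))

  per <- split(seq_len(nrow(data)), data$patient_id)
  first_record_all <- as.Date(vapply(per, function(i)
    format(min(data$date[i])), character(1)))
  rows <- list(); meta <- list()
  for (pid in names(per)) {
    idx <- per[[pid]]
    days <- as.integer(data$date[idx] - min(data$date[idx]))
    lookup <- rep(NA_integer_, max(days) + 1L)
    lookup[days + 1L] <- idx
    n_slots <- length(lookup)
    for (t in w:(n_slots)) {
      hist_slots <- (t - w + 1L):t
      targ_slot <- t + h
      if (targ_slot > n_slots) next
      hist_idx <- lookup[hist_slots]
      targ_idx <- lookup[targ_slot]
      if (anyNA(hist_idx) || is.na(targ_idx)) next
      rows[[length(rows) + 1L]] <- as.vector(t(norm[hist_idx, , drop = FALSE]))
      meta[[length(meta) + 1L]] <- list(
        patient_id = pid,
        anchor_date = data$date[lookup[t]],
        target_date = data$date[targ_idx],
        y = data$mood[targ_idx])
    }
  }
  if (length(rows) == 0) {
    X <- matrix(numeric(0), 0, length(feature_names),
                dimnames = list(NULL, feature_names))
    return(structure(list(
      X = X, y = numeric(0), patient_id = character(0),
      patient_index = integer(0), anchor_date = as.Date(character(0)),
      target_date = as.Date(character(0)), patients = character(0),
      first_record = as.Date(character(0)),
      feature_names = feature_names, w = w, h = h, J = 0L, N = 0L),
      class = "forecast_dataset"))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- feature_names
  pid <- vapply(meta, `[[`, character(1), "patient_id")
  patients <- sort(unique(pid))
  structure(list(
    X = X,
    y = vapply(meta, `[[`, numeric(1), "y"),
    patient_id = pid,
    patient_index = match(pid, patients),
    anchor_date = as.Date(vapply(meta, function(m)
      format(m$anchor_date), character(1))),
    target_date = as.Date(vapply(meta, function(m)
      format(m$target_date), character(1))),
    patients = patients,
    first_record = first_record_all[patients],
    feature_names = feature_names,
    w = w, h = h, J = length(patients), N = length(pid)),
    class = "forecast_dataset")
}

#' @export
print.forecast_dataset <- function(x, ...) {
  cat(sprintf(
    "Forecast dataset: N=%d examples, J=%d patients, w=%d day(s), h=%d day(s), %d features\n",
    x$N, x$J, x$w, x$h, length(x$feature_names)))
  invisible(x)
}

#' Subset a forecast dataset by example indices
#'
#' Keeps the selected examples and re-indexes patients (patients left with
#' zero examples are dropped and J updated), preserving w, h and the
#' feature layout. Used by the cross-validation machinery to materialize
#' fold training and test sets.
#'
#' @param data A \code{forecast_dataset}.
#' @param idx Integer vector of example indices.
#' @return A \code{forecast_dataset}.
#' @export
subset_dataset <- function(data, idx) {
  pid <- data$patient_id[idx]
  patients <- sort(unique(pid))
  structure(list(
    X = data$X[idx, , drop = FALSE],
    y = data$y[idx],
    patient_id = pid,
    patient_index = match(pid, patients),
    anchor_date = data$anchor_date[idx],
    target_date = data$target_date[idx],
    patients = patients,
    first_record = if (!is.null(data$first_record))
      data$first_record[patients],
    feature_names = data$feature_names,
    w = data$w, h = data$h,
    J = length(patients), N = length(idx)),
    class = "forecast_dataset")
}

#' Write / read a windowed dataset as flat CSV plus JSON sidecar
#'
#' The CSV has one row per example: \code{patient_id}, \code{anchor_date},
#' \code{target_date}, the 12 w feature columns (named \code{item.lag}
#' after R column mangling of \code{item@lag}), and \code{target}. The JSON
#' sidecar (same path with extension \code{.json}) records w, h, J, N and
#' the canonical feature names.
#'
#' @param ds A \code{forecast_dataset}.
#' @param path Output CSV path.
#' @return \code{write_windows_csv} returns \code{path} invisibly;
#'   \code{read_windows_csv} returns a \code{forecast_dataset}.
#' @export
write_windows_csv <- function(ds, path) {
  df <- data.frame(patient_id = ds$patient_id,
                   anchor_date = format(ds$anchor_date),
                   target_date = format(ds$target_date),
                   ds$X, target = ds$y, check.names = TRUE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(
    list(w = ds$w, h = ds$h, J = ds$J, N = ds$N,
         feature_names = ds$feature_names,
         first_record = as.list(stats::setNames(format(ds$first_record),
                                                ds$patients))),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(names(df), c("patient_id", "anchor_date",
                                           "target_date", "target"))])
  colnames(X) <- meta$feature_names
  pid <- df$patient_id
  patients <- sort(unique(pid))
  structure(list(
    X = X, y = df$target, patient_id = pid,
    patient_index = match(pid, patients),
    anchor_date = as.Date(df$anchor_date),
    target_date = as.Date(df$target_date),
    patients = patients, feature_names = meta$feature_names,
    first_record = if (!is.null(meta$first_record))
      as.Date(stats::setNames(unlist(meta$first_record),
                              names(meta$first_record)))[patients],
    w = meta$w, h = meta$h, J = length(patients), N = nrow(df)),
    class = "forecast_dataset")
}
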