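#' Body surface area by the Mosteller formula
#'
#' BSA (m2) = sqrt(height_cm * weight_kg / 3600). Used to scale the insulin
#' infusion rate (mU per m2 BSA per minute).
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return Body surface area in m2.
#' @examples
#' compute_bsa(175.6, 90.9)
#' @export
compute_bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive and finite", call. = FALSE)
  }
  sqrt(height_cm * weight_kg / 3600)
}

#' Construct a study subject
#'
#' Anthropometry plus group label and the optional MRI-derived body
#' composition covariates. Missing covariates stay `NA` (never silently
#' zero); BSA is derived via [compute_bsa()].
#'
#' @param id Subject identifier (string).
#' @param group Group label, one of `"BAM"` or `"WEM"` (black African /
#'   white European men in the motivating study design; any two-group
#'   labelling maps onto these).
#' @param weight_kg,height_cm Anthropometry (> 0).
#' @param vat_kg,sat_kg,muscle_kg Optional visceral adipose, subcutaneous
#'   adipose and skeletal-muscle masses in kg (`NA` if not measured).
#' @return An object of class `clamp_subject`.
#' @examples
#' subject("S01", "BAM", weight_kg = 90.9, height_cm = 175.6, vat_kg = 3.7)
#' @export
subject <- function(id, group, weight_kg, height_cm,
                    vat_kg = NA_real_, sat_kg = NA_real_,
                    muscle_kg = NA_real_) {
  group <- match.arg(group, c("BAM", "WEM"))
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("`weight_kg` must be positive", call. = FALSE)
  }
  if (!is.finite(height_cm) || height_cm <= 0) {
    stop("`height_cm` must be positive", call. = FALSE)
  }
  for (nm in c("vat_kg", "sat_kg", "muscle_kg")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop(sprintf("`%s` must be >= 0 or NA", nm),
                                 call. = FALSE)
  }
  structure(
    list(id = as.character(id), group = group,
         weight_kg = weight_kg, height_cm = height_cm,
         bsa_m2 = compute_bsa(height_cm, weight_kg),
         vat_kg = vat_kg, sat_kg = sat_kg, muscle_kg = muscle_kg),
    class = "clamp_subject"
  )
}

#' @export
print.clamp_subject <- function(x, ...) {
  cat(sprintf("<clamp_subject> %s [%s] %.1f kg, %.1f cm, BSA %.2f m2\n",
              x$id, x$group, x$weight_kg, x$height_cm, x$bsa_m2))
  covs <- c(VAT = x$vat_kg, SAT = x$sat_kg, muscle = x$muscle_kg)
  cat("  body composition (kg):",
      paste(sprintf("%s=%s", names(covs),
                    ifelse(is.na(covs), "NA", sprintf("%.2f", covs))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a subject table
#'
#' One row per subject with columns `id, group, weight_kg, height_cm,
#' vat_kg, sat_kg, muscle_kg`; empty cells encode missing covariates.
#'
#' @param path CSV file path.
#' @return `read_subjects()`: a list of [subject()] objects, named by id.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "weight_kg", "height_cm")
  if (!all(need %in% names(df))) {
    stop("subject table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("vat_kg", "sat_kg", "muscle_kg")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  subs <- lapply(seq_len(nrow(df)), function(i) {
    subject(df$id[i], df$group[i], df$weight_kg[i], df$height_cm[i],
            as.numeric(df$vat_kg[i]), as.numeric(df$sat_kg[i]),
            as.numeric(df$muscle_kg[i]))
  })
  stats::setNames(subs, vapply(subs, `[[`, "", "id"))
}

#' @rdname read_subjects
#' @param subjects List of `clamp_subject` objects.
#' @export
write_subjects <- function(subjects, path) {
  df <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(id = s$id, group = s$group, weight_kg = s$weight_kg,
               height_cm = s$height_cm, vat_kg = s$vat_kg,
               sat_kg = s$sat_kg, muscle_kg = s$muscle_kg)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
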