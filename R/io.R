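# Cohort schema readers/writers. One lesion per row with treatment-level
# fields repeated (CSV, UTF-8, comma, versioned comment header), or an
# equivalent nested JSON. Units are fixed by the schema: masses kg, volumes
# ml, doses Gy, activities GBq, msA kBq.

COHORT_SCHEMA_VERSION <- "sirtdose_cohort_v1"

COHORT_COLUMNS <- c(
  "treatment_id", "patient_id", "lobe_mass_kg", "normal_liver_mass_kg",
  "whole_liver_mass_kg", "lung_shunt_fraction", "tnr",
  "targeted_volume_fraction", "injected_activity_gbq",
  "microsphere_specific_activity_kbq", "normal_liver_dpa_delivered",
  "normal_liver_dpa_planning", "lesion_id", "lesion_volume_ml",
  "lesion_dpa_delivered", "lesion_dpa_planning")

#' Write a cohort to CSV or JSON
#'
#' CSV gets a `# sirtdose_cohort_v1` header comment and one row per lesion;
#' JSON is nested (one object per treatment with a `lesions` array). Format
#' follows the file extension.
#'
#' @param cohort A [sirt_cohort()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "sirt_cohort"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- cohort_lesions(cohort)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", COHORT_SCHEMA_VERSION), con)
    utils::write.csv(df, con, row.names = FALSE)
  } else if (ext == "json") {
    payload <- list(schema = COHORT_SCHEMA_VERSION,
                    treatments = lapply(cohort, function(tr) {
                      tr <- unclass(tr)
                      tr$lesions <- lapply(tr$lesions, unclass)
                      tr
                    }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    stop("unsupported cohort format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a cohort from CSV or JSON
#'
#' Validates the schema header, required columns and every domain invariant;
#' violations are reported with the offending row or treatment.
#'
#' @param path Path to a file written in the cohort schema.
#' @return A [sirt_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    read_cohort_csv(path)
  } else if (ext == "json") {
    read_cohort_json(path)
  } else {
    stop("unsupported cohort format: .", ext, call. = FALSE)
  }
}

read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl(COHORT_SCHEMA_VERSION, first, fixed = TRUE)) {
    stop(sprintf("'%s' lacks the '# %s' schema header", path,
                 COHORT_SCHEMA_VERSION), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in intersect(c("treatment_id", "patient_id", "lesion_id"),
                        names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("'%s': missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df_to_cohort(df, origin = path)
}

df_to_cohort <- function(df, origin = "data") {
  treatments <- lapply(split(df, factor(df$treatment_id,
                                        levels = unique(df$treatment_id))),
                       function(rows) {
    hdr <- rows[1, ]
    lesions <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      tryCatch(
        lesion(lesion_id = r$lesion_id, volume = r$lesion_volume_ml,
               delivered_dose_per_activity = r$lesion_dpa_delivered,
               planning_dose_per_activity = r$lesion_dpa_planning),
        error = function(e) {
          stop(sprintf("%s, treatment '%s', row %s: %s", origin,
                       hdr$treatment_id, rownames(rows)[i],
                       conditionMessage(e)), call. = FALSE)
        })
    })
    tryCatch(
      treatment(treatment_id = hdr$treatment_id,
                patient_id = hdr$patient_id,
                lobe_mass = hdr$lobe_mass_kg,
                normal_liver_mass = hdr$normal_liver_mass_kg,
                whole_liver_mass = hdr$whole_liver_mass_kg,
                lung_shunt_fraction = hdr$lung_shunt_fraction,
                tnr = hdr$tnr,
                lesions = lesions,
                targeted_volume_fraction = hdr$targeted_volume_fraction,
                normal_liver_dose_per_activity_delivered =
                  hdr$normal_liver_dpa_delivered,
                normal_liver_dose_per_activity_planning =
                  hdr$normal_liver_dpa_planning,
                microsphere_specific_activity =
                  hdr$microsphere_specific_activity_kbq,
                injected_activity = hdr$injected_activity_gbq),
      error = function(e) {
        stop(sprintf("%s: %s", origin, conditionMessage(e)), call. = FALSE)
      })
  })
  sirt_cohort(unname(treatments))
}

read_cohort_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$schema, COHORT_SCHEMA_VERSION)) {
    stop(sprintf("'%s': schema is '%s', expected '%s'", path,
                 paste(payload$schema, collapse = ""), COHORT_SCHEMA_VERSION),
         call. = FALSE)
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  treatments <- lapply(payload$treatments, function(tr) {
    lesions <- lapply(tr$lesions, function(l) {
      lesion(lesion_id = l$lesion_id, volume = as.numeric(l$volume),
             delivered_dose_per_activity =
               as.numeric(l$delivered_dose_per_activity),
             planning_dose_per_activity =
               num_or_na(l$planning_dose_per_activity))
    })
    treatment(treatment_id = tr$treatment_id,
              patient_id = if (is.null(tr$patient_id)) NA_character_ else
                tr$patient_id,
              lobe_mass = as.numeric(tr$lobe_mass),
              normal_liver_mass = as.numeric(tr$normal_liver_mass),
              whole_liver_mass = as.numeric(tr$whole_liver_mass),
              lung_shunt_fraction = as.numeric(tr$lung_shunt_fraction),
              tnr = as.numeric(tr$tnr),
              lesions = lesions,
              targeted_volume_fraction =
                as.numeric(tr$targeted_volume_fraction),
              normal_liver_dose_per_activity_delivered =
                num_or_na(tr$normal_liver_dose_per_activity_delivered),
              normal_liver_dose_per_activity_planning =
                num_or_na(tr$normal_liver_dose_per_activity_planning),
              microsphere_specific_activity =
                num_or_na(tr$microsphere_specific_activity),
              injected_activity = num_or_na(tr$injected_activity))
  })
  sirt_cohort(treatments)
}
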