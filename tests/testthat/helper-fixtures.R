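# Builders for small in-code fixtures.

make_records <- function(patient_id, dispense_date, atc_code,
                         medication_name = "DRUG 10MG TABS",
                         birth_date = "1945-03-04", sex = "F",
                         n_packages = 1L, unit_dose_mg = NA_real_) {
  n <- max(length(patient_id), length(dispense_date), length(atc_code))
  medication_name <- rep_len(medication_name, n)
  birth_date <- rep_len(birth_date, n)
  sex <- rep_len(sex, n)
  n_packages <- rep_len(n_packages, n)
  unit_dose_mg <- rep_len(unit_dose_mg, n)
  data.frame(patient_id = patient_id,
             birth_date = as.Date(birth_date),
             sex = sex,
             dispense_date = as.Date(dispense_date),
             atc_code = atc_code,
             medication_name = medication_name,
             n_packages = as.integer(n_packages),
             unit_dose_mg = unit_dose_mg,
             stringsAsFactors = FALSE)
}

# minimal two-rule catalog written/loaded through YAML, for io-level tests
write_mini_catalog <- function(path, duplicate_id = FALSE) {
  writeLines(c(
    "version: mini-1",
    "rules:",
    "  - id: ppi",
    "    category: AVOID",
    "    label: PPI",
    "    atc: [A02BC]",
    "    condition: {type: DURATION_OVER_8_WEEKS}",
    if (duplicate_id) c(
      "  - id: ppi",
      "    category: AVOID",
      "    label: PPI again",
      "    atc: [A02BC]",
      "    condition: {type: ALWAYS}"
    ) else c(
      "  - id: paroxetine",
      "    category: AVOID",
      "    label: Paroxetine",
      "    atc: [N06AB05]",
      "    condition: {type: ALWAYS}"
    ),
    "acb:",
    "  - {atc: N06AB05, score: 3}"
  ), path)
  path
}
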