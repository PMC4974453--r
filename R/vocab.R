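#' Categorical vocabularies used by the ward schema
#'
#' The raw admission tables carry several coarse categorical attributes:
#' admission type (5 levels), referral source (49 levels), patient class
#' (21 levels), gender (2 levels). Two further categoricals are derived at
#' ingest time: an 8-level age band and a 4-level "number of wards visited"
#' band (1, 2, 3, 4-or-more). Real hospital extracts use site-specific codes;
#' the labels here are synthetic placeholders with the right cardinalities,
#' and every ingest/feature function takes the vocabulary as an argument so a
#' site can substitute its own code lists.
#'
#' @param n_admission_type Number of admission-type levels (default 5).
#' @return Named list of character vectors: `admission_type`, `referral`,
#'   `patient_class`, `gender`, `age_band`, `wards_visited`.
#' @export
#' @examples
#' lengths(ward_vocab())
ward_vocab <- function(n_admission_type = 5L) {
  list(
    admission_type = sprintf("AT_%02d", seq_len(n_admission_type)),
    referral       = sprintf("REF_%02d", 1:49),
    patient_class  = sprintf("PC_%02d", 1:21),
    gender         = c("F", "M"),
    age_band       = c("AGE_00_14", "AGE_15_29", "AGE_30_44", "AGE_45_59",
                       "AGE_60_69", "AGE_70_79", "AGE_80_89", "AGE_90_PLUS"),
    wards_visited  = c("WV_1", "WV_2", "WV_3", "WV_4_PLUS")
  )
}

# Age in years -> 8-level band.
age_to_band <- function(age, vocab = ward_vocab()) {
  breaks <- c(-Inf, 14, 29, 44, 59, 69, 79, 89, Inf)
  as.character(cut(age, breaks = breaks, labels = vocab$age_band))
}

# Total number of distinct wards touched during the admission (this ward
# included) -> 4-level band, top-coded at 4.
wards_to_band <- function(n_wards, vocab = ward_vocab()) {
  vocab$wards_visited[pmin(pmax(as.integer(n_wards), 1L), 4L)]
}
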