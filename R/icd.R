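#' The ten ICD-10 chapters under study
#'
#' Returns the definition table of the ten most common ICD-10 chapters in a
#' midlife birth cohort: chapter number, short name, the ICD-10 category
#' range, and the corresponding ICD-9 three-digit category range used for
#' admissions coded before the ICD-10 switch.
#'
#' @return A data.frame with columns `chapter`, `name`, `icd10_from`,
#'   `icd10_to`, `icd9_from`, `icd9_to`.
#' @export
#' @examples
#' icd_chapters()
icd_chapters <- function() {
  data.frame(
    chapter = c(1L, 2L, 4L, 5L, 6L, 9L, 10L, 11L, 13L, 14L),
    name = c(
      "Infectious & parasitic", "Neoplasms",
      "Endocrine, nutritional & metabolic", "Mental & behavioural",
      "Nervous system", "Circulatory system", "Respiratory system",
      "Digestive system", "Musculoskeletal & connective tissue",
      "Genitourinary system"
    ),
    icd10_from = c("A00", "C00", "E00", "F00", "G00",
                   "I00", "J00", "K00", "M00", "N00"),
    icd10_to   = c("B99", "D48", "E90", "F99", "G99",
                   "I99", "J99", "K93", "M99", "N99"),
    icd9_from = c(1L, 140L, 240L, 290L, 320L, 390L, 460L, 520L, 710L, 580L),
    icd9_to   = c(139L, 239L, 279L, 319L, 389L, 459L, 519L, 579L, 739L, 629L),
    stringsAsFactors = FALSE
  )
}

## integer key for an ICD-10 category: letter block * 100 + two digits, so
## that category ranges such as C00-D48 are contiguous integer intervals
icd10_key <- function(code) {
  m <- regexpr("^[A-Z][0-9]{2}", code)
  bad <- m == -1L
  if (any(bad)) {
    stop_parage("malformed ICD-10 code(s): ",
                paste(unique(code[bad]), collapse = ", "))
  }
  cat3 <- regmatches(code, m)
  (match(substr(cat3, 1L, 1L), LETTERS) - 1L) * 100L +
    as.integer(substr(cat3, 2L, 3L))
}

icd9_key <- function(code) {
  m <- regexpr("^[0-9]{3}", code)
  bad <- m == -1L
  if (any(bad)) {
    stop_parage("malformed ICD-9 code(s): ",
                paste(unique(code[bad]), collapse = ", "))
  }
  as.integer(regmatches(code, m))
}

#' Map diagnosis codes to the studied ICD-10 chapters
#'
#' Classifies diagnosis codes into the ten studied chapters using the
#' printed category ranges: ICD-10 codes by their leading letter + two
#' digits, ICD-9 codes by their leading three-digit category.  Codes outside
#' all ten ranges map to `NA` (not studied).
#'
#' @param code_system `"ICD10"` or `"ICD9"`; recycled along `code`.
#' @param code character vector of diagnosis codes (e.g. `"I21"`, `"4109"`).
#' @return Integer vector of chapter numbers (`1, 2, 4, 5, 6, 9, 10, 11,
#'   13, 14`) with `NA` for codes outside the studied chapters.
#' @export
#' @examples
#' map_icd_chapter("ICD10", c("I21", "Z99"))
#' map_icd_chapter("ICD9", "410")
map_icd_chapter <- function(code_system, code) {
  if (length(code) == 0L) return(integer(0))
  code <- toupper(trimws(as.character(code)))
  if (any(!nzchar(code) | is.na(code))) {
    stop_parage("empty or missing diagnosis code")
  }
  code_system <- rep_len(toupper(code_system), length(code))
  if (!all(code_system %in% c("ICD9", "ICD10"))) {
    stop_parage("code_system must be 'ICD9' or 'ICD10'")
  }
  ch <- icd_chapters()
  out <- rep(NA_integer_, length(code))

  i10 <- code_system == "ICD10"
  if (any(i10)) {
    key <- icd10_key(code[i10])
    lo <- icd10_key(ch$icd10_from)
    hi <- icd10_key(ch$icd10_to)
    hit <- outer(key, lo, ">=") & outer(key, hi, "<=")
    idx <- max.col(hit, ties.method = "first")
    idx[rowSums(hit) == 0L] <- NA_integer_
    out[i10] <- ch$chapter[idx]
  }
  i9 <- !i10
  if (any(i9)) {
    key <- icd9_key(code[i9])
    hit <- outer(key, ch$icd9_from, ">=") & outer(key, ch$icd9_to, "<=")
    idx <- max.col(hit, ties.method = "first")
    idx[rowSums(hit) == 0L] <- NA_integer_
    out[i9] <- ch$chapter[idx]
  }
  out
}

## uniform draw of a category code within a chapter's printed range
sample_icd10_code <- function(chapter, n) {
  ch <- icd_chapters()
  row <- match(chapter, ch$chapter)
  key <- sample(icd10_key(ch$icd10_from[row]):icd10_key(ch$icd10_to[row]),
                n, replace = TRUE)
  paste0(LETTERS[key %/% 100L + 1L], sprintf("%02d", key %% 100L))
}

sample_icd9_code <- function(chapter, n) {
  ch <- icd_chapters()
  row <- match(chapter, ch$chapter)
  sprintf("%03d", sample(ch$icd9_from[row]:ch$icd9_to[row], n, replace = TRUE))
}
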