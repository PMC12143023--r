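# Outcome classification from ICD-9 / ICD-10 diagnosis codes.
#
# Cause-specific hospitalization outcomes are defined by category ranges
# (three-character categories; subcodes inherit their category's class).
# External-cause / injury / supplemental codes are not natural-cause
# morbidity and classify to the empty set.

.icd10_ranges <- data.table::data.table(
  label = c(
    rep("respiratory", 16L),
    rep("cardiovascular", 5L),
    "cerebrovascular",
    rep("renal", 5L)
  ),
  letter = c(
    rep("J", 14L), "R", "R",
    rep("I", 5L),
    "I",
    rep("N", 4L), "R"
  ),
  lo = c(
    0L, 12L, 20L, 30L, 31L, 33L, 34L, 38L, 39L, 40L, 80L, 90L, 94L, 96L,
    4L, 9L,
    0L, 5L, 20L, 30L, 70L,
    60L,
    0L, 10L, 15L, 25L, 30L
  ),
  hi = c(
    6L, 18L, 22L, 30L, 31L, 33L, 34L, 38L, 39L, 47L, 86L, 92L, 94L, 99L,
    7L, 9L,
    2L, 16L, 28L, 52L, 79L,
    69L,
    8L, 13L, 23L, 29L, 39L
  )
)

# Alphanumeric categories that fall inside a printed range but not the
# numeric grid: I30-I5A includes category I5A.
.icd10_extra <- data.table::data.table(
  label = "cardiovascular", category = "I5A"
)

.icd9_ranges <- data.table::data.table(
  label = c(
    rep("respiratory", 10L),
    rep("cardiovascular", 4L),
    "cerebrovascular",
    rep("renal", 3L)
  ),
  lo = c(
    460L, 471L, 472L, 477L, 478L, 480L, 490L, 511L, 513L, 786L,
    390L, 401L, 420L, 440L,
    430L,
    580L, 591L, 788L
  ),
  hi = c(
    466L, 471L, 472L, 477L, 478L, 487L, 496L, 511L, 519L, 786L,
    398L, 417L, 429L, 449L,
    438L,
    589L, 599L, 788L
  )
)

.outcome_labels <- c("all_natural", "respiratory", "cardiovascular",
                     "cerebrovascular", "renal")

# Internal, vectorized: logical matrix (n x 5) of outcome membership.
classify_outcome_matrix <- function(codes, versions) {
  codes <- toupper(gsub("[. ]", "", as.character(codes)))
  versions <- as.integer(versions)
  n <- length(codes)
  if (length(versions) == 1L) versions <- rep(versions, n)
  out <- matrix(FALSE, n, 5L, dimnames = list(NULL, .outcome_labels))

  i10 <- versions == 10L
  i9 <- versions == 9L
  bad <- !(i10 | i9)

  # ---- ICD-10: category = letter + two alphanumerics
  if (any(i10)) {
    cat10 <- substr(codes[i10], 1L, 3L)
    ok <- grepl("^[A-Z][0-9][0-9A-Z]$", cat10)
    bad[i10][!ok] <- TRUE
    letter <- substr(cat10, 1L, 1L)
    num <- suppressWarnings(as.integer(substr(cat10, 2L, 3L)))
    # natural-cause chapters: A-R (S/T injury-poisoning, U-Y external/special,
    # Z factors influencing health status)
    natural <- ok & letter >= "A" & letter <= "R"
    m10 <- matrix(FALSE, sum(i10), 5L, dimnames = list(NULL, .outcome_labels))
    m10[, "all_natural"] <- natural
    for (lab in unique(.icd10_ranges$label)) {
      rr <- .icd10_ranges[.icd10_ranges$label == lab, ]
      hit <- rep(FALSE, sum(i10))
      for (k in seq_len(nrow(rr))) {
        hit <- hit | (!is.na(num) & letter == rr$letter[k] &
                        num >= rr$lo[k] & num <= rr$hi[k])
      }
      ex <- .icd10_extra[.icd10_extra$label == lab, ]
      if (nrow(ex)) hit <- hit | cat10 %in% ex$category
      m10[, lab] <- ok & natural & hit
    }
    out[i10, ] <- m10
  }

  # ---- ICD-9: category = leading three digits; V/E codes are supplemental /
  # external cause and never natural-cause morbidity
  if (any(i9)) {
    c9 <- codes[i9]
    ve <- grepl("^[VE][0-9]", c9)
    okn <- grepl("^[0-9]{3}", c9)
    bad[i9][!(ve | okn)] <- TRUE
    num <- suppressWarnings(as.integer(substr(c9, 1L, 3L)))
    natural <- okn & !ve & !is.na(num) & num >= 1L & num <= 799L
    m9 <- matrix(FALSE, sum(i9), 5L, dimnames = list(NULL, .outcome_labels))
    m9[, "all_natural"] <- natural
    for (lab in unique(.icd9_ranges$label)) {
      rr <- .icd9_ranges[.icd9_ranges$label == lab, ]
      hit <- rep(FALSE, sum(i9))
      for (k in seq_len(nrow(rr))) {
        hit <- hit | (!is.na(num) & num >= rr$lo[k] & num <= rr$hi[k])
      }
      m9[, lab] <- natural & hit
    }
    out[i9, ] <- m9
  }

  if (any(bad)) {
    hs_stop("heatsmoke_parse_error", "malformed ICD code(s): %s",
            paste(unique(codes[bad]), collapse = ", "))
  }
  out
}

#' Classify an ICD diagnosis code into hospitalization outcome groups
#'
#' Maps a single ICD-9 or ICD-10 diagnosis code to the set of outcome
#' labels whose category ranges contain it. Natural-cause codes always
#' carry `"all_natural"`; cause-specific labels (`"respiratory"`,
#' `"cardiovascular"`, `"cerebrovascular"`, `"renal"`) are added when the
#' code's three-character category falls in the corresponding range.
#' External-cause, injury/poisoning and supplemental codes return an
#' empty set.
#'
#' Membership is decided on the code's category (e.g. `"J45.9"` classifies
#' like `"J45"`), so subcodes inherit the category's classification.
#'
#' @param icd_code Diagnosis code string (dots allowed, case-insensitive).
#' @param icd_version 9 or 10.
#' @return Character vector of outcome labels (possibly empty).
#' @examples
#' classify_outcome("J45.9", 10)  # all_natural, respiratory
#' classify_outcome("I63", 10)    # all_natural, cerebrovascular
#' classify_outcome("S72", 10)    # character(0): injury
#' @export
classify_outcome <- function(icd_code, icd_version) {
  stopifnot(length(icd_code) == 1L)
  m <- classify_outcome_matrix(icd_code, icd_version)
  .outcome_labels[m[1L, ]]
}

# Internal: enumerate the three-character categories of an outcome, used by
# the synthetic case generator to draw plausible diagnosis codes.
icd_categories <- function(label, icd_version) {
  if (icd_version == 10L) {
    rr <- .icd10_ranges[.icd10_ranges$label == label, ]
    cats <- unlist(lapply(seq_len(nrow(rr)), function(k) {
      sprintf("%s%02d", rr$letter[k], rr$lo[k]:rr$hi[k])
    }))
    c(cats, .icd10_extra$category[.icd10_extra$label == label])
  } else {
    rr <- .icd9_ranges[.icd9_ranges$label == label, ]
    unlist(lapply(seq_len(nrow(rr)), function(k) {
      sprintf("%03d", rr$lo[k]:rr$hi[k])
    }))
  }
}

# Natural-cause categories outside the four cause-specific outcomes, for
# "other natural" synthetic cases.
.other_natural_codes <- list(
  icd10 = c("A09", "C50", "E11", "F32", "G40", "K35", "K80", "L03", "M54"),
  icd9  = c("008", "174", "250", "296", "345", "540", "574", "682", "724")
)
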