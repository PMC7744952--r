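#' The default triage-dataset design
#'
#' The enumeration design of the 580-patient outcome table, shipped as a
#' declarative JSON file rather than code: the standard nine vital blocks,
#' six dataset segments (disease class, symptom spelling style, factorial or
#' explicit row layout, row count) and the positions at which the printed
#' table labels its class blocks. [build_triage_dataset()] expands it
#' row-for-row.
#'
#' @param path JSON file; default the packaged design.
#' @return A list with elements `vital_blocks`, `symptom_order`, `segments`,
#'   `printed_labels`.
#' @export
default_design <- function(path = system.file("extdata", "table6_design.json",
                                              package = "triagesim",
                                              mustWork = TRUE)) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# printed ECG feature strings for one disease class, derived from its profile
profile_feature_strings <- function(class) {
  if (class == "normal") {
    return(tibble::tibble(peaks = "normal", qrs_width = "", pp = "Regular",
                          st = ""))
  }
  if (class == "normal_hr110") {
    return(tibble::tibble(peaks = "110", qrs_width = "", pp = "Regular",
                          st = ""))
  }
  p <- class_profile(class)$profile
  tibble::tibble(
    peaks = as.character(p$peaks),
    qrs_width = format(p$qrs_width, trim = TRUE, drop0trailing = TRUE),
    pp = p$pp_label,
    st = tolower(as.character(p$st_elevated))
  )
}

expand_segment <- function(seg, vital_blocks) {
  if (identical(seg$layout, "factorial")) {
    blocks <- dplyr::bind_rows(lapply(vital_blocks, tibble::as_tibble))
    rows <- enumerate_combinations(blocks, order = "rest_fastest")
    rows <- rows[seq_len(seg$n_rows), ]
  } else if (identical(seg$layout, "explicit")) {
    rows <- dplyr::bind_rows(lapply(seg$rows, function(r) {
      sy <- strsplit(r$symptoms, "")[[1]] == "Y"
      tibble::tibble(spo2 = r$spo2, bp_high = r$bp_high, bp_low = r$bp_low,
                     chest_pain = sy[1], short_breath = sy[2],
                     palpitation = sy[3], at_rest = sy[4])
    }))
  } else {
    stop("Unknown segment layout: ", seg$layout)
  }
  known <- c(class_profile_table()$name)
  if (!seg$ecg_class %in% known) {
    stop("Segment references unknown ECG class `", seg$ecg_class,
         "`. Known classes: ", toString(known))
  }
  feats <- profile_feature_strings(seg$ecg_class)
  rows <- dplyr::bind_cols(rows, feats[rep(1, nrow(rows)), ])
  rows$ecg_class <- seg$ecg_class
  rows$symptom_style <- seg$symptom_style
  rows
}

#' Build the 580-patient triage dataset
#'
#' Expands the enumeration design into per-patient 11-feature vectors (the
#' ECG feature block of each segment comes from its [class_profile()]
#' targets, which the extractor provably reproduces on noise-free synthetic
#' signals), classifies every vector with the rule-list model, and formats
#' the result in the printed table schema.
#'
#' @param design Design list from [default_design()].
#' @param model A [induce_decision_model()] fit used for the output labels.
#' @return A tibble in the printed 14-column schema (`p. no.`,
#'   `ECG Records`, the 11 feature columns, `Output Triage level`), with the
#'   tidy per-row data in the `"tidy"` attribute.
#' @export
#' @examples
#' tab6 <- build_triage_dataset()
#' nrow(tab6)  # 580
build_triage_dataset <- function(design = default_design(),
                                 model = induce_decision_model()) {
  rows <- dplyr::bind_rows(lapply(design$segments, expand_segment,
                                  vital_blocks = design$vital_blocks))
  rows <- classify(rows, model)
  rows$p_no <- seq_len(nrow(rows))
  labels <- character(nrow(rows))
  for (at in names(design$printed_labels)) {
    labels[as.integer(at)] <- design$printed_labels[[at]]
  }
  sym_fmt <- function(val, style) {
    ifelse(style == "YN", ifelse(val, "Y", "N"), ifelse(val, "true", "false"))
  }
  printed <- tibble::tibble(
    `p. no.` = rows$p_no,
    `ECG Records` = labels,
    Spo2 = as.integer(rows$spo2),
    `H. Blood(mHg)` = as.integer(rows$bp_high),
    `L. Blood(mHg)` = as.integer(rows$bp_low),
    `Chest Pain` = sym_fmt(rows$chest_pain, rows$symptom_style),
    `Short-ness of Breath` = sym_fmt(rows$short_breath, rows$symptom_style),
    `Palpitation.` = sym_fmt(rows$palpitation, rows$symptom_style),
    `rest?` = sym_fmt(rows$at_rest, rows$symptom_style),
    Peaks = rows$peaks,
    `QRS width` = rows$qrs_width,
    `Peak to Peak` = rows$pp,
    `ST El.` = rows$st,
    `Output Triage level` = printed_triage(rows$triage)
  )
  attr(printed, "tidy") <- rows
  printed
}

# canonical level -> the spelling the outcome table prints
printed_triage <- function(x) {
  map <- c("Normal" = "Normal", "Cold State" = "Cold State", "Sick" = "Sick",
           "Urgent" = "Urgent", "Risk" = "risk")
  unname(map[as.character(x)])
}

#' The default enumeration-table design
#'
#' The nine vital blocks of the 143-row enumeration table in printed order,
#' with the blood-pressure pair stored as printed (the printed High/Low
#' columns carry the low value first; see [triage_fixture()]).
#'
#' @return A list with `blocks` (tibble `spo2`, `bp_col1`, `bp_col2`) and
#'   `n_rows` (the printed truncation, 143).
#' @export
enumeration_design <- function() {
  list(
    blocks = tibble::tibble(
      spo2    = c(97L, 92L, 97L, 92L, 97L, 92L, 80L, 80L, 80L),
      bp_col1 = c(12L, 12L, 10L, 10L, 8L, 8L, 8L, 10L, 12L),
      bp_col2 = c(23L, 23L, 15L, 15L, 12L, 12L, 12L, 15L, 23L)
    ),
    n_rows = 143L
  )
}

#' Build the symptom-by-vitals enumeration table
#'
#' Expands the enumeration design with the chest-pain-fastest bit order and
#' truncates to the printed row count, reproducing the 143-row table in its
#' printed 8-column schema.
#'
#' @param design Design list from [enumeration_design()].
#' @return A tibble in the printed schema.
#' @export
#' @examples
#' nrow(build_enumeration_table())  # 143
build_enumeration_table <- function(design = enumeration_design()) {
  blocks <- design$blocks
  if (nrow(blocks) == 0) {
    rows <- enumerate_combinations(
      tibble::tibble(spo2 = integer(), bp_high = integer(),
                     bp_low = integer()), order = "chest_fastest")
    rows$bp_col1 <- integer()
    rows$bp_col2 <- integer()
  } else {
    rows <- dplyr::bind_rows(lapply(seq_len(nrow(blocks)), function(i) {
      r <- enumerate_combinations(
        tibble::tibble(spo2 = blocks$spo2[i], bp_high = blocks$bp_col2[i],
                       bp_low = blocks$bp_col1[i]), order = "chest_fastest")
      r$bp_col1 <- blocks$bp_col1[i]
      r$bp_col2 <- blocks$bp_col2[i]
      r
    }))
  }
  n <- min(design$n_rows %||% nrow(rows), nrow(rows))
  rows <- rows[seq_len(n), ]
  yn <- function(x) ifelse(x, "Y", "N")
  tibble::tibble(
    `Patient number` = seq_len(nrow(rows)),
    `Chest pain` = yn(rows$chest_pain),
    `Shortness of Breath` = yn(rows$short_breath),
    `Palpitation.` = yn(rows$palpitation),
    `Patient at rest` = yn(rows$at_rest),
    `SpO2 Value` = rows$spo2,
    `High Blood Pressure (Bp) Value (mHg)` = rows$bp_col1,
    `Low Blood Pressure (Bp) Value (mHg)` = rows$bp_col2
  )
}

#' Cell-by-cell comparison of a built table against a fixture
#'
#' @param built,fixture Data frames with identical schemas (same column
#'   names in the same order, same row count).
#' @return A tibble of differences (`row`, `column`, `expected`, `got`);
#'   zero rows means the tables agree everywhere.
#' @export
#' @examples
#' f <- build_enumeration_table()
#' nrow(validate_table(f, f))  # 0
validate_table <- function(built, fixture) {
  if (!identical(names(built), names(fixture))) {
    stop("schema mismatch: column names differ (",
         toString(setdiff(names(fixture), names(built))), " missing; ",
         toString(setdiff(names(built), names(fixture))), " extra)")
  }
  if (nrow(built) != nrow(fixture)) {
    stop("schema mismatch: row counts differ (", nrow(built), " vs ",
         nrow(fixture), ")")
  }
  diffs <- list()
  for (cc in names(built)) {
    b <- as.character(built[[cc]])
    f <- as.character(fixture[[cc]])
    ix <- which(b != f | is.na(b) != is.na(f))
    if (length(ix)) {
      diffs[[cc]] <- tibble::tibble(row = ix, column = cc,
                                    expected = f[ix], got = b[ix])
    }
  }
  if (length(diffs)) {
    dplyr::arrange(dplyr::bind_rows(diffs), .data$row, .data$column)
  } else {
    tibble::tibble(row = integer(), column = character(),
                   expected = character(), got = character())
  }
}

#' Read a printed-form fixture CSV as shipped
#'
#' Returns the packaged CSV in its printed schema (all cells as character),
#' the representation [validate_table()] compares against.
#'
#' @param table `"table6"` or `"table5"`.
#' @return A tibble with the printed column headers.
#' @export
fixture_printed <- function(table = c("table6", "table5")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, ".csv"), package = "triagesim",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    colClasses = "character"))
}
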