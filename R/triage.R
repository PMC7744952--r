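#' Ordered triage levels
#'
#' The five emergency levels in increasing severity. The printed tables use
#' variant spellings (`"risk"`, and `"Cold case"` as a synonym of
#' `"Cold State"`); [normalize_triage()] maps them onto the canonical set
#' while [printed_triage()] restores a canonical level to the spelling a
#' given table printed.
#'
#' @return `triage_levels()`: character vector of the five canonical levels.
#' @export
triage_levels <- function() {
  c("Normal", "Cold State", "Sick", "Urgent", "Risk")
}

#' @rdname triage_levels
#' @param x Character vector of printed labels.
#' @return `normalize_triage()`: an ordered factor on the canonical levels.
#' @export
normalize_triage <- function(x) {
  canon <- c("normal" = "Normal", "cold state" = "Cold State",
             "cold case" = "Cold State", "sick" = "Sick",
             "urgent" = "Urgent", "risk" = "Risk")
  key <- tolower(trimws(x))
  bad <- setdiff(unique(key), names(canon))
  if (length(bad)) stop("Unknown triage label(s): ", toString(bad))
  factor(unname(canon[key]), levels = triage_levels(), ordered = TRUE)
}

#' The sixteen symptom combinations
#'
#' Enumerates every yes/no combination of the four text-input symptoms
#' (chest pain, shortness of breath, palpitation, patient at rest). Two
#' printed orderings exist: `"rest_fastest"` counts in binary with chest
#' pain as the most significant bit (FFFF, FFFT, FFTF, ...), the convention
#' of the 580-row outcome table; `"chest_fastest"` flips chest pain first
#' (NNNN, YNNN, NYNN, ...), the convention of the 143-row enumeration table.
#'
#' @param order Bit-order convention, one of `"rest_fastest"`,
#'   `"chest_fastest"`.
#' @return A 16-row tibble with logical columns `chest_pain`,
#'   `short_breath`, `palpitation`, `at_rest`.
#' @export
symptom_grid <- function(order = c("rest_fastest", "chest_fastest")) {
  order <- match.arg(order)
  lv <- c(FALSE, TRUE)
  if (order == "rest_fastest") {
    g <- expand.grid(at_rest = lv, palpitation = lv, short_breath = lv,
                     chest_pain = lv, KEEP.OUT.ATTRS = FALSE)
  } else {
    g <- expand.grid(chest_pain = lv, short_breath = lv, palpitation = lv,
                     at_rest = lv, KEEP.OUT.ATTRS = FALSE)
  }
  tibble::as_tibble(g)[, c("chest_pain", "short_breath", "palpitation",
                           "at_rest")]
}

#' Cross vital blocks with all symptom combinations
#'
#' For each vital block (an SpO2 / high BP / low BP triple) all sixteen
#' symptom vectors are enumerated in the requested bit-order convention,
#' yielding the full-factorial patient grid.
#'
#' @param blocks Data frame with columns `spo2`, `bp_high`, `bp_low` (zero
#'   rows allowed).
#' @param order Bit-order convention passed to [symptom_grid()].
#' @return A tibble with `16 * nrow(blocks)` rows: block columns plus the
#'   four symptom columns.
#' @export
#' @examples
#' enumerate_combinations(tibble::tibble(spo2 = 97, bp_high = 23, bp_low = 12))
enumerate_combinations <- function(blocks,
                                   order = c("rest_fastest", "chest_fastest")) {
  order <- match.arg(order)
  need <- c("spo2", "bp_high", "bp_low")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stop("`blocks` is missing column(s): ", toString(miss))
  if (nrow(blocks) == 0) {
    return(tibble::tibble(spo2 = integer(), bp_high = integer(),
                          bp_low = integer(), chest_pain = logical(),
                          short_breath = logical(), palpitation = logical(),
                          at_rest = logical()))
  }
  grid <- symptom_grid(order)
  blocks <- tibble::as_tibble(blocks)[need]
  dplyr::bind_rows(lapply(seq_len(nrow(blocks)), function(i) {
    dplyr::bind_cols(blocks[rep(i, nrow(grid)), ], grid)
  }))
}

# ---- fixtures ----------------------------------------------------------

#' Load the packaged ground-truth triage tables
#'
#' `triage_fixture("table6")` returns the 580-row, 11-feature outcome table
#' (per-patient vitals, symptoms, ECG feature block and printed triage
#' level); `triage_fixture("table5")` the 143-row symptom-by-vitals
#' enumeration. Both are stored as printed; the loader adds tidy columns:
#' logical symptoms, canonical triage levels, and the disease class implied
#' by each row's ECG feature block. In the enumeration table the printed
#' blood-pressure columns appear in the opposite order to the outcome table;
#' the loader maps them so `bp_high`/`bp_low` always follow the outcome
#' table's convention (e.g. 23/12).
#'
#' @param table `"table6"` or `"table5"`.
#' @return A tibble; printed cells are kept in columns suffixed `_printed`
#'   or with their printed header names.
#' @export
triage_fixture <- function(table = c("table6", "table5")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, ".csv"), package = "triagesim",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (table == "table5") {
    out <- tibble::tibble(
      patient = as.integer(raw[["Patient number"]]),
      chest_pain = raw[["Chest pain"]] == "Y",
      short_breath = raw[["Shortness of Breath"]] == "Y",
      palpitation = raw[["Palpitation."]] == "Y",
      at_rest = raw[["Patient at rest"]] == "Y",
      spo2 = as.integer(raw[["SpO2 Value"]]),
      # printed order is low-first: High column 12 / Low column 23 pairs with
      # the outcome table's (bp_high, bp_low) = (23, 12)
      bp_high = as.integer(raw[["Low Blood Pressure (Bp) Value (mHg)"]]),
      bp_low = as.integer(raw[["High Blood Pressure (Bp) Value (mHg)"]])
    )
    return(out)
  }
  as_sym <- function(x) x %in% c("true", "Y")
  lab <- raw[["ECG Records"]]
  for (i in seq_along(lab)) if (lab[i] == "") lab[i] <- lab[i - 1]
  out <- tibble::tibble(
    p_no = as.integer(raw[["p. no."]]),
    ecg_label = lab,
    spo2 = as.integer(raw[["Spo2"]]),
    bp_high = as.integer(raw[["H. Blood(mHg)"]]),
    bp_low = as.integer(raw[["L. Blood(mHg)"]]),
    chest_pain = as_sym(raw[["Chest Pain"]]),
    short_breath = as_sym(raw[["Short-ness of Breath"]]),
    palpitation = as_sym(raw[["Palpitation."]]),
    at_rest = as_sym(raw[["rest?"]]),
    peaks = raw[["Peaks"]],
    qrs_width = raw[["QRS width"]],
    pp = raw[["Peak to Peak"]],
    st = raw[["ST El."]],
    triage_printed = raw[["Output Triage level"]]
  )
  out$triage <- normalize_triage(out$triage_printed)
  out$ecg_class <- feature_block_class(out$peaks, out$qrs_width)
  out
}

# disease class implied by the printed ECG feature block of a row
feature_block_class <- function(peaks, qrs) {
  dplyr::case_when(
    peaks == "67" & qrs == "0.06" ~ "sleep_apnea",
    peaks == "54" & qrs == "0.5" ~ "arrhythmia_wide",
    peaks == "77" & qrs == "0.047" ~ "arrhythmia_narrow",
    peaks == "64" & qrs == "0.169" ~ "heart_failure",
    peaks == "normal" ~ "normal",
    peaks == "110" ~ "normal_hr110",
    TRUE ~ NA_character_
  )
}

# the 11 printed feature columns, pasted into a single lookup key
feature_cols <- function() {
  c("spo2", "bp_high", "bp_low", "chest_pain", "short_breath", "palpitation",
    "at_rest", "peaks", "qrs_width", "pp", "st")
}

feature_key <- function(df) {
  miss <- setdiff(feature_cols(), names(df))
  if (length(miss)) {
    stop("feature vector is missing field(s): ", toString(miss))
  }
  do.call(paste, c(lapply(df[feature_cols()], as.character), sep = "\r"))
}

# ---- consistency, model induction, classification ----------------------

#' Find label conflicts in a triage table
#'
#' Groups rows sharing an identical 11-feature vector and reports every
#' group whose printed triage labels disagree. An empty result means the
#' table defines a function from feature vectors to levels.
#'
#' @param table A tibble with the 11 feature columns and a `triage` column
#'   (e.g. from [triage_fixture()]).
#' @return A tibble with one row per conflict group: `key`, `rows` (list of
#'   row numbers, `p_no` when available), `labels` (list of the distinct
#'   labels), `n`.
#' @export
check_consistency <- function(table) {
  key <- feature_key(table)
  lab <- as.character(table$triage)
  ids <- if ("p_no" %in% names(table)) table$p_no else seq_len(nrow(table))
  grp <- split(seq_len(nrow(table)), key)
  confl <- purrr::keep(grp, function(ix) length(unique(lab[ix])) > 1)
  keys <- names(confl)
  confl <- unname(confl)
  tibble::tibble(
    key = keys,
    rows = purrr::map(confl, ~ unname(ids[.x])),
    labels = purrr::map(confl, ~ unique(lab[.x])),
    n = purrr::map_int(confl, length)
  )
}

#' Induce the triage decision model from a ground-truth table
#'
#' Builds a deterministic, total classifier as an exact-fit rule list: one
#' rule per distinct 11-feature vector, labelled with that vector's printed
#' level. Conflicting vectors (identical features, differing labels) are
#' resolved by majority vote with ties broken by first printed occurrence
#' (`conflicts = "majority"`), or rejected (`conflicts = "strict"`). Vectors
#' not covered by any rule are routed at prediction time to the nearest rule
#' and flagged as extrapolation.
#'
#' @param table Ground-truth tibble (default the packaged 580-row table).
#' @param conflicts `"majority"` or `"strict"`.
#' @return An object of class `triage_model` with elements `rules`
#'   (tibble of feature columns + `triage`), `conflicts` (from
#'   [check_consistency()]) and `n_train`.
#' @export
#' @examples
#' m <- induce_decision_model()
#' glance(m)
induce_decision_model <- function(table = triage_fixture("table6"),
                                  conflicts = c("majority", "strict")) {
  conflicts <- match.arg(conflicts)
  confl <- check_consistency(table)
  if (conflicts == "strict" && nrow(confl) > 0) {
    stop("irreconcilable label conflicts in ", nrow(confl), " group(s): rows ",
         toString(unlist(confl$rows)))
  }
  key <- feature_key(table)
  lab <- as.character(table$triage)
  rules <- dplyr::bind_rows(lapply(split(seq_len(nrow(table)), key), function(ix) {
    tab <- table(lab[ix])
    winners <- names(tab)[tab == max(tab)]
    pick <- if (length(winners) == 1) winners else
      lab[ix][which(lab[ix] %in% winners)[1]]  # first printed occurrence
    out <- table[ix[1], feature_cols()]
    out$triage <- pick
    out
  }))
  rules$triage <- factor(rules$triage, levels = triage_levels(), ordered = TRUE)
  structure(
    list(rules = tibble::as_tibble(rules), conflicts = confl,
         n_train = nrow(table)),
    class = "triage_model"
  )
}

#' Classify patient feature vectors
#'
#' Looks each 11-feature vector up in the model's rule list. Vectors with no
#' exact rule are matched to the nearest rule (fewest disagreeing feature
#' fields, earliest rule on ties) and flagged `extrapolated`.
#'
#' @param features Data frame with the 11 feature columns (see
#'   [triage_fixture()] for the encoding: printed strings for `peaks`,
#'   `qrs_width`, `pp`, `st`).
#' @param model A [induce_decision_model()] fit.
#' @return `features` plus columns `triage` (ordered factor) and
#'   `extrapolated` (logical).
#' @export
classify <- function(features, model = induce_decision_model()) {
  if (!inherits(model, "triage_model")) stop("`model` must be a `triage_model`.")
  fkey <- feature_key(features)        # errors naming any missing field
  rkey <- feature_key(model$rules)
  hit <- match(fkey, rkey)
  triage <- model$rules$triage[hit]
  extrapolated <- is.na(hit)
  if (any(extrapolated)) {
    rule_mat <- vapply(feature_cols(),
                       function(cc) as.character(model$rules[[cc]]),
                       character(nrow(model$rules)))
    for (i in which(extrapolated)) {
      fv <- vapply(feature_cols(), function(cc) as.character(features[[cc]][i]),
                   character(1))
      dist <- rowSums(rule_mat != matrix(fv, nrow = nrow(rule_mat),
                                         ncol = length(fv), byrow = TRUE))
      triage[i] <- model$rules$triage[which.min(dist)]
    }
  }
  out <- tibble::as_tibble(features)
  out$triage <- triage
  out$extrapolated <- extrapolated
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname induce_decision_model
#' @param x A `triage_model`.
#' @param ... Unused.
#' @method tidy triage_model
#' @export
tidy.triage_model <- function(x, ...) x$rules

#' @rdname induce_decision_model
#' @method glance triage_model
#' @export
glance.triage_model <- function(x, ...) {
  tibble::tibble(
    n_rules = nrow(x$rules),
    n_train = x$n_train,
    n_conflict_groups = nrow(x$conflicts),
    n_conflict_rows = sum(x$conflicts$n)
  )
}

#' @export
print.triage_model <- function(x, ...) {
  cat("Triage rule-list model:", nrow(x$rules), "rules from", x$n_train,
      "rows;", nrow(x$conflicts), "conflict group(s)\n")
  invisible(x)
}

#' Audit symptom monotonicity of a triage table
#'
#' For every rule-covered vector, flips each single symptom from no to yes
#' and, when the flipped vector is also covered, checks that the triage
#' level did not decrease. Violations are reported, not enforced: the
#' ground-truth table is canonical even where it is non-monotone.
#'
#' @param table Ground-truth tibble (default the packaged 580-row table).
#' @return A tibble of violations: the origin row id, the flipped symptom,
#'   and the two levels.
#' @export
audit_monotonicity <- function(table = triage_fixture("table6")) {
  model <- induce_decision_model(table)
  rules <- model$rules
  rkey <- feature_key(rules)
  syms <- c("chest_pain", "short_breath", "palpitation", "at_rest")
  res <- list()
  for (i in seq_len(nrow(rules))) {
    for (sy in syms) {
      if (isTRUE(rules[[sy]][i])) next
      flipped <- rules[i, ]
      flipped[[sy]] <- TRUE
      j <- match(feature_key(flipped), rkey)
      if (!is.na(j) && rules$triage[j] < rules$triage[i]) {
        res[[length(res) + 1]] <- tibble::tibble(
          rule = i, symptom = sy,
          level_before = as.character(rules$triage[i]),
          level_after = as.character(rules$triage[j])
        )
      }
    }
  }
  if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(rule = integer(), symptom = character(),
                   level_before = character(), level_after = character())
}
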