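#' Stratification thresholds
#'
#' Thresholds used to convert neuropsychological scores into clinical
#' subgroups. CBCL t-score bands follow the instrument's convention:
#' below `cbcl_none_below` no clinical symptoms, from `cbcl_none_below`
#' to `cbcl_clinical_at - 1` at risk, at or above `cbcl_clinical_at`
#' clinical symptoms. The ADOS-2 calibrated severity score (CSS, 1-10)
#' splits at `css_severe_at` into mild/moderate vs severe autism, and
#' IQ/DQ below `iq_cidd_below` defines the cognitive impairment /
#' developmental delay (CI/DD) subgroup.
#'
#' @param cbcl_none_below t-score below which symptoms are non-clinical
#'   (default 60).
#' @param cbcl_clinical_at t-score at or above which symptoms are clinical
#'   (default 64).
#' @param css_severe_at CSS at or above which autism is severe (default 8).
#' @param iq_cidd_below IQ/DQ below which a subject is CI/DD (default 70).
#' @return list of class `strat_config`.
#' @export
strat_config <- function(cbcl_none_below = 60, cbcl_clinical_at = 64,
                         css_severe_at = 8, iq_cidd_below = 70) {
  stopifnot(cbcl_none_below > 0, cbcl_clinical_at > cbcl_none_below,
            css_severe_at > 0, iq_cidd_below > 0)
  structure(list(cbcl_none_below = cbcl_none_below,
                 cbcl_clinical_at = cbcl_clinical_at,
                 css_severe_at = css_severe_at,
                 iq_cidd_below = iq_cidd_below),
            class = "strat_config")
}

#' Read a clinical metadata table
#'
#' Reads a delimited table (TSV or CSV, autodetected from the extension)
#' with one row per subject. Column names can be remapped via `dialect`,
#' a named character vector `c(canonical = "file_column")` for the
#' canonical names `subject_id`, `age`, `gender`, `css`, `cbcl_int`,
#' `cbcl_ext`, `cbcl_tot`, `iq_dq`. Unparseable numeric cells become
#' missing; age and gender are required for every subject.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping canonical to
#'   file column names.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path, dialect = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("subject_id", "age", "gender", "css",
                 "cbcl_int", "cbcl_ext", "cbcl_tot", "iq_dq")
  for (nm in names(dialect)) {
    if (!dialect[[nm]] %in% names(df))
      stop("dialect column not in file: ", dialect[[nm]])
    names(df)[names(df) == dialect[[nm]]] <- nm
  }
  names(df) <- tolower(names(df))
  if (!"subject_id" %in% names(df)) stop("no subject_id column")
  if (!all(c("age", "gender") %in% names(df)))
    stop("age and gender columns are required covariates")
  out <- data.frame(subject_id = as.character(df$subject_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$subject_id)) stop("duplicated subject id")
  num <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(df[[col]]))
  }
  out$age <- num("age")
  g <- tolower(trimws(as.character(df$gender)))
  g[g %in% c("m", "male")] <- "male"
  g[g %in% c("f", "female")] <- "female"
  if (!all(g %in% c("male", "female")))
    stop("gender must be male/female")
  out$gender <- g
  if (anyNA(out$age) || any(out$age <= 0))
    stop("every subject needs a positive age")
  out$css <- num("css")
  if (any(!is.na(out$css) & (out$css < 1 | out$css > 10)))
    stop("css out of [1,10]")
  out$cbcl_int <- num("cbcl_int")
  out$cbcl_ext <- num("cbcl_ext")
  out$cbcl_tot <- num("cbcl_tot")
  out$iq_dq <- num("iq_dq")
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Stratify CBCL t-scores into three symptom bands
#'
#' @param t_scores numeric t-scores (NA allowed).
#' @param cfg a [strat_config()].
#' @return factor with levels `no_symptoms`, `at_risk`, `symptoms`;
#'   missing scores give NA, never a default class.
#' @export
stratify_cbcl <- function(t_scores, cfg = strat_config()) {
  if (any(!is.na(t_scores) & t_scores < 0)) stop("negative t-score")
  lab <- ifelse(is.na(t_scores), NA_character_,
         ifelse(t_scores < cfg$cbcl_none_below, "no_symptoms",
         ifelse(t_scores >= cfg$cbcl_clinical_at, "symptoms", "at_risk")))
  factor(lab, levels = c("no_symptoms", "at_risk", "symptoms"))
}

#' Stratify ADOS-2 CSS into mild/moderate vs severe autism
#'
#' @param css numeric CSS in [1, 10] (NA allowed).
#' @param cfg a [strat_config()].
#' @return factor with levels `mild_moderate`, `severe`.
#' @export
stratify_css <- function(css, cfg = strat_config()) {
  if (any(!is.na(css) & (css < 1 | css > 10))) stop("css out of [1,10]")
  lab <- ifelse(is.na(css), NA_character_,
         ifelse(css >= cfg$css_severe_at, "severe", "mild_moderate"))
  factor(lab, levels = c("mild_moderate", "severe"))
}

#' Stratify IQ/DQ into CI/DD vs no CI/DD
#'
#' @param iq numeric IQ/DQ (NA allowed).
#' @param cfg a [strat_config()].
#' @return factor with levels `cidd`, `no_cidd`.
#' @export
stratify_iq <- function(iq, cfg = strat_config()) {
  lab <- ifelse(is.na(iq), NA_character_,
         ifelse(iq < cfg$iq_cidd_below, "cidd", "no_cidd"))
  factor(lab, levels = c("cidd", "no_cidd"))
}

#' Stratify a clinical table on every supported variable
#'
#' @param clinical a `clinical_table`.
#' @param cfg a [strat_config()].
#' @return named list of per-subject label factors (names: CSS, CBCL_INT,
#'   CBCL_EXT, CBCL_TOT, IQ_DQ), each carrying `names()` = subject ids.
#' @export
stratify_all <- function(clinical, cfg = strat_config()) {
  put <- function(f) stats::setNames(f, clinical$subject_id)
  list(CSS = put(stratify_css(clinical$css, cfg)),
       CBCL_INT = put(stratify_cbcl(clinical$cbcl_int, cfg)),
       CBCL_EXT = put(stratify_cbcl(clinical$cbcl_ext, cfg)),
       CBCL_TOT = put(stratify_cbcl(clinical$cbcl_tot, cfg)),
       IQ_DQ = put(stratify_iq(clinical$iq_dq, cfg)))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Subgroup counts and percentages
#'
#' Counts subjects per label and reports integer percentages over the
#' non-missing subjects only (subjects with missing scores drop from the
#' denominator). Percentages are rounded half away from zero.
#'
#' @param labels a factor of subgroup labels (NA = missing score).
#' @return data.frame with columns `label`, `count`, `percent`, plus
#'   attribute `n_scored`.
#' @export
cohort_summary <- function(labels) {
  labels <- as.factor(labels)
  n <- sum(!is.na(labels))
  if (n == 0L) stop("all labels missing")
  counts <- table(labels)
  out <- data.frame(label = names(counts),
                    count = as.integer(counts),
                    percent = as.integer(round_half_away(100 * as.integer(counts) / n)),
                    stringsAsFactors = FALSE)
  attr(out, "n_scored") <- n
  out
}

#' Write subgroup labels in tidy long format
#' @param labels named list as from [stratify_all()].
#' @param path output TSV path.
#' @export
write_labels <- function(labels, path) {
  rows <- do.call(rbind, lapply(names(labels), function(v) {
    data.frame(subject_id = names(labels[[v]]), variable = v,
               label = as.character(labels[[v]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
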