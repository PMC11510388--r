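#' Synthetic cohort configuration
#'
#' Defaults emulate the study cohort structure this pipeline targets:
#' 70 cases and 70 matched controls, 80/20 male/female, ages 3-17 years
#' (mean 6.91, SD 3.17), ADOS-2 CSS centred near 7 on the 1-10 scale,
#' three-band CBCL t-scores, IQ/DQ mean 63 (SD 20), 300 ASVs under a
#' hierarchical taxonomy, per-sample compositions drawn from a Dirichlet
#' around a log-normal ranked base composition, and sequencing depths
#' from a negative binomial floored at 1000 reads.
#'
#' @param n_cases,n_controls cohort sizes (default 70 each).
#' @param male_fraction fraction of male cases (default 0.8; allocated
#'   exactly, e.g. 56/14 at n = 70).
#' @param age_range years, default `c(3, 17)`.
#' @param age_mean,age_sd age distribution before truncation (6.91, 3.17).
#' @param n_asv number of ASVs (default 300).
#' @param depth_mean,depth_dispersion negative-binomial depth model
#'   (default mean 20000, size 10); depths are floored at `depth_floor`.
#' @param depth_floor minimum depth (default 1000, the QC floor).
#' @param base_concentration Dirichlet precision around the base
#'   composition (default 50; smaller = noisier compositions).
#' @param planted_effects data.frame with columns `taxon` (a feature id),
#'   `variable` (stratification variable), `subgroup` (label receiving
#'   the effect) and `logfold` (natural-log fold change); NULL = none.
#' @param css_mean,css_sd CSS distribution (7.0, 1.5), discretized and
#'   truncated to 1-10.
#' @param cbcl_means,cbcl_sds named per-scale t-score means/SDs, chosen
#'   so all three bands are populated.
#' @param iq_mean,iq_sd IQ/DQ distribution (63, 20).
#' @param missing_css,missing_cbcl,missing_iq missing-score counts per 70
#'   subjects (defaults 5, 9, 1), scaled proportionally to `n_cases`.
#' @param seed integer seed; generation is fully reproducible.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 70L, n_controls = 70L, male_fraction = 0.8,
                         age_range = c(3, 17), age_mean = 6.91, age_sd = 3.17,
                         n_asv = 300L, depth_mean = 20000, depth_dispersion = 10,
                         depth_floor = 1000, base_concentration = 50,
                         planted_effects = NULL,
                         css_mean = 7.0, css_sd = 1.5,
                         cbcl_means = c(cbcl_int = 65, cbcl_ext = 59, cbcl_tot = 64),
                         cbcl_sds = c(cbcl_int = 8, cbcl_ext = 8, cbcl_tot = 9),
                         iq_mean = 63, iq_sd = 20,
                         missing_css = 5L, missing_cbcl = 9L, missing_iq = 1L,
                         seed = 1L) {
  stopifnot(male_fraction >= 0, male_fraction <= 1, n_asv >= 1,
            depth_floor > 0, base_concentration > 0)
  if (!is.null(planted_effects)) {
    stopifnot(all(c("taxon", "variable", "subgroup", "logfold") %in%
                    names(planted_effects)),
              all(is.finite(planted_effects$logfold)),
              nrow(planted_effects) <= n_asv)
  }
  structure(as.list(environment()), class = "synth_config")
}

# hierarchical taxonomy with Greengenes2-style suffixed names
make_taxonomy <- function(n_asv) {
  n_phy <- 8L
  suffix <- function(id) {
    # deterministic pseudo-suffix on ~1/4 of names to exercise name handling
    h <- sum(utf8ToInt(id))
    if (h %% 4L == 0L) paste0("_", LETTERS[1L + h %% 3L]) else ""
  }
  phy <- sample.int(n_phy, n_asv, replace = TRUE,
                    prob = exp(-0.4 * seq_len(n_phy)))
  cls <- paste0(phy, ".", sample.int(2L, n_asv, replace = TRUE))
  ord <- paste0(cls, ".", sample.int(2L, n_asv, replace = TRUE))
  fam <- paste0(ord, ".", sample.int(3L, n_asv, replace = TRUE))
  gen <- paste0(fam, ".", sample.int(3L, n_asv, replace = TRUE))
  spc <- paste0(gen, ".", sample.int(2L, n_asv, replace = TRUE))
  nm <- function(prefix, path) {
    ids <- paste0(prefix, gsub(".", "", path, fixed = TRUE))
    vapply(ids, function(i) paste0(i, suffix(i)), character(1L),
           USE.NAMES = FALSE)
  }
  data.frame(feature_id = sprintf("ASV%04d", seq_len(n_asv)),
             domain = "Bacteria",
             phylum = nm("Phy", as.character(phy)),
             class = nm("Cls", cls), order = nm("Ord", ord),
             family = nm("Fam", fam), genus = nm("Gen", gen),
             species = nm("Sp", spc), stringsAsFactors = FALSE)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

sample_clinical <- function(cfg, ids) {
  n <- length(ids)
  n_male <- round(cfg$male_fraction * n)
  gender <- sample(c(rep("male", n_male), rep("female", n - n_male)))
  age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd,
                     cfg$age_range[1L], cfg$age_range[2L])
  css <- pmin(10, pmax(1, round(stats::rnorm(n, cfg$css_mean, cfg$css_sd))))
  cbcl <- lapply(names(cfg$cbcl_means), function(s)
    pmax(30, round(stats::rnorm(n, cfg$cbcl_means[[s]], cfg$cbcl_sds[[s]]))))
  names(cbcl) <- names(cfg$cbcl_means)
  iq <- pmax(20, round(stats::rnorm(n, cfg$iq_mean, cfg$iq_sd)))
  miss <- function(x, k70) {
    k <- round(k70 * n / 70)
    if (k > 0) x[sample.int(n, k)] <- NA
    x
  }
  out <- data.frame(subject_id = ids, age = round(age, 1), gender = gender,
                    css = miss(css, cfg$missing_css),
                    cbcl_int = miss(cbcl$cbcl_int, cfg$missing_cbcl),
                    cbcl_ext = miss(cbcl$cbcl_ext, cfg$missing_cbcl),
                    cbcl_tot = miss(cbcl$cbcl_tot, cfg$missing_cbcl),
                    iq_dq = miss(iq, cfg$missing_iq),
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Pick default planted biomarker taxa
#'
#' Chooses `n` taxa from the mid-abundance band of a base composition
#' (relative abundance between `band[1]` and `band[2]`, most abundant
#' first). The band balances two constraints: a fold change planted on a
#' taxon below the pipeline's own 1% abundance filter is removed before
#' any test sees it, while planting on the dominant taxa moves so much
#' mass that compositional renormalization induces a visible shift on
#' every other feature. Falls back to the most abundant taxa when the
#' band holds fewer than `n`.
#'
#' @param base named base composition over features.
#' @param n number of taxa (default 5).
#' @param variable,subgroup stratification variable and label carrying
#'   the effect (defaults CSS / severe).
#' @param logfold natural-log fold change (default 1.5).
#' @param band relative-abundance band, default 0.5% to 3%.
#' @return planted-effects data.frame for [synth_config()].
#' @export
default_planted_effects <- function(base, n = 5L, variable = "CSS",
                                    subgroup = "severe", logfold = 1.5,
                                    band = c(0.005, 0.03)) {
  ord <- sort(base, decreasing = TRUE)
  pool <- names(ord)[ord >= band[1L] & ord <= band[2L]]
  if (length(pool) < n) pool <- names(ord)
  data.frame(taxon = pool[seq_len(n)], variable = variable,
             subgroup = subgroup, logfold = logfold,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic case/control cohort
#'
#' Draws a hierarchical taxonomy, a log-normal ranked base composition,
#' per-sample Dirichlet compositions with subgroup-specific log-fold
#' perturbations on planted taxa, multinomial counts at negative-binomial
#' depths (floored at the QC minimum), and clinical scores whose subgroup
#' labels are derived through the cohort module, so labels and scores are
#' consistent by construction. Fully reproducible for a fixed seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `case` and `control` (counts `feature_table`s),
#'   `taxonomy`, `clinical` (cases) and `truth` (planted effects, labels,
#'   per-subject expected compositions).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  tax <- make_taxonomy(cfg$n_asv)
  w <- exp(stats::rnorm(cfg$n_asv, 0, 1.5))
  base <- stats::setNames(w / sum(w), tax$feature_id)

  planted <- cfg$planted_effects
  if (!is.null(planted) && !all(planted$taxon %in% tax$feature_id))
    stop("planted taxon not in taxonomy: ",
         paste(setdiff(planted$taxon, tax$feature_id), collapse = ", "))

  case_ids <- sprintf("ASD%03d", seq_len(cfg$n_cases))
  ctrl_ids <- sprintf("CTRL%03d", seq_len(cfg$n_controls))
  clinical <- sample_clinical(cfg, case_ids)
  labels <- stratify_all(clinical)

  expected <- matrix(base, cfg$n_asv, cfg$n_cases,
                     dimnames = list(tax$feature_id, case_ids))
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      lab <- labels[[planted$variable[k]]]
      hit <- names(lab)[!is.na(lab) & lab == planted$subgroup[k]]
      expected[planted$taxon[k], hit] <-
        expected[planted$taxon[k], hit] * exp(planted$logfold[k])
    }
    expected <- sweep(expected, 2L, colSums(expected), "/")
  }

  draw_counts <- function(target, ids) {
    depth <- pmax(cfg$depth_floor,
                  stats::rnbinom(length(ids), mu = cfg$depth_mean,
                                 size = cfg$depth_dispersion))
    m <- vapply(seq_along(ids), function(j) {
      comp <- rdirichlet1(cfg$base_concentration * target[, j])
      stats::rmultinom(1L, depth[j], comp)[, 1L]
    }, numeric(cfg$n_asv))
    dimnames(m) <- list(tax$feature_id, ids)
    feature_table(m, "counts")
  }
  case_tab <- draw_counts(expected, case_ids)
  ctrl_base <- matrix(base, cfg$n_asv, cfg$n_controls,
                      dimnames = list(tax$feature_id, ctrl_ids))
  ctrl_tab <- draw_counts(ctrl_base, ctrl_ids)

  list(case = case_tab, control = ctrl_tab, taxonomy = tax,
       clinical = clinical,
       truth = list(planted = planted, labels = labels,
                    base = base, expected = expected))
}

#' Construct a composition at an exact dysbiosis-index distance
#'
#' Drains mass proportionally from all coordinates into the largest one:
#' with a drain fraction `s`, the result `q` has `q_k = (1 - s) b_k` off
#' the recipient and `q_j = b_j + s (1 - b_j)`, so the quadratic
#' dissimilarity against the base is linear in `s`,
#' \eqn{Z(s) = s \sqrt{0.5 (\sum_{k \ne j} b_k^2 + (1 - b_j)^2)}},
#' and `s` solves exactly for the requested target. The feasible maximum
#' (`s = 1`, everything on the recipient) bounds the target.
#'
#' @param base named composition vector (sums to 1, length >= 2).
#' @param target requested dissimilarity fraction in `[0, 1)`.
#' @param partial if the target exceeds the feasible maximum, return the
#'   closest achievable composition instead of erroring.
#' @return composition vector with `mdi_score(result, base)` equal to
#'   `100 * target` (up to floating point).
#' @export
perturb_for_mdi <- function(base, target, partial = FALSE) {
  stopifnot(length(base) >= 2L, target >= 0, target < 1 || partial)
  if (abs(sum(base) - 1) > 1e-9) stop("base must sum to 1")
  if (target == 0) return(base)
  j <- which.max(base)
  z1 <- sqrt(0.5 * (sum(base[-j]^2) + (1 - base[j])^2))
  s <- target / z1
  if (s > 1) {
    if (!partial)
      stop(sprintf("target %.4g infeasible: maximum attainable is %.4g",
                   target, z1))
    s <- 1
  }
  out <- (1 - s) * base
  out[j] <- base[j] + s * (1 - base[j])
  out
}
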