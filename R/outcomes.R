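#' Motor progression change score
#'
#' `post - pre` on the UPDRS-III; positive values mean worsening
#' (progression), negative values improvement. `NA` inputs propagate.
#'
#' @param pre,post UPDRS-III scores (vectors recycle as usual).
#' @return numeric change score.
#' @export
progression_score <- function(pre, post) post - pre

#' Percent improvement on the UPDRS-III
#'
#' `100 * (pre - post) / pre`; positive values mean improvement.
#'
#' @param pre,post UPDRS-III scores; `pre` must be > 0 where defined.
#' @return numeric percent change; `NA` where `pre` is 0 or missing.
#' @export
percent_improvement <- function(pre, post) {
  out <- 100 * (pre - post) / pre
  out[!is.na(pre) & pre == 0] <- NA_real_
  out
}

#' Improvement-polarity outcome for a cohort table
#'
#' Normalises both outcome conventions to "higher = clinically better":
#' the negated progression change score for washout-style change
#' outcomes, or the percent improvement for long-term percent-change
#' outcomes.
#'
#' @param cohort `cohort_table`.
#' @param type `"progression"` (improvement = -(post - pre), points) or
#'   `"percent"` (improvement = percent change, %).
#' @return numeric vector aligned with the cohort rows.
#' @export
cohort_improvement <- function(cohort, type = c("progression", "percent")) {
  type <- match.arg(type)
  switch(type,
         progression = -progression_score(cohort$updrs3_pre,
                                          cohort$updrs3_post),
         percent = percent_improvement(cohort$updrs3_pre,
                                       cohort$updrs3_post))
}

#' Levodopa equivalent daily dose
#'
#' Sums `dose * factor` over medication entries using a conversion-factor
#' table. The shipped default follows the standard published conversion
#' scheme (levodopa-equivalent units per mg).
#'
#' @param entries data.frame with columns `drug` and `daily_dose_mg` (an
#'   empty data.frame gives 0).
#' @param factors data.frame with columns `drug` and `factor`; default
#'   [ledd_factors()].
#' @return LEDD in mg.
#' @export
ledd <- function(entries, factors = ledd_factors()) {
  if (nrow(entries) == 0L) return(0)
  i <- match(entries$drug, factors$drug)
  if (anyNA(i))
    stop("unknown drug(s) in LEDD computation: ",
         paste(unique(entries$drug[is.na(i)]), collapse = ", "))
  sum(entries$daily_dose_mg * factors$factor[i])
}

#' Shipped LEDD conversion factor table
#'
#' Read from the package's editable `extdata/ledd_factors.csv`; pass a
#' path to use a custom table.
#'
#' @param path CSV with columns `drug`, `factor`.
#' @return data.frame.
#' @export
ledd_factors <- function(path = system.file("extdata", "ledd_factors.csv",
                                            package = "stimmap")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with asymptotic p-value
#'
#' Average-rank ties; two-sided p from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `rho`, `p`, `n`. `rho` is `NA` when either vector has
#'   zero variance.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Permutation p-value for a Spearman correlation
#'
#' Monte-Carlo p with add-one smoothing:
#' `(1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)` (two-sided default;
#' one-sided uses signed exceedances in the observed direction).
#'
#' @param scores,improvements paired numeric vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for reproducibility (`NULL` = current RNG
#'   state).
#' @param sided `"two"` or `"one"`.
#' @return list: `p`, `rho_obs`, `n_perm`.
#' @export
permutation_p <- function(scores, improvements, n_perm = 999, seed = NULL,
                          sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n_perm < 100) stop("n_perm must be >= 100")
  keep <- !is.na(scores) & !is.na(improvements)
  scores <- scores[keep]; improvements <- improvements[keep]
  if (!is.null(seed)) set.seed(seed)
  rs <- rank(scores)
  ry <- rank(improvements)
  rho_obs <- stats::cor(rs, ry)
  rho_perm <- vapply(seq_len(n_perm), function(b)
    stats::cor(rs, ry[sample.int(length(ry))]), numeric(1))
  exceed <- if (sided == "two") abs(rho_perm) >= abs(rho_obs)
            else if (rho_obs >= 0) rho_perm >= rho_obs
            else rho_perm <= rho_obs
  list(p = (1 + sum(exceed)) / (n_perm + 1), rho_obs = rho_obs,
       n_perm = n_perm)
}

#' Validate model scores against cohort outcomes
#'
#' Joins per-patient model scores to the cohort by `patient_id`,
#' excludes undefined scores (counting them), and reports the Spearman
#' correlation with asymptotic and permutation p-values plus the scatter
#' data.
#'
#' @param scores data.frame with `patient_id`, a score column, and
#'   `defined` (from [sweet_spot_score_cohort()] or
#'   [weighted_fiber_score_cohort()]).
#' @param cohort `cohort_table`.
#' @param outcome_type passed to [cohort_improvement()].
#' @param score_col score column name; auto-detected (`rho` or
#'   `weighted_mean_r`) when `NULL`.
#' @param n_perm,seed,sided permutation-test settings.
#' @param min_n minimum usable sample size (default 5).
#' @return object of class `validation_result`: list with `rho`,
#'   `p_asymptotic`, `p_permutation`, `n_used`, `n_undefined_excluded`,
#'   and `scatter` (patient_id, score, improvement).
#' @export
validate_cohort <- function(scores, cohort, outcome_type = "percent",
                            score_col = NULL, n_perm = 999, seed = NULL,
                            sided = "two", min_n = 5) {
  if (is.null(score_col))
    score_col <- intersect(c("rho", "weighted_mean_r"), names(scores))[1]
  if (is.na(score_col) || !score_col %in% names(scores))
    stop("cannot find a score column in `scores`")
  imp <- data.frame(patient_id = cohort$patient_id,
                    improvement = cohort_improvement(cohort, outcome_type),
                    stringsAsFactors = FALSE)
  m <- merge(scores, imp, by = "patient_id", sort = TRUE)
  s <- m[[score_col]]
  usable <- !is.na(s) & !is.na(m$improvement)
  n_used <- sum(usable)
  n_excl <- nrow(m) - n_used
  if (n_used < min_n)
    stop("sample-size error: only ", n_used,
         " usable score/outcome pairs (need >= ", min_n, ")")
  sp <- spearman_rho(s[usable], m$improvement[usable])
  pp <- permutation_p(s[usable], m$improvement[usable], n_perm = n_perm,
                      seed = seed, sided = sided)
  structure(list(rho = sp$rho, p_asymptotic = sp$p, p_permutation = pp$p,
                 n_used = n_used, n_undefined_excluded = n_excl,
                 scatter = data.frame(patient_id = m$patient_id[usable],
                                      score = s[usable],
                                      improvement = m$improvement[usable],
                                      stringsAsFactors = FALSE)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> Spearman R = %.3f, p = %.4f (asymptotic), p = %.4f (permutation), n = %d (%d undefined excluded)\n",
              x$rho, x$p_asymptotic, x$p_permutation, x$n_used,
              x$n_undefined_excluded))
  invisible(x)
}

#' Partition a cohort into top responders and the rest
#'
#' Top responders are patients whose progression change score
#' (`post - pre`) is at or below the threshold. Also reports each
#' patient's Euclidean distance (mm) from the mirrored active contact to
#' a reference coordinate (typically the sweet-spot peak), and per-group
#' means of progression, LEDD change, and stimulation amplitude.
#'
#' @param cohort `cohort_table`.
#' @param contacts `electrode_stims` aligned by `patient_id` (mirror to
#'   one hemisphere first).
#' @param threshold progression-score cut (points).
#' @param reference_mm length-3 mm coordinate.
#' @return list: `patients` (per-patient table with `group` and
#'   `distance_mm`), `group_stats` (per-group means; groups with no
#'   members are absent).
#' @export
responder_partition <- function(cohort, contacts, threshold, reference_mm) {
  m <- merge(as.data.frame(cohort), as.data.frame(contacts),
             by = "patient_id", sort = TRUE)
  prog <- progression_score(m$updrs3_pre, m$updrs3_post)
  dist <- sqrt((m$contact_x - reference_mm[1])^2 +
               (m$contact_y - reference_mm[2])^2 +
               (m$contact_z - reference_mm[3])^2)
  grp <- ifelse(prog <= threshold, "top", "remaining")
  pat <- data.frame(patient_id = m$patient_id, progression = prog,
                    ledd_change = m$ledd_post - m$ledd_pre,
                    amplitude = m$amplitude, distance_mm = dist,
                    group = grp, stringsAsFactors = FALSE)
  gs <- do.call(rbind, lapply(split(pat, pat$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               mean_progression = mean(g$progression, na.rm = TRUE),
               mean_ledd_change = mean(g$ledd_change, na.rm = TRUE),
               mean_amplitude = mean(g$amplitude, na.rm = TRUE),
               mean_distance_mm = mean(g$distance_mm, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(gs) <- NULL
  list(patients = pat, group_stats = gs)
}

#' Sweep the responder threshold
#'
#' Repeats [responder_partition()] over a grid of thresholds and
#' tabulates group sizes, mean contact-to-reference distances, and mean
#' outcomes per group.
#'
#' @inheritParams responder_partition
#' @param thresholds numeric vector of >= 2 progression-score cuts.
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(cohort, contacts, thresholds, reference_mm) {
  if (length(thresholds) < 2L) stop("need at least 2 thresholds")
  do.call(rbind, lapply(sort(thresholds), function(th) {
    p <- responder_partition(cohort, contacts, th, reference_mm)$patients
    top <- p[p$group == "top", ]
    rem <- p[p$group == "remaining", ]
    data.frame(threshold = th, n_top = nrow(top), n_remaining = nrow(rem),
               mean_distance_top = if (nrow(top)) mean(top$distance_mm)
                                   else NA_real_,
               mean_distance_remaining = if (nrow(rem)) mean(rem$distance_mm)
                                         else NA_real_,
               mean_progression_top = if (nrow(top)) mean(top$progression)
                                      else NA_real_,
               mean_progression_remaining = if (nrow(rem))
                 mean(rem$progression) else NA_real_)
  }))
}
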