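#' Score trial logs into FER accuracy
#'
#' Applies the reaction-time exclusion (only trials with RT strictly below
#' the cutoff, default 3 s, enter the analysis), marks a trial correct when
#' the response matches the target-present flag, and computes accuracy per
#' subject and condition.  Trials without a response are excluded, not
#' counted as errors.  By default the denominator is the number of
#' included trials; `denominator = "all"` divides by all trials instead.
#'
#' @param trials data.frame with columns `subject_id`, `condition`
#'   (`"happy"`/`"fearful"`), `set_size`, `target_present` (logical),
#'   `response` (`"target"`/`"no-target"`, `NA` = no keypress) and `rt_ms`.
#' @param rt_max_s Inclusion cutoff in seconds (strict `<`).
#' @param denominator `"included"` (post-filter trials) or `"all"`.
#' @return data.frame with one row per (subject, condition): `subject_id`,
#'   `condition`, `n_total`, `n_included`, `n_correct`, `accuracy`.  When a
#'   condition has zero included trials its accuracy is `NA` and a warning
#'   is emitted.
#' @export
#' @examples
#' log <- data.frame(subject_id = "s1", condition = "fearful",
#'                   set_size = 2, target_present = c(TRUE, TRUE, TRUE, FALSE),
#'                   response = c("target", "target", "target", "target"),
#'                   rt_ms = c(1000, 2900, 3200, 500))
#' score_accuracy(log)$accuracy  # 2/3: one trial too slow, one wrong
score_accuracy <- function(trials, rt_max_s = 3,
                           denominator = c("included", "all")) {
  denominator <- match.arg(denominator)
  need <- c("subject_id", "condition", "set_size", "target_present",
            "response", "rt_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    stop("trial log is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(trials) == 0L) stop("trial log is empty")
  if (any(trials$rt_ms <= 0, na.rm = TRUE)) stop("rt_ms must be positive")
  if (!all(trials$condition %in% c("happy", "fearful")))
    stop("condition must be 'happy' or 'fearful'")
  included <- !is.na(trials$response) & trials$rt_ms < rt_max_s * 1000
  correct <- included &
    (trials$response == ifelse(trials$target_present, "target", "no-target"))
  key <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  agg <- function(v) as.vector(tapply(v, key, sum))
  # tapply orders by factor level; recover each level's subject/condition
  lev_order <- match(levels(key), as.character(key))
  out <- data.frame(subject_id = trials$subject_id[lev_order],
                    condition = trials$condition[lev_order],
                    n_total = agg(rep(1L, nrow(trials))),
                    n_included = agg(as.integer(included)),
                    n_correct = agg(as.integer(correct)),
                    stringsAsFactors = FALSE)
  denom <- if (denominator == "included") out$n_included else out$n_total
  out$accuracy <- ifelse(denom > 0, out$n_correct / denom, NA_real_)
  bad <- which(out$n_included == 0L)
  if (length(bad))
    warning("zero included trials (accuracy undefined) for: ",
            paste(sprintf("%s/%s", out$subject_id[bad], out$condition[bad]),
                  collapse = ", "))
  out[order(out$subject_id, out$condition), , drop = FALSE]
}

#' Group-level descriptive summary of FER accuracy
#'
#' Mean and sample standard deviation (n - 1 denominator) of accuracy per
#' group and condition, formatted as `mean +/- SD`.  Purely descriptive: no
#' inferential statistics.
#'
#' @param results An accuracy table from [score_accuracy()], or any
#'   data.frame with `subject_id`, `condition`, `accuracy`.
#' @param phenotypes Phenotype table with `subject_id` and `group`.
#' @return data.frame with `group`, `condition`, `n`, `mean`, `sd`,
#'   `formatted`.  `sd` is `NA` for a single subject.
#' @export
summarize_groups <- function(results, phenotypes) {
  stopifnot(all(c("subject_id", "condition", "accuracy") %in% names(results)),
            all(c("subject_id", "group") %in% names(phenotypes)))
  m <- merge(results, phenotypes[, c("subject_id", "group")],
             by = "subject_id")
  if (nrow(m) == 0L) stop("no subjects shared between results and phenotypes")
  sp <- split(m, list(m$group, m$condition), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    mu <- mean(d$accuracy, na.rm = TRUE)
    s <- if (sum(!is.na(d$accuracy)) > 1L) sd(d$accuracy, na.rm = TRUE)
         else NA_real_
    data.frame(group = d$group[1], condition = d$condition[1],
               n = nrow(d), mean = mu, sd = s,
               formatted = if (is.na(s)) sprintf("%.2f ± NA", mu) else
                 sprintf("%.2f ± %.2f", mu, s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$group), , drop = FALSE]
}
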