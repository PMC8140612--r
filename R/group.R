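# Group-level (second-level) statistics: linear mixed-effects models on
# per-subject response estimates, with subject as a random intercept.
# Fixed effects are tested with Wald z statistics; a degenerate
# random-effect variance falls back to an ordinary linear model.

#' Build a subject estimate table
#'
#' Canonical long format consumed by all second-level models: one row
#' per (subject, roi, condition, chroma) estimate in uM, tagged with the
#' `source` analysis that produced it.
#'
#' @param subject,roi,condition,chroma,estimate vectors of equal length.
#' @param source label of the producing analysis (e.g. `"averaging"`,
#'   `"glm_none"`, `"glm_corrected"`).
#' @return data.frame of class `subject_estimates`.
#' @export
subject_estimates <- function(subject, roi, condition, chroma, estimate,
                              source = "glm_corrected") {
  d <- data.frame(subject = factor(subject), roi = as.character(roi),
                  condition = as.character(condition),
                  chroma = as.character(chroma),
                  estimate = as.numeric(estimate),
                  source = source, stringsAsFactors = FALSE)
  if (any(!is.finite(d$estimate))) stop("estimates must be finite")
  if (anyDuplicated(d[c("subject", "roi", "condition", "chroma", "source")]))
    stop("duplicate (subject, roi, condition, chroma, source) rows")
  class(d) <- c("subject_estimates", class(d))
  d
}

# Mixed model with Wald tests on fixed effects. The reference
# distribution is t with (subjects - fixed effects) degrees of freedom,
# which keeps small-cohort tests close to nominal where a plain normal
# reference is anticonservative. A degenerate or failed random-intercept
# fit falls back to ordinary least squares with a logged note.
wald_lmm <- function(formula, data, fallback_formula) {
  n_subj <- length(unique(data$subject))
  cf <- tryCatch(suppressMessages(suppressWarnings({
    fit <- lme4::lmer(formula, data = data, REML = TRUE)
    if (lme4::isSingular(fit, tol = 1e-6)) NULL
    else {
      co <- summary(fit)$coefficients
      if (any(!is.finite(co[, "Std. Error"]))) NULL else co
    }
  })), error = function(e) NULL)
  if (is.null(cf)) {
    message("random-intercept variance degenerate; using ordinary ",
            "least squares")
    cf <- suppressWarnings(
      summary(stats::lm(fallback_formula, data = data))$coefficients)
  }
  est <- cf[, 1]
  se <- cf[, 2]
  z <- est / se
  df <- max(n_subj - nrow(cf), 1)
  data.frame(term = rownames(cf), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pt(-abs(z), df)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-means summary model
#'
#' Fits `estimate ~ -1 + condition:roi:chroma + (1 | subject)`: one fixed
#' effect per (condition, ROI, chromophore) cell with a subject random
#' intercept. Wald z tests ask, per cell, whether a response is present.
#'
#' @param table a [subject_estimates()] table (single source).
#' @return data.frame: `condition`, `roi`, `chroma`, `estimate`, `se`,
#'   `z`, `p`.
#' @export
summary_model <- function(table) {
  if (length(unique(table$subject)) < 2)
    stop("summary model needs at least 2 subjects")
  cells <- with(table, table(condition, roi, chroma))
  if (any(cells == 0))
    warning("missing cells: ",
            paste(utils::head(which(cells == 0), 10), collapse = ", "))
  d <- table
  d$cell <- interaction(d$condition, d$roi, d$chroma, sep = ":")
  res <- wald_lmm(estimate ~ 0 + cell + (1 | subject), d,
                  estimate ~ 0 + cell)
  parts <- strsplit(sub("^cell", "", res$term), ":", fixed = TRUE)
  res$condition <- vapply(parts, `[`, "", 1)
  res$roi <- vapply(parts, `[`, "", 2)
  res$chroma <- vapply(parts, `[`, "", 3)
  res[, c("condition", "roi", "chroma", "estimate", "se", "z", "p")]
}

#' Speech-versus-noise condition contrast
#'
#' Fits `estimate ~ condition + (1 | subject)` on the STG rows,
#' separately per chromophore, and reports the speech - noise fixed
#' effect with its Wald p value.
#'
#' @param table a [subject_estimates()] table containing speech and
#'   noise rows over the STG ROIs (both hemispheres are used as one
#'   region).
#' @param rois ROIs to include (default both STG).
#' @return data.frame: `chroma`, `delta` (uM, speech - noise), `se`, `p`.
#' @export
condition_contrast <- function(table,
                               rois = c("left_STG", "right_STG")) {
  d <- table[table$roi %in% rois &
               table$condition %in% c("speech", "noise"), ]
  if (!all(c("speech", "noise") %in% d$condition))
    stop("need both speech and noise rows")
  out <- list()
  for (tag in unique(d$chroma)) {
    di <- d[d$chroma == tag, ]
    di$condition <- factor(di$condition, levels = c("noise", "speech"))
    res <- wald_lmm(estimate ~ condition + (1 | subject), di,
                    estimate ~ condition)
    row <- res[res$term == "conditionspeech", ]
    out[[tag]] <- data.frame(chroma = tag, delta = row$estimate,
                             se = row$se, p = row$p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Left-versus-right lateralization contrast
#'
#' Fits `estimate ~ roi + (1 | subject)` on the speech rows of the two
#' STG ROIs, separately per chromophore: the fixed effect is the right
#' minus left hemisphere difference.
#'
#' @param table a [subject_estimates()] table with speech rows in both
#'   STG ROIs.
#' @param condition condition to test (default `"speech"`).
#' @return data.frame: `chroma`, `delta` (uM, right - left), `se`, `p`.
#' @export
lateralization_contrast <- function(table, condition = "speech") {
  d <- table[table$condition == condition &
               table$roi %in% c("left_STG", "right_STG"), ]
  if (!all(c("left_STG", "right_STG") %in% d$roi))
    stop("need both hemispheres")
  out <- list()
  for (tag in unique(d$chroma)) {
    di <- d[d$chroma == tag, ]
    di$roi <- factor(di$roi, levels = c("left_STG", "right_STG"))
    res <- wald_lmm(estimate ~ roi + (1 | subject), di,
                    estimate ~ roi)
    row <- res[res$term == "roiright_STG", ]
    out[[tag]] <- data.frame(chroma = tag, delta = row$estimate,
                             se = row$se, p = row$p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cross-method agreement report
#'
#' Computes the condition and lateralization contrasts for each source
#' table and flags whether every source reaches the same conclusion
#' (same effect sign and same significance status at `alpha`) as the
#' first source.
#'
#' @param tables named list of [subject_estimates()] tables (e.g.
#'   `averaging`, `glm_corrected`).
#' @param alpha significance level for the concordance flags
#'   (default 0.05; no multiplicity correction is applied).
#' @return data.frame: `question`, `source`, `chroma`, `delta`, `p`,
#'   `significant`, `concordant`.
#' @export
agreement_report <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  rows <- list()
  for (q in c("condition", "lateralization")) {
    for (src in names(tables)) {
      ct <- if (q == "condition") condition_contrast(tables[[src]])
            else lateralization_contrast(tables[[src]])
      ct$question <- q
      ct$source <- src
      rows[[paste(q, src)]] <- ct
    }
  }
  rep_ <- do.call(rbind, c(rows, make.row.names = FALSE))
  rep_$significant <- rep_$p < alpha
  rep_$concordant <- NA
  for (q in unique(rep_$question)) for (tag in unique(rep_$chroma)) {
    sel <- rep_$question == q & rep_$chroma == tag
    if (!any(sel)) next
    ref <- rep_[sel, ][1, ]
    rep_$concordant[sel] <-
      (sign(rep_$delta[sel]) == sign(ref$delta) |
         (!rep_$significant[sel] & !ref$significant)) &
      rep_$significant[sel] == ref$significant
  }
  rep_[, c("question", "source", "chroma", "delta", "p",
           "significant", "concordant")]
}
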