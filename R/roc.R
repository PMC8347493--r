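# ROC/AUC machinery, DeLong comparison of correlated AUCs, sensitivity at
# fixed specificity, dependent-correlation comparison and the
# case-classification rule set.

# Internal: validate scores/labels, return list(cases, controls) of scores.
split_classes <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("both classes must be present (positive = '", positive, "')",
         call. = FALSE)
  }
  list(cases = scores[pos], controls = scores[!pos])
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with half credit for ties — identical to the trapezoidal area
#' under the empirical ROC curve. Computed with midranks, so it is exact
#' for any tie pattern. Scores are oriented larger = more glaucomatous.
#'
#' @param scores Numeric vector.
#' @param labels Vector of class labels.
#' @param positive Label of the disease class; default `"glaucoma"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = "glaucoma") {
  s <- split_classes(scores, labels, positive)
  n1 <- length(s$cases); n0 <- length(s$controls)
  r <- rank(c(s$cases, s$controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Internal: DeLong structural components. Midrank identity: for case i,
# V10_i = mean_j [I(x_i > y_j) + 0.5 I(x_i = y_j)], computed in O(n log n).
delong_components <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  all <- c(cases, controls)
  r_all <- rank(all)
  v10 <- (r_all[seq_len(m)] - rank(cases)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(controls)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance/covariance machinery for one or two markers
#'
#' Nonparametric comparison of the AUCs of two markers measured on the same
#' eyes, using the structural-components covariance estimator: the
#' placement values of each case among the controls (and vice versa) give
#' an asymptotically normal estimate of `AUC_A - AUC_B` and its standard
#' error; the two-sided p-value comes from the normal approximation. When
#' the two score vectors induce identical rankings the difference is 0 and
#' p = 1 by construction.
#'
#' @param scores_a,scores_b Paired score vectors on the same eyes.
#' @param labels Class labels (same length).
#' @param positive Disease class label; default `"glaucoma"`.
#' @return A tibble of class `delong_comparison`: `auc_a`, `auc_b`, `diff`,
#'   `se_diff`, `z`, `p_value`, `n_cases`, `n_controls`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "glaucoma") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must be paired (same length)",
         call. = FALSE)
  }
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]; labels <- labels[ok]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  ca <- delong_components(scores_a[pos], scores_a[!pos])
  cb <- delong_components(scores_b[pos], scores_b[!pos])
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  se <- sqrt(max(var_diff, 0))
  if (d == 0 || se == 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / se
  }
  p <- if (d == 0) 1 else 2 * pnorm(-abs(z))
  out <- tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, diff = d,
                        se_diff = se, z = z, p_value = p,
                        n_cases = m, n_controls = n)
  class(out) <- c("delong_comparison", class(out))
  out
}

#' DeLong standard error of a single AUC
#'
#' @inheritParams roc_auc
#' @return Named vector `c(auc =, se =)`.
#' @export
delong_se <- function(scores, labels, positive = "glaucoma") {
  s <- split_classes(scores, labels, positive)
  cc <- delong_components(s$cases, s$controls)
  se <- sqrt(var(cc$v10) / length(s$cases) + var(cc$v01) / length(s$controls))
  c(auc = cc$auc, se = se)
}

#' Sensitivity at fixed specificity
#'
#' The decision threshold is the most permissive cut (smallest value) whose
#' empirical specificity among the controls reaches at least `spec`, with
#' no interpolation; the returned sensitivity is the fraction of cases
#' strictly beyond that cut. Conservative and exactly reproducible.
#'
#' @inheritParams roc_auc
#' @param spec Target specificity in (0, 1), e.g. 0.95 or 0.99.
#' @return Sensitivity in \[0, 1\], with attribute `threshold`.
#' @export
sensitivity_at_specificity <- function(scores, labels, spec,
                                       positive = "glaucoma") {
  if (spec <= 0 || spec >= 1) stop("spec must be in (0, 1)", call. = FALSE)
  s <- split_classes(scores, labels, positive)
  if (length(s$controls) < 20) {
    warning("fewer than 20 controls: the empirical threshold is unstable",
            call. = FALSE)
  }
  cuts <- sort(unique(s$controls))
  spec_at <- vapply(cuts, function(t) mean(s$controls <= t), numeric(1))
  ok <- which(spec_at >= spec)
  thr <- cuts[ok[1]]                 # smallest (most permissive) passing cut
  sens <- mean(s$cases > thr)
  structure(sens, threshold = thr)
}

#' Combine indices into a z-mean score
#'
#' z-normalizes each listed index against the normal cohort (sign-aligned
#' so larger = more glaucomatous; see [z_normalize()]) and averages them.
#' This is how heterogeneous indices — GDF, TCV, PSDr, OCT measurements —
#' are fused before ROC analysis.
#'
#' @param data Cohort data frame (one row per eye).
#' @param indices Character vector of index columns to combine.
#' @param stats A [reference_cohort_stats()] covering those indices.
#' @param na_policy `"omit"` (default): a record's missing indices are
#'   dropped from its mean; `"strict"`: any missing index gives `NA`.
#' @return `data` with an added `combined_z` column (tibble).
#' @export
combine_indices <- function(data, indices, stats, na_policy = c("omit",
                                                                "strict")) {
  na_policy <- match.arg(na_policy)
  data <- tibble::as_tibble(data)
  indices <- unique(indices)
  zs <- purrr::map(indices, ~z_normalize(data[[.x]], .x, stats)) |>
    rlang::set_names(indices) |> tibble::as_tibble()
  zmat <- as.matrix(zs)
  combined <- rowMeans(zmat, na.rm = na_policy == "omit")
  combined[!is.finite(combined)] <- NA_real_
  dplyr::mutate(data, combined_z = combined)
}

#' ROC analysis of cohort indices
#'
#' Per-index (and optional combination) AUC with DeLong SE, a normal
#' approximation 95% CI clipped to \[0, 1\], and sensitivities at 95% and
#' 99% specificity. Indices are z-normalized against the named normal group
#' first so every score is oriented larger = more glaucomatous.
#'
#' @param data Cohort tibble with a group column and index columns.
#' @param indices Character vector of index columns to evaluate singly.
#' @param combinations Optional list of character vectors, each a set of
#'   indices fused by [combine_indices()] (named entries name the rows).
#' @param group_col Name of the group column; default `"group"`.
#' @param normal Label of the normal group; default `"normal"`.
#' @param case_groups Labels counted as disease; default all non-normal
#'   groups (restrict to `"confirmed"` or `"suspect"` to reproduce
#'   separate-group analyses).
#' @param stats Optional [reference_cohort_stats()]; computed from the
#'   normal group when `NULL`.
#' @return Tibble of class `onhe_roc`: one row per index/combination with
#'   `index`, `auc`, `se`, `ci_lo`, `ci_hi`, `sens95`, `sens99`,
#'   `n_cases`, `n_controls`.
#' @export
cohort_roc <- function(data, indices, combinations = NULL,
                       group_col = "group", normal = "normal",
                       case_groups = NULL, stats = NULL) {
  data <- tibble::as_tibble(data)
  if (!group_col %in% names(data)) stop("no column '", group_col, "'",
                                        call. = FALSE)
  groups <- data[[group_col]]
  case_groups <- case_groups %||% setdiff(unique(groups), normal)
  keep <- groups == normal | groups %in% case_groups
  data <- data[keep, , drop = FALSE]
  labels <- ifelse(data[[group_col]] == normal, "normal", "glaucoma")
  stats <- stats %||%
    reference_cohort_stats(data[labels == "normal", , drop = FALSE], indices)
  specs <- c(purrr::map(rlang::set_names(indices), identity),
             combinations %||% list())
  if (is.null(names(specs)) || any(names(specs) == "")) {
    nm <- names(specs) %||% rep("", length(specs))
    nm[nm == ""] <- vapply(specs[nm == ""], paste, "", collapse = "+")
    names(specs) <- nm
  }
  rows <- purrr::imap(specs, function(ix, nm) {
    scored <- combine_indices(data, ix, stats)
    sc <- scored$combined_z
    ok <- !is.na(sc)
    a <- delong_se(sc[ok], labels[ok])
    s95 <- sensitivity_at_specificity(sc[ok], labels[ok], 0.95)
    s99 <- sensitivity_at_specificity(sc[ok], labels[ok], 0.99)
    tibble::tibble(
      index = nm, auc = a[["auc"]], se = a[["se"]],
      ci_lo = max(0, a[["auc"]] - qnorm(0.975) * a[["se"]]),
      ci_hi = min(1, a[["auc"]] + qnorm(0.975) * a[["se"]]),
      sens95 = as.numeric(s95), sens99 = as.numeric(s99),
      thr95 = attr(s95, "threshold"), thr99 = attr(s99, "threshold"),
      n_cases = sum(labels[ok] == "glaucoma"),
      n_controls = sum(labels[ok] == "normal"))
  })
  out <- purrr::list_rbind(rows)
  attr(out, "scores") <- purrr::map(specs, function(ix) {
    scored <- combine_indices(data, ix, stats)
    tibble::tibble(score = scored$combined_z, label = labels)
  })
  class(out) <- c("onhe_roc", class(out))
  out
}

#' @method tidy onhe_roc
#' @export
tidy.onhe_roc <- function(x, ...) {
  out <- x
  attr(out, "scores") <- NULL
  class(out) <- setdiff(class(out), "onhe_roc")
  out
}

#' @method glance onhe_roc
#' @export
glance.onhe_roc <- function(x, ...) {
  tibble::tibble(n_indices = nrow(x),
                 best_index = x$index[which.max(x$auc)],
                 best_auc = max(x$auc))
}

#' Plot ROC curves of a cohort analysis
#'
#' Empirical ROC curves for every index/combination analysed by
#' [cohort_roc()].
#'
#' @param object An `onhe_roc`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot onhe_roc
#' @export
autoplot.onhe_roc <- function(object, ...) {
  scores <- attr(object, "scores")
  df <- purrr::imap(scores, function(s, nm) {
    s <- s[!is.na(s$score), ]
    cuts <- c(-Inf, sort(unique(s$score)))
    purrr::map(cuts, function(t) {
      tibble::tibble(
        index = nm,
        fpr = mean(s$score[s$label == "normal"] > t),
        tpr = mean(s$score[s$label == "glaucoma"] > t))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$index)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = "ROC curves")
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether `cor(x, y1)` differs from `cor(x, y2)` when y1 and y2 are
#' measured on the same eyes (so the two correlations share the variable x
#' and are themselves correlated). Default: Steiger's modification of the
#' Dunn-Clark z using the Fisher transform and the backtransformed mean
#' correlation. A permutation alternative (randomly swapping y1 and y2
#' within each eye) is available when the normal approximation is in doubt.
#'
#' @param x,y1,y2 Numeric vectors of equal length (complete triples used).
#' @param method `"steiger"` (default) or `"permutation"`.
#' @param n_perm Permutation count; default 2000.
#' @param seed Seed for the permutation method.
#' @return Tibble: `r1`, `r2`, `r12`, `z`, `p_value`, `n`, `method`.
#' @export
compare_dependent_correlations <- function(x, y1, y2,
                                           method = c("steiger", "permutation"),
                                           n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  ok <- complete.cases(x, y1, y2)
  x <- x[ok]; y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete triples", call. = FALSE)
  if (any(c(sd(x), sd(y1), sd(y2)) == 0)) {
    stop("zero variance in x, y1 or y2", call. = FALSE)
  }
  r1 <- cor(x, y1); r2 <- cor(x, y2); r12 <- cor(y1, y2)
  stat <- function(r1, r2, r12, n) {
    if (abs(r1) >= 1 || abs(r2) >= 1) return(sign(abs(r1) - abs(r2)) * Inf)
    rbar <- (r1 + r2) / 2
    f <- min((1 - r12) / (2 * (1 - rbar^2)), 1)
    h <- (1 - f * rbar^2) / (1 - rbar^2)
    (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  if (method == "steiger") {
    z <- stat(r1, r2, r12, n)
    p <- if (r1 == r2) 1 else 2 * pnorm(-abs(z))
  } else {
    if (!is.null(seed)) set.seed(seed)
    obs <- abs(atanh(min(r1, 1 - 1e-15)) - atanh(min(r2, 1 - 1e-15)))
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      swap <- runif(n) < 0.5
      y1b <- ifelse(swap, y2, y1); y2b <- ifelse(swap, y1, y2)
      d <- abs(atanh(min(cor(x, y1b), 1 - 1e-15)) -
                 atanh(min(cor(x, y2b), 1 - 1e-15)))
      if (d >= obs - 1e-12) exceed <- exceed + 1L
    }
    z <- NA_real_
    p <- (exceed + 1) / (n_perm + 1)
  }
  tibble::tibble(r1 = r1, r2 = r2, r12 = r12, z = z, p_value = p, n = n,
                 method = method)
}

#' Classify a case from percentiles, pressure and risk factors
#'
#' Decision rules for the three-way label:
#' * **confirmed** glaucoma: glaucomatous field loss (PSD or MD percentile
#'   < 5 in the normal population) *and* signs of glaucomatous neuropathy
#'   (GDF or rim-area percentile < 5);
#' * otherwise **suspect** when any suspicion criterion holds: IOP above
#'   25 mmHg; IOP between 21 and 25 mmHg with a thin cornea (CCT below
#'   500 um); or IOP above 21 mmHg together with a risk flag
#'   (`"family_history"`, `"dubious_disc"`, `"borderline_field"`);
#' * otherwise **normal**.
#'
#' All percentiles are oriented so that low = abnormal (use
#' [normative_percentile()] on sign-aligned values). If the case is not
#' confirmed and IOP is missing with no risk flags, there is not enough
#' information to separate normal from suspect and the call errors with
#' class `hbdisc_insufficient_data`.
#'
#' @param percentiles Named list/vector with any of `psd`, `md` (visual
#'   field) and `gdf`, `rim_area` (structural); at least one of each group.
#' @param iop Intraocular pressure, mmHg (`NA` if unmeasured).
#' @param cct Central corneal thickness, um (`NA` if unmeasured).
#' @param risk_flags Character vector of risk flags (see above).
#' @return `"confirmed"`, `"suspect"` or `"normal"`.
#' @export
classify_case <- function(percentiles, iop = NA, cct = NA,
                          risk_flags = character()) {
  p <- function(nm) {
    v <- percentiles[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  vf <- c(psd = p("psd"), md = p("md"))
  st <- c(gdf = p("gdf"), rim_area = p("rim_area"))
  if (all(is.na(vf)) || all(is.na(st))) {
    stop("need at least one visual-field and one structural percentile",
         call. = FALSE)
  }
  vf_hit <- any(vf < 5, na.rm = TRUE)
  st_hit <- any(st < 5, na.rm = TRUE)
  if (vf_hit && st_hit) return("confirmed")
  flags <- intersect(risk_flags,
                     c("family_history", "dubious_disc", "borderline_field"))
  if (is.na(iop)) {
    if (length(flags) == 0) {
      rlang::abort(
        "insufficient data: IOP missing, no risk flags, not confirmed",
        class = "hbdisc_insufficient_data")
    }
    return("normal")   # flags alone, without raised IOP, do not raise suspicion
  }
  suspect <- iop > 25 ||
    (iop >= 21 && iop <= 25 && !is.na(cct) && cct < 500) ||
    (iop > 21 && length(flags) > 0)
  if (suspect) "suspect" else "normal"
}
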