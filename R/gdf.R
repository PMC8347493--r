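# The Globin Distribution Function (GDF): a composite index mixing a
# normalized classifier score (45% by default) with the mean of normalized
# morphology/perfusion components (the remaining 55%), negated so that
# lower GDF = more glaucomatous.

# Orientation of the field's usual indices: TRUE when larger raw values
# indicate disease. Hb-type features and MD/GDF/rim/RNFLT are healthier
# when larger; variability and cup indices are worse when larger.
default_higher_is_worse <- function(ix, quiet = FALSE) {
  lower_worse <- c("md", "gdf", "rim_area", "rnflt")
  higher_worse <- c("tcv", "psd", "psdr", "oct_cd", "vertical_cd", "area_cd",
                    "hb_cd", "iop")
  key <- tolower(ix)
  if (key %in% lower_worse || grepl("hb", key)) return(FALSE)
  if (key %in% higher_worse) return(TRUE)
  if (!quiet) {
    message("orientation of index '", ix,
            "' unknown; assuming larger = more glaucomatous")
  }
  TRUE
}

#' Reference cohort statistics for z-normalization
#'
#' Per-index mean and SD estimated from the normal group, plus the
#' orientation of each index (whether larger raw values indicate disease).
#' All fusion in the package happens in the resulting z-space, where larger
#' always means more glaucomatous.
#'
#' Known index names get a default orientation: `MD`, `GDF`, `rim_area`,
#' `RNFLT`, and Hb-percentage features are healthier when larger
#' (`higher_is_worse = FALSE`); `TCV`, `PSD`, `PSDr` and cup/disc ratios are
#' worse when larger. Unknown indices default to `higher_is_worse = TRUE`
#' with a message; override via `orientation`.
#'
#' @param data Data frame containing the normal group's index values.
#' @param indices Character vector of index column names.
#' @param orientation Optional named logical vector, `TRUE` where larger raw
#'   values indicate disease.
#' @return A tibble of class `reference_cohort_stats` with columns `index`,
#'   `mean`, `sd`, `higher_is_worse`, `n`.
#' @export
reference_cohort_stats <- function(data, indices = NULL, orientation = NULL) {
  data <- tibble::as_tibble(data)
  indices <- indices %||% names(data)[vapply(data, is.numeric, logical(1))]
  missing <- setdiff(indices, names(data))
  if (length(missing)) stop("indices not in data: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  out <- purrr::map(indices, function(ix) {
    v <- data[[ix]][!is.na(data[[ix]])]
    s <- sd(v)
    if (!is.finite(s) || s <= 0) {
      stop("index '", ix, "' has non-positive SD in the reference cohort",
           call. = FALSE)
    }
    hw <- if (!is.null(orientation) && ix %in% names(orientation))
      orientation[[ix]] else default_higher_is_worse(ix)
    tibble::tibble(index = ix, mean = mean(v), sd = s,
                   higher_is_worse = hw, n = length(v))
  }) |> purrr::list_rbind()
  class(out) <- c("reference_cohort_stats", class(out))
  out
}

#' z-normalize an index value against the normal cohort
#'
#' `(value - mean) / SD`, then sign-aligned so that larger z always means
#' more glaucomatous (the z of an index where larger raw values are
#' healthier is negated).
#'
#' @param value Numeric vector of raw index values.
#' @param index Index name present in `stats`.
#' @param stats A [reference_cohort_stats()].
#' @return Sign-aligned z-scores.
#' @export
z_normalize <- function(value, index, stats) {
  stopifnot(inherits(stats, "reference_cohort_stats"))
  row <- stats[stats$index == index, ]
  if (nrow(row) != 1) stop("index '", index, "' not in reference stats",
                           call. = FALSE)
  z <- (value - row$mean) / row$sd
  if (row$higher_is_worse) z else -z
}

#' Globin Distribution Function
#'
#' Composite index: a weighted mix of the normalized classifier score
#' (weight `w`, default 0.45) and the unweighted mean of the normalized
#' morphology/perfusion component z-scores (weight `1 - w`), negated so
#' that, as in the Laguna-ONhE literature, lower GDF indicates glaucoma:
#' \deqn{GDF = -( w\,z_{clf} + (1-w)\,\overline{z}_{comp} ).}
#' Missing components are excluded from the mean with a warning; if all are
#' missing the call errors.
#'
#' @param classifier_z Sign-aligned z-score of the classifier output
#'   (larger = more glaucomatous).
#' @param component_zs Numeric vector of sign-aligned component z-scores.
#' @param w Classifier weight in \[0, 1\]; default 0.45.
#' @return GDF value (lower = more glaucomatous).
#' @export
gdf <- function(classifier_z, component_zs, w = 0.45) {
  stopifnot(length(component_zs) >= 1, w >= 0, w <= 1)
  ok <- !is.na(component_zs)
  if (!any(ok)) stop("all GDF components missing", call. = FALSE)
  if (!all(ok)) {
    warning(sum(!ok), " missing GDF component(s) excluded from the mean",
            call. = FALSE)
  }
  -(w * classifier_z + (1 - w) * mean(component_zs[ok]))
}

#' Default GDF component set
#'
#' The morphology/perfusion features entering the 55% block: mean disc Hb%,
#' vertical Hb-C/D, area C/D, and the mean Hb% of the inferior-temporal
#' sector (the sector most vulnerable in early glaucoma). Fully
#' configurable — this is just the shipped default.
#'
#' @return Character vector of component names.
#' @export
gdf_components <- function() {
  c("mean_hb", "vertical_cd", "area_cd", "inferotemporal_hb")
}

#' Fit the reference linear-discriminant classifier
#'
#' A deterministic, closed-form two-class linear discriminant over per-eye
#' feature vectors. It fills the classifier slot of the GDF so the pipeline
#' runs end-to-end; the contract is pluggable and any external scorer (a
#' CNN, a logistic model, ...) can take its place — [gdf()] only sees a
#' normalized score.
#'
#' Weights are `S_pooled^{-1} (mu_case - mu_normal)` (scoring by dot
#' product, larger = more glaucomatous); `ridge` adds `ridge * mean(diag(S))`
#' to the diagonal when the pooled covariance is singular.
#'
#' @param features Data frame (or matrix) of numeric features, one row per
#'   eye.
#' @param labels Vector with exactly two classes; the positive (glaucoma)
#'   class is `positive`.
#' @param positive Label of the disease class; default `"glaucoma"`.
#' @param ridge Non-negative ridge fraction; default 0 (error when singular).
#' @return Object of class `onhe_lda`: `weights`, `intercept` (midpoint
#'   offset), `features`, `positive`, `provenance = "reference-LDA"`.
#' @export
fit_reference_classifier <- function(features, labels, positive = "glaucoma",
                                     ridge = 0) {
  X <- as.matrix(tibble::as_tibble(features))
  if (!is.numeric(X)) stop("features must be numeric", call. = FALSE)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) {
    stop("need exactly two classes, got: ", paste(cls, collapse = ", "),
         call. = FALSE)
  }
  if (!positive %in% cls) stop("positive class '", positive, "' absent",
                               call. = FALSE)
  pos <- labels == positive
  if (min(sum(pos), sum(!pos)) < 10) {
    stop("need at least 10 observations per class", call. = FALSE)
  }
  X0 <- X[!pos, , drop = FALSE]; X1 <- X[pos, , drop = FALSE]
  S <- ((nrow(X0) - 1) * stats::cov(X0) + (nrow(X1) - 1) * stats::cov(X1)) /
    (nrow(X0) + nrow(X1) - 2)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), ncol(S))
  w <- tryCatch(solve(S, colMeans(X1) - colMeans(X0)),
                error = function(e) {
                  stop("pooled covariance is singular; refit with ridge > 0",
                       call. = FALSE)
                })
  mid <- sum(w * (colMeans(X0) + colMeans(X1)) / 2)
  structure(list(weights = w, intercept = -mid,
                 features = colnames(X), positive = positive,
                 provenance = "reference-LDA"),
            class = "onhe_lda")
}

#' Score eyes with a fitted reference classifier
#'
#' @param object An `onhe_lda` from [fit_reference_classifier()].
#' @param newdata Data frame with the training feature columns.
#' @param ... Ignored.
#' @return Numeric scores (larger = more glaucomatous).
#' @export
predict.onhe_lda <- function(object, newdata, ...) {
  X <- as.matrix(tibble::as_tibble(newdata)[, object$features, drop = FALSE])
  drop(X %*% object$weights) + object$intercept
}

#' @export
print.onhe_lda <- function(x, ...) {
  cat("<onhe_lda> linear discriminant,", length(x$weights), "features;",
      "positive class:", x$positive, "\n")
  invisible(x)
}

#' @rdname fit_reference_classifier
#' @param x An `onhe_lda`.
#' @param ... Ignored.
#' @method tidy onhe_lda
#' @export
tidy.onhe_lda <- function(x, ...) {
  tibble::tibble(term = c(x$features, "(intercept)"),
                 estimate = c(unname(x$weights), x$intercept))
}

#' Persist / load classifier weights as JSON
#'
#' @param object An `onhe_lda`.
#' @param path JSON path.
#' @return `path` invisibly; `read_classifier()` returns the object.
#' @export
write_classifier <- function(object, path) {
  jsonlite::write_json(
    list(weights = as.list(object$weights), intercept = object$intercept,
         features = object$features, positive = object$positive,
         provenance = object$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  j <- jsonlite::read_json(path)
  structure(list(weights = rlang::set_names(as.numeric(unlist(j$weights)),
                                            unlist(j$features)),
                 intercept = j$intercept,
                 features = unlist(j$features), positive = j$positive,
                 provenance = j$provenance),
            class = "onhe_lda")
}
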