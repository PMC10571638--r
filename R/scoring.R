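## AUD scoring: top-quantile criterion flags, criterion count (AUD index),
## composite z-score severity (AUD score), and prone/resistant classification.
## The fitting function aud_phenotype() ties these together in a classed
## result with the usual modelling methods.

.behavior_values <- function(x, behaviors) {
  df <- as.data.frame(x)
  miss <- setdiff(behaviors, names(df))
  if (length(miss) > 0) {
    stop_audcage(paste0("behavior column(s) missing: ",
                        paste(miss, collapse = ", ")), "audcage_scoring_error")
  }
  m <- as.matrix(df[behaviors])
  storage.mode(m) <- "double"
  dir <- attr(x, "direction")
  if (!is.null(dir)) {
    # orient columns so larger = more AUD-like; columns without direction
    # metadata (e.g. delta variants) default to +1
    d <- dir[behaviors]
    d[is.na(d)] <- 1
    m <- sweep(m, 2, unname(d), "*")
  }
  m
}

#' Top-quantile criterion flags
#'
#' An animal is positive for a behavior's AUD-like criterion when its score
#' lies in the uppermost `q` fraction of the population. The threshold is the
#' nearest-rank `(1 - q)` quantile — the `ceiling((1 - q) * n)`-th smallest
#' value — and an animal is flagged iff its value is *strictly* greater than
#' the threshold, so with all-distinct values and `q * n` integral exactly
#' `q * n` animals are flagged, and animals tied with the threshold are never
#' flagged.
#'
#' @param x a `"behavior_matrix"` (or any data.frame/matrix containing the
#'   behavior columns).
#' @param q upper-tail fraction in (0, 1); default 0.35.
#' @param behaviors which columns to flag (default the five scored
#'   behaviors).
#' @return Logical animals x behaviors matrix. A zero-variance column is
#'   degenerate: no animal is flagged and a warning is emitted (column names
#'   in `attr(, "degenerate")`).
#' @export
criterion_flags <- function(x, q = 0.35, behaviors = .behaviors) {
  if (q <= 0 || q >= 1) {
    stop_audcage("criterion quantile q must lie in (0, 1)", "audcage_config_error")
  }
  m <- .behavior_values(x, behaviors)
  n <- nrow(m)
  if (n < 3) {
    stop_audcage("criterion flags need at least 3 animals", "audcage_scoring_error")
  }
  thr <- .criterion_thresholds(m, q)
  flags <- sweep(m, 2, thr, ">")
  degen <- names(which(apply(m, 2, function(col) diff(range(col)) == 0)))
  if (length(degen) > 0) {
    flags[, degen] <- FALSE
    warning(sprintf("zero-variance behavior column(s) %s: degenerate criterion, no animal flagged",
                    paste(degen, collapse = ", ")))
  }
  rn <- if (!is.null(as.data.frame(x)$animal_id)) as.data.frame(x)$animal_id else rownames(m)
  dimnames(flags) <- list(rn, behaviors)
  attr(flags, "thresholds") <- thr
  attr(flags, "degenerate") <- degen
  flags
}

.criterion_thresholds <- function(m, q) {
  n <- nrow(m)
  idx <- ceiling((1 - q) * n)
  apply(m, 2, function(col) sort(col)[idx])
}

#' Criterion count (AUD index)
#'
#' @param flags logical animals x behaviors matrix from [criterion_flags()].
#' @return Integer vector: the number of fulfilled criteria per animal.
#' @export
aud_index <- function(flags) {
  as.integer(rowSums(flags))
}

#' Classify animals as AUD-prone or AUD-resistant
#'
#' An animal is AUD-prone when it fulfils at least `k` criteria (default
#' `k = 2`), AUD-resistant otherwise.
#'
#' @param index integer criterion counts from [aud_index()].
#' @param k prone threshold (criteria fulfilled), default 2.
#' @return Character vector, `"prone"` or `"resistant"`.
#' @export
classify_aud <- function(index, k = 2L) {
  if (k < 1) stop_audcage("k must be >= 1", "audcage_config_error")
  ifelse(index >= k, "prone", "resistant")
}

#' Composite AUD score (z-sum severity)
#'
#' Each behavior column is normalized against the population,
#' `z = (V_i - mean) / SD`, and the z-scores are summed over the behaviors,
#' giving a continuous severity measure whose population sum is zero.
#'
#' @param x a `"behavior_matrix"` (or data.frame/matrix with the behavior
#'   columns).
#' @param behaviors columns entering the score (default the five scored
#'   behaviors, equally weighted).
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`
#'   (n denominator).
#' @return Numeric vector of per-animal scores. Errors if any column has
#'   zero SD (naming the column).
#' @export
aud_score <- function(x, behaviors = .behaviors, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- .behavior_values(x, behaviors)
  if (nrow(m) < 3) {
    stop_audcage("AUD score needs at least 3 animals", "audcage_scoring_error")
  }
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  if (sd_type == "population") {
    sdv <- sdv * sqrt((nrow(m) - 1) / nrow(m))
  }
  zero <- names(which(sdv == 0 | !is.finite(sdv)))
  if (length(zero) > 0) {
    stop_audcage(paste0("zero-SD behavior column(s): ",
                        paste(zero, collapse = ", ")), "audcage_scoring_error")
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  unname(rowSums(z))
}

#' Fit the AUD phenotype classifier
#'
#' The central fitting function: from an animals-by-behaviors matrix it
#' derives per-behavior top-`q` criterion flags, the per-animal criterion
#' count (AUD index, 0-5), the composite z-sum severity (AUD score), and the
#' AUD-prone (index >= `k`) versus AUD-resistant classification.
#'
#' @param x a `"behavior_matrix"` from [build_behavior_matrix()], or any
#'   data.frame with an `animal_id` column plus the behavior columns.
#' @param q criterion quantile (uppermost fraction), default 0.35.
#' @param k prone threshold (criteria fulfilled), default 2.
#' @param behaviors behavior columns used (default `M, E, CR, AR, P`;
#'   alternates such as `E_delta` may be substituted).
#' @param sd_type standard-deviation convention for the score, see
#'   [aud_score()].
#' @return An object of class `"aud_phenotype"` with components `flags`,
#'   `index`, `score`, `class`, `thresholds`, `center`/`scale` (z-scoring
#'   parameters reused by `predict`), `q`, `k`, `behaviors`, `n` and
#'   `animal_id`. Methods: `print`, `summary`, `coef` (criterion
#'   thresholds), `predict` (score new animals against the fitted
#'   population), `plot` (AUD score vs AUD index) and `as.data.frame`.
#' @examples
#' set.seed(1)
#' bm <- data.frame(animal_id = sprintf("A%02d", 1:20),
#'                  M = sample(c(2, 4, 8, 12), 20, TRUE),
#'                  E = rpois(20, 20), CR = rpois(20, 40),
#'                  AR = rgamma(20, 4), P = rpois(20, 30))
#' fit <- aud_phenotype(bm)
#' fit
#' summary(fit)
#' @export
aud_phenotype <- function(x, q = 0.35, k = 2L, behaviors = .behaviors,
                          sd_type = "sample") {
  m <- .behavior_values(x, behaviors)
  flags <- criterion_flags(x, q = q, behaviors = behaviors)
  idx <- aud_index(flags)
  score <- aud_score(x, behaviors = behaviors, sd_type = sd_type)
  cls <- classify_aud(idx, k = k)
  ids <- as.data.frame(x)$animal_id %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  sdv <- apply(m, 2, stats::sd)
  if (sd_type == "population") sdv <- sdv * sqrt((nrow(m) - 1) / nrow(m))
  structure(list(
    animal_id = ids,
    behaviors = behaviors,
    values = m,
    flags = flags,
    index = idx,
    score = score,
    class = cls,
    thresholds = attr(flags, "thresholds"),
    degenerate = attr(flags, "degenerate"),
    center = colMeans(m),
    scale = sdv,
    q = q, k = as.integer(k), n = nrow(m),
    call = match.call()
  ), class = "aud_phenotype")
}

#' @export
print.aud_phenotype <- function(x, ...) {
  cat(sprintf("AUD phenotype classification (top %.0f%% criterion rule, >= %d criteria = prone)\n",
              100 * x$q, x$k))
  cat(sprintf("  %d animals: %d AUD-prone (%.1f%%), %d AUD-resistant\n",
              x$n, sum(x$class == "prone"), 100 * mean(x$class == "prone"),
              sum(x$class == "resistant")))
  cat("  criterion thresholds:\n")
  print(round(x$thresholds, 2))
  invisible(x)
}

#' @export
summary.aud_phenotype <- function(object, ...) {
  out <- list(
    q = object$q, k = object$k, n = object$n,
    n_prone = sum(object$class == "prone"),
    prone_fraction = mean(object$class == "prone"),
    thresholds = object$thresholds,
    index_table = table(factor(object$index, levels = 0:length(object$behaviors))),
    flags_per_behavior = colSums(object$flags),
    score_range = range(object$score),
    score_by_class = tapply(object$score, object$class, mean)
  )
  class(out) <- "summary.aud_phenotype"
  out
}

#' @export
print.summary.aud_phenotype <- function(x, ...) {
  cat(sprintf("AUD phenotype summary (q = %.2f, k = %d, n = %d)\n", x$q, x$k, x$n))
  cat(sprintf("  AUD-prone: %d (%.1f%%)\n", x$n_prone, 100 * x$prone_fraction))
  cat("  animals per AUD index value:\n")
  print(x$index_table)
  cat("  positives per behavior:\n")
  print(x$flags_per_behavior)
  class_mean <- function(g) {
    if (g %in% names(x$score_by_class)) x$score_by_class[[g]] else NA_real_
  }
  cat(sprintf("  AUD score range: [%.2f, %.2f]; class means: prone %.2f, resistant %.2f\n",
              x$score_range[1], x$score_range[2],
              class_mean("prone"), class_mean("resistant")))
  invisible(x)
}

#' @export
#' @rdname aud_phenotype
#' @param object,... an `"aud_phenotype"` fit; further arguments ignored.
coef.aud_phenotype <- function(object, ...) {
  object$thresholds
}

#' Score new animals against a fitted population
#'
#' Applies the fitted criterion thresholds and z-scoring parameters to new
#' behavior data (the new animals do not shift the population reference).
#'
#' @param object an `"aud_phenotype"` fit.
#' @param newdata data.frame/matrix with the fitted behavior columns; if
#'   omitted, returns the training-set results.
#' @param ... ignored.
#' @return data.frame: `animal_id`, per-behavior flags, `aud_index`,
#'   `aud_score`, `class`.
#' @export
predict.aud_phenotype <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.data.frame(object))
  m <- .behavior_values(newdata, object$behaviors)
  flags <- sweep(m, 2, object$thresholds, ">")
  idx <- as.integer(rowSums(flags))
  z <- sweep(sweep(m, 2, object$center, "-"), 2, object$scale, "/")
  score <- rowSums(z)
  ids <- as.data.frame(newdata)$animal_id %||% as.character(seq_len(nrow(m)))
  res <- data.frame(animal_id = ids, stringsAsFactors = FALSE)
  colnames(flags) <- paste0("flag_", object$behaviors)
  cbind(res, as.data.frame(flags),
        data.frame(aud_index = idx, aud_score = score,
                   class = classify_aud(idx, object$k),
                   stringsAsFactors = FALSE))
}

#' @export
as.data.frame.aud_phenotype <- function(x, ...) {
  flags <- x$flags
  colnames(flags) <- paste0("flag_", x$behaviors)
  out <- data.frame(animal_id = x$animal_id, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(flags, row.names = seq_len(x$n)),
        data.frame(aud_index = x$index, aud_score = x$score, class = x$class,
                   stringsAsFactors = FALSE))
}

#' Plot an AUD phenotype fit
#'
#' Scatter of the continuous AUD score against the discrete AUD index
#' (jittered), colored by class — the standard view of how the two severity
#' measures agree.
#'
#' @param x an `"aud_phenotype"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.aud_phenotype <- function(x, ...) {
  col <- ifelse(x$class == "prone", "firebrick", "steelblue")
  graphics::plot(jitter(x$index, 0.3), x$score, col = col, pch = 19,
                 xlab = "AUD index (criteria fulfilled)",
                 ylab = "AUD score (z-sum)", ...)
  graphics::abline(v = x$k - 0.5, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = c("AUD-prone", "AUD-resistant"),
                   col = c("firebrick", "steelblue"), pch = 19, bty = "n")
  invisible(x)
}
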