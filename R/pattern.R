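#' Temporal pattern classes
#'
#' Time courses of metabolites and transcripts in batch culture fall into
#' four recurring temporal patterns — continuous increase, continuous
#' decrease, variable (single large excursion), and constant — with the
#' remainder unclassified. `classify_pattern()` is a deterministic,
#' scale-invariant rule chain standing in for classification by eye.
#'
#' Let `m = max(|v|)` (if `m = 0` the series is constant), relative steps
#' `s_t = (v[t+1] - v[t]) / m`, net change `net = (v[T] - v[1]) / m`, and
#' `CV = sd(v) / |mean(v)|` (infinite when the mean is 0 but the series is
#' not). The rules, in order:
#' \itemize{
#'   \item constant: `CV < const_cv`
#'   \item increase: `net >= net_change` and every `s_t >= -step_tol`
#'   \item decrease: `net <= -net_change` and every `s_t <= step_tol`
#'   \item variable: `max(v) - min(v) >= net_change * m` and
#'     `|net| < net_change`
#'   \item otherwise unclassified
#' }
#' All three thresholds are relative, so the label is invariant under
#' rescaling `v -> c * v`, `c > 0`.
#'
#' @param means Numeric vector of per-time replicate means (length >= 3).
#' @param const_cv Coefficient-of-variation threshold below which a series
#'   counts as constant (default 0.10).
#' @param net_change Minimum relative net change for a monotone call, and
#'   minimum relative range for a variable call (default 0.20).
#' @param step_tol Tolerated relative counter-movement per step in a
#'   monotone series (default 0.05).
#' @return A length-1 factor with levels
#'   `increase, decrease, variable, constant, unclassified`.
#' @export
classify_pattern <- function(means, const_cv = 0.10, net_change = 0.20,
                             step_tol = 0.05) {
  means <- as.numeric(means)
  if (length(means) < 3L)
    stop("'means' must have at least 3 time points", call. = FALSE)
  if (!all(is.finite(means)))
    stop("'means' must be finite", call. = FALSE)
  stopifnot(const_cv > 0, net_change > 0, step_tol > 0)
  lv <- c("increase", "decrease", "variable", "constant", "unclassified")
  lab <- function(x) factor(x, levels = lv)
  m <- max(abs(means))
  if (m == 0) return(lab("constant"))
  s <- diff(means) / m
  net <- (means[length(means)] - means[1L]) / m
  mu <- mean(means)
  cv <- if (mu != 0) stats::sd(means) / abs(mu) else Inf
  if (cv < const_cv) return(lab("constant"))
  if (net >= net_change && all(s >= -step_tol)) return(lab("increase"))
  if (net <= -net_change && all(s <= step_tol)) return(lab("decrease"))
  if ((max(means) - min(means)) >= net_change * m && abs(net) < net_change)
    return(lab("variable"))
  lab("unclassified")
}

#' Classify every profile in a dataset
#'
#' Applies [classify_pattern()] to the replicate-mean series of each
#' (entity, condition) profile.
#'
#' @param d An `omics_dataset`.
#' @param const_cv,net_change,step_tol Passed to [classify_pattern()].
#' @return data.frame with columns `entity_id`, `entity_kind`, `condition`,
#'   `pattern`, `net_change_value` (relative net change) and `cv_value`,
#'   one row per profile, ordered by entity then condition.
#' @export
classify_dataset <- function(d, const_cv = 0.10, net_change = 0.20,
                             step_tol = 0.05) {
  stopifnot(inherits(d, "omics_dataset"))
  if (!length(d$profiles))
    return(data.frame(entity_id = character(), entity_kind = character(),
                      condition = character(), pattern = character(),
                      net_change_value = numeric(), cv_value = numeric()))
  rows <- lapply(d$profiles, function(p) {
    v <- mean_profile(p)$mean
    m <- max(abs(v))
    mu <- mean(v)
    data.frame(
      entity_id = p$entity_id, entity_kind = p$entity_kind,
      condition = p$condition,
      pattern = as.character(classify_pattern(v, const_cv, net_change,
                                              step_tol)),
      net_change_value = if (m > 0) (v[length(v)] - v[1L]) / m else 0,
      cv_value = if (mu != 0) stats::sd(v) / abs(mu) else
        if (m > 0) Inf else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$entity_id, out$condition), , drop = FALSE]
}
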