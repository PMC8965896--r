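#' Epigenetic-clock age calibration transform (and inverse)
#'
#' The standard piecewise calibration used by linear methylation clocks:
#' logarithmic in childhood and linear in adulthood,
#' F(age) = log(age + 1) - log(adult_age + 1) for age <= adult_age and
#' (age - adult_age) / (adult_age + 1) above, continuous at `adult_age`.
#' The clock's linear score lives on the F scale; predicted ages come back
#' through the inverse.
#'
#' @param age chronological age in years (> -1); vectorized.
#' @param adult_age calibration knot in years (default 20).
#' @return transformed value(s).
#' @export
age_transform <- function(age, adult_age = 20) {
  stopifnot(adult_age > 0, all(age > -1))
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @param x transformed value(s).
#' @export
age_transform_inverse <- function(x, adult_age = 20) {
  stopifnot(adult_age > 0)
  ifelse(x <= 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Predict DNA-methylation age and age acceleration
#'
#' Applies a sparse linear clock to a beta matrix: linear score =
#' intercept + sum(coef * beta) over the clock's probes, mapped to years
#' through the inverse age calibration. Clock probes missing from the matrix
#' are imputed with the clock's stored per-probe reference means (common
#' clock-implementation practice); if fewer than half of the clock probes are
#' present the prediction is refused. When chronological ages are supplied
#' (via `sheet`), age acceleration = predicted - chronological is computed
#' per sample together with the Spearman correlation of predicted versus
#' chronological age.
#'
#' @param beta beta matrix (probes x samples).
#' @param clock a `clock_model` (see [make_clock()]): `intercept`, named
#'   `coefficients`, `adult_age`, `reference_means`.
#' @param sheet optional sample sheet with `sample_id` and `age`.
#' @return an `age_result` list: `ages` (data.frame sample_id,
#'   predicted_age, and when ages are known chronological_age and
#'   acceleration) and `spearman_rho` (or NA).
#' @export
predict_age <- function(beta, clock, sheet = NULL) {
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(beta)
  if (mean(present) < 0.5) {
    stop_input("only %d of %d clock probes present in the matrix (need >= 50%%)",
               sum(present), length(probes))
  }
  X <- matrix(clock$reference_means, length(probes), ncol(beta),
              dimnames = list(probes, colnames(beta)))
  X[probes[present], ] <- beta[probes[present], , drop = FALSE]
  # per-probe missing values also fall back to the reference means
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- clock$reference_means[idx[, 1]]
  }
  score <- clock$intercept + drop(crossprod(X, clock$coefficients))
  predicted <- age_transform_inverse(score, clock$adult_age)

  ages <- data.frame(sample_id = colnames(beta), predicted_age = predicted,
                     stringsAsFactors = FALSE)
  rho <- NA_real_
  if (!is.null(sheet)) {
    chron <- sheet$age[match(colnames(beta), sheet$sample_id)]
    ages$chronological_age <- chron
    ages$acceleration <- ages$predicted_age - chron
    if (sum(!is.na(chron)) >= 3 && sd(chron, na.rm = TRUE) > 0 &&
        sd(predicted) > 0) {
      rho <- stats::cor(predicted, chron, method = "spearman",
                        use = "complete.obs")
    }
  }
  rownames(ages) <- NULL
  structure(list(ages = ages, spearman_rho = rho), class = "age_result")
}

#' Compare age acceleration between groups
#'
#' Reports the per-group median and range of the age acceleration and a
#' Kruskal-Wallis omnibus p-value across groups. If all accelerations are
#' identical the omnibus p is missing with a note.
#'
#' @param age_result an `age_result` from [predict_age()] (with
#'   acceleration).
#' @param sheet sample sheet with `sample_id` and `group`.
#' @return list with `by_group` (data.frame: group, n, median, min, max)
#'   and `kruskal_p` (plus `note` when degenerate).
#' @export
compare_acceleration <- function(age_result, sheet) {
  ages <- age_result$ages
  if (is.null(ages$acceleration)) {
    stop_input("age_result carries no acceleration; supply the sheet to predict_age")
  }
  grp <- sheet$group[match(ages$sample_id, sheet$sample_id)]
  if (length(unique(grp)) < 2) stop_input("need >= 2 groups")
  by_group <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    a <- ages$acceleration[grp == g]
    data.frame(group = g, n = length(a), median = median(a),
               min = min(a), max = max(a), stringsAsFactors = FALSE)
  }))
  if (var(ages$acceleration) == 0) {
    return(list(by_group = by_group, kruskal_p = NA_real_,
                note = "all accelerations identical; omnibus test undefined"))
  }
  list(by_group = by_group,
       kruskal_p = kruskal.test(ages$acceleration, factor(grp))$p.value)
}
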