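#' Single imputation of missing sex
#'
#' Fits a logistic regression of sex on the other record-level variables
#' (year, month, age, cause group of the underlying cause, number of Part II
#' mentions) over complete records, then draws each missing sex once from the
#' fitted conditional probability. Observed values are never touched and the
#' draw is reproducible under `seed`. When the predictors are degenerate (or
#' the model fails to fit) the imputation falls back to a marginal Bernoulli
#' draw, with a message.
#'
#' @param records Cleaned records ([clean_certificates()]); imputation runs on
#'   the analysis frame, so `ucod_group` and `n_part2_clean` must be present.
#' @param seed Integer seed for the single draw.
#' @param predictors Character vector of predictor columns; `age` is used only
#'   for rows where it is observed (rows missing age fall back to the median
#'   observed age for prediction).
#' @return `records` with `sex` completed and an attribute
#'   `imputed_sex` giving the number of imputed values.
#' @export
impute_sex <- function(records, seed = 1L,
                       predictors = c("age", "year", "month", "ucod_group",
                                      "n_part2_clean")) {
  miss <- is.na(records$sex)
  if (!any(miss)) {
    attr(records, "imputed_sex") <- 0L
    return(records)
  }
  if (all(miss)) stop("all sex values missing; model unfittable", call. = FALSE)
  fit_df <- records[c("sex", predictors)]
  if ("age" %in% predictors) {
    fill <- median(records$age, na.rm = TRUE)
    fit_df$age[is.na(fit_df$age)] <- fill
  }
  fit_df$y <- fit_df$sex == "F"
  p <- tryCatch({
    useful <- predictors[vapply(fit_df[predictors],
                                function(v) length(unique(v)) > 1, TRUE)]
    if (length(useful) == 0) stop("degenerate predictors")
    form <- stats::as.formula(paste("y ~", paste(useful, collapse = " + ")))
    fit <- stats::glm(form, family = stats::binomial(), data = fit_df[!miss, ])
    as.numeric(predict(fit, newdata = fit_df[miss, ], type = "response"))
  }, error = function(e) {
    message("sex imputation: falling back to marginal draw (", conditionMessage(e), ")")
    rep(mean(fit_df$y[!miss]), sum(miss))
  })
  withr::with_seed(seed, {
    records$sex[miss] <- ifelse(runif(sum(miss)) < p, "F", "M")
  })
  attr(records, "imputed_sex") <- sum(miss)
  records
}

#' Single imputation of missing age
#'
#' Two methods, both conditional on the other record variables and both
#' seeded single draws. `"multinomial_groups"` fits a multinomial logistic
#' regression over age-group labels, draws a group for each missing record
#' from the fitted probabilities, then draws a uniform integer age within the
#' group (85-99 for the open band). `"pmm"` (predictive mean matching) fits a
#' linear model for age, and for each missing record copies the observed age
#' of one of the `donors` records whose predicted mean is nearest to the
#' missing record's predicted mean.
#'
#' @param records Cleaned records ([clean_certificates()]).
#' @param method `"pmm"` or `"multinomial_groups"`.
#' @param seed Integer seed.
#' @param predictors Predictor columns; `sex` rows still missing are filled
#'   with the modal sex for prediction only.
#' @param age_breaks Age bands for the multinomial method.
#' @param donors Donor-pool size for predictive mean matching.
#' @return `records` with `age` completed and an attribute `imputed_age`.
#' @export
impute_age <- function(records, method = c("pmm", "multinomial_groups"),
                       seed = 1L,
                       predictors = c("sex", "year", "month", "ucod_group",
                                      "n_part2_clean"),
                       age_breaks = default_age_breaks(), donors = 5L) {
  method <- match.arg(method)
  miss <- is.na(records$age)
  if (!any(miss)) {
    attr(records, "imputed_age") <- 0L
    return(records)
  }
  if (all(miss)) stop("all age values missing; model unfittable", call. = FALSE)
  fit_df <- records[c("age", predictors)]
  if ("sex" %in% predictors && anyNA(fit_df$sex)) {
    tab <- table(fit_df$sex)
    fit_df$sex[is.na(fit_df$sex)] <- names(tab)[which.max(tab)]
  }
  useful <- predictors[vapply(fit_df[predictors],
                              function(v) length(unique(v)) > 1, TRUE)]
  rhs <- if (length(useful)) paste(useful, collapse = " + ") else "1"

  if (method == "multinomial_groups") {
    fit_df$grp <- factor(age_group_label(fit_df$age, age_breaks),
                         levels = age_group_labels(age_breaks))
    fit <- nnet::multinom(stats::as.formula(paste("grp ~", rhs)),
                          data = fit_df[!miss, ], trace = FALSE, maxit = 200)
    pr <- predict(fit, newdata = fit_df[miss, , drop = FALSE], type = "probs")
    if (is.null(dim(pr))) {
      # two fitted classes (vector of second-class probs) or a single row
      pr <- if (length(fit$lev) == 2 || length(fit$lab) == 2) {
        matrix(c(1 - pr, pr), ncol = 2, dimnames = list(NULL, fit$lab %||% fit$lev))
      } else {
        matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
      }
    }
    lev <- colnames(pr)
    lo <- setNames(age_breaks, age_group_labels(age_breaks))
    hi <- setNames(c(age_breaks[-1] - 1L, 99L), age_group_labels(age_breaks))
    withr::with_seed(seed, {
      g <- apply(pr, 1, function(p) sample(lev, 1, prob = p))
      records$age[miss] <- as.integer(floor(runif(sum(miss), lo[g], hi[g] + 1)))
    })
  } else {
    fit <- stats::lm(stats::as.formula(paste("age ~", rhs)), data = fit_df[!miss, ])
    pred_obs <- as.numeric(predict(fit))
    pred_mis <- as.numeric(predict(fit, newdata = fit_df[miss, , drop = FALSE]))
    ord <- order(pred_obs)
    po <- pred_obs[ord]
    ages_obs <- records$age[!miss][ord]
    n_obs <- length(po)
    k <- min(donors, n_obs)
    eps <- 1e-9
    withr::with_seed(seed, {
      records$age[miss] <- vapply(pred_mis, function(pm) {
        # distance of the k-th nearest donor, then sample uniformly among all
        # donors at or inside that distance (ties share the pool; with flat
        # predictions this collapses to a draw from the whole donor set)
        j <- findInterval(pm, po)
        win <- seq(max(1L, j - k), min(n_obs, j + k))
        thr <- sort(abs(po[win] - pm), partial = k)[k]
        lo_i <- findInterval(pm - thr - eps, po) + 1L
        hi_i <- findInterval(pm + thr + eps, po)
        ages_obs[sample(lo_i:hi_i, 1L)]
      }, 0L)
    })
  }
  attr(records, "imputed_age") <- sum(miss)
  records
}
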