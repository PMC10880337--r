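#' Fit a propensity-score model
#'
#' Logistic regression (maximum likelihood) of exposure on the matching
#' covariates; the fitted probability of exposure is the propensity score.
#' Complete separation (or quasi-separation) is reported with a warning and
#' the fit falls back to a lightly ridge-penalised logistic model so that
#' finite scores are still produced.
#'
#' @param covariates data.frame of covariates (numeric or 2-level factors);
#'   any `patient_id` column is ignored as a predictor.
#' @param exposed Logical (or 0/1) vector, one per row of `covariates`.
#' @return Numeric vector of scores in (0, 1), with attribute `model`
#'   (`"glm"` or `"ridge"`).
#' @export
fit_propensity <- function(covariates, exposed) {
  exposed <- as.logical(exposed)
  if (anyNA(exposed) || length(unique(exposed)) < 2L) {
    stop("both exposure groups must be present to fit a propensity model",
         call. = FALSE)
  }
  X <- covariates[, setdiff(names(covariates), "patient_id"), drop = FALSE]
  if (any(!complete.cases(X))) {
    stop("matching covariates contain missing values", call. = FALSE)
  }
  dat <- cbind(.exposed = exposed, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.exposed ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eps <- 1e-8
  ps <- fitted(fit)
  if (sep || any(ps < eps) || any(ps > 1 - eps)) {
    warning("separation or non-convergence in the propensity model; ",
            "falling back to a ridge-penalised logistic fit", call. = FALSE)
    mm <- stats::model.matrix(~ ., data = X)[, -1, drop = FALSE]
    if (ncol(mm) < 2L) mm <- cbind(mm, .const = 0) # glmnet needs >= 2 cols
    rfit <- glmnet::glmnet(mm, factor(exposed), family = "binomial",
                           alpha = 0, lambda = 0.01, standardize = TRUE)
    ps <- as.numeric(predict(rfit, newx = mm, type = "response"))
    ps <- pmin(pmax(ps, eps), 1 - eps)
    attr(ps, "model") <- "ridge"
  } else {
    ps <- as.numeric(ps)
    attr(ps, "model") <- "glm"
  }
  ps
}

# standardized mean difference: |m1 - m0| / sqrt((v1 + v0)/2); 0 when both
# variances vanish
smd <- function(x, g) {
  x <- as.numeric(x)
  m1 <- mean(x[g]); m0 <- mean(x[!g])
  s <- sqrt((var(x[g]) + var(x[!g])) / 2)
  if (!is.finite(s) || s == 0) {
    return(if (isTRUE(all.equal(m1, m0))) 0 else Inf)
  }
  abs(m1 - m0) / s
}

#' Greedy nearest-neighbour caliper matching
#'
#' Matches each exposed patient to `ratio` unexposed patients by propensity
#' score, without replacement. Exposed units are processed in descending
#' score order (ties by patient id); each takes its nearest available
#' controls by absolute score distance, subject to a caliper of
#' `caliper` x SD of the pooled scores (or `caliper` probability units when
#' `caliper_units = "absolute"`). In strict mode exposed units that cannot
#' fill all `ratio` slots are dropped and their provisional controls return
#' to the pool.
#'
#' @param scores Propensity scores for all patients.
#' @param exposed Logical vector, same length.
#' @param ids Patient identifiers, same length.
#' @param ratio Controls per exposed unit (default 3).
#' @param caliper Caliper width (default 0.25 SD of the pooled scores).
#' @param caliper_units `"sd"` (default) or `"absolute"`.
#' @param strict Drop exposed units with fewer than `ratio` matches
#'   (default TRUE).
#' @param covariates Optional covariate data.frame (for balance diagnostics).
#' @return List of class `matched_cohort`: `sets` (data.frame
#'   `set_id, exposed_id, control_id, distance`), `matched_exposed`,
#'   `matched_controls`, `dropped_exposed`, `caliper_width`, and `balance`
#'   (pre/post standardized mean differences per covariate, when covariates
#'   are given).
#' @export
nearest_neighbor_match <- function(scores, exposed, ids, ratio = 3L,
                                   caliper = 0.25,
                                   caliper_units = c("sd", "absolute"),
                                   strict = TRUE, covariates = NULL) {
  caliper_units <- match.arg(caliper_units)
  exposed <- as.logical(exposed)
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  if (caliper <= 0) stop("caliper must be > 0", call. = FALSE)
  stopifnot(length(scores) == length(exposed), length(ids) == length(scores))
  width <- if (caliper_units == "sd") caliper * sd(scores) else caliper
  if (!is.finite(width) || width <= 0) width <- .Machine$double.eps

  e_ord <- order(-scores[exposed], ids[exposed])
  e_scores <- scores[exposed][e_ord]
  e_ids <- ids[exposed][e_ord]
  # controls sorted by (score, id) so equal-score ties resolve by id
  c_ord <- order(scores[!exposed], ids[!exposed])
  c_scores <- scores[!exposed][c_ord]
  c_ids <- ids[!exposed][c_ord]

  m <- nn_match_cpp(e_scores, c_scores, as.integer(ratio), width, strict)
  got <- rowSums(!is.na(m))
  kept <- if (strict) got == ratio else got > 0
  sets <- data.frame(
    set_id = rep(seq_len(sum(kept)), times = got[kept]),
    exposed_id = rep(e_ids[kept], times = got[kept]),
    control_id = c_ids[t(m[kept, , drop = FALSE])[!is.na(t(m[kept, , drop = FALSE]))]],
    stringsAsFactors = FALSE
  )
  sets$distance <- abs(scores[match(sets$exposed_id, ids)] -
                         scores[match(sets$control_id, ids)])
  out <- list(
    sets = sets,
    matched_exposed = e_ids[kept],
    matched_controls = sets$control_id,
    dropped_exposed = e_ids[!kept],
    caliper_width = width,
    ratio = as.integer(ratio),
    strict = strict
  )
  if (!is.null(covariates)) {
    cv <- covariates[, setdiff(names(covariates), "patient_id"), drop = FALSE]
    pre <- vapply(cv, smd, numeric(1), g = exposed)
    in_post <- ids %in% c(out$matched_exposed, out$matched_controls)
    post <- if (any(in_post & exposed) && any(in_post & !exposed)) {
      vapply(cv[in_post, , drop = FALSE], smd, numeric(1), g = exposed[in_post])
    } else rep(NA_real_, ncol(cv))
    out$balance <- data.frame(covariate = names(cv), smd_pre = unname(pre),
                              smd_post = unname(post), stringsAsFactors = FALSE)
  }
  class(out) <- "matched_cohort"
  out
}

#' @exportS3Method base::print
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d exposed x %d controls (1:%d, caliper %.4g)\n",
              length(x$matched_exposed), length(x$matched_controls),
              x$ratio, x$caliper_width))
  if (length(x$dropped_exposed)) {
    cat(sprintf("  %d exposed dropped (no full match within caliper)\n",
                length(x$dropped_exposed)))
  }
  if (!is.null(x$balance)) {
    cat("  balance (SMD pre -> post):\n")
    for (i in seq_len(nrow(x$balance))) {
      cat(sprintf("    %-20s %.3f -> %.3f\n", x$balance$covariate[i],
                  x$balance$smd_pre[i], x$balance$smd_post[i]))
    }
  }
  invisible(x)
}
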