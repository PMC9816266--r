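## Binomial mixed-model analysis of single-trial accuracy.
##
## The pipeline mirrors standard psychophysics practice: fit the full
## factorial binomial GLMM (logit link, per-participant random effects,
## starting from the maximal random structure and simplifying on
## non-convergence), then backward-eliminate fixed terms by likelihood-
## ratio chi-squared tests, removing the highest-order term with the
## largest non-significant p until every remaining removable term is
## significant. Effect sizes are standardized odds ratios; post hoc
## contrasts on retained interactions use estimated marginal means on the
## link scale with a max-|z| multiplicity adjustment simulated from the
## contrast covariance (a parametric analogue of multivariate-t
## adjustment), or Bonferroni as a conservative fallback.

#' Fit a binomial GLMM with backward elimination of fixed terms
#'
#' Fits `correct ~ <full factorial of fixed_factors>` with a logit link and
#' per-participant random effects, then iteratively removes fixed terms:
#' at each step every *removable* term (one not contained in a retained
#' higher-order term) is tested by a likelihood-ratio chi-squared test, and
#' the term with the largest p >= `alpha` is dropped; the procedure stops
#' when all removable terms are significant. Every test performed is logged
#' in the elimination ledger.
#'
#' @param trials Trial-record data frame with a logical/0-1 `correct`
#'   column, a `participant` column, and the factor columns named in
#'   `fixed_factors`. Practice trials (if flagged) are dropped.
#' @param fixed_factors Character vector of fixed-factor column names.
#' @param random_spec `"intercept"` for `(1 | participant)`, `"maximal"`
#'   to start from random slopes for all fixed main effects and simplify
#'   on non-convergence or singularity, or a random-effects formula string
#'   such as `"(1 + attention | participant)"`.
#' @param alpha Retention threshold for the likelihood-ratio tests.
#' @return An object of class `glmm_fit_result`: the final `model`, a
#'   `fixed_table` with log-odds estimates and standardized ORs, the
#'   elimination `ledger`, `final_terms`, the random-effects formula used,
#'   and a `converged` flag.
#' @export
fit_glmm_backward <- function(trials, fixed_factors,
                              random_spec = "intercept", alpha = 0.05) {
  if ("practice" %in% names(trials)) trials <- trials[!trials$practice, ]
  if (length(unique(trials$participant)) < 2) {
    stop("at least two participants are required", call. = FALSE)
  }
  dat <- trials
  dat$correct <- as.integer(dat$correct)
  for (f in fixed_factors) {
    if (!f %in% names(dat)) stop(sprintf("factor `%s` not in data", f),
                                 call. = FALSE)
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2) {
      stop(sprintf("factor `%s` has fewer than 2 levels", f), call. = FALSE)
    }
  }
  dat$participant <- factor(dat$participant)

  fixed_rhs <- paste(fixed_factors, collapse = " * ")
  random_candidates <- if (identical(random_spec, "maximal")) {
    c(sprintf("(1 + %s | participant)", paste(fixed_factors, collapse = " + ")),
      sprintf("(1 + %s | participant)", fixed_factors[1]),
      "(1 | participant)")
  } else if (identical(random_spec, "intercept")) {
    "(1 | participant)"
  } else {
    c(random_spec, "(1 | participant)")
  }

  fit_one <- function(rhs_fixed, rhs_random) {
    fo <- stats::as.formula(paste("correct ~", rhs_fixed, "+", rhs_random))
    warned <- FALSE
    fit <- withCallingHandlers(
      tryCatch(lme4::glmer(fo, data = dat, family = stats::binomial),
               error = function(e) e),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warned = warned)
  }

  ## choose the random structure on the full fixed model
  random_used <- NULL
  full <- NULL
  for (rc in random_candidates) {
    res <- fit_one(fixed_rhs, rc)
    ok <- !inherits(res$fit, "error") && !res$warned &&
      !lme4::isSingular(res$fit, tol = 1e-4)
    if (ok || rc == random_candidates[length(random_candidates)]) {
      if (inherits(res$fit, "error")) {
        stop("GLMM failed to converge under all random-effect structures: ",
             conditionMessage(res$fit), call. = FALSE)
      }
      random_used <- rc
      full <- res
      break
    }
  }

  current_terms <- attr(stats::terms(stats::as.formula(
    paste("correct ~", fixed_rhs))), "term.labels")
  current_fit <- full$fit
  ledger <- data.frame(step = integer(0), term = character(0),
                       chisq = numeric(0), df = integer(0),
                       p = numeric(0), removed = logical(0),
                       stringsAsFactors = FALSE)

  term_vars <- function(tm) strsplit(tm, ":", fixed = TRUE)[[1]]
  removable <- function(terms) {
    vapply(terms, function(tm) {
      v <- term_vars(tm)
      !any(vapply(setdiff(terms, tm), function(ot) {
        all(v %in% term_vars(ot))
      }, logical(1)))
    }, logical(1))
  }

  step <- 0L
  repeat {
    step <- step + 1L
    cand <- current_terms[removable(current_terms)]
    if (length(cand) == 0) break
    tests <- lapply(cand, function(tm) {
      reduced_terms <- setdiff(current_terms, tm)
      rhs <- if (length(reduced_terms) == 0) "1" else
        paste(reduced_terms, collapse = " + ")
      red <- fit_one(rhs, random_used)
      if (inherits(red$fit, "error")) return(NULL)
      an <- stats::anova(red$fit, current_fit)
      list(term = tm, chisq = an$Chisq[2], df = an$Df[2],
           p = an$`Pr(>Chisq)`[2], fit = red$fit)
    })
    tests <- Filter(Negate(is.null), tests)
    if (length(tests) == 0) break
    ps <- vapply(tests, function(t) t$p, numeric(1))
    worst <- which.max(ps)
    remove_it <- ps[worst] >= alpha
    for (i in seq_along(tests)) {
      ledger <- rbind(ledger, data.frame(
        step = step, term = tests[[i]]$term, chisq = tests[[i]]$chisq,
        df = tests[[i]]$df, p = tests[[i]]$p,
        removed = remove_it && i == worst, stringsAsFactors = FALSE))
    }
    if (!remove_it) break
    current_terms <- setdiff(current_terms, tests[[worst]]$term)
    current_fit <- tests[[worst]]$fit
    if (length(current_terms) == 0) break
  }

  est <- lme4::fixef(current_fit)
  se <- sqrt(diag(as.matrix(stats::vcov(current_fit))))
  fixed_table <- data.frame(
    term = names(est), estimate = as.numeric(est), se = se,
    z = as.numeric(est) / se,
    or = exp(as.numeric(est)),
    band = or_effect_size(as.numeric(est))$band,
    stringsAsFactors = FALSE)
  rownames(fixed_table) <- NULL

  structure(
    list(model = current_fit, fixed_table = fixed_table, ledger = ledger,
         final_terms = current_terms, random_formula = random_used,
         fixed_factors = fixed_factors, alpha = alpha, data = dat,
         converged = !full$warned),
    class = "glmm_fit_result")
}

#' @export
print.glmm_fit_result <- function(x, ...) {
  cat(sprintf("<glmm_fit_result> final terms: %s\n",
              if (length(x$final_terms)) paste(x$final_terms, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  random effects: %s; %d elimination tests, %d terms removed\n",
              x$random_formula, nrow(x$ledger), sum(x$ledger$removed)))
  invisible(x)
}

#' Standardized odds-ratio effect size
#'
#' Exponentiates logistic coefficients into odds ratios and labels their
#' magnitude by the nearest of the standardized anchors OR = 1.68, 3.47,
#' 6.71 (equivalent to Cohen's d of 0.2, 0.5, 0.8; nearest on the log
#' scale). ORs whose magnitude is below 1.68 are labelled `below-small`;
#' the sign of the log-odds does not affect the band.
#'
#' @param log_odds Numeric vector of log-odds estimates.
#' @return Data frame with `log_odds`, `or` and `band`.
#' @examples
#' or_effect_size(log(c(1, 3.47, 6.71)))
#' @export
or_effect_size <- function(log_odds) {
  if (any(!is.finite(log_odds))) stop("estimates must be finite", call. = FALSE)
  or <- exp(log_odds)
  mag <- exp(abs(log_odds))
  cuts <- c(1.68, sqrt(1.68 * 3.47), sqrt(3.47 * 6.71))
  band <- ifelse(mag < cuts[1], "below-small",
          ifelse(mag < cuts[2], "small",
          ifelse(mag < cuts[3], "medium", "large")))
  data.frame(log_odds = log_odds, or = or, band = band,
             stringsAsFactors = FALSE)
}

#' Post hoc pairwise contrasts on a retained interaction
#'
#' Computes estimated marginal means on the linear-predictor (log-odds)
#' scale for the cells of an interaction retained in the final model
#' (averaging over the other fixed factors with equal weights), forms all
#' pairwise contrasts, and adjusts p-values for multiplicity. The `"mvt"`
#' adjustment simulates the null distribution of the maximum absolute z
#' statistic from the estimated contrast correlation (`ndraws` draws,
#' seeded), so correlated contrast families are adjusted less severely
#' than by Bonferroni; `"bonferroni"` is the conservative fallback.
#'
#' @param fit A [fit_glmm_backward()] result.
#' @param interaction Interaction term, e.g. `"condition:attention"` (must
#'   be in the final model).
#' @param adjust `"mvt"` or `"bonferroni"`.
#' @param ndraws Monte-Carlo draws for the max-|z| null distribution.
#' @param seed Seed for the adjustment draws.
#' @return A data frame of class `contrast_table`: contrast label,
#'   log-odds estimate, SE, z, unadjusted and adjusted p, significance at
#'   .05.
#' @export
posthoc_contrasts <- function(fit, interaction, adjust = c("mvt", "bonferroni"),
                              ndraws = 100000L, seed = 1L) {
  stopifnot(inherits(fit, "glmm_fit_result"))
  adjust <- match.arg(adjust)
  want <- sort(strsplit(interaction, ":", fixed = TRUE)[[1]])
  hit <- vapply(fit$final_terms, function(tm) {
    identical(sort(strsplit(tm, ":", fixed = TRUE)[[1]]), want)
  }, logical(1))
  if (!any(hit)) {
    stop(sprintf("interaction `%s` is not in the final model", interaction),
         call. = FALSE)
  }

  beta <- lme4::fixef(fit$model)
  if (anyNA(beta)) {
    stop("rank-deficient fixed effects; aliased coefficients: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  V <- as.matrix(stats::vcov(fit$model))
  dat <- fit$data
  facs <- fit$fixed_factors
  lv <- lapply(dat[facs], levels)
  cell_facs <- want
  other_facs <- setdiff(facs, cell_facs)

  grid <- expand.grid(lv[cell_facs], stringsAsFactors = FALSE)
  names(grid) <- cell_facs
  mm_formula <- stats::as.formula(
    paste("~", paste(facs, collapse = " * ")))
  ## L: one row per cell, averaging the design over the other factors
  L <- t(vapply(seq_len(nrow(grid)), function(i) {
    nd <- if (length(other_facs)) {
      expand.grid(lv[other_facs], stringsAsFactors = FALSE)
    } else data.frame(row.names = 1)
    if (length(other_facs)) names(nd) <- other_facs
    for (f in cell_facs) nd[[f]] <- grid[i, f]
    for (f in facs) nd[[f]] <- factor(nd[[f]], levels = lv[[f]])
    X <- stats::model.matrix(mm_formula, nd)
    ## restrict to the final model's columns
    colMeans(X)[names(beta)]
  }, numeric(length(beta))))

  cell_names <- apply(grid, 1, paste, collapse = " ")
  k <- nrow(grid)
  pairs <- utils::combn(k, 2)
  C <- matrix(0, ncol(pairs), k)
  C[cbind(seq_len(ncol(pairs)), pairs[1, ])] <- 1
  C[cbind(seq_len(ncol(pairs)), pairs[2, ])] <- -1
  CL <- C %*% L
  est <- as.numeric(CL %*% beta)
  cv <- CL %*% V %*% t(CL)
  se <- sqrt(diag(cv))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))

  if (adjust == "bonferroni") {
    p_adj <- pmin(1, length(p) * p)
  } else {
    R <- stats::cov2cor(cv)
    ev <- eigen(R, symmetric = TRUE)
    A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
    maxabs <- with_seed(seed, {
      zdraw <- matrix(stats::rnorm(ndraws * nrow(R)), ndraws) %*% t(A)
      apply(abs(zdraw), 1, max)
    })
    p_adj <- vapply(abs(z), function(zi) {
      (1 + sum(maxabs >= zi)) / (ndraws + 1)
    }, numeric(1))
    p_adj <- pmin(1, pmax(p_adj, p))
  }

  out <- data.frame(
    contrast = sprintf("%s - %s", cell_names[pairs[1, ]],
                       cell_names[pairs[2, ]]),
    estimate = est, se = se, z = z, p.value = p, p.adjusted = p_adj,
    significant = p_adj < 0.05, stringsAsFactors = FALSE)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Cell-wise accuracy summary
#'
#' Per-participant accuracies in every cell of the requested factors, with
#' the across-participant mean and SD per cell (the format in which 2IFC
#' accuracy is usually reported and plotted, against the 50% chance
#' level). Practice trials are dropped when flagged.
#'
#' @param trials Trial-record data frame.
#' @param by Character vector of grouping columns.
#' @return A list of class `accuracy_summary`: `cells` (mean/SD accuracy
#'   in percent, per cell), `participants` (participant-level points) and
#'   `chance` (50).
#' @export
accuracy_summary <- function(trials, by = c("condition", "attention")) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("no trial records supplied", call. = FALSE)
  }
  if ("practice" %in% names(trials)) trials <- trials[!trials$practice, ]
  fml <- stats::as.formula(paste("correct ~ participant +",
                                 paste(by, collapse = " + ")))
  pts <- stats::aggregate(fml, data = trials, FUN = mean)
  names(pts)[names(pts) == "correct"] <- "accuracy"
  pts$accuracy <- 100 * pts$accuracy
  nfl <- stats::aggregate(fml, data = trials, FUN = length)
  pts$n_trials <- nfl$correct
  cfl <- stats::as.formula(paste("accuracy ~", paste(by, collapse = " + ")))
  cells <- stats::aggregate(cfl, data = pts,
                            FUN = function(a) c(mean = mean(a), sd = stats::sd(a),
                                                n = length(a)))
  cells <- cbind(cells[by],
                 mean_accuracy = cells$accuracy[, "mean"],
                 sd_accuracy = cells$accuracy[, "sd"],
                 n_participants = as.integer(cells$accuracy[, "n"]))
  structure(list(cells = cells, participants = pts, chance = 50),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("<accuracy_summary> mean accuracy (%) by cell; chance = 50%\n")
  print(x$cells)
  invisible(x)
}

#' Plot an accuracy summary
#'
#' Box plot of participant-level accuracies per cell with the chance line,
#' using ggplot2 when available.
#'
#' @param summary An [accuracy_summary()].
#' @param x_var Column of the participant table mapped to the x axis.
#' @param colour_var Optional column mapped to fill.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(summary, x_var = "condition",
                          colour_var = NULL) {
  stopifnot(inherits(summary, "accuracy_summary"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  pts <- summary$participants
  aes <- ggplot2::aes(x = .data[[x_var]], y = .data[["accuracy"]])
  gg <- ggplot2::ggplot(pts, aes) +
    ggplot2::geom_hline(yintercept = summary$chance, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(
      if (!is.null(colour_var)) ggplot2::aes(fill = .data[[colour_var]])) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1),
                        alpha = 0.6, size = 1) +
    ggplot2::labs(y = "Accuracy (%)") +
    ggplot2::theme_minimal()
  gg
}
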