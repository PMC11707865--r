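#' Assemble the displacement model frame
#'
#' Joins per-fish-month displacement records to monthly habitat availability
#' and (optionally) projected fork lengths, producing one row per
#' fish-month-year for [fit_additive_model()].
#'
#' @param displacement data frame with `transmitter_id`, `year`, `month`,
#'   `displacement_km`.
#' @param monthly monthly habitat summary ([monthly_mean_volumes()]) with
#'   `prop_suitable`, `prop_optimum`, `volume_hypoxic`.
#' @param projections optional data frame `transmitter_id`, `year`,
#'   `projected_fork_length_mm`.
#' @return Data frame with columns `fish_id`, `year`, `month`,
#'   `displacement_km`, `suitable`, `optimum`, `hypoxic_volume`
#'   (+ `fork_length` when projections are given). `suitable` and `optimum`
#'   are monthly mean proportions of total lake volume; `suitable` is all
#'   non-hypoxic water (DO above the hypoxia threshold at any temperature),
#'   i.e. the suitable and optimum partition classes combined, of which
#'   `optimum` is the subset in the optimal temperature/DO window.
#' @export
model_frame <- function(displacement, monthly, projections = NULL) {
  assert_cols(displacement, c("transmitter_id", "year", "month",
                              "displacement_km"), "displacement table")
  assert_cols(monthly, c("year", "month", "prop_suitable", "prop_optimum",
                         "volume_hypoxic"), "monthly habitat table")
  i <- match(paste(displacement$year, displacement$month),
             paste(monthly$year, monthly$month))
  if (anyNA(i))
    stopf("no monthly habitat summary for %d fish-month(s)", sum(is.na(i)))
  out <- data.frame(fish_id = factor(displacement$transmitter_id),
                    year = factor(displacement$year),
                    month = displacement$month,
                    displacement_km = displacement$displacement_km,
                    suitable = monthly$prop_suitable[i] + monthly$prop_optimum[i],
                    optimum = monthly$prop_optimum[i],
                    hypoxic_volume = monthly$volume_hypoxic[i])
  if (!is.null(projections)) {
    assert_cols(projections, c("transmitter_id", "year",
                               "projected_fork_length_mm"), "projections")
    j <- match(paste(displacement$transmitter_id, displacement$year),
               paste(projections$transmitter_id, projections$year))
    out$fork_length <- projections$projected_fork_length_mm[j]
  }
  out
}

term_smooth <- function(term, k) {
  sprintf("s(%s, k = %d, bs = \"cs\")", term, k)
}

#' Fit a smooth additive mixed model of displacement on habitat
#'
#' Gamma GAMM with log link (keeping the fitted mean positive): penalized
#' cubic regression splines (shrinkage basis, dimension `k`) for the habitat
#' and length terms, penalized random intercepts for fish and year, and
#' REML smoothness selection, via `mgcv::gam`. Rows with non-positive
#' displacement are excluded with a warning.
#'
#' @param frame a [model_frame()]-style data frame.
#' @param terms character subset of `c("suitable", "optimum", "fork_length")`
#'   to include as smooths; may be empty for the intercept-only model.
#' @param random random intercepts, subset of `c("fish_id", "year")`.
#' @param k smooth basis dimension (default 5).
#' @param family `"Gamma"` (default) or `"gaussian_log"` (Gaussian with log
#'   link, a fallback for light-tailed responses).
#' @return List of class `oxytel_fit`: `model` (the `gam` object), `terms`,
#'   `aic`, `deviance_explained` (percent), `edf` (per-smooth table),
#'   `random_variances`, `smooth_grids` (fitted smooth curves on a 100-point
#'   grid per habitat term), `n`.
#' @export
fit_additive_model <- function(frame, terms = c("suitable", "optimum"),
                               random = c("fish_id", "year"), k = 5,
                               family = c("Gamma", "gaussian_log")) {
  family <- match.arg(family)
  bad <- setdiff(terms, c("suitable", "optimum", "fork_length"))
  if (length(bad)) stopf("unknown model term(s): %s", paste(bad, collapse = ", "))
  assert_cols(frame, c("displacement_km", terms, random), "model frame")
  pos <- frame$displacement_km > 0
  if (!all(pos)) {
    warnf("excluding %d row(s) with non-positive displacement", sum(!pos))
    frame <- frame[pos, ]
  }
  if (nrow(frame) < 20L)
    stopf("at least 20 rows are required to fit the additive model (got %d)",
          nrow(frame))
  if (any(!is.finite(as.matrix(frame[terms]))))
    stopf("non-finite predictor values")
  for (r in random) frame[[r]] <- factor(frame[[r]])
  # a random intercept needs at least two groups
  droppable <- vapply(random, function(r) nlevels(frame[[r]]) < 2L, TRUE)
  if (any(droppable)) {
    message("dropping single-level random effect(s): ",
            paste(random[droppable], collapse = ", "))
    random <- random[!droppable]
  }
  # the cubic basis needs at least k distinct covariate values
  k_term <- vapply(terms, function(tm) {
    max(3L, min(as.integer(k), length(unique(frame[[tm]]))))
  }, 0L)
  rhs <- c(if (length(terms)) mapply(term_smooth, terms, k_term),
           if (length(random)) sprintf("s(%s, bs = \"re\")", random))
  if (length(rhs) == 0L) rhs <- "1"
  fml <- stats::as.formula(paste("displacement_km ~", paste(rhs, collapse = " + ")))
  fam <- if (family == "Gamma") stats::Gamma(link = "log")
         else stats::gaussian(link = "log")
  fit <- mgcv::gam(fml, data = frame, family = fam, method = "REML")
  if (!fit$converged) stopf("GAMM did not converge")
  sm <- summary(fit)
  dev_expl <- 100 * (1 - fit$deviance / fit$null.deviance)
  edf <- if (length(fit$smooth)) {
    data.frame(term = rownames(sm$s.table), edf = sm$s.table[, "edf"],
               p_value = sm$s.table[, ncol(sm$s.table)], row.names = NULL)
  } else data.frame(term = character(), edf = numeric(), p_value = numeric())
  vc <- tryCatch({
    tmp <- utils::capture.output(v <- mgcv::gam.vcomp(fit, rescale = FALSE))
    v
  }, error = function(e) NULL)
  grids <- lapply(intersect(terms, c("suitable", "optimum", "fork_length")),
                  function(tm) {
    x <- seq(min(frame[[tm]]), max(frame[[tm]]), length.out = 100)
    nd <- frame[rep(1L, 100), , drop = FALSE]
    nd[[tm]] <- x
    for (other in setdiff(terms, tm)) nd[[other]] <- mean(frame[[other]])
    pt <- stats::predict(fit, nd, type = "terms")
    col <- grep(paste0("s\\(", tm), colnames(pt))
    data.frame(x = x, smooth = pt[, col[1]])
  })
  names(grids) <- intersect(terms, c("suitable", "optimum", "fork_length"))
  structure(list(model = fit, terms = terms, random = random,
                 formula = deparse(fml), aic = stats::AIC(fit),
                 deviance_explained = dev_expl, edf = edf,
                 random_variances = vc, smooth_grids = grids,
                 n = nrow(frame), family = family),
            class = "oxytel_fit")
}

#' @export
print.oxytel_fit <- function(x, ...) {
  cat(sprintf("GAMM (%s, log link): %s\n  n = %d, AIC = %.1f, deviance explained = %.1f%%\n",
              x$family, x$formula, x$n, x$aic, x$deviance_explained))
  invisible(x)
}

#' Backward model selection by AIC
#'
#' Fits all admissible sub-models of the candidate term set on the stage's
#' row subset and ranks them by AIC (smaller is better; exact ties go to the
#' smaller model). The two stages mirror a two-step analysis: `full_period`
#' uses every row; `hypoxia_only` restricts to months whose hypoxic volume is
#' positive, the period when habitat compression actually occurs. Stages are
#' ranked separately and must not be cross-compared. The joint
#' suitable + optimum model is fitted only when `include_joint = TRUE`
#' because the two proportions are carved from the same water column and are
#' strongly concurved (see [concurvity_check()]).
#'
#' @param frame a [model_frame()]-style data frame.
#' @param candidates candidate smooth terms.
#' @param stage `"full_period"` or `"hypoxia_only"`.
#' @param include_joint allow models containing both `suitable` and
#'   `optimum` (default `FALSE`).
#' @param ... passed to [fit_additive_model()].
#' @return List of class `oxytel_selection`: `table` (data frame `model`,
#'   `n_terms`, `deviance_explained`, `aic`, `rank`), `fits` (named list of
#'   `oxytel_fit`s), `best` (name of the AIC-best model), `stage`, `n`.
#' @export
backward_select <- function(frame, candidates = c("suitable", "optimum",
                                                  "fork_length"),
                            stage = c("full_period", "hypoxia_only"),
                            include_joint = FALSE, ...) {
  stage <- match.arg(stage)
  if (length(candidates) == 0L) stopf("candidate term set is empty")
  if (stage == "hypoxia_only") {
    assert_cols(frame, "hypoxic_volume", "model frame")
    frame <- frame[frame$hypoxic_volume > 0, , drop = FALSE]
    if (nrow(frame) == 0L)
      stopf("hypoxia_only stage: no months with hypoxia present")
  }
  subsets <- list(character(0))
  for (tm in candidates)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, tm)))
  if (!include_joint)
    subsets <- Filter(function(s) !all(c("suitable", "optimum") %in% s), subsets)
  labels <- vapply(subsets, function(s)
    if (length(s) == 0L) "(intercept)" else paste(s, collapse = " + "), "")
  fits <- lapply(subsets, function(s) fit_additive_model(frame, terms = s, ...))
  names(fits) <- labels
  tab <- data.frame(model = labels,
                    n_terms = vapply(subsets, length, 0L),
                    deviance_explained = vapply(fits, `[[`, 0,
                                                "deviance_explained"),
                    aic = vapply(fits, `[[`, 0, "aic"))
  # AIC ascending; parsimony tie-break
  tab <- tab[order(tab$aic, tab$n_terms), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, best = tab$model[1L],
                 stage = stage, n = fits[[1L]]$n),
            class = "oxytel_selection")
}

#' @export
print.oxytel_selection <- function(x, ...) {
  cat(sprintf("model selection (%s, n = %d), best: %s\n", x$stage, x$n, x$best))
  print(x$table, digits = 4)
  invisible(x)
}

#' Pairwise concurvity of smooth predictors
#'
#' Concurvity is the additive-model analogue of collinearity: one smooth
#' term can be approximated by a smooth of another predictor. For each
#' ordered pair this projects the target term's (centred) spline basis onto
#' the span of the predictor term's basis and reports the proportion of
#' basis variance captured — an R-squared-like index in [0, 1], near 0 for
#' independent predictors and near 1 when one predictor is a smooth
#' function of the other. Indices above `warn_at` trigger a warning. A
#' single term is a no-op.
#'
#' @param frame a [model_frame()]-style data frame.
#' @param terms smooth terms to check (>= 2 for a non-trivial result).
#' @param k basis dimension (matching the model).
#' @param warn_at warning threshold (default 0.8).
#' @return Data frame `predictor` (basis used), `target` (smooth predicted),
#'   `index` in [0, 1]; empty for fewer than 2 terms.
#' @export
concurvity_check <- function(frame, terms = c("suitable", "optimum"), k = 5,
                             warn_at = 0.8) {
  if (length(terms) < 2L)
    return(data.frame(predictor = character(), target = character(),
                      index = numeric()))
  assert_cols(frame, terms, "model frame")
  frame <- frame[stats::complete.cases(frame[terms]), , drop = FALSE]
  # centred spline basis of each predictor
  bases <- lapply(terms, function(tm) {
    spec <- eval(parse(text = sprintf("mgcv::s(%s, k = %d, bs = \"cs\")", tm, k)))
    X <- mgcv::smoothCon(spec, data = frame, absorb.cons = TRUE)[[1]]$X
    scale(X, center = TRUE, scale = FALSE)
  })
  names(bases) <- terms
  out <- do.call(rbind, lapply(terms, function(p) {
    Q <- qr.Q(qr(bases[[p]]))
    do.call(rbind, lapply(setdiff(terms, p), function(tg) {
      Xt <- bases[[tg]]
      fitted <- Q %*% crossprod(Q, Xt)
      r2 <- sum(fitted^2) / sum(Xt^2)
      data.frame(predictor = p, target = tg, index = min(max(r2, 0), 1))
    }))
  }))
  rownames(out) <- NULL
  if (any(out$index > warn_at))
    warnf("concurvity above %.2f for: %s — consider dropping one term",
          warn_at,
          paste(unique(out$target[out$index > warn_at]), collapse = ", "))
  out
}
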