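## Forward stepwise DDM model search, mirroring the three-stage procedure:
## stage 1 compares the null model against the four single-free-parameter
## models; stage 2 adds a second free parameter to the stage-1 winner;
## stage 3 fits the regression models built on the two best dual models,
## with one striatal summary regressed on v and another on the second free
## parameter.  Models are ranked by DIC (lower is better); |dDIC| >= 10 is
## the conventional strong-evidence threshold.

.regressor_components <- c("d_diff", "d_minus_i", "i_diff", "i_all")

#' Enumerate the regression DDM models for a dual-parameter family
#'
#' For the `(v, p2)` family the twelve models assign one striatal summary
#' regressor to `v` and a different one to `p2`, enumerated in the
#' conventional order (models I-XII for `p2 = "a"`, XIII-XXIV for
#' `p2 = "z"`).
#'
#' @param p2 the second regressed parameter, `"a"` or `"z"`
#' @param components regressor component names
#' @return list of [ddm_model()] objects
#' @export
ddm_regression_models <- function(p2 = c("a", "z"),
                                  components = .regressor_components) {
  p2 <- match.arg(p2)
  stopifnot(length(components) == 4)
  ## (v, p2) component-index pairs in table order: for v = k, first the
  ## partners above k ascending, then those below k ascending
  pairs <- list()
  for (k in 1:4) {
    for (j in c(setdiff(k:4, k), setdiff(1:4, k:4))) {
      pairs[[length(pairs) + 1L]] <- c(k, j)
    }
  }
  numerals <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
                "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
                "XIX", "XX", "XXI", "XXII", "XXIII", "XXIV")
  offset <- if (p2 == "a") 0 else 12
  lapply(seq_along(pairs), function(i) {
    reg <- list(components[pairs[[i]][1]], components[pairs[[i]][2]])
    names(reg) <- c("v", p2)
    ddm_model(regress = reg, label = numerals[i + offset])
  })
}

#' Three-stage forward stepwise DDM model selection
#'
#' Stage 1 fits the null model and the four single-free-parameter models
#' (`a`, `tr`, `v`, `z` free by condition). Stage 2 adds one of the remaining
#' parameters to the stage-1 winner. Stage 3 fits the regression models built
#' on the two best dual models (twelve per family, 24 total when both
#' families are `(v, a)` and `(v, z)`), each regressing one trialwise
#' striatal summary on `v` and another on the second parameter. Any model
#' whose fit fails is recorded and excluded.
#'
#' @inheritParams ddm_fit
#' @param stages run stages `1:stages` (default all three)
#' @param families optional character vector restricting stage-3 families,
#'   e.g. `"a"` to fit only the twelve `(v, a)` regression models
#' @param components regressor column names used in stage 3
#' @return object of class `ddm_search`: a ranked results table plus fits
#' @export
stepwise_search <- function(data, n_samples = 2000, burn = 1200,
                            hierarchical = FALSE, seed = NULL, stages = 3,
                            families = NULL,
                            components = .regressor_components,
                            progress = FALSE) {
  stopifnot(length(unique(data$condition)) >= 2)
  seeds <- derive_seeds(seed %||% 1L, 64L)
  si <- 0L
  results <- list()
  fits <- list()
  fit_one <- function(model, stage) {
    si <<- si + 1L
    if (progress) message("fitting [stage ", stage, "] ", model$label)
    f <- tryCatch(
      ddm_fit(data, model, n_samples = n_samples, burn = burn,
              hierarchical = hierarchical, seed = seeds[si]),
      error = function(e) e)
    if (inherits(f, "error")) {
      results[[length(results) + 1L]] <<- data.frame(
        stage = stage, model = model$label, dic = NA_real_, pD = NA_real_,
        failed = TRUE, reason = conditionMessage(f), stringsAsFactors = FALSE)
      return(NULL)
    }
    fits[[model$label]] <<- f
    results[[length(results) + 1L]] <<- data.frame(
      stage = stage, model = model$label, dic = f$dic$dic, pD = f$dic$pD,
      failed = FALSE, reason = "", stringsAsFactors = FALSE)
    f
  }
  ## stage 1
  null_fit <- fit_one(ddm_model(label = "null"), 1)
  for (p in c("a", "tr", "v", "z")) fit_one(ddm_model(free = p), 1)
  tab1 <- do.call(rbind, results)
  s1 <- tab1[tab1$stage == 1 & !tab1$failed & tab1$model != "null", ]
  winner1 <- s1$model[which.min(s1$dic)]
  best_dual <- NULL
  if (stages >= 2) {
    for (p in setdiff(c("a", "tr", "v", "z"), winner1)) {
      fit_one(ddm_model(free = c(winner1, p)), 2)
    }
    tab2 <- do.call(rbind, results)
    s2 <- tab2[tab2$stage == 2 & !tab2$failed, ]
    s2 <- s2[order(s2$dic), ]
    best_dual <- head(s2$model, 2)
  }
  if (stages >= 3) {
    fams <- families %||% vapply(best_dual, function(m) {
      setdiff(strsplit(m, ",")[[1]], "v")
    }, "")
    fams <- intersect(fams, c("a", "z"))
    for (fam in fams) {
      for (m in ddm_regression_models(fam, components)) fit_one(m, 3)
    }
  }
  tab <- do.call(rbind, results)
  null_dic <- tab$dic[tab$model == "null"]
  tab$delta_dic <- tab$dic - null_dic
  tab <- tab[order(tab$failed, tab$dic), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, stage1_winner = winner1,
                 best_dual = best_dual, null_dic = null_dic),
            class = "ddm_search")
}

#' @export
print.ddm_search <- function(x, n = 12, ...) {
  cat("Stepwise DDM model search\n")
  cat("  stage-1 winner:", x$stage1_winner, "\n")
  if (!is.null(x$best_dual)) {
    cat("  best dual models:", paste(x$best_dual, collapse = ", "), "\n")
  }
  cat("  top models by DIC:\n")
  print(head(x$table[, c("stage", "model", "dic", "pD", "delta_dic")], n))
  invisible(x)
}
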