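## Lande-Arnold style selection analysis: directional, quadratic and
## correlational differentials and gradients, log-fitness-model p-values
## and case-resampling bootstrap confidence intervals.

#' Standardize traits to mean 0, sample variance 1
#'
#' `(trait - mean(trait)) / sd(trait)` with the n - 1 SD, so selection
#' coefficients are in per-trait-SD fitness units. Rows with any missing
#' trait must be removed upstream (listwise deletion).
#'
#' @param plants Data frame containing the trait columns.
#' @param traits Character vector of trait column names.
#' @return Object of class `trait_matrix`: list with `z` (matrix, one
#'   column per trait), `means`, `sds`, `plant_id`.
#' @export
standardize <- function(plants, traits = trait_names()) {
  X <- as.matrix(plants[, traits, drop = FALSE])
  if (anyNA(X)) stop_validation("missing trait values: apply listwise deletion first")
  if (nrow(X) < 3) stop_validation("need at least 3 plants to standardize")
  s <- apply(X, 2, stats::sd)
  if (any(s <= 0))
    stop_validation("zero-variance trait(s): ",
                    paste(traits[s <= 0], collapse = ", "))
  z <- sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
  structure(list(z = z, means = colMeans(X), sds = s,
                 plant_id = plants$plant_id %||% seq_len(nrow(X))),
            class = "trait_matrix")
}

## least squares with rank check; returns coefficients without intercept
.ls_coef <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1L) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    stop_validation("rank-deficient design; aliased columns: ",
                    paste(bad, collapse = ", "))
  }
  fit$coefficients[-1L]
}

## second-order design: linear, squared and pairwise cross-product columns
.design_full <- function(Z) {
  cn <- colnames(Z)
  quad <- Z^2
  colnames(quad) <- paste0("Q(", cn, ")")
  if (ncol(Z) >= 2) {
    pr <- utils::combn(ncol(Z), 2)
    cross <- Z[, pr[1, ], drop = FALSE] * Z[, pr[2, ], drop = FALSE]
    colnames(cross) <- paste0("X(", cn[pr[1, ]], ":", cn[pr[2, ]], ")")
  } else cross <- NULL
  cbind(Z, quad, cross)
}

#' Single-trait selection differentials
#'
#' For each trait j: the directional selection differential `S_j` is the
#' slope of relative fitness on the standardized trait (it captures both
#' direct and indirect selection), and the quadratic selection differential
#' `C_jj` comes from the quadratic coefficient of the one-trait
#' linear-plus-quadratic regression, by convention doubled so that it
#' estimates the curvature of the fitness surface.
#'
#' @param z A `trait_matrix` from [standardize()], or a numeric matrix of
#'   standardized traits.
#' @param w Relative fitness (untransformed; estimates always come from the
#'   untransformed fit).
#' @param double_C Double the raw quadratic coefficient (default `TRUE`;
#'   interpretive -- see the methods vignette).
#' @return Data frame: `trait`, `S`, `C_ii`.
#' @export
selection_differentials <- function(z, w, double_C = TRUE) {
  Z <- if (inherits(z, "trait_matrix")) z$z else as.matrix(z)
  res <- t(vapply(seq_len(ncol(Z)), function(j) {
    zj <- Z[, j]
    S <- .ls_coef(cbind(z = zj), w)[["z"]]
    cf <- .ls_coef(cbind(z = zj, z2 = zj^2), w)
    c(S = S, C_ii = (if (double_C) 2 else 1) * cf[["z2"]])
  }, numeric(2)))
  data.frame(trait = colnames(Z) %||% paste0("z", seq_len(ncol(Z))),
             S = res[, "S"], C_ii = res[, "C_ii"], row.names = NULL)
}

#' Multivariate selection gradients
#'
#' `beta` are partial regression coefficients of relative fitness on all
#' standardized traits jointly (direct selection, indirect selection via
#' correlated traits removed). The full second-order model adds squared and
#' cross-product terms: quadratic gradients `gamma_ii` are twice the
#' partial quadratic coefficients (stabilizing < 0, disruptive > 0) and
#' correlational gradients `gamma_ij` are the cross-product coefficients
#' (not doubled).
#'
#' @inheritParams selection_differentials
#' @param double_gamma Double raw partial quadratic coefficients (default
#'   `TRUE`, the standard convention).
#' @param quadratic Fit the full second-order model (default `TRUE`).
#'   `FALSE` returns only `beta` from the linear model, useful when
#'   bootstrapping directional gradients alone.
#' @return List: `beta` (named vector), `gamma_ii` (named vector),
#'   `gamma_ij` (data frame `trait_1`, `trait_2`, `estimate`).
#' @export
selection_gradients <- function(z, w, double_gamma = TRUE, quadratic = TRUE) {
  Z <- if (inherits(z, "trait_matrix")) z$z else as.matrix(z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  p <- ncol(Z)
  if (!quadratic) {
    if (nrow(Z) <= p + 1)
      stop_validation("n must exceed the linear model's parameter count")
    return(list(beta = .ls_coef(Z, w), gamma_ii = NULL, gamma_ij = NULL))
  }
  n_par_full <- 1 + 2 * p + choose(p, 2)
  if (nrow(Z) <= n_par_full)
    stop_validation("n = ", nrow(Z), " does not exceed the ", n_par_full,
                    " parameters of the full second-order model")
  beta <- .ls_coef(Z, w)
  full <- .ls_coef(.design_full(Z), w)
  gii <- (if (double_gamma) 2 else 1) * full[paste0("Q(", colnames(Z), ")")]
  names(gii) <- colnames(Z)
  if (p >= 2) {
    pr <- utils::combn(p, 2)
    gij <- data.frame(trait_1 = colnames(Z)[pr[1, ]],
                      trait_2 = colnames(Z)[pr[2, ]],
                      estimate = unname(full[paste0("X(", colnames(Z)[pr[1, ]],
                                                    ":", colnames(Z)[pr[2, ]], ")")]))
  } else {
    gij <- data.frame(trait_1 = character(0), trait_2 = character(0),
                      estimate = numeric(0))
  }
  list(beta = beta, gamma_ii = gii, gamma_ij = gij)
}

## t-test p-values for all non-intercept coefficients of y ~ X
.ols_pvalues <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) stop_validation("rank-deficient design in log model")
  rdf <- length(y) - fit$rank
  s2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(Xi)))
  se <- sqrt(diag(XtXinv) * s2)
  tval <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(tval), rdf)
  p[-1L]
}

#' Log-fitness-model p-values for all selection coefficients
#'
#' Refits every selection regression with response `log(w + offset)` and
#' returns partial t-test p-values. Point estimates are *not* taken from
#' these fits: the log transform improves residual behaviour for inference
#' only, while coefficients are reported from the untransformed
#' regressions. With zero-fitness plants present an offset of 0 is a domain
#' error; use a positive offset or bootstrap-only inference.
#'
#' @inheritParams selection_differentials
#' @param offset Nonnegative constant added to w before the log.
#' @return Data frame: `coefficient` (names matching
#'   [selection_coefficients()]) and `p_value`.
#' @export
pvalues_log_model <- function(z, w, offset = if (any(w == 0)) 1 else 0) {
  Z <- if (inherits(z, "trait_matrix")) z$z else as.matrix(z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  assert_scalar_number(offset, "offset", lower = 0)
  if (any(w + offset <= 0))
    stop_validation("log model undefined: some w + offset <= 0; ",
                    "use a positive offset or bootstrap-only inference")
  y <- log(w + offset)
  out <- list()
  for (j in seq_len(ncol(Z))) {
    zj <- Z[, j]; tr <- colnames(Z)[j]
    out[[paste0("S.", tr)]] <- .ols_pvalues(cbind(z = zj), y)[["z"]]
    out[[paste0("C_ii.", tr)]] <-
      .ols_pvalues(cbind(z = zj, z2 = zj^2), y)[["z2"]]
  }
  pb <- .ols_pvalues(Z, y)
  for (tr in colnames(Z)) out[[paste0("beta.", tr)]] <- pb[[tr]]
  pf <- .ols_pvalues(.design_full(Z), y)
  for (tr in colnames(Z))
    out[[paste0("gamma_ii.", tr)]] <- pf[[paste0("Q(", tr, ")")]]
  if (ncol(Z) >= 2) {
    pr <- utils::combn(ncol(Z), 2)
    for (k in seq_len(ncol(pr))) {
      t1 <- colnames(Z)[pr[1, k]]; t2 <- colnames(Z)[pr[2, k]]
      out[[paste0("gamma_ij.", t1, ":", t2)]] <-
        pf[[paste0("X(", t1, ":", t2, ")")]]
    }
  }
  data.frame(coefficient = names(out), p_value = unlist(out, use.names = FALSE))
}

#' All selection coefficients as one named vector
#'
#' Convenience estimator combining [selection_differentials()] and
#' [selection_gradients()]; the unit bootstrapped by [bootstrap_cis()].
#' Names are `S.<trait>`, `C_ii.<trait>`, `beta.<trait>`,
#' `gamma_ii.<trait>`, `gamma_ij.<t1>:<t2>`.
#'
#' @inheritParams selection_differentials
#' @inheritParams selection_gradients
#' @return Named numeric vector.
#' @export
selection_coefficients <- function(z, w, double_C = TRUE, double_gamma = TRUE) {
  Z <- if (inherits(z, "trait_matrix")) z$z else as.matrix(z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  sd_ <- selection_differentials(Z, w, double_C = double_C)
  gr <- selection_gradients(Z, w, double_gamma = double_gamma)
  out <- c(stats::setNames(sd_$S, paste0("S.", sd_$trait)),
           stats::setNames(sd_$C_ii, paste0("C_ii.", sd_$trait)),
           stats::setNames(unname(gr$beta), paste0("beta.", names(gr$beta))),
           stats::setNames(unname(gr$gamma_ii),
                           paste0("gamma_ii.", names(gr$gamma_ii))))
  if (nrow(gr$gamma_ij))
    out <- c(out, stats::setNames(gr$gamma_ij$estimate,
                                  paste0("gamma_ij.", gr$gamma_ij$trait_1,
                                         ":", gr$gamma_ij$trait_2)))
  out
}

#' Bootstrap settings
#'
#' @param B Number of case-resampling replicates (default 1000).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Integer seed.
#' @param restandardize Re-standardize traits and re-relativize fitness
#'   within each replicate (default `TRUE`), mirroring the estimation
#'   pipeline end to end.
#' @param max_retries Replicates that collapse (zero-variance trait,
#'   all-zero fitness, rank deficiency) are redrawn at most this many
#'   times each before erroring.
#' @return Object of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(B = 1000, level = 0.95, seed = 1,
                               restandardize = TRUE, max_retries = 100) {
  assert_scalar_number(B, "B", lower = 1)
  assert_scalar_number(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(max_retries, "max_retries", lower = 0)
  structure(list(B = as.integer(B), level = level, seed = as.integer(seed),
                 restandardize = isTRUE(restandardize),
                 max_retries = as.integer(max_retries)),
            class = "bootstrap_settings")
}

#' Case-resampling bootstrap percentile confidence intervals
#'
#' Resamples rows of `data` with replacement `B` times, applies `estimator`
#' to each replicate, and returns percentile intervals at the requested
#' level. The estimator sees raw resampled rows, so any within-replicate
#' re-standardization or re-relativization is its own responsibility (the
#' estimators built by [selection_report()] do both). Replicates on which
#' the estimator throws are redrawn, up to `max_retries` per replicate.
#'
#' @param data Data frame of cases (plants).
#' @param estimator Function `data -> named numeric vector`.
#' @param settings A [bootstrap_settings()].
#' @return Data frame `coefficient`, `ci_lower`, `ci_upper`, `significant`
#'   (CI excludes 0), with the B x p replicate matrix in attribute
#'   `"replicates"`.
#' @export
bootstrap_cis <- function(data, estimator, settings = bootstrap_settings()) {
  if (!inherits(settings, "bootstrap_settings"))
    stop_config("settings must come from bootstrap_settings()")
  n <- nrow(data)
  est0 <- estimator(data)
  reps <- matrix(NA_real_, settings$B, length(est0),
                 dimnames = list(NULL, names(est0)))
  with_seed(settings$seed, {
    for (b in seq_len(settings$B)) {
      for (try_ in seq_len(settings$max_retries + 1L)) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(estimator(data[idx, , drop = FALSE]),
                        error = function(e) NULL)
        if (!is.null(val)) break
        if (try_ > settings$max_retries)
          stop_validation("bootstrap replicate kept degenerating after ",
                          settings$max_retries, " redraws")
      }
      reps[b, ] <- val
    }
  })
  a <- (1 - settings$level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  out <- data.frame(coefficient = names(est0), estimate = unname(est0),
                    ci_lower = ci[, 1], ci_upper = ci[, 2])
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  attr(out, "replicates") <- reps
  out
}

#' Full pollinator-specific selection analysis
#'
#' Runs the whole analysis: seed attribution for every species under the
#' `visited` and `tripped` bases plus the all-pollinator `total` basis,
#' then, within each species x basis block, estimates all five coefficient
#' kinds (S, beta, C_ii, gamma_ii, gamma_ij) on untransformed relative
#' fitness, log-model p-values, and case-resampling bootstrap percentile
#' CIs in which fitness is re-relativized and traits re-standardized within
#' every replicate.
#'
#' @param plants Plant table: `plant_id`, trait columns, `total_seeds`.
#'   Plants missing any trait or the seed count are dropped (listwise).
#' @param visits Long visit table.
#' @param rates Named tripping rates (needed for the `tripped` basis).
#' @param settings A [bootstrap_settings()].
#' @param bases Bases to run.
#' @param traits Trait columns to analyse.
#' @param log_model `TRUE`, `FALSE`, or a character vector of
#'   species/basis labels (`"leafcutting"`-style species names or
#'   `"all"`) for which the log model is fitted; blocks without it get
#'   `NA` p-values (bootstrap-only inference, appropriate when
#'   zero-inflation leaves the transformed residuals pathological).
#' @param log_offset Offset for the log model; `NULL` (default) uses 1
#'   when a block contains zero fitness values and 0 otherwise.
#' @param double_C,double_gamma Doubling conventions, see
#'   [selection_differentials()] and [selection_gradients()].
#' @return Tidy data frame: `species`, `basis`, `coefficient_kind`,
#'   `trait_1`, `trait_2`, `estimate`, `p_log_model`, `ci_lower`,
#'   `ci_upper`, `significant`, `B`, `seed`.
#' @export
selection_report <- function(plants, visits, rates = NULL,
                             settings = bootstrap_settings(),
                             bases = c("visited", "tripped", "total"),
                             traits = trait_names(),
                             log_model = TRUE, log_offset = NULL,
                             double_C = TRUE, double_gamma = TRUE) {
  keep <- stats::complete.cases(plants[, c(traits, "total_seeds")])
  dropped <- sum(!keep)
  if (dropped) message("listwise deletion dropped ", dropped, " plant(s)")
  plants <- plants[keep, , drop = FALSE]
  ft <- fitness_table(plants, visits, rates, bases = bases)
  blocks <- unique(ft[, c("species", "basis")])
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    sp <- blocks$species[i]; b <- blocks$basis[i]
    fb <- ft[ft$species == sp & ft$basis == b, ]
    dat <- plants[match(fb$plant_id, plants$plant_id), traits, drop = FALSE]
    dat$.abs_fitness <- fb$attributed_seeds
    use_log <- isTRUE(log_model) ||
      (is.character(log_model) && sp %in% log_model)
    out[[i]] <- .selection_block(dat, traits, settings,
                                 use_log, log_offset, double_C, double_gamma)
    out[[i]]$species <- sp
    out[[i]]$basis <- b
  }
  res <- do.call(rbind, out)
  res <- res[, c("species", "basis", "coefficient_kind", "trait_1", "trait_2",
                 "estimate", "p_log_model", "ci_lower", "ci_upper",
                 "significant", "B", "seed")]
  rownames(res) <- NULL
  res
}

## one species x basis block: estimates, p-values, bootstrap CIs
.selection_block <- function(dat, traits, settings, use_log, log_offset,
                             double_C, double_gamma) {
  estimator <- function(d) {
    z <- standardize(d, traits)
    w <- relative_fitness(d$.abs_fitness)
    selection_coefficients(z, w, double_C = double_C,
                           double_gamma = double_gamma)
  }
  if (!settings$restandardize) {
    z0 <- standardize(dat, traits)
    w0 <- relative_fitness(dat$.abs_fitness)
    estimator <- local({
      zm <- z0$means; zs <- z0$sds; mw <- mean(dat$.abs_fitness)
      function(d) {
        z <- sweep(sweep(as.matrix(d[, traits]), 2, zm), 2, zs, "/")
        selection_coefficients(z, d$.abs_fitness / mw,
                               double_C = double_C, double_gamma = double_gamma)
      }
    })
  }
  ci <- bootstrap_cis(dat, estimator, settings)
  pv <- if (use_log) {
    z <- standardize(dat, traits)
    w <- relative_fitness(dat$.abs_fitness)
    off <- log_offset %||% (if (any(w == 0)) 1 else 0)
    tryCatch(pvalues_log_model(z, w, offset = off), error = function(e) NULL)
  } else NULL
  parts <- strsplit(ci$coefficient, ".", fixed = TRUE)
  kind <- vapply(parts, `[`, "", 1L)
  rest <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
  tr <- strsplit(rest, ":", fixed = TRUE)
  res <- data.frame(
    coefficient_kind = kind,
    trait_1 = vapply(tr, `[`, "", 1L),
    trait_2 = vapply(tr, function(x) if (length(x) > 1) x[2] else "", ""),
    estimate = ci$estimate,
    p_log_model = if (is.null(pv)) NA_real_ else
      pv$p_value[match(ci$coefficient, pv$coefficient)],
    ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
    significant = ci$significant,
    B = settings$B, seed = settings$seed)
  res
}
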