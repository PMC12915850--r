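#' Per-cohort association of taxa with case status
#'
#' Simplified two-mode association testing within a single cohort.
#' Abundance mode regresses `log10(abundance + pseudocount)` on the case
#' indicator (plus optional covariates) by ordinary least squares; the
#' effect is the case coefficient (mean log10 difference, case minus
#' control) with its Wald p-value. Prevalence mode fits a logistic model of
#' presence on the same design; when complete or quasi-complete separation
#' occurs, a Firth-type bias-reduced fit is substituted. Rows missing a
#' required covariate are dropped per model; a taxon that is present in
#' every sample (or absent from all) is flagged not estimable in prevalence
#' mode.
#'
#' @param ds A single-cohort [mgba_dataset()] with at least 3 cases and 3
#'   controls.
#' @param mode `"abundance"` or `"prevalence"`.
#' @param covariates Optional metadata columns (e.g. `c("age", "sex")`)
#'   adjusted for.
#' @param pseudocount Added before the log10 transform (abundance mode).
#' @param presence_threshold Abundance strictly above this counts as
#'   presence (prevalence mode).
#' @return A tibble with columns `taxon`, `cohort`, `disease`, `mode`,
#'   `effect`, `se`, `statistic`, `p`, `q` (BH within this call) and
#'   `estimable`.
#' @export
cohort_association <- function(ds, mode = c("abundance", "prevalence"),
                               covariates = character(),
                               pseudocount = 5e-5,
                               presence_threshold = 0) {
  mode <- match.arg(mode)
  study <- unique(ds$samples$study_id)
  if (length(study) != 1) {
    stop("cohort_association() expects a single cohort; ",
         "use associate_cohorts() for multi-study data", call. = FALSE)
  }
  disease <- setdiff(unique(ds$samples$disease), ds$healthy_label)
  disease <- if (length(disease) == 0) NA_character_ else disease[1]
  md <- ds$samples
  complete <- rep(TRUE, nrow(md))
  for (cv in covariates) {
    if (is.null(md[[cv]])) stop("covariate column not found: ", cv, call. = FALSE)
    complete <- complete & !is.na(md[[cv]])
  }
  md <- md[complete, , drop = FALSE]
  m <- taxon_matrix(ds)[complete, , drop = FALSE]
  y_case <- as.numeric(md$is_case)
  if (sum(y_case) < 3 || sum(1 - y_case) < 3) {
    stop("need at least 3 cases and 3 controls", call. = FALSE)
  }
  x <- stats::model.matrix(
    stats::reformulate(c("is_case", covariates)),
    data = md
  )
  case_col <- which(colnames(x) == "is_caseTRUE")

  if (mode == "abundance") {
    yy <- log10(m + pseudocount)
    qr_x <- qr(x)
    coefs <- qr.coef(qr_x, yy)
    res <- yy - x %*% coefs
    df <- nrow(x) - qr_x$rank
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qr_x))
    se <- sqrt(sigma2 * xtx_inv[case_col, case_col])
    eff <- coefs[case_col, ]
    stat <- eff / se
    p <- 2 * stats::pt(-abs(stat), df)
    estimable <- is.finite(se) & se > 0
    p[!estimable] <- NA_real_
    out <- tibble::tibble(taxon = colnames(m), effect = eff, se = se,
                          statistic = stat, p = p, estimable = estimable)
  } else {
    pres <- (m > presence_threshold) * 1
    fit_one <- function(yv) {
      if (length(unique(yv)) < 2) {
        return(c(NA, NA, NA, NA, 0))
      }
      sep <- FALSE
      fit <- withCallingHandlers(
        stats::glm.fit(x, yv, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
            sep <<- TRUE
          }
          invokeRestart("muffleWarning")
        }
      )
      co <- fit$coefficients
      if (sep || any(!is.finite(co)) || any(abs(co) > 15)) {
        fr <- firth_logit(x, yv)
        c(fr$coef[case_col], fr$se[case_col],
          fr$coef[case_col] / fr$se[case_col],
          2 * stats::pnorm(-abs(fr$coef[case_col] / fr$se[case_col])), 1)
      } else {
        w <- fit$weights
        cov_mat <- tryCatch(solve(crossprod(x, x * w)), error = function(e) NULL)
        if (is.null(cov_mat)) return(c(NA, NA, NA, NA, 0))
        se1 <- sqrt(cov_mat[case_col, case_col])
        z <- co[case_col] / se1
        c(co[case_col], se1, z, 2 * stats::pnorm(-abs(z)), 1)
      }
    }
    res <- t(apply(pres, 2, fit_one))
    out <- tibble::tibble(taxon = colnames(m), effect = res[, 1], se = res[, 2],
                          statistic = res[, 3], p = res[, 4],
                          estimable = res[, 5] == 1)
  }
  out$q <- NA_real_
  out$q[out$estimable] <- bh_adjust(out$p[out$estimable])
  dplyr::bind_cols(
    tibble::tibble(cohort = study, disease = disease, mode = mode),
    out
  )[, c("taxon", "cohort", "disease", "mode", "effect", "se", "statistic",
        "p", "q", "estimable")]
}

#' Run cohort associations across every study of a dataset
#'
#' @inheritParams cohort_association
#' @param ds A multi-study [mgba_dataset()].
#' @return Row-bound [cohort_association()] tibbles, one block per study.
#' @export
associate_cohorts <- function(ds, mode = c("abundance", "prevalence"),
                              covariates = character(),
                              pseudocount = 5e-5, presence_threshold = 0) {
  mode <- match.arg(mode)
  studies <- unique(ds$samples$study_id)
  purrr::map_dfr(studies, function(s) {
    sub <- subset_samples(ds, ds$samples$study_id == s)
    cohort_association(sub, mode, covariates, pseudocount, presence_threshold)
  })
}

## Firth-type bias-reduced logistic regression: Newton iterations on the
## hat-diagonal-adjusted score. Used as the separation fallback.
firth_logit <- function(x, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    info <- crossprod(x, x * w)
    info_inv <- solve(info)
    h <- rowSums((x %*% info_inv) * x) * w
    score <- crossprod(x, y - p + h * (0.5 - p))
    step <- drop(info_inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(x %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  se <- sqrt(diag(solve(crossprod(x, x * w))))
  list(coef = beta, se = se)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-cohort effect sizes with the moment-based DerSimonian-Laird
#' estimator: with fixed-effect weights `w_i = 1 / se_i^2`,
#' `Q = sum w_i (e_i - e_bar_w)^2` and
#' `tau2 = max(0, (Q - (k-1)) / (sum w_i - sum w_i^2 / sum w_i))`; the
#' pooled effect is the `1 / (se_i^2 + tau2)`-weighted mean with standard
#' error `(sum 1/(se_i^2 + tau2))^(-1/2)` and a two-sided normal p-value.
#'
#' @param effects Per-cohort effect sizes.
#' @param ses Their standard errors (positive, same length).
#' @return A one-row tibble with `effect`, `se`, `tau_squared`, `statistic`,
#'   `p`, `k` (number of cohorts) and `pooled` (`FALSE` for the single-
#'   cohort pass-through, which carries the lone estimate unchanged).
#' @export
random_effects_pool <- function(effects, ses) {
  stopifnot(length(effects) == length(ses), all(ses > 0))
  k <- length(effects)
  if (k == 1) {
    z <- effects / ses
    return(tibble::tibble(effect = effects, se = ses, tau_squared = 0,
                          statistic = z, p = 2 * stats::pnorm(-abs(z)),
                          k = 1L, pooled = FALSE))
  }
  w <- 1 / ses^2
  e_bar <- sum(w * effects) / sum(w)
  q_stat <- sum(w * (effects - e_bar)^2)
  tau2 <- max(0, (q_stat - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (ses^2 + tau2)
  pooled <- sum(w_star * effects) / sum(w_star)
  se_pooled <- sqrt(1 / sum(w_star))
  z <- pooled / se_pooled
  tibble::tibble(effect = pooled, se = se_pooled, tau_squared = tau2,
                 statistic = z, p = 2 * stats::pnorm(-abs(z)),
                 k = as.integer(k), pooled = TRUE)
}

#' Pool per-cohort associations across cohorts
#'
#' Groups [associate_cohorts()] output by taxon, disease and mode, pools the
#' estimable per-cohort effects with [random_effects_pool()], and adjusts
#' the pooled p-values by Benjamini-Hochberg within each (disease, mode)
#' family.
#'
#' @param assoc Long tibble from [associate_cohorts()] (possibly row-bound
#'   across diseases).
#' @return A tibble with one row per (taxon, disease, mode): pooled
#'   `effect`, `se`, `tau_squared`, `p`, `q`, `k`, `pooled` and `direction`
#'   (`"health_enriched"` for negative effects — lower in cases —
#'   `"disease_enriched"` otherwise).
#' @export
pool_associations <- function(assoc) {
  est <- dplyr::filter(assoc, .data$estimable, is.finite(.data$se),
                       .data$se > 0)
  pooled <- est |>
    dplyr::group_by(.data$taxon, .data$disease, .data$mode) |>
    dplyr::group_modify(function(df, key) {
      random_effects_pool(df$effect, df$se)
    }) |>
    dplyr::ungroup()
  pooled |>
    dplyr::group_by(.data$disease, .data$mode) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(direction = ifelse(.data$effect < 0, "health_enriched",
                                     "disease_enriched"))
}

#' Classify taxa by cross-disease direction consistency
#'
#' For each taxon, collects the diseases where its pooled association is
#' significant (`q < q_threshold`) and classifies the taxon by the sign
#' agreement of those significant effects: consistently lower in cases
#' (`"consistent_health"`), consistently higher (`"consistent_disease"`),
#' or discordant across diseases (`"context_dependent"`). Taxa significant
#' nowhere are labelled `"not_significant"`.
#'
#' @param pooled Output of [pool_associations()] (filter to one `mode`
#'   before calling if both were computed).
#' @param q_threshold FDR threshold (default 0.1).
#' @return A tibble with `taxon`, `n_significant`, `n_health`, `n_disease`,
#'   `diseases_significant` and `category`.
#' @export
classify_directions <- function(pooled, q_threshold = 0.1) {
  pooled |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_significant = sum(.data$q < q_threshold, na.rm = TRUE),
      n_health = sum(.data$q < q_threshold & .data$effect < 0, na.rm = TRUE),
      n_disease = sum(.data$q < q_threshold & .data$effect >= 0, na.rm = TRUE),
      diseases_significant = paste(
        sort(unique(.data$disease[.data$q < q_threshold & !is.na(.data$q)])),
        collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      n_significant == 0 ~ "not_significant",
      n_health > 0 & n_disease == 0 ~ "consistent_health",
      n_disease > 0 & n_health == 0 ~ "consistent_disease",
      TRUE ~ "context_dependent"
    ))
}
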