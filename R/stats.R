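#' Fit the per-descriptor mixed-effects model
#'
#' Linear mixed model for one cluster descriptor:
#' `value ~ group * eyo + sex + site + (1 | family_id)`, fit by REML. The
#' fixed effects are mutation-carrier status, EYO, their interaction, sex
#' and site; the random family intercept lets the marker be correlated
#' between family members. Age is deliberately not a covariate (it is
#' nearly collinear with EYO in onset-anchored cohorts). With fewer than
#' two families (or a failed mixed fit) the model falls back to fixed
#' effects only, with a warning.
#'
#' @param table a `ClusterFeatureTable` (see [feature_table()]).
#' @param descriptor `"amplitude"` or `"orientation"`.
#' @param cluster cluster index (1-based).
#' @return a fitted model handle (list with `fit`, `descriptor`,
#'   `cluster`, `mixed` flag).
#' @export
fit_cluster_model <- function(table,
                              descriptor = c("amplitude", "orientation"),
                              cluster) {
  descriptor <- match.arg(descriptor)
  col <- paste0(if (descriptor == "amplitude") "amp_c" else "ori_c", cluster)
  if (!col %in% names(table)) stop("no column '", col, "' in feature table")
  df <- data.frame(
    value = table[[col]],
    group = factor(table$group, levels = c("noncarrier", "carrier")),
    eyo = as.numeric(table$eyo),
    sex = factor(table$sex),
    site = factor(table$site),
    family_id = factor(table$family_id))
  if (nlevels(df$group) < 2) stop("both groups must be present")
  rhs <- "group * eyo"
  if (nlevels(df$sex) > 1) rhs <- paste(rhs, "+ sex")
  if (nlevels(df$site) > 1) rhs <- paste(rhs, "+ site")
  mixed <- nlevels(df$family_id) >= 2
  fit <- NULL
  if (mixed) {
    fit <- tryCatch(
      lme4::lmer(as.formula(paste("value ~", rhs, "+ (1 | family_id)")),
                 data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular =
                                               lme4::.makeCC("ignore",
                                                             tol = 1e-4))),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("mixed fit failed; falling back to fixed effects only")
      mixed <- FALSE
    }
  } else {
    warning("fewer than 2 families; fitting fixed effects only")
  }
  if (!mixed)
    fit <- stats::lm(as.formula(paste("value ~", rhs)), data = df)
  list(fit = fit, descriptor = descriptor, cluster = as.integer(cluster),
       mixed = mixed)
}

.fixed_coefs <- function(handle) {
  if (handle$mixed) {
    b <- lme4::fixef(handle$fit)
    C <- as.matrix(vcov(handle$fit))
  } else {
    b <- coef(handle$fit)
    C <- vcov(handle$fit)
  }
  list(b = b, C = C,
       i_grp = which(names(b) == "groupcarrier"),
       i_int = which(names(b) == "groupcarrier:eyo"))
}

.wald_quad <- function(b, C, idx) {
  bv <- b[idx]
  as.numeric(t(bv) %*% solve(C[idx, idx, drop = FALSE]) %*% bv)
}

.stat_row <- function(handle, test, chi2, df, nfam, estimate = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_) {
  p <- pchisq(chi2, df, lower.tail = FALSE)
  data.frame(descriptor = handle$descriptor, cluster = handle$cluster,
             test = test, wald_chi2 = chi2, df = df, p_raw = p,
             p_bonferroni = min(1, p * nfam), n_tests_family = nfam,
             estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             stringsAsFactors = FALSE)
}

#' Wald tests for group differences
#'
#' Two Wald chi-square tests per fitted descriptor model: T1, the joint
#' test of the carrier main effect and the carrier-by-EYO interaction
#' (df = 2, "is there any group difference"); and T2, the interaction
#' alone (df = 1, "do group differences evolve over time"). p-values are
#' Bonferroni-corrected within a family of `n_tests_family` tests
#' (default 20 = 10 clusters x 2 descriptors).
#'
#' @param handle a handle from [fit_cluster_model()].
#' @param n_tests_family Bonferroni family size (default 20).
#' @return data.frame of `StatResult` rows.
#' @export
wald_tests <- function(handle, n_tests_family = 20) {
  fc <- .fixed_coefs(handle)
  idx1 <- c(fc$i_grp, fc$i_int)
  chi1 <- .wald_quad(fc$b, fc$C, idx1)
  chi2v <- .wald_quad(fc$b, fc$C, fc$i_int)
  rbind(.stat_row(handle, "T1_group", chi1, 2L, n_tests_family),
        .stat_row(handle, "T2_group_by_time", chi2v, 1L, n_tests_family))
}

#' Wald tests of the group contrast at fixed EYO offsets
#'
#' Tests `H0: b_carrier + b_interaction * t = 0` (the model-implied group
#' contrast at EYO = t, df = 1) at each grid time, Bonferroni-corrected
#' over the grid. Also returns the contrast estimate with a
#' Bonferroni-adjusted confidence interval. The default grid runs every 5
#' years from 20 years before to 10 years after the expected onset.
#'
#' @param handle a handle from [fit_cluster_model()].
#' @param eyo_grid EYO values (default `c(-20, -15, -10, -5, 0, 5, 10)`).
#' @param conf base confidence level (default 0.95).
#' @return data.frame of `StatResult` rows (tests `at_eyo(t)`).
#' @export
wald_at_eyo <- function(handle, eyo_grid = c(-20, -15, -10, -5, 0, 5, 10),
                        conf = 0.95) {
  fc <- .fixed_coefs(handle)
  m <- length(eyo_grid)
  zc <- qnorm(1 - (1 - conf) / (2 * m))
  out <- lapply(eyo_grid, function(t) {
    L <- c(1, t)
    idx <- c(fc$i_grp, fc$i_int)
    est <- sum(L * fc$b[idx])
    v <- as.numeric(t(L) %*% fc$C[idx, idx] %*% L)
    chi <- est^2 / v
    .stat_row(handle, sprintf("at_eyo(%g)", t), chi, 1L, m,
              estimate = est, ci_low = est - zc * sqrt(v),
              ci_high = est + zc * sqrt(v))
  })
  do.call(rbind, out)
}

#' Analyse a full feature table
#'
#' Fits the mixed model and runs [wald_tests()] for every cluster and both
#' descriptors, then runs [wald_at_eyo()] for every descriptor/cluster
#' whose T1 or T2 survives the Bonferroni correction.
#'
#' @param table a `ClusterFeatureTable`.
#' @param eyo_grid grid for the time-resolved tests.
#' @param alpha significance level for the screening step (default 0.05).
#' @return list with `omnibus` (T1/T2 rows for all cluster-descriptors)
#'   and `at_eyo` (time-resolved rows for the selected ones).
#' @export
analyse_features <- function(table, eyo_grid = c(-20, -15, -10, -5, 0, 5, 10),
                             alpha = 0.05) {
  K <- sum(grepl("^amp_c", names(table)))
  nfam <- 2L * K
  omnibus <- list()
  handles <- list()
  for (desc in c("amplitude", "orientation")) {
    for (k in seq_len(K)) {
      h <- fit_cluster_model(table, desc, k)
      handles[[paste(desc, k)]] <- h
      omnibus[[paste(desc, k)]] <- wald_tests(h, nfam)
    }
  }
  omnibus <- do.call(rbind, omnibus)
  rownames(omnibus) <- NULL
  sel <- unique(omnibus[omnibus$p_bonferroni <= alpha,
                        c("descriptor", "cluster")])
  at_eyo <- NULL
  if (nrow(sel) > 0) {
    at_eyo <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i)
      wald_at_eyo(handles[[paste(sel$descriptor[i], sel$cluster[i])]],
                  eyo_grid)))
    rownames(at_eyo) <- NULL
  }
  list(omnibus = omnibus, at_eyo = at_eyo)
}

#' Earliest significant EYO grid point
#'
#' From a set of [wald_at_eyo()] rows, the smallest grid time whose
#' Bonferroni-corrected p-value is below `alpha` (NA if none).
#'
#' @param at_eyo data.frame of `at_eyo(t)` rows.
#' @param alpha significance level (default 0.05).
#' @return scalar EYO value or NA.
#' @export
earliest_significant_eyo <- function(at_eyo, alpha = 0.05) {
  if (is.null(at_eyo) || nrow(at_eyo) == 0) return(NA_real_)
  ts <- as.numeric(sub("^at_eyo\\((.*)\\)$", "\\1", at_eyo$test))
  sig <- ts[at_eyo$p_bonferroni <= alpha]
  if (length(sig) == 0) NA_real_ else min(sig)
}
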