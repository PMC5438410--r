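#' Cohort survival analysis for single and concurrent protein markers
#'
#' Follow-up runs from surgery to recurrence, death or last contact.
#' Patients who died of unknown cause (DUC) are excluded from both
#' endpoints, as are patients with unknown vital status or no follow-up.
#' The overall-survival (OS) event is death of disease (DOD); the
#' disease-free-survival (DFS) event is recurrence or death of disease
#' (status AWD or DOD), so "disease-free" is the censored state. The
#' estimators are the Kaplan-Meier product-limit curve, the k-group
#' log-rank test, and a Cox proportional-hazards model fitted by Newton
#' iteration on the Efron-tie partial likelihood with Wald intervals on
#' the log hazard-ratio scale.
#'
#' @name survival_analysis
NULL

#' Derive survival observations from subject records
#'
#' @param subjects data.frame of subject records (see
#'   [read_cohort_table()]).
#' @param endpoint `"OS"` or `"DFS"`.
#' @return data.frame with `subject_id`, `time` (months) and `event`
#'   (0/1); attribute `n_excluded` counts the DUC / unknown-status /
#'   missing-follow-up subjects dropped.
#' @export
prepare_survival <- function(subjects, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  validate_subjects(subjects)
  drop <- is.na(subjects$status) |
    subjects$status %in% c("DUC", "alive_unknown", "lost") |
    is.na(subjects$followup_months)
  kept <- subjects[!drop, , drop = FALSE]
  if (nrow(kept) == 0) stop("no eligible subjects for ", endpoint,
                            call. = FALSE)
  event <- if (endpoint == "OS") {
    as.integer(kept$status == "DOD")
  } else {
    as.integer(kept$status %in% c("AWD", "DOD"))
  }
  out <- data.frame(subject_id = kept$subject_id,
                    time = kept$followup_months,
                    event = event, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative event/censoring times.
#' @param event 0/1 event indicators (1 = event).
#' @return data.frame over distinct event times: `time`, `n_risk`,
#'   `n_event`, `survival` (the step value just after `time`); S(0) = 1
#'   and censoring reduces the risk set without a step.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("need at least one observation", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  stopifnot(length(time) == length(event))
  event <- as.integer(event)
  etimes <- sort(unique(time[event == 1]))
  n_risk <- vapply(etimes, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(etimes, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
             survival = surv)
}

#' k-group log-rank test
#'
#' Observed-minus-expected statistic over pooled event times with the
#' hypergeometric covariance, referred to chi-square on k-1 degrees of
#' freedom.
#'
#' @param time,event As in [km_curve()].
#' @param group Group labels (>= 2 non-empty groups).
#' @return A `pnet_test_result` with the chi-square statistic, `df`, the
#'   per-group `observed` and `expected` event counts, and the two-sided
#'   p-value.
#' @export
logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  event <- as.integer(event)
  group <- as.factor(droplevels(as.factor(group)))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (sum(event) == 0) stop("no events in any group: test undefined",
                            call. = FALSE)
  etimes <- sort(unique(time[event == 1]))
  ne <- length(etimes)
  # risk counts via sorted time vectors (fast for repeated simulation)
  n_at_risk <- function(tt) {
    st <- sort(tt)
    length(tt) - findInterval(etimes - 1e-9, st)
  }
  Ntot <- n_at_risk(time)
  dtot <- vapply(etimes, function(t) sum(time == t & event == 1), numeric(1))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  Ng <- matrix(0, ne, k)
  Dg <- matrix(0, ne, k)
  for (g in seq_len(k)) {
    sel <- group == levels(group)[g]
    Ng[, g] <- n_at_risk(time[sel])
    tg <- time[sel & event == 1]
    Dg[, g] <- vapply(etimes, function(t) sum(tg == t), numeric(1))
  }
  for (i in seq_len(ne)) {
    ni <- Ntot[i]; di <- dtot[i]
    p <- Ng[i, ] / ni
    E <- E + di * p
    O <- O + Dg[i, ]
    if (ni > 1) {
      mult <- di * (ni - di) / (ni - 1)
      V <- V + mult * (diag(p, k) - tcrossprod(p))
    }
  }
  idx <- seq_len(k - 1)
  oe <- (O - E)[idx]
  stat <- drop(t(oe) %*% solve(V[idx, idx, drop = FALSE], oe))
  new_test_result(
    method = "log-rank test", statistic = stat,
    p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
    df = k - 1,
    observed = stats::setNames(O, levels(group)),
    expected = stats::setNames(E, levels(group))
  )
}

# Efron-tie Cox partial log-likelihood, gradient and Hessian at beta.
# Risk-set sums come from cumulative sums over observations sorted by
# decreasing time, so one evaluation is O(n p^2) plus O(events p^2) for
# the Efron tie adjustments.
cox_loglik <- function(beta, time, event, X) {
  ord <- order(-time)
  time <- time[ord]; event <- event[ord]
  X <- X[ord, , drop = FALSE]
  n <- length(time); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  W1 <- X * w                                   # n x p
  pairs <- expand.grid(a = seq_len(p), b = seq_len(p))
  W2 <- X[, pairs$a, drop = FALSE] * X[, pairs$b, drop = FALSE] * w  # n x p^2
  S0c <- cumsum(w)
  S1c <- apply(W1, 2, cumsum)
  S2c <- apply(W2, 2, cumsum)
  if (p == 1) { S1c <- matrix(S1c, ncol = 1) }
  if (n == 1) { S1c <- matrix(S1c, nrow = 1); S2c <- matrix(S2c, nrow = 1) }

  grp_end <- cumsum(rle(time)$lengths)  # last row of each tied-time block
  grp_id <- rep(seq_along(grp_end), rle(time)$lengths)
  ll <- 0; g <- numeric(p); H <- matrix(0, p, p)
  ev <- which(event == 1)
  if (length(ev)) {
    d_by_grp <- tapply(rep(1, length(ev)), grp_id[ev], sum)
    D0g <- tapply(w[ev], grp_id[ev], sum)
    D1g <- rowsum(W1[ev, , drop = FALSE], grp_id[ev])
    D2g <- rowsum(W2[ev, , drop = FALSE], grp_id[ev])
    ll <- sum(eta[ev])
    g <- colSums(X[ev, , drop = FALSE])
    for (k in seq_along(d_by_grp)) {
      gi <- as.integer(names(d_by_grp)[k])
      iend <- grp_end[gi]
      d <- d_by_grp[k]
      S0 <- S0c[iend]; S1 <- S1c[iend, ]; S2 <- matrix(S2c[iend, ], p, p)
      D0 <- D0g[k]; D1 <- D1g[k, ]; D2 <- matrix(D2g[k, ], p, p)
      for (l in seq_len(d) - 1) {
        f <- l / d
        R0 <- S0 - f * D0
        R1 <- S1 - f * D1
        R2 <- S2 - f * D2
        ll <- ll - log(R0)
        g <- g - R1 / R0
        H <- H - (R2 / R0 - tcrossprod(R1 / R0))
      }
    }
  }
  list(loglik = as.numeric(ll), gradient = as.numeric(g), hessian = H)
}

#' Cox proportional-hazards fit (Efron ties, Newton iteration)
#'
#' Maximizes the partial likelihood by Newton-Raphson with step halving,
#' declaring convergence when the gradient max-norm falls below `tol`.
#' Monotone likelihood (complete separation) is flagged via
#' `converged = FALSE` rather than reported silently.
#'
#' @param time,event As in [km_curve()]; at least one event required.
#' @param covariates Numeric matrix or data.frame of per-subject
#'   covariates (indicator coding for factors is the caller's choice).
#' @param tol Gradient tolerance (default 1e-8).
#' @param max_iter Iteration bound (default 30).
#' @return List of class `cox_fit`: `coefficients` data.frame (per
#'   covariate: `coef`, `hr`, `ci_lower`, `ci_upper`, `p_value`, `se`),
#'   `loglik`, `loglik_null`, `converged`, `iterations`.
#' @export
cox_fit <- function(time, event, covariates, tol = 1e-8, max_iter = 30) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  event <- as.integer(event)
  stopifnot(length(time) == length(event), nrow(X) == length(time))
  if (sum(event) == 0) stop("no events: Cox model undefined", call. = FALSE)
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    stop("degenerate covariate (constant): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  beta <- numeric(p)
  f <- cox_loglik(beta, time, event, X)
  loglik_null <- f$loglik
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(-f$hessian, f$gradient), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    f_new <- cox_loglik(new_beta, time, event, X)
    halvings <- 0
    while (!is.finite(f_new$loglik) || f_new$loglik < f$loglik - 1e-12) {
      halvings <- halvings + 1
      if (halvings > 20) break
      new_beta <- (beta + new_beta) / 2
      f_new <- cox_loglik(new_beta, time, event, X)
    }
    beta <- new_beta; f <- f_new
    if (max(abs(f$gradient)) < tol) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 15) converged <- FALSE  # monotone likelihood guard
  info <- tryCatch(solve(-f$hessian), error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(info), 0))
  z <- beta / se
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(
    covariate = colnames(X) %||% paste0("x", seq_len(p)),
    coef = beta,
    hr = exp(beta),
    ci_lower = exp(beta - zq * se),
    ci_upper = exp(beta + zq * se),
    se = se,
    p_value = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, loglik = f$loglik,
                 loglik_null = loglik_null, converged = converged,
                 iterations = iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %s: HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                cf$covariate[i], cf$hr[i], cf$ci_lower[i], cf$ci_upper[i],
                cf$p_value[i]))
  }
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Subgroup filters on subject records
#'
#' @param subjects data.frame of subject records.
#' @param rule One of `stage_II_III` (stages IIa, IIb, III), `insulinoma`,
#'   `non_insulinoma`, `functional`, `nonfunctional`, `cohort_I`,
#'   `cohort_II`, `combined` (identity). Filters compose by repeated
#'   application.
#' @return The filtered data.frame.
#' @export
subgroup_filter <- function(subjects,
                            rule = c("combined", "stage_II_III",
                                     "insulinoma", "non_insulinoma",
                                     "functional", "nonfunctional",
                                     "cohort_I", "cohort_II")) {
  rule <- match.arg(rule)
  keep <- switch(
    rule,
    combined = rep(TRUE, nrow(subjects)),
    stage_II_III = subjects$stage %in% c("IIa", "IIb", "III"),
    insulinoma = subjects$subtype == "insulinoma",
    non_insulinoma = subjects$subtype == "non_insulinoma",
    functional = subjects$functional == "functional",
    nonfunctional = subjects$functional == "nonfunctional",
    cohort_I = subjects$cohort == "I",
    cohort_II = subjects$cohort == "II"
  )
  keep[is.na(keep)] <- FALSE
  subjects[keep, , drop = FALSE]
}

#' Single and concurrent marker status from IHC percentages
#'
#' @param subjects data.frame with `uchl1_percent` and `inx_percent`.
#' @return data.frame with `uchl1`, `inx` (positive/negative/`NA`) and
#'   `concurrent` (`present` iff both positive, `absent` if both observed
#'   and either negative, `NA` when either marker is missing — such
#'   patients are excluded from concurrent-status analyses).
#' @export
marker_status <- function(subjects) {
  u <- classify_ihc(subjects$uchl1_percent)
  i <- classify_ihc(subjects$inx_percent)
  concurrent <- ifelse(
    is.na(u) | is.na(i), NA_character_,
    ifelse(u == "positive" & i == "positive", "present", "absent")
  )
  data.frame(uchl1 = u, inx = i, concurrent = concurrent,
             stringsAsFactors = FALSE)
}

#' Cross-sectional association of clinicopathological features with
#' concurrent marker status
#'
#' One row per feature: counts by status, the test applied (Fisher exact
#' for 2x2, Pearson chi-square for r x c, exact Mann-Whitney for
#' continuous features) and its two-sided p. Deaths of unknown cause are
#' excluded only from the survival-status rows (death, disease-free
#' survival); every row's counts sum to the subjects eligible for that
#' row.
#'
#' @param subjects data.frame of subject records.
#' @return data.frame with `feature`, `method`, `n`, `n_present`,
#'   `n_absent`, `p_value`.
#' @export
clinicopath_report <- function(subjects) {
  ms <- marker_status(subjects)
  eligible <- !is.na(ms$concurrent)
  sub <- subjects[eligible, , drop = FALSE]
  status <- ms$concurrent[eligible]

  rows <- list()
  add <- function(feature, method, n, n_present, n_absent, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      feature = feature, method = method, n = n,
      n_present = n_present, n_absent = n_absent, p_value = p,
      stringsAsFactors = FALSE)
  }

  categorical <- function(feature, values) {
    ok <- !is.na(values) & values != "unknown"
    tab <- table(factor(values[ok]), factor(status[ok],
                                            levels = c("present", "absent")))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || any(colSums(tab) == 0)) return(invisible(NULL))
    if (nrow(tab) == 2) {
      res <- fisher_exact_2x2(contingency_2x2(tab[1, 1], tab[1, 2],
                                              tab[2, 1], tab[2, 2]))
    } else {
      res <- chi_square_rxc(unclass(tab))
    }
    add(feature, res$method, sum(tab), sum(tab[, "present"]),
        sum(tab[, "absent"]), res$p_value)
  }
  continuous <- function(feature, values) {
    ok <- !is.na(values)
    g1 <- values[ok & status == "present"]
    g2 <- values[ok & status == "absent"]
    if (!length(g1) || !length(g2)) return(invisible(NULL))
    res <- mann_whitney_exact(g1, g2)
    add(feature, res$method, length(g1) + length(g2), length(g1),
        length(g2), res$p_value)
  }

  continuous("age", sub$age)
  categorical("sex", sub$sex)
  categorical("grade", sub$grade)
  categorical("stage", sub$stage)
  categorical("metastasis", ifelse(sub$metastasis, "yes", "no"))
  categorical("location", sub$location)
  categorical("ki67", sub$ki67_class)
  continuous("size_cm", sub$size_cm)

  # survival-status rows: DUC (and unknown-status) excluded
  surv_ok <- !is.na(sub$status) &
    !sub$status %in% c("DUC", "alive_unknown", "lost")
  ss <- sub$status[surv_ok]; st <- status[surv_ok]
  death <- factor(ifelse(ss == "DOD", "dead", "alive"),
                  levels = c("dead", "alive"))
  tab <- table(death, factor(st, levels = c("present", "absent")))
  if (all(rowSums(tab) > 0)) {
    res <- fisher_exact_2x2(contingency_2x2(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]))
    add("death", res$method, sum(tab), sum(tab[, "present"]),
        sum(tab[, "absent"]), res$p_value)
  }
  dfs <- factor(ifelse(ss == "DFS", "disease_free", "disease_or_death"),
                levels = c("disease_free", "disease_or_death"))
  tab <- table(dfs, factor(st, levels = c("present", "absent")))
  if (all(rowSums(tab) > 0)) {
    res <- fisher_exact_2x2(contingency_2x2(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]))
    add("disease_free_survival", res$method, sum(tab),
        sum(tab[, "present"]), sum(tab[, "absent"]), res$p_value)
  }

  do.call(rbind, rows)
}
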