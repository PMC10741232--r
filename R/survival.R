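#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times, with the standard convention that deaths tied with
#' censorings at the same time are processed first (a censoring at t leaves
#' the risk set only after t). Greenwood standard errors are included.
#'
#' @param time numeric follow-up times in months (>= 0).
#' @param event event indicator, 1/TRUE = death, 0/FALSE = censored.
#' @return A list of class `km_curve`: `times` (distinct event times,
#'   ascending), `survival`, `at_risk`, `n_event`, `greenwood_se`, `n`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("at least one record required")
  if (any(is.na(time)) || any(is.na(event)))
    stop("missing time/event values")
  if (any(time < 0)) stop("negative survival time")
  event <- as.integer(event)
  tt <- sort(unique(time[event == 1L]))
  n <- length(time)
  if (!length(tt))
    return(structure(list(times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_event = integer(0),
                          greenwood_se = numeric(0), n = n),
                     class = "km_curve"))
  at_risk <- vapply(tt, function(t) sum(time >= t), 0L)
  d <- vapply(tt, function(t) sum(time == t & event == 1L), 0L)
  surv <- cumprod(1 - d / at_risk)
  gw <- surv * sqrt(cumsum(d / (at_risk * (at_risk - d + (d == at_risk)))))
  gw[surv == 0] <- 0
  structure(list(times = tt, survival = surv, at_risk = at_risk,
                 n_event = d, greenwood_se = gw, n = n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", x$n, " records, ", sum(x$n_event), " events\n", sep = "")
  if (length(x$times))
    print(data.frame(time = x$times, at_risk = x$at_risk, events = x$n_event,
                     survival = round(x$survival, 4)), row.names = FALSE)
  else cat("  no events: S(t) = 1 throughout\n")
  invisible(x)
}

#' Log-rank (Mantel-Cox) test
#'
#' Unweighted log-rank comparison of two or more survival groups:
#' `chi2 = sum_g (O_g - E_g)^2` weighted through the hypergeometric variance
#' of the per-time event allocation, on `groups - 1` degrees of freedom.
#'
#' @param time numeric follow-up times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group group labels (>= 2 non-empty groups; each group needs at
#'   least one record and at least one event must occur overall).
#' @return A list of class `logrank_test`: `chi2`, `df`, `p`, `observed`,
#'   `expected` (per group).
#' @export
log_rank <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) stop("log-rank test needs at least two non-empty groups")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events observed in any group")
  tt <- sort(unique(time[event == 1L]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k)
  for (t in tt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1L & time == t)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g), 0)
    d_g <- vapply(levels(group),
                  function(g) sum(at_risk & group == g & event == 1L &
                                    time == t), 0)
    e_g <- d_t * n_g / n_t
    O <- O + d_g
    E <- E + e_g
    if (n_t > 1) {
      vfac <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + vfac * (diag(n_g / n_t, k) - tcrossprod(n_g / n_t))
    }
  }
  # drop one group (sum-to-zero constraint) and invert
  idx <- seq_len(k - 1L)
  u <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chi2 <- tryCatch(drop(t(u) %*% solve(Vi, u)), error = function(e) NA_real_)
  p <- if (is.na(chi2)) NA_real_
       else stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = k - 1L, p = p, observed = O, expected = E),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.3f (df %d), p = %.4g\n", x$chi2, x$df, x$p))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 2)), row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test by genotype
#'
#' Partitions the cases of a panel by their genotype at one SNP, applies
#' administrative censoring at `censor_time` months, estimates a KM curve
#' per genotype group and, when two or more groups are populated, compares
#' them with the log-rank test. Individuals missing the genotype are
#' excluded; empty genotype groups are noted, and a single populated group
#' (a monomorphic SNP among followed cases) yields curves without a test.
#'
#' @param panel a [genotype_panel] with survival fields on cases.
#' @param snp SNP id.
#' @param censor_time administrative cap in months (default 60).
#' @return A list of class `genotype_survival`: `snp`, `curves` (named list
#'   of `km_curve` by genotype label), `test` (`logrank_test` or `NULL`),
#'   `notes`.
#' @export
survival_by_genotype <- function(panel, snp, censor_time = 60) {
  if (is.null(panel$time)) stop("panel carries no survival data")
  cases <- filter_group(panel, "case")
  keep <- !is.na(cases$time)
  g <- cases$genotypes[, match_snp(cases, snp)]
  keep <- keep & !is.na(g)
  if (!any(keep)) stop("no followed cases with a genotype at ", snp)
  time <- pmin(cases$time[keep], censor_time)
  event <- ifelse(cases$time[keep] > censor_time, 0L, cases$event[keep])
  s <- cases$snps[match_snp(cases, snp), ]
  lab <- c(paste0(s$allele_major, "/", s$allele_major),
           paste0(s$allele_major, "/", s$allele_minor),
           paste0(s$allele_minor, "/", s$allele_minor))[g[keep] + 1L]
  notes <- character(0)
  empty <- setdiff(c(paste0(s$allele_major, "/", s$allele_major),
                     paste0(s$allele_major, "/", s$allele_minor),
                     paste0(s$allele_minor, "/", s$allele_minor)),
                   unique(lab))
  if (length(empty))
    notes <- c(notes, paste0("empty genotype group(s) excluded: ",
                             paste(empty, collapse = ", ")))
  curves <- lapply(split(seq_along(time), lab), function(i)
    km_estimate(time[i], event[i]))
  test <- NULL
  if (length(curves) >= 2L && sum(event) > 0L)
    test <- log_rank(time, event, lab)
  else
    notes <- c(notes, "fewer than two populated genotype groups (or no events); no log-rank test")
  structure(list(snp = snp, curves = curves, test = test, notes = notes),
            class = "genotype_survival")
}

#' @export
print.genotype_survival <- function(x, ...) {
  cat("<genotype_survival> ", x$snp, ": groups ",
      paste(names(x$curves), collapse = ", "), "\n", sep = "")
  for (nm in names(x$curves)) {
    k <- x$curves[[nm]]
    cat(sprintf("  %s: n = %d, events = %d, S(end) = %.3f\n", nm, k$n,
                sum(k$n_event),
                if (length(k$survival)) k$survival[length(k$survival)] else 1))
  }
  if (!is.null(x$test))
    cat(sprintf("  log-rank chi2 = %.3f, p = %.4g\n", x$test$chi2, x$test$p))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
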