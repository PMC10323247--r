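#' Mann-Whitney U test
#'
#' Rank-sum test with midranks and tie correction. The p-value is computed
#' by exact enumeration of all rank assignments when the pooled sample size
#' is at most `exact_max` and there are no ties, and otherwise by the normal
#' approximation with tie-corrected variance and continuity correction.
#' Two-sided by default, matching the convention used for all reported
#' p-values in single-molecule binding comparisons.
#'
#' @param a,b numeric samples (non-empty)
#' @param alternative only `"two.sided"` is implemented
#' @param exact_max pooled-size threshold for exact enumeration
#' @return list: `U` (statistic for sample `a`), `p`, `method`
#'   ("exact" or "normal")
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided", exact_max = 16L) {
  stopifnot(length(a) > 0, length(b) > 0,
            alternative == "two.sided")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)                         # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (length(unique(pooled)) == 1)          # all identical
    return(list(U = U, p = 1, method = "degenerate"))

  if (n <= exact_max && !has_ties) {
    # exact null distribution of U by enumeration of rank assignments
    combos <- utils::combn(n, na)
    Us <- colSums(matrix(seq_len(n)[combos], nrow = na)) - na * (na + 1) / 2
    p <- 2 * min(mean(Us <= U), mean(Us >= U))
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  mu <- na * nb / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- na * nb / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(U = U, p = 1, method = "degenerate"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Median with distribution-free 95% confidence interval
#'
#' The confidence interval is the binomial order-statistic interval
#' \eqn{(x_{(l)}, x_{(n+1-l)})} with \eqn{l} the largest index such that the
#' two-sided Binomial(n, 1/2) coverage is at least `level`. For very small
#' samples (n < 8), where the order-statistic interval degenerates to the
#' range, a bootstrap percentile interval on the median is used instead.
#'
#' @param x numeric sample with at least 5 values
#' @param level confidence level (default 0.95)
#' @param n_boot bootstrap replicates for the small-sample fallback
#' @return list: `median`, `ci_low`, `ci_high`, `coverage` (attained
#'   coverage of the order-statistic interval, NA for bootstrap), `method`
#' @export
median_ci <- function(x, level = 0.95, n_boot = 2000L) {
  n <- length(x)
  stopifnot(n >= 5)
  med <- stats::median(x)
  if (length(unique(x)) == 1)
    return(list(median = med, ci_low = med, ci_high = med,
                coverage = 1, method = "degenerate"))
  alpha <- 1 - level
  if (n >= 8) {
    xs <- sort(x)
    l <- stats::qbinom(alpha / 2, n, 0.5)
    # step back until two-sided coverage >= level
    while (l >= 1 && (1 - 2 * stats::pbinom(l - 1, n, 0.5)) < level) l <- l - 1
    if (l < 1) l <- 1
    cov <- 1 - 2 * stats::pbinom(l - 1, n, 0.5)
    return(list(median = med, ci_low = xs[l], ci_high = xs[n + 1 - l],
                coverage = cov, method = "order-statistic"))
  }
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(x, n, replace = TRUE)), numeric(1))
  qs <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(median = med, ci_low = qs[1], ci_high = qs[2], coverage = NA_real_,
       method = "bootstrap")
}

#' Hierarchical bootstrap of a regression slope
#'
#' Bootstrap procedure for replicate-structured dose-response data: in each
#' of `n_boot` iterations the replicate set is resampled with replacement
#' (same size), then for every drawn replicate and every concentration one
#' data point is drawn with replacement; the pooled points are fit by
#' ordinary least squares and the slope recorded. The reported slope is the
#' median of the bootstrap distribution with its 2.5/97.5 percentile
#' interval. An alternative single-replicate reading (draw one replicate
#' per iteration, then one point per concentration from it) is available
#' via `scheme = "single_replicate"`.
#'
#' @param data data.frame with columns `replicate`, `concentration`,
#'   `response`
#' @param n_boot number of bootstrap iterations (default 1000)
#' @param seed integer seed (deterministic output)
#' @param scheme `"all_replicates"` (default) or `"single_replicate"`
#' @return object of class `bootstrap_slope`: list with `slope_median`,
#'   `ci_low`, `ci_high` (95%), `n_boot`, `seed`, `slopes` (per-iteration)
#' @export
bootstrap_slope <- function(data, n_boot = 1000L, seed = 1L,
                            scheme = c("all_replicates", "single_replicate")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("replicate", "concentration", "response") %in% names(data)))
  reps <- unique(data$replicate)
  concs <- sort(unique(data$concentration))
  if (length(concs) < 2) stop("need >= 2 concentrations")
  nr <- length(reps); nc <- length(concs)
  # point indices per (replicate, concentration) cell
  cells <- vector("list", nr * nc)
  dim(cells) <- c(nr, nc)
  ri <- match(data$replicate, reps)
  ci <- match(data$concentration, concs)
  for (k in seq_len(nrow(data)))
    cells[[ri[k], ci[k]]] <- c(cells[[ri[k], ci[k]]], k)
  x_all <- data$concentration; y_all <- data$response
  ols_slope <- function(x, y) {
    xm <- mean(x); ym <- mean(y)
    sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  }
  set.seed(seed)
  slopes <- numeric(n_boot)
  it <- 1L
  redraws <- 0L
  while (it <= n_boot) {
    drawn <- if (scheme == "single_replicate") sample.int(nr, 1L)
             else sample.int(nr, nr, replace = TRUE)
    rows <- integer(length(drawn) * nc)
    bad <- FALSE
    q <- 0L
    for (rp in drawn) {
      for (cc in seq_len(nc)) {
        idx <- cells[[rp, cc]]
        if (is.null(idx)) { bad <- TRUE; break }
        q <- q + 1L
        rows[q] <- if (length(idx) == 1L) idx else
          idx[sample.int(length(idx), 1L)]
      }
      if (bad) break
    }
    if (bad) {                               # a drawn replicate lacks a dose
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot) stop("too many redraws: missing doses")
      next
    }
    slopes[it] <- ols_slope(x_all[rows], y_all[rows])
    it <- it + 1L
  }
  qs <- stats::quantile(slopes, c(0.025, 0.975), names = FALSE)
  structure(list(slope_median = stats::median(slopes), ci_low = qs[1],
                 ci_high = qs[2], n_boot = n_boot, seed = seed,
                 scheme = scheme, n_redraws = redraws, slopes = slopes),
            class = "bootstrap_slope")
}

#' @export
print.bootstrap_slope <- function(x, ...) {
  cat(sprintf("bootstrap slope: median %.4g, 95%% c.i. [%.4g, %.4g] (n_boot = %d)\n",
              x$slope_median, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Titration curve for a binding-isotherm fit
#'
#' @param ligand_total titrated ligand totals, nM
#' @param response instrument response per point
#' @param fixed_partner_conc concentration of the fixed, labelled partner, nM
#' @return object of class `titration_curve`
#' @export
titration_curve <- function(ligand_total, response, fixed_partner_conc) {
  stopifnot(length(ligand_total) == length(response),
            all(ligand_total >= 0), fixed_partner_conc > 0)
  if (length(ligand_total) < 6)
    stop("need >= 6 titration points for a fit")
  pos <- ligand_total[ligand_total > 0]
  if (log10(max(pos) / min(pos)) < 2)
    stop("titration must span >= 2 decades of ligand concentration")
  structure(list(ligand_total = ligand_total, response = response,
                 fixed_partner_conc = fixed_partner_conc),
            class = "titration_curve")
}

# bound fraction of the fixed partner under 1:1 binding with ligand
# depletion (quadratic isotherm); A = fixed partner total, L = ligand total
quadratic_bound_fraction <- function(L, A, Kd) {
  s <- A + L + Kd
  (s - sqrt(pmax(s^2 - 4 * A * L, 0))) / (2 * A)
}

#' Fit a 1:1 binding isotherm with ligand depletion (quadratic model)
#'
#' Nonlinear least squares of `response = r_free + (r_bound - r_free) * f(L)`
#' with the depletion-corrected bound fraction
#' \deqn{f(L) = \frac{(A + L + K_d) - \sqrt{(A + L + K_d)^2 - 4AL}}{2A}}
#' where A is the fixed labelled-partner concentration. Appropriate when A
#' is comparable to the dissociation constant, as in thermophoresis
#' titrations of tight binders; in the depletion-free limit (A << Kd) it
#' reduces to the hyperbolic isotherm `f = L/(L + Kd)`.
#'
#' @param curve a [titration_curve()]
#' @param model `"quadratic"` (default) or `"hyperbolic"`
#' @param weights optional per-point weights for the fit
#' @return list: `Kd` (nM), `Kd_se`, `r_free`, `r_bound`, `residual_sd`,
#'   `converged`, `uninformative` (TRUE when the curve is saturated or Kd
#'   sits at its bound), `fit` (the nls.lm object)
#' @export
fit_kd_quadratic <- function(curve, model = c("quadratic", "hyperbolic"),
                             weights = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "titration_curve"))
  L <- curve$ligand_total; y <- curve$response
  A <- curve$fixed_partner_conc
  if (is.null(weights)) weights <- rep(1, length(y))
  fmod <- if (model == "quadratic")
    function(Kd) quadratic_bound_fraction(L, A, Kd)
  else function(Kd) L / (L + Kd)

  r_free0 <- y[which.min(L)]; r_bound0 <- y[which.max(L)]
  half <- r_free0 + 0.5 * (r_bound0 - r_free0)
  Kd0 <- L[which.min(abs(y - half))]
  if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- stats::median(L[L > 0])

  resid_fn <- function(p) sqrt(weights) *
    (y - (p[2] + (p[3] - p[2]) * fmod(p[1])))
  lo <- c(1e-6, -Inf, -Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(c(Kd = Kd0, r_free = r_free0, r_bound = r_bound0),
                       fn = resid_fn, lower = lo,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5))
    return(list(Kd = NA_real_, Kd_se = NA_real_, r_free = NA_real_,
                r_bound = NA_real_, residual_sd = NA_real_,
                converged = FALSE, uninformative = TRUE, fit = fit))
  p <- fit$par
  f <- fmod(p[1])
  # a titration is uninformative when the curve never leaves saturation,
  # when the fitted amplitude collapses, or when the response barely varies
  uninformative <- (min(f) > 0.95) || p[1] <= 2e-6 ||
    diff(range(y)) < 1e-3 * max(abs(y), 1e-300) ||
    abs(p[3] - p[2]) < 1e-3 * max(abs(y))
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[1], error = function(e) NA_real_)
  list(Kd = unname(p[1]), Kd_se = unname(se), r_free = unname(p[2]),
       r_bound = unname(p[3]),
       residual_sd = sqrt(sum(fit$fvec^2) / max(1, length(y) - 3)),
       converged = TRUE, uninformative = uninformative, fit = fit)
}
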